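# Internal helpers shared across modules.

# Stop with a classed condition so tests can assert on error class.
stop_mirdx <- function(msg, class = "mirdx_error", ...) {
  abort(msg, class = c(class, "mirdx_error"), ...)
}

# Validate an expression matrix: numeric matrix, unique dimnames.
check_expression_matrix <- function(x, arg = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_mirdx(sprintf("`%s` must be a numeric matrix (features x samples)", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_mirdx(sprintf("`%s` must have feature rownames and sample colnames", arg))
  }
  dup_f <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_f) > 0) {
    stop_mirdx(sprintf("duplicate feature id(s): %s", paste(unique(dup_f), collapse = ", ")),
               class = "mirdx_format_error")
  }
  dup_s <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_s) > 0) {
    stop_mirdx(sprintf("duplicate sample id(s): %s", paste(unique(dup_s), collapse = ", ")),
               class = "mirdx_format_error")
  }
  invisible(x)
}

# Derive a stage-specific seed from a master seed; stays inside 32-bit range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  idx <- sum(utf8ToInt(stage))
  as.integer((abs(seed) * 7919 + idx * 104729) %% 2147483647L)
}

# Classical pooled-variance two-sample t-test, vectorized over matrix rows.
# Returns list(stat, p, df, mean_diff) with mean_diff = rowMeans(x1) - rowMeans(x2).
row_t_unpaired <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2); v2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (v1 + v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  stat <- (m1 - m2) / se
  stat[se == 0 & (m1 - m2) == 0] <- 0
  p <- 2 * pt(-abs(stat), df)
  p[is.na(stat)] <- NA_real_
  list(stat = unname(stat), p = unname(p), df = df,
       mean_diff = unname(m1 - m2))
}

# One-sample t on within-pair differences (rows = features, cols = pairs).
row_t_paired <- function(d) {
  n <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  se <- s / sqrt(n)
  stat <- m / se
  stat[se == 0 & m == 0] <- 0
  p <- 2 * pt(-abs(stat), n - 1)
  p[is.na(stat)] <- NA_real_
  list(stat = unname(stat), p = unname(p), df = n - 1, mean_diff = unname(m))
}
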