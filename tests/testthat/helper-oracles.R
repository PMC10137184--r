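# Independent oracles used by the test suite. These deliberately use
# plain loops and direct formulas, not the package's vectorized paths.

# Brute-force SAM statistics and q-values by exhaustive enumeration of
# group-label assignments (unpaired) or sign flips (paired).
sam_oracle <- function(x, tumor_ids, normal_ids, design = "unpaired",
                       s0_percentile = 0.05) {
  p <- nrow(x)
  d_of <- function(xt, xn, s0) {
    vapply(seq_len(nrow(xt)), function(i) {
      n1 <- ncol(xt); n2 <- ncol(xn)
      sp2 <- (sum((xt[i, ] - mean(xt[i, ]))^2) + sum((xn[i, ] - mean(xn[i, ]))^2)) /
        (n1 + n2 - 2)
      s <- sqrt(sp2 * (1 / n1 + 1 / n2))
      (mean(xt[i, ]) - mean(xn[i, ])) / (s + s0)
    }, numeric(1))
  }
  s_vec <- function(xt, xn) {
    vapply(seq_len(nrow(xt)), function(i) {
      n1 <- ncol(xt); n2 <- ncol(xn)
      sp2 <- (sum((xt[i, ] - mean(xt[i, ]))^2) + sum((xn[i, ] - mean(xn[i, ]))^2)) /
        (n1 + n2 - 2)
      sqrt(sp2 * (1 / n1 + 1 / n2))
    }, numeric(1))
  }
  if (design == "unpaired") {
    xt <- x[, tumor_ids, drop = FALSE]; xn <- x[, normal_ids, drop = FALSE]
    n1 <- length(tumor_ids)
    all_ids <- c(tumor_ids, normal_ids)
    s0 <- unname(quantile(s_vec(xt, xn), s0_percentile, type = 7))
    d_obs <- d_of(xt, xn, s0)
    sel <- utils::combn(length(all_ids), n1)
    d_star <- matrix(NA_real_, nrow = p, ncol = ncol(sel))
    for (b in seq_len(ncol(sel))) {
      g1 <- all_ids[sel[, b]]; g2 <- setdiff(all_ids, g1)
      d_star[, b] <- d_of(x[, g1, drop = FALSE], x[, g2, drop = FALSE], s0)
    }
  } else {
    dm <- x[, tumor_ids, drop = FALSE] - x[, normal_ids, drop = FALSE]
    k <- ncol(dm)
    one_sample <- function(m2, s0) {
      vapply(seq_len(nrow(m2)), function(i) {
        se <- sd(m2[i, ]) / sqrt(k)
        mean(m2[i, ]) / (se + s0)
      }, numeric(1))
    }
    s0 <- unname(quantile(vapply(seq_len(p), function(i) sd(dm[i, ]) / sqrt(k),
                                 numeric(1)), s0_percentile, type = 7))
    d_obs <- one_sample(dm, s0)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
    d_star <- matrix(NA_real_, nrow = p, ncol = nrow(signs))
    for (b in seq_len(nrow(signs))) {
      d_star[, b] <- one_sample(sweep(dm, 2, signs[b, ], "*"), s0)
    }
  }
  q_raw <- numeric(p)
  for (i in seq_len(p)) {
    counts_b <- vapply(seq_len(ncol(d_star)),
                       function(b) sum(abs(d_star[, b]) >= abs(d_obs[i])),
                       numeric(1))
    R <- sum(abs(d_obs) >= abs(d_obs[i]))
    q_raw[i] <- min(1, median(counts_b) / R)
  }
  ord <- order(abs(d_obs), decreasing = TRUE)
  q <- numeric(p); q[ord] <- cummax(q_raw[ord])
  list(d = d_obs, q = q)
}

# Direct observed-minus-expected two-group log-rank computation
# (all-event data or with censoring encoded as events = 0).
oe_logrank_oracle <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  U <- 0; V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d <- d1 + sum(t2 == tt & e2 == 1)
    U <- U + d1 - n1 * d / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# Exhaustive best 2-partition by total within-cluster pairwise Manhattan
# distance (n <= 12 samples).
best_two_partition_oracle <- function(x) {
  n <- ncol(x)
  d <- as.matrix(dist(t(x), method = "manhattan"))
  best <- NULL; best_cost <- Inf
  for (code in 1:(2^(n - 1) - 1)) {   # sample 1 fixed in cluster 1
    member <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2)))))
    if (all(member) || !any(member)) next
    cost <- sum(d[member, member]) / 2 + sum(d[!member, !member]) / 2
    if (cost < best_cost) { best_cost <- cost; best <- member }
  }
  ifelse(best, 1L, 2L)
}

# Independent pan-call predicate over a single layer's per-drug calls.
pan_oracle <- function(calls_vec) {
  any_s <- any(calls_vec == "sensitive"); any_r <- any(calls_vec == "resistant")
  if (any_s && !any_r) "pansensitive" else if (any_r && !any_s) "panresistant" else "neither"
}

# Independent prognostic-call predicate over five evidence slots.
prognostic_oracle <- function(ev) {
  n_h <- sum(ev == "hazardous"); n_p <- sum(ev == "protective")
  if (n_h >= 2 && n_p == 0) "hazardous"
  else if (n_p >= 2 && n_h == 0) "protective"
  else "neither"
}

# Small deterministic two-class matrix builder for io/diff tests.
make_toy_matrix <- function(n_features = 5, tumor = 4, normal = 4, seed = 42,
                            shift_first = 0) {
  set.seed(seed)
  x <- matrix(rnorm(n_features * (tumor + normal), mean = 6),
              nrow = n_features,
              dimnames = list(sprintf("f%02d", seq_len(n_features)),
                              c(sprintf("T%d", seq_len(tumor)),
                                sprintf("N%d", seq_len(normal)))))
  x[1, seq_len(tumor)] <- x[1, seq_len(tumor)] + shift_first
  x
}

toy_metadata <- function(x) {
  tibble::tibble(
    sample_id = colnames(x),
    class_label = ifelse(startsWith(colnames(x), "T"), "tumor", "normal")
  )
}
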