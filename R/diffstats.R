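#' Marker-selection thresholds
#'
#' The gates applied to call a feature a diagnostic marker: fold change
#' above `fc_up` or below `fc_down` (linear scale), classical t-test
#' p-value below `alpha`, and SAM permutation q-value below `fdr`.
#' `sam_s0_percentile` is the percentile of the per-feature standard-error
#' distribution used as the SAM fudge factor s0, and `n_permutations` the
#' permutation budget (exhaustive enumeration is used when the permutation
#' space has at most 10,000 elements).
#'
#' @param fc_up,fc_down Linear fold-change gates (`0 < fc_down < 1 < fc_up`).
#' @param alpha t-test significance level.
#' @param fdr SAM q-value gate.
#' @param sam_s0_percentile Percentile in `[0, 1]` defining s0.
#' @param n_permutations Permutation budget.
#' @return A `mirdx_thresholds` list.
#' @export
marker_thresholds <- function(fc_up = 2, fc_down = 0.5, alpha = 0.05,
                              fdr = 0.05, sam_s0_percentile = 0.05,
                              n_permutations = 1000L) {
  if (!(0 < fc_down && fc_down < 1 && 1 < fc_up)) {
    stop_mirdx("require 0 < fc_down < 1 < fc_up")
  }
  if (!(alpha > 0 && alpha < 1 && fdr > 0 && fdr < 1)) {
    stop_mirdx("alpha and fdr must be in (0, 1)")
  }
  structure(list(fc_up = fc_up, fc_down = fc_down, alpha = alpha, fdr = fdr,
                 sam_s0_percentile = sam_s0_percentile,
                 n_permutations = as.integer(n_permutations)),
            class = "mirdx_thresholds")
}

# Resolve tumor/normal sample columns (and pairs for the paired design).
.resolve_groups <- function(x, metadata, design) {
  metadata <- as_tibble(metadata)
  meta <- metadata[metadata$sample_id %in% colnames(x), ]
  tumor <- meta$sample_id[meta$class_label == "tumor"]
  normal <- meta$sample_id[meta$class_label == "normal"]
  if (design == "unpaired") {
    if (length(tumor) < 2 || length(normal) < 2) {
      stop_mirdx("each group needs >= 2 samples")
    }
    return(list(tumor = tumor, normal = normal))
  }
  pr <- meta[!is.na(meta$pair_id), ]
  pairs <- split(pr, pr$pair_id)
  bad <- names(pairs)[vapply(pairs, function(d) {
    !(nrow(d) == 2 && sum(d$class_label == "tumor") == 1 &&
        sum(d$class_label == "normal") == 1)
  }, logical(1))]
  if (length(bad) > 0) {
    stop_mirdx(sprintf("incomplete pair(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(pairs) < 2) stop_mirdx("paired design needs >= 2 complete pairs")
  list(
    tumor = vapply(pairs, function(d) d$sample_id[d$class_label == "tumor"], character(1)),
    normal = vapply(pairs, function(d) d$sample_id[d$class_label == "normal"], character(1))
  )
}

#' Two-group t statistics and fold changes
#'
#' Classical pooled-variance two-sample t-test (unpaired design) or
#' one-sample t-test on within-pair tumor-minus-normal differences (paired
#' design), with two-sided p-values. The fold change is
#' `2^(mean tumor log2 - mean normal log2)`, i.e. the geometric-mean ratio.
#'
#' @param x Log2 expression matrix (features x samples).
#' @param metadata Sample metadata with `sample_id`, `class_label`, and
#'   (for the paired design) `pair_id`.
#' @param design `"unpaired"` or `"paired"`.
#' @return Tibble with `feature_id`, `mean_log2_diff`, `fold_change`,
#'   `t_stat`, `t_p`, `df`, `design`.
#' @export
#' @examples
#' x <- rbind(m1 = c(1, 2, 3, 3, 4, 5))
#' colnames(x) <- c("a", "b", "c", "d", "e", "f")
#' md <- tibble::tibble(sample_id = colnames(x),
#'                      class_label = rep(c("tumor", "normal"), each = 3))
#' two_group_stats(x, md)
two_group_stats <- function(x, metadata, design = c("unpaired", "paired")) {
  design <- match.arg(design)
  check_expression_matrix(x)
  g <- .resolve_groups(x, metadata, design)
  if (design == "unpaired") {
    tt <- row_t_unpaired(x[, g$tumor, drop = FALSE], x[, g$normal, drop = FALSE])
  } else {
    tt <- row_t_paired(x[, g$tumor, drop = FALSE] - x[, g$normal, drop = FALSE])
  }
  tibble(feature_id = rownames(x),
         mean_log2_diff = tt$mean_diff,
         fold_change = 2^tt$mean_diff,
         t_stat = tt$stat, t_p = tt$p, df = tt$df, design = design)
}

# SAM per-feature scale s: pooled SE (unpaired) or SE of pair-difference mean.
.sam_scale <- function(sums) sums

#' SAM relative-difference statistics with permutation q-values
#'
#' Computes the Tusher-style relative difference
#' `d = (mean_tumor - mean_normal) / (s + s0)` per feature, with `s` the
#' pooled standard error (unpaired) or the standard error of the mean
#' pair difference (paired design), and `s0` a fixed percentile of the
#' per-feature `s` distribution. Per-feature q-values are estimated from
#' group-label permutations (sign-flip permutations of pair differences in
#' the paired design): `q_i` is the median across permutations of the
#' number of null `|d*|` values at or above `|d_i|`, divided by the number
#' of observed `|d|` values at or above `|d_i|`, capped at 1 and made
#' non-increasing in `|d|`. Enumeration is exhaustive when the permutation
#' space has at most 10,000 elements, otherwise `n_permutations` seeded
#' draws are used.
#'
#' @inheritParams two_group_stats
#' @param thresholds A [marker_thresholds()] object (supplies
#'   `sam_s0_percentile` and `n_permutations`).
#' @param seed Integer seed for sampled permutations.
#' @return Tibble with `feature_id`, `sam_d`, `sam_s`, `sam_q`,
#'   `n_permutations_used`, `exhaustive`.
#' @export
sam_stats <- function(x, metadata, design = c("unpaired", "paired"),
                      thresholds = marker_thresholds(), seed = 1L) {
  design <- match.arg(design)
  check_expression_matrix(x)
  n_perm <- thresholds$n_permutations
  if (n_perm < 10) stop_mirdx("n_permutations must be >= 10")
  if (n_perm < 100) warn("n_permutations < 100: q-value estimates will be coarse")
  g <- .resolve_groups(x, metadata, design)

  if (design == "unpaired") {
    xt <- x[, g$tumor, drop = FALSE]; xn <- x[, g$normal, drop = FALSE]
    xx <- cbind(xt, xn)
    n1 <- ncol(xt); n2 <- ncol(xn); n <- n1 + n2
    df <- n1 + n2 - 2
    mean_diff <- rowMeans(xt) - rowMeans(xn)
    s <- sqrt((rowSums((xt - rowMeans(xt))^2) +
                 rowSums((xn - rowMeans(xn))^2)) / df * (1 / n1 + 1 / n2))
    s0 <- unname(quantile(s, thresholds$sam_s0_percentile, type = 7))
    d_obs <- mean_diff / (s + s0)

    n_space <- choose(n, n1)
    exhaustive <- n_space <= 10000
    if (exhaustive) {
      sel <- combn(n, n1)
    } else {
      set.seed(derive_seed(seed, "sam-unpaired"))
      sel <- replicate(n_perm, sample.int(n, n1))
    }
    B <- ncol(sel)
    P <- matrix(0, nrow = n, ncol = B)
    P[cbind(as.vector(sel), rep(seq_len(B), each = n1))] <- 1
    tot <- rowSums(xx); tot2 <- rowSums(xx^2)
    T1 <- xx %*% P; T1sq <- (xx^2) %*% P
    m1 <- T1 / n1; m2 <- (tot - T1) / n2
    ss1 <- T1sq - T1^2 / n1
    ss2 <- (tot2 - T1sq) - (tot - T1)^2 / n2
    sp <- sqrt((ss1 + ss2) / df * (1 / n1 + 1 / n2))
    d_star <- (m1 - m2) / (sp + s0)
  } else {
    dmat <- x[, g$tumor, drop = FALSE] - x[, g$normal, drop = FALSE]
    k <- ncol(dmat)
    m <- rowMeans(dmat)
    s <- sqrt((rowSums(dmat^2) - k * m^2) / (k - 1)) / sqrt(k)
    s0 <- unname(quantile(s, thresholds$sam_s0_percentile, type = 7))
    d_obs <- m / (s + s0)

    n_space <- 2^k
    exhaustive <- n_space <= 10000
    if (exhaustive) {
      S <- t(as.matrix(expand.grid(rep(list(c(-1, 1)), k))))
    } else {
      set.seed(derive_seed(seed, "sam-paired"))
      S <- matrix(sample(c(-1, 1), k * n_perm, replace = TRUE), nrow = k)
    }
    B <- ncol(S)
    M <- (dmat %*% S) / k
    ss_tot <- rowSums(dmat^2)   # invariant under sign flips
    sp <- sqrt(sweep(-k * M^2, 1, ss_tot, "+") / (k - 1)) / sqrt(k)
    d_star <- M / (sp + s0)
  }

  # q_i = median_b #{ |d*_b| >= |d_i| } / #{ |d| >= |d_i| }, capped, monotone
  abs_obs <- abs(d_obs)
  p_feat <- length(abs_obs)
  # count |d*| >= |d_i| with a relative tolerance so that structural ties
  # (e.g. the identity permutation) survive BLAS round-off
  thr <- abs_obs - 1e-9 * (1 + abs_obs)
  counts <- vapply(seq_len(ncol(d_star)), function(b) {
    col <- sort(abs(d_star[, b]))
    p_feat - findInterval(thr, col)
  }, numeric(p_feat))
  if (p_feat == 1) counts <- matrix(counts, nrow = 1)
  V <- apply(counts, 1, median)
  R <- vapply(abs_obs, function(t) sum(abs_obs >= t), numeric(1))
  q_raw <- pmin(1, V / R)
  ord <- order(abs_obs, decreasing = TRUE)
  q <- numeric(p_feat)
  q[ord] <- cummax(q_raw[ord])

  tibble(feature_id = rownames(x), sam_d = unname(d_obs), sam_s = unname(s),
         sam_q = q, n_permutations_used = ncol(d_star), exhaustive = exhaustive)
}

#' Combined differential-expression statistics
#'
#' Joins [two_group_stats()] and [sam_stats()] into the per-feature table
#' consumed by [select_markers()].
#'
#' @inheritParams sam_stats
#' @return Tibble with t-test, fold-change, and SAM columns per feature.
#' @export
diff_stats <- function(x, metadata, design = c("unpaired", "paired"),
                       thresholds = marker_thresholds(), seed = 1L) {
  design <- match.arg(design)
  left_join(two_group_stats(x, metadata, design),
            sam_stats(x, metadata, design, thresholds, seed),
            by = "feature_id")
}

#' Select diagnostic markers by fold-change, t-test, and SAM gates
#'
#' Retains features with fold change above `fc_up` or below `fc_down`, t-test
#' p below `alpha`, and SAM q below `fdr`. Direction is the sign of the mean
#' log2 difference (tumor minus normal).
#'
#' @param stats A [diff_stats()] tibble (needs `fold_change`, `t_p`, `sam_q`,
#'   `mean_log2_diff`). If `sam_q` is absent (e.g. a t-test-only analysis,
#'   as used for blood samples) the FDR gate is skipped.
#' @param thresholds A [marker_thresholds()] object.
#' @param provenance Label recorded for this analysis, e.g.
#'   `"unpaired_cohort"`.
#' @return A marker-set tibble: `feature_id`, `direction`, `provenance`.
#' @export
select_markers <- function(stats, thresholds = marker_thresholds(),
                           provenance = "unpaired_cohort") {
  keep <- (stats$fold_change > thresholds$fc_up |
             stats$fold_change < thresholds$fc_down) &
    !is.na(stats$t_p) & stats$t_p < thresholds$alpha
  if ("sam_q" %in% names(stats)) {
    keep <- keep & !is.na(stats$sam_q) & stats$sam_q < thresholds$fdr
  }
  out <- stats[which(keep), ]
  tibble(feature_id = out$feature_id,
         direction = ifelse(out$mean_log2_diff > 0, "up", "down"),
         provenance = provenance)
}

#' Union of two marker sets
#'
#' Set union keyed by feature id with provenance merged (comma-joined,
#' sorted). Features whose direction conflicts between the inputs are
#' excluded with a warning.
#'
#' @param a,b Marker-set tibbles from [select_markers()].
#' @return A merged marker-set tibble.
#' @export
union_marker_sets <- function(a, b) {
  all <- bind_rows(a, b)
  merged <- all %>%
    group_by(.data$feature_id) %>%
    summarise(
      n_dir = n_distinct(.data$direction),
      direction = .data$direction[1],
      provenance = paste(sort(unique(.data$provenance)), collapse = ","),
      .groups = "drop"
    )
  conflict <- merged$feature_id[merged$n_dir > 1]
  if (length(conflict) > 0) {
    warn(sprintf("excluding %d feature(s) with conflicting directions: %s",
                 length(conflict), paste(conflict, collapse = ", ")))
  }
  merged %>%
    filter(.data$n_dir == 1) %>%
    select("feature_id", "direction", "provenance") %>%
    arrange(match(.data$feature_id, all$feature_id))
}

#' Per-histology expression profile of markers versus normal
#'
#' For each marker and each tumor histology present in the cohort, runs an
#' unpaired t-test of that histology subgroup against the normal samples.
#' Subgroups with fewer than 2 samples are reported with `p = NA`;
#' histologies absent from the cohort are omitted with a warning when
#' requested via `histologies`.
#'
#' @param x Log2 expression matrix.
#' @param metadata Metadata with `sample_id`, `class_label`, `histology`.
#' @param markers Marker-set tibble (or character vector of feature ids).
#' @param histologies Histologies to profile (default: all non-normal
#'   histologies, in `NSCLC`, `SCLC`, `carcinoid` order).
#' @return Tibble: `feature_id`, `histology`, `n`, `mean_log2_diff`, `p`,
#'   `significant`.
#' @export
histology_profile <- function(x, metadata, markers,
                              histologies = c("NSCLC", "SCLC", "carcinoid")) {
  check_expression_matrix(x)
  metadata <- as_tibble(metadata)
  ids <- if (is.data.frame(markers)) markers$feature_id else markers
  missing_ids <- setdiff(ids, rownames(x))
  if (length(missing_ids) > 0) {
    warn(sprintf("dropping %d marker(s) absent from the matrix", length(missing_ids)))
    ids <- setdiff(ids, missing_ids)
  }
  normal <- metadata$sample_id[metadata$class_label == "normal"]
  normal <- intersect(normal, colnames(x))
  if (length(normal) == 0) stop_mirdx("no normal samples in cohort")
  present <- intersect(histologies, unique(metadata$histology))
  absent <- setdiff(histologies, present)
  if (length(absent) > 0) {
    warn(sprintf("histology absent from cohort, omitted: %s",
                 paste(absent, collapse = ", ")))
  }
  xn <- x[ids, normal, drop = FALSE]
  rows <- purrr::map(present, function(h) {
    smp <- intersect(metadata$sample_id[!is.na(metadata$histology) &
                                          metadata$histology == h], colnames(x))
    xh <- x[ids, smp, drop = FALSE]
    md <- rowMeans(xh) - rowMeans(xn)
    if (length(smp) >= 2) {
      p <- row_t_unpaired(xh, xn)$p
    } else {
      p <- rep(NA_real_, length(ids))
    }
    tibble(feature_id = ids, histology = h, n = length(smp),
           mean_log2_diff = unname(md), p = unname(p),
           significant = !is.na(p) & p < 0.05)
  })
  bind_rows(rows)
}

#' Summarize marker consistency across histologies
#'
#' Labels each marker by whether it is significantly over- or
#' under-expressed (p < 0.05, same direction) in every profiled histology:
#' `"consistently over-expressed"`, `"consistently under-expressed"`, or
#' `"mixed"`.
#'
#' @param profile Output of [histology_profile()].
#' @return Tibble: `feature_id`, `pattern`.
#' @export
histology_summary <- function(profile) {
  profile %>%
    group_by(.data$feature_id) %>%
    summarise(pattern = {
      up_all <- all(.data$significant & .data$mean_log2_diff > 0)
      down_all <- all(.data$significant & .data$mean_log2_diff < 0)
      if (up_all) "consistently over-expressed"
      else if (down_all) "consistently under-expressed"
      else "mixed"
    }, .groups = "drop")
}
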