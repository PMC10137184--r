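#' Two-group hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on the marker submatrix using
#' Manhattan distance and Ward's linkage applied through the Lance-Williams
#' recurrence directly on the dissimilarities (`hclust` method `"ward.D"`,
#' the variant that pairs coherently with a non-Euclidean metric), with the
#' tree cut into exactly two clusters.
#'
#' @param x Log2 expression matrix (features x samples).
#' @param markers Marker-set tibble or character vector of feature ids;
#'   `NULL` uses all features. Requested features missing from the matrix
#'   are dropped with a warning.
#' @return A `mirdx_clust` list: `assignment` (tibble `sample_id`,
#'   `cluster`), `hclust` (the merge tree), `features_used`.
#' @export
hcluster_two <- function(x, markers = NULL) {
  check_expression_matrix(x)
  if (ncol(x) < 2) stop_mirdx("need >= 2 samples to cluster")
  ids <- rownames(x)
  if (!is.null(markers)) {
    ids <- if (is.data.frame(markers)) markers$feature_id else markers
    missing_ids <- setdiff(ids, rownames(x))
    if (length(missing_ids) > 0) {
      warn(sprintf("dropping %d requested feature(s) absent from the matrix",
                   length(missing_ids)))
      ids <- setdiff(ids, missing_ids)
    }
    if (length(ids) == 0) stop_mirdx("no requested features present")
  }
  d <- stats::dist(t(x[ids, , drop = FALSE]), method = "manhattan")
  hc <- stats::hclust(d, method = "ward.D")
  cl <- stats::cutree(hc, k = 2)
  structure(list(
    assignment = tibble(sample_id = colnames(x)[match(names(cl), colnames(x))],
                        cluster = unname(cl)),
    hclust = hc,
    features_used = ids
  ), class = "mirdx_clust")
}

#' Confusion report from raw counts
#'
#' Builds the standard classification report (tumor = positive class) from
#' true/false positive/negative counts. Sensitivity is `tp / (tp + fn)`,
#' specificity `tn / (tn + fp)`, accuracy `(tp + tn) / total`; undefined
#' ratios (empty denominator) are reported as `NA`.
#'
#' @param tp,fn,tn,fp Confusion counts.
#' @return One-row tibble with counts and `sensitivity`, `specificity`,
#'   `accuracy` as fractions.
#' @export
#' @examples
#' report_from_counts(tp = 84, fn = 3, tn = 21, fp = 1)
report_from_counts <- function(tp, fn, tn, fp) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble(tp = tp, fn = fn, tn = tn, fp = fp,
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp),
         accuracy = ratio(tp + tn, tp + fn + tn + fp))
}

#' Evaluate a two-cluster assignment against true class labels
#'
#' Each cluster is labeled with the majority true class among its members
#' (ties are labeled tumor), and the induced tumor/normal prediction is
#' scored against the truth.
#'
#' @param clustering A `mirdx_clust` from [hcluster_two()] (or a tibble with
#'   `sample_id` and `cluster`).
#' @param metadata Metadata with `sample_id` and `class_label` for every
#'   clustered sample.
#' @return A one-row confusion-report tibble (see [report_from_counts()]).
#' @export
evaluate_clusters <- function(clustering, metadata) {
  assignment <- if (inherits(clustering, "mirdx_clust")) clustering$assignment else as_tibble(clustering)
  metadata <- as_tibble(metadata)
  truth <- metadata$class_label[match(assignment$sample_id, metadata$sample_id)]
  if (any(is.na(truth))) stop_mirdx("true class missing for some clustered sample(s)")
  cluster_label <- vapply(sort(unique(assignment$cluster)), function(k) {
    members <- truth[assignment$cluster == k]
    n_t <- sum(members == "tumor"); n_n <- sum(members == "normal")
    if (n_t >= n_n) "tumor" else "normal"   # tie -> tumor
  }, character(1))
  pred <- cluster_label[assignment$cluster]
  report_from_counts(
    tp = sum(pred == "tumor" & truth == "tumor"),
    fn = sum(pred == "normal" & truth == "tumor"),
    tn = sum(pred == "normal" & truth == "normal"),
    fp = sum(pred == "tumor" & truth == "normal")
  )
}
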