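#' Fit tumor and normal class centroids
#'
#' The centroid of a class is the per-feature arithmetic mean of log2
#' expression over all training samples with that true label (including any
#' samples an unsupervised clustering would misclassify).
#'
#' @param x Log2 expression matrix (features x samples).
#' @param metadata Metadata with `sample_id` and `class_label`.
#' @param markers Marker-set tibble or feature ids; `NULL` uses all features.
#' @param cohort_id Provenance label stored with the model.
#' @return A `mirdx_centroid` object.
#' @export
fit_centroids <- function(x, metadata, markers = NULL,
                          cohort_id = "training") {
  check_expression_matrix(x)
  metadata <- as_tibble(metadata)
  ids <- rownames(x)
  if (!is.null(markers)) {
    ids <- if (is.data.frame(markers)) markers$feature_id else markers
    ids <- intersect(ids, rownames(x))
    if (length(ids) == 0) stop_mirdx("no marker features present in matrix")
  }
  tumor <- intersect(metadata$sample_id[metadata$class_label == "tumor"], colnames(x))
  normal <- intersect(metadata$sample_id[metadata$class_label == "normal"], colnames(x))
  if (length(tumor) == 0 || length(normal) == 0) {
    stop_mirdx("both tumor and normal samples are required to fit centroids")
  }
  structure(list(
    feature_ids = ids,
    tumor_centroid = rowMeans(x[ids, tumor, drop = FALSE]),
    normal_centroid = rowMeans(x[ids, normal, drop = FALSE]),
    n_tumor = length(tumor), n_normal = length(normal),
    training_provenance = cohort_id
  ), class = "mirdx_centroid")
}

#' Classify samples by nearest centroid
#'
#' Computes Pearson correlations between each sample profile and the tumor
#' and normal centroids over the intersected feature set, and predicts tumor
#' when the tumor-centroid correlation is the greater (ties predict tumor
#' with a flag; a screening rule that favors sensitivity). Profiles with
#' zero variance over the shared features get `predicted = NA` with a
#' diagnostic flag. At least three shared features are required.
#'
#' @param x Log2 expression matrix of samples to classify.
#' @param model A `mirdx_centroid` from [fit_centroids()].
#' @return Tibble: `sample_id`, `r_tumor`, `r_normal`, `predicted`,
#'   `n_features_used`, `flag`.
#' @export
classify_cohort <- function(x, model) {
  check_expression_matrix(x)
  shared <- intersect(model$feature_ids, rownames(x))
  if (length(shared) < 3) {
    stop_mirdx(sprintf("only %d feature(s) shared with the model; need >= 3",
                       length(shared)))
  }
  ct <- model$tumor_centroid[shared]
  cn <- model$normal_centroid[shared]
  xs <- x[shared, , drop = FALSE]
  out <- purrr::map(seq_len(ncol(xs)), function(j) {
    v <- xs[, j]
    if (sd(v) == 0) {
      return(tibble(sample_id = colnames(xs)[j], r_tumor = NA_real_,
                    r_normal = NA_real_, predicted = NA_character_,
                    n_features_used = length(shared), flag = "zero_variance_profile"))
    }
    rt <- cor(v, ct); rn <- cor(v, cn)
    tibble(sample_id = colnames(xs)[j], r_tumor = rt, r_normal = rn,
           predicted = if (rt >= rn) "tumor" else "normal",
           n_features_used = length(shared),
           flag = if (rt == rn) "tie_predicted_tumor" else NA_character_)
  })
  bind_rows(out)
}

#' Evaluate nearest-centroid predictions against true labels
#'
#' @param predictions Tibble from [classify_cohort()].
#' @param metadata Metadata with `sample_id` and `class_label`.
#' @return A one-row confusion-report tibble (tumor = positive class).
#' @export
evaluate_predictions <- function(predictions, metadata) {
  predictions <- as_tibble(predictions)
  if (nrow(predictions) == 0) stop_mirdx("empty prediction set")
  metadata <- as_tibble(metadata)
  truth <- metadata$class_label[match(predictions$sample_id, metadata$sample_id)]
  if (any(is.na(truth))) stop_mirdx("true class missing for some predicted sample(s)")
  pred <- predictions$predicted
  report_from_counts(
    tp = sum(pred == "tumor" & truth == "tumor", na.rm = TRUE),
    fn = sum(pred == "normal" & truth == "tumor", na.rm = TRUE),
    tn = sum(pred == "normal" & truth == "normal", na.rm = TRUE),
    fp = sum(pred == "tumor" & truth == "normal", na.rm = TRUE)
  )
}

#' @method tidy mirdx_centroid
#' @export
tidy.mirdx_centroid <- function(x, ...) {
  tibble(feature_id = x$feature_ids,
         tumor_centroid = unname(x$tumor_centroid),
         normal_centroid = unname(x$normal_centroid))
}

#' @method glance mirdx_centroid
#' @export
glance.mirdx_centroid <- function(x, ...) {
  tibble(n_features = length(x$feature_ids), n_tumor = x$n_tumor,
         n_normal = x$n_normal, training_provenance = x$training_provenance)
}

#' @export
print.mirdx_centroid <- function(x, ...) {
  cat(sprintf("<mirdx_centroid> %d features; trained on %d tumor / %d normal (%s)\n",
              length(x$feature_ids), x$n_tumor, x$n_normal, x$training_provenance))
  invisible(x)
}
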