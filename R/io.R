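#' Read a log2 expression matrix from TSV/CSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' Missing cells (`NA` or empty) are kept as missing, never coerced to zero.
#'
#' @param path File path.
#' @param layer Molecular layer label: `"miRNA"`, `"mRNA"`, or `"protein"`.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return A numeric matrix (features x samples) with a `layer` attribute.
#' @export
read_expression <- function(path, layer = c("miRNA", "mRNA", "protein"),
                            sep = "\t") {
  layer <- match.arg(layer)
  lines <- readLines(path)
  if (length(lines) < 1) stop_mirdx("empty expression file", class = "mirdx_format_error")
  fields <- strsplit(lines, sep, fixed = TRUE)
  ncol_expect <- length(fields[[1]])
  ragged <- which(vapply(fields, length, integer(1)) != ncol_expect)
  if (length(ragged) > 0) {
    stop_mirdx(sprintf("ragged row at line %d (expected %d fields)",
                       ragged[1], ncol_expect), class = "mirdx_format_error")
  }
  sample_ids <- fields[[1]][-1]
  body <- fields[-1]
  feature_ids <- vapply(body, `[[`, character(1), 1)
  vals <- vapply(body, function(f) {
    suppressWarnings(as.numeric(ifelse(f[-1] %in% c("NA", ""), NA, f[-1])))
  }, numeric(ncol_expect - 1))
  x <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = ncol_expect - 1)
  dimnames(x) <- list(feature_ids, sample_ids)
  check_expression_matrix(x)
  bad <- x[!is.na(x) & !is.finite(x)]
  if (length(bad) > 0) stop_mirdx("non-finite values in expression matrix",
                                  class = "mirdx_format_error")
  attr(x, "layer") <- layer
  x
}

#' Write an expression matrix as TSV/CSV
#'
#' @param x Numeric matrix (features x samples) with dimnames.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, sep = "\t") {
  check_expression_matrix(x)
  header <- paste(c("feature_id", colnames(x)), collapse = sep)
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

.metadata_cols <- c("sample_id", "class_label", "pair_id", "histology",
                    "stage", "radiotherapy", "time_months", "event")
.histology_levels <- c("NSCLC", "SCLC", "carcinoid", "normal")

#' Read and validate sample metadata
#'
#' Recognized columns: `sample_id`, `class_label` (tumor/normal), `pair_id`,
#' `histology` (NSCLC/SCLC/carcinoid/normal), `stage` (I-IV), `radiotherapy`
#' (logical), `time_months` (>= 0), `event` (logical). Extra columns are
#' dropped with a warning; enums are validated; each `pair_id` must occur on
#' exactly one tumor and one normal sample; `event` requires `time_months`.
#'
#' @param path TSV file path.
#' @return A tibble of validated metadata.
#' @export
read_metadata <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param df A data frame of metadata to validate in place of a file.
#' @export
validate_metadata <- function(df) {
  df <- as_tibble(df)
  if (!"sample_id" %in% names(df)) stop_mirdx("metadata requires a sample_id column")
  extra <- setdiff(names(df), .metadata_cols)
  if (length(extra) > 0) {
    warn(sprintf("ignoring unrecognized metadata column(s): %s",
                 paste(extra, collapse = ", ")))
    df <- df[intersect(names(df), .metadata_cols)]
  }
  if (anyDuplicated(df$sample_id)) stop_mirdx("duplicate sample_id in metadata")
  if ("class_label" %in% names(df)) {
    bad <- setdiff(unique(df$class_label[!is.na(df$class_label)]), c("tumor", "normal"))
    if (length(bad) > 0) {
      stop_mirdx(sprintf("invalid class_label '%s'; accepted: tumor, normal", bad[1]))
    }
  }
  if ("histology" %in% names(df)) {
    bad <- setdiff(unique(df$histology[!is.na(df$histology)]), .histology_levels)
    if (length(bad) > 0) {
      stop_mirdx(sprintf("invalid histology '%s'; accepted: %s", bad[1],
                         paste(.histology_levels, collapse = ", ")))
    }
  }
  if ("stage" %in% names(df)) {
    bad <- setdiff(unique(as.character(df$stage[!is.na(df$stage)])),
                   c("I", "II", "III", "IV"))
    if (length(bad) > 0) {
      stop_mirdx(sprintf("invalid stage '%s'; accepted: I, II, III, IV", bad[1]))
    }
  }
  if ("pair_id" %in% names(df) && "class_label" %in% names(df)) {
    pr <- df[!is.na(df$pair_id), c("pair_id", "class_label")]
    if (nrow(pr) > 0) {
      tab <- table(pr$pair_id, pr$class_label)
      ok <- all(dim(tab) == c(nrow(tab), 2)) && "tumor" %in% colnames(tab) &&
        "normal" %in% colnames(tab) && all(tab[, "tumor"] == 1) && all(tab[, "normal"] == 1)
      if (!ok || any(rowSums(tab) != 2)) {
        stop_mirdx("each pair_id must occur on exactly one tumor and one normal sample")
      }
    }
  }
  if ("event" %in% names(df)) {
    has_event <- !is.na(df$event) & df$event
    if (!"time_months" %in% names(df) || any(has_event & is.na(df$time_months))) {
      stop_mirdx("event = TRUE requires time_months")
    }
  }
  if ("time_months" %in% names(df) &&
      any(!is.na(df$time_months) & df$time_months < 0)) {
    stop_mirdx("time_months must be >= 0")
  }
  df
}

#' Write up/down gene lists as plain-text GRP files
#'
#' Writes one gene symbol per line, no header, first-occurrence order with
#' duplicates removed. One file per list, named `<label>_up.grp` and
#' `<label>_down.grp`.
#'
#' @param lists A `mirdx_signature` (see [signature_lists()]) or a named list
#'   with `label`, `up`, `down` character vectors.
#' @param dir Output directory (created if needed).
#' @return Tibble of written files with their line counts, invisibly.
#' @export
write_gene_lists <- function(lists, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- purrr::map(c(up = "up", down = "down"), function(side) {
    genes <- unique(lists[[side]])
    path <- file.path(dir, sprintf("%s_%s.grp", lists$label, side))
    if (length(genes) == 0) {
      warn(sprintf("empty %s-list for '%s'; writing 0-line file", side, lists$label))
      writeLines(character(0), path)
    } else {
      writeLines(genes, path)
    }
    tibble(list = lists$label, side = side, path = path, n = length(genes))
  })
  invisible(bind_rows(out))
}
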