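#' Normalize a dependency screen against anchor genes
#'
#' Per cell line, applies the unique affine map that sends the median raw
#' effect of the essential anchor genes to -1 and the median of the
#' non-essential anchors to 0:
#' `f(x) = (x - m_non) / (m_non - m_ess)`. The anchor medians hold exactly
#' after normalization (medians are affine-equivariant).
#'
#' @param screen A `mirdx_depscreen` (from [gen_dependency_screen()]) or a
#'   list with `raw` (gene x line matrix), `essential_ids`,
#'   `nonessential_ids`, and optionally `assay`.
#' @return The screen with a `normalized` matrix added.
#' @export
normalize_dependency <- function(screen) {
  raw <- screen$raw
  check_expression_matrix(raw, arg = "screen$raw")
  ess <- intersect(screen$essential_ids, rownames(raw))
  non <- intersect(screen$nonessential_ids, rownames(raw))
  if (length(ess) == 0 || length(non) == 0) {
    stop_mirdx("both anchor sets must be non-empty and present in the matrix")
  }
  if (length(intersect(ess, non)) > 0) stop_mirdx("anchor sets overlap")
  m_ess <- apply(raw[ess, , drop = FALSE], 2, median)
  m_non <- apply(raw[non, , drop = FALSE], 2, median)
  degenerate <- which(m_ess == m_non)
  if (length(degenerate) > 0) {
    stop_mirdx(sprintf("anchor medians coincide in line(s): %s",
                       paste(colnames(raw)[degenerate], collapse = ", ")))
  }
  normalized <- sweep(sweep(raw, 2, m_non, "-"), 2, m_non - m_ess, "/")
  screen$normalized <- normalized
  screen
}

#' Proliferation profile from normalized CRISPR and RNAi screens
#'
#' Per gene and assay, the fraction of cell lines with normalized
#' dependency score strictly below `threshold` (default -0.5; a score of
#' exactly -0.5 is not significant). Classes: `both_major` (fraction > 0.5
#' in both assays), `either_major` (> 0.5 in at least one), `
#' none_significant` (no affected line in either assay), else `other`.
#' Genes present in only one screen are classified on the available assay
#' and flagged.
#'
#' @param crispr,rnai Normalized screens (from [normalize_dependency()]);
#'   `rnai` may be `NULL` for a single-assay profile.
#' @param genes Gene ids to profile; default: all non-anchor genes present
#'   in either screen.
#' @param threshold Significance threshold on the normalized score.
#' @return Tibble: `gene_id`, `frac_crispr`, `frac_rnai`, `class`, `flag`.
#' @export
proliferation_profile <- function(crispr, rnai = NULL, genes = NULL,
                                  threshold = -0.5) {
  frac_affected <- function(screen, gene) {
    if (is.null(screen) || !gene %in% rownames(screen$normalized)) return(NA_real_)
    mean(screen$normalized[gene, ] < threshold)
  }
  if (is.null(genes)) {
    pool <- function(s) if (is.null(s)) character(0) else
      setdiff(rownames(s$normalized), c(s$essential_ids, s$nonessential_ids))
    genes <- union(pool(crispr), pool(rnai))
  }
  rows <- purrr::map(genes, function(g) {
    fc <- frac_affected(crispr, g)
    fr <- frac_affected(rnai, g)
    fracs <- c(fc, fr)
    avail <- fracs[!is.na(fracs)]
    cls <- if (length(avail) == 0) NA_character_
    else if (length(avail) == 2 && all(avail > 0.5)) "both_major"
    else if (any(avail > 0.5)) "either_major"
    else if (all(avail == 0)) "none_significant"
    else "other"
    tibble(gene_id = g, frac_crispr = fc, frac_rnai = fr, class = cls,
           flag = if (anyNA(fracs)) "single_assay" else NA_character_)
  })
  bind_rows(rows)
}
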