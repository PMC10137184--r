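#' Construct an up/down signature list pair
#'
#' @param label List label (used in output file names).
#' @param up,down Ordered gene-id vectors; duplicates are removed keeping
#'   first occurrence; `up` and `down` must be disjoint.
#' @return A `mirdx_signature` list.
#' @export
signature_lists <- function(label, up = character(), down = character()) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  clash <- intersect(up, down)
  if (length(clash) > 0) {
    stop_mirdx(sprintf("gene(s) in both up and down lists: %s",
                       paste(clash, collapse = ", ")))
  }
  structure(list(label = label, up = up, down = down),
            class = "mirdx_signature")
}

#' Build the two connectivity-query signature lists
#'
#' Combines per-gene prognostic calls with proliferation profiles into two
#' up/down signature list pairs for connectivity queries:
#' \describe{
#'   \item{list 1 up}{protective genes with affected-line fraction < 0.5 in
#'     both screening assays}
#'   \item{list 1 down}{hazardous genes affected in > 50% of lines in both
#'     assays (`both_major`)}
#'   \item{list 2 up}{protective genes with no affected line in either
#'     assay (`none_significant`)}
#'   \item{list 2 down}{hazardous genes affected in > 50% of lines in at
#'     least one assay (`either_major` or `both_major`)}
#' }
#' Genes with a `neither` prognostic call never enter any list. Ordering is
#' the input row order of `prognostic`.
#'
#' @param prognostic Tibble with `gene_id` and `category`
#'   (`hazardous`/`protective`/`neither`), e.g. rows of
#'   [prognostic_gene_call()].
#' @param proliferation Tibble from [proliferation_profile()].
#' @return A list of two `mirdx_signature` objects (`list1`, `list2`).
#' @export
build_cmap_lists <- function(prognostic, proliferation) {
  joined <- left_join(as_tibble(prognostic), as_tibble(proliferation),
                      by = "gene_id")
  prot <- joined %>% filter(.data$category == "protective")
  haz <- joined %>% filter(.data$category == "hazardous")
  below_half_both <- function(d) {
    !is.na(d$class) &
      (!is.na(d$frac_crispr) & d$frac_crispr < 0.5) &
      (!is.na(d$frac_rnai) & d$frac_rnai < 0.5)
  }
  l1 <- signature_lists(
    "list1",
    up = prot$gene_id[below_half_both(prot)],
    down = haz$gene_id[!is.na(haz$class) & haz$class == "both_major"]
  )
  l2 <- signature_lists(
    "list2",
    up = prot$gene_id[!is.na(prot$class) & prot$class == "none_significant"],
    down = haz$gene_id[!is.na(haz$class) &
                         haz$class %in% c("both_major", "either_major")]
  )
  if (length(l1$up) == 0 || length(l1$down) == 0 ||
      length(l2$up) == 0 || length(l2$down) == 0) {
    warn("one or more signature lists are empty")
  }
  list(list1 = l1, list2 = l2)
}

#' Filter connectivity-query results
#'
#' Retains compounds with connectivity score strictly above `score_min` and
#' p-value at or below `p_max`.
#'
#' @param records Tibble with `compound`, `score`, `p` (additional columns
#'   pass through).
#' @param score_min Score threshold (strict `>`; default 0.9).
#' @param p_max p-value threshold (inclusive `<=`; default 0.05).
#' @return The retained rows.
#' @export
filter_connectivity <- function(records, score_min = 0.9, p_max = 0.05) {
  records <- as_tibble(records)
  records %>% filter(.data$score > score_min, .data$p <= p_max)
}
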