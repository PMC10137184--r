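#' Categorize cell lines as drug-sensitive, resistant, or excluded
#'
#' Default `"tertile"` method: within each (drug, source, measure) stratum,
#' lines are ordered by response value (lower = more sensitive for IC50-type
#' measures) and split by position: the lowest `floor(n/3)` are sensitive,
#' the highest `floor(n/3)` resistant, the middle excluded. Ties are broken
#' deterministically by cell-line id; a stratum with all-identical values
#' carries no ordering information and is wholly excluded, as is any
#' stratum with fewer than 6 lines (with a warning). The `"threshold"`
#' method instead compares values to fixed bounds.
#'
#' @param panel Long tibble with columns `cell_line`, `drug`, `measure`,
#'   `value`, `source`.
#' @param method `"tertile"` (default) or `"threshold"`.
#' @param sensitive_max,resistant_min Fixed bounds for the threshold method.
#' @return The panel with a `category` column
#'   (`sensitive`/`resistant`/`excluded`).
#' @export
categorize_lines <- function(panel, method = c("tertile", "threshold"),
                             sensitive_max = -1, resistant_min = 1) {
  method <- match.arg(method)
  panel <- as_tibble(panel)
  need <- c("cell_line", "drug", "measure", "value", "source")
  if (!all(need %in% names(panel))) {
    stop_mirdx(sprintf("panel requires columns: %s", paste(need, collapse = ", ")))
  }
  if (method == "tertile") {
    small <- panel %>% count(.data$drug, .data$source, .data$measure) %>%
      filter(n < 6)
    if (nrow(small) > 0) {
      warn(sprintf("%d drug stratum/strata with < 6 lines: all lines excluded",
                   nrow(small)))
    }
  }
  panel %>%
    group_by(.data$drug, .data$source, .data$measure) %>%
    mutate(category = {
      nn <- n()
      if (method == "threshold") {
        ifelse(.data$value <= sensitive_max, "sensitive",
               ifelse(.data$value >= resistant_min, "resistant", "excluded"))
      } else if (nn < 6 || n_distinct(.data$value) == 1) {
        rep("excluded", nn)
      } else {
        k <- floor(nn / 3)
        pos <- order(order(.data$value, .data$cell_line))  # 1..nn by (value, id)
        ifelse(pos <= k, "sensitive", ifelse(pos > nn - k, "resistant", "excluded"))
      }
    }) %>%
    ungroup()
}

#' Per-feature drug association calls
#'
#' For one drug, compares each feature's expression between sensitive and
#' resistant cell lines with a two-sample t-test: significantly higher
#' expression in sensitive lines yields a `sensitive` call, in resistant
#' lines a `resistant` call, otherwise `neutral`. When the categorized
#' panel holds several (measure, source) strata for the drug, each stratum
#' is evaluated separately and the per-drug call is `sensitive`
#' (`resistant`) if any stratum yields it and none yields the opposite;
#' opposite calls across strata veto to `neutral` with a flag.
#'
#' @param expr Expression matrix (features x cell lines) for one layer.
#' @param categorized_panel Output of [categorize_lines()].
#' @param drug Drug name to evaluate.
#' @param layer Layer label recorded in the output.
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `id`, `drug`, `layer`, `call`, `p`, `flag`.
#' @export
gene_drug_call <- function(expr, categorized_panel, drug, layer = "mRNA",
                           alpha = 0.05) {
  check_expression_matrix(expr)
  pan <- categorized_panel %>% filter(.data$drug == !!drug)
  if (nrow(pan) == 0) stop_mirdx(sprintf("drug '%s' not in panel", drug))
  strata <- pan %>% distinct(.data$source, .data$measure)
  per_stratum <- purrr::map(seq_len(nrow(strata)), function(i) {
    ps <- pan %>% filter(.data$source == strata$source[i],
                         .data$measure == strata$measure[i])
    sens <- intersect(ps$cell_line[ps$category == "sensitive"], colnames(expr))
    res <- intersect(ps$cell_line[ps$category == "resistant"], colnames(expr))
    if (length(sens) < 2 || length(res) < 2) {
      return(tibble(id = rownames(expr), call = "neutral", p = NA_real_,
                    flag = "insufficient_lines"))
    }
    tt <- row_t_unpaired(expr[, sens, drop = FALSE], expr[, res, drop = FALSE])
    tibble(id = rownames(expr),
           call = ifelse(is.na(tt$p) | tt$p >= alpha, "neutral",
                         ifelse(tt$mean_diff > 0, "sensitive", "resistant")),
           p = tt$p, flag = NA_character_)
  })
  bind_rows(per_stratum) %>%
    group_by(.data$id) %>%
    summarise(
      any_s = any(.data$call == "sensitive"),
      any_r = any(.data$call == "resistant"),
      all_insufficient = all(!is.na(.data$flag) &
                               .data$flag == "insufficient_lines"),
      p = if (all(is.na(.data$p))) NA_real_ else min(.data$p, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      call = case_when(.data$any_s & .data$any_r ~ "neutral",
                       .data$any_s ~ "sensitive",
                       .data$any_r ~ "resistant",
                       TRUE ~ "neutral"),
      flag = case_when(.data$any_s & .data$any_r ~ "conflicting_strata",
                       .data$all_insufficient ~ "insufficient_lines",
                       TRUE ~ NA_character_),
      drug = !!drug, layer = !!layer
    ) %>%
    select("id", "drug", "layer", "call", "p", "flag") %>%
    arrange(match(.data$id, rownames(expr)))
}

#' Pansensitive / panresistant call across a drug panel
#'
#' Within each required layer, an id is pansensitive when it has no
#' resistant call for any drug and at least one sensitive call, and
#' panresistant in the mirror case. The overall call is made only when all
#' required layers agree (genes: mRNA and protein; miRNAs: the miRNA layer
#' alone); discordant or missing layers give `neither` with a flag.
#'
#' @param calls Tibble of per-drug calls (`id`, `drug`, `layer`, `call`)
#'   from [gene_drug_call()], covering the drug panel.
#' @param layers_required Character vector of layers that must concur.
#' @param n_drugs_expected If not `NULL`, ids evaluated on fewer drugs are
#'   flagged.
#' @return Tibble: `id`, `call`
#'   (`pansensitive`/`panresistant`/`neither`), `n_drugs_evaluated`,
#'   `layers_concordant`, `flag`.
#' @export
pan_call <- function(calls, layers_required = c("mRNA", "protein"),
                     n_drugs_expected = NULL) {
  calls <- as_tibble(calls)
  per_layer <- calls %>%
    filter(.data$layer %in% layers_required) %>%
    group_by(.data$id, .data$layer) %>%
    summarise(
      n_drugs = n_distinct(.data$drug),
      any_s = any(.data$call == "sensitive"),
      any_r = any(.data$call == "resistant"),
      .groups = "drop"
    ) %>%
    mutate(layer_call = case_when(
      .data$any_s & !.data$any_r ~ "pansensitive",
      .data$any_r & !.data$any_s ~ "panresistant",
      TRUE ~ "neither"
    ))
  per_layer %>%
    group_by(.data$id) %>%
    summarise(
      n_layers = n(),
      n_drugs_evaluated = min(.data$n_drugs),
      concordant = n_distinct(.data$layer_call) == 1,
      layer_call = .data$layer_call[1],
      .groups = "drop"
    ) %>%
    mutate(
      layers_concordant = .data$concordant & .data$n_layers == length(layers_required),
      call = ifelse(.data$layers_concordant, .data$layer_call, "neither"),
      incomplete = if (is.null(n_drugs_expected)) FALSE else
        .data$n_drugs_evaluated < n_drugs_expected,
      flag = case_when(
        .data$n_layers < length(layers_required) ~ "missing_layer",
        !.data$concordant ~ "discordant_layers",
        .data$incomplete ~ "incomplete_panel",
        TRUE ~ NA_character_
      )
    ) %>%
    select("id", "call", "n_drugs_evaluated", "layers_concordant", "flag")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Radiotherapy response association calls
#'
#' Restricted to stage III/IV patients who received radiotherapy, compares
#' each gene's expression between long-survival (`time > long_min` months)
#' and short-survival (`time < short_max` months) patients with a
#' two-sample t-test; the intervals are open, so patients at or between the
#' boundaries are excluded. Significantly higher expression in the
#' long-survival group yields `rt_sensitive`, in the short-survival group
#' `rt_resistant`, otherwise `neutral`.
#'
#' @param expr Expression matrix (genes x patients).
#' @param metadata Metadata with `sample_id`, `stage`, `radiotherapy`,
#'   `time_months`.
#' @param long_min,short_max Group boundaries in months (defaults 58 and 20).
#' @param alpha Significance level.
#' @return Tibble: `gene_id`, `call`, `p`, `n_long`, `n_short`.
#' @export
radiotherapy_call <- function(expr, metadata, long_min = 58, short_max = 20,
                              alpha = 0.05) {
  check_expression_matrix(expr)
  metadata <- as_tibble(metadata)
  elig <- metadata %>%
    filter(.data$stage %in% c("III", "IV"),
           !is.na(.data$radiotherapy) & .data$radiotherapy,
           .data$sample_id %in% colnames(expr))
  long_ids <- elig$sample_id[!is.na(elig$time_months) & elig$time_months > long_min]
  short_ids <- elig$sample_id[!is.na(elig$time_months) & elig$time_months < short_max]
  if (length(long_ids) < 2 || length(short_ids) < 2) {
    stop_mirdx("need >= 2 patients in both the long- and short-survival groups")
  }
  tt <- row_t_unpaired(expr[, long_ids, drop = FALSE],
                       expr[, short_ids, drop = FALSE])
  tibble(gene_id = rownames(expr),
         call = ifelse(is.na(tt$p) | tt$p >= alpha, "neutral",
                       ifelse(tt$mean_diff > 0, "rt_sensitive", "rt_resistant")),
         p = unname(tt$p), n_long = length(long_ids), n_short = length(short_ids))
}

#' Compound responder genes with mRNA-protein concordance
#'
#' Genes significantly associated with response to one compound in the same
#' direction in both the mRNA and protein layers. Direction labels the gene
#' sensitive-associated (higher in sensitive lines) or resistant-associated.
#'
#' @param mrna,protein Expression matrices (genes x cell lines).
#' @param categorized_panel Output of [categorize_lines()].
#' @param compound Drug name.
#' @param alpha Significance level.
#' @return Tibble: `gene_id`, `direction`, `p_mrna`, `p_protein`.
#' @export
responder_genes <- function(mrna, protein, categorized_panel, compound,
                            alpha = 0.05) {
  cm <- gene_drug_call(mrna, categorized_panel, compound, layer = "mRNA", alpha = alpha)
  cp <- gene_drug_call(protein, categorized_panel, compound, layer = "protein", alpha = alpha)
  joined <- left_join(
    cm %>% select("id", call_mrna = "call", p_mrna = "p"),
    cp %>% select("id", call_protein = "call", p_protein = "p"),
    by = "id"
  )
  joined %>%
    filter(.data$call_mrna != "neutral",
           !is.na(.data$call_protein),
           .data$call_mrna == .data$call_protein) %>%
    mutate(direction = ifelse(.data$call_mrna == "sensitive",
                              "sensitive_associated", "resistant_associated")) %>%
    select(gene_id = "id", "direction", "p_mrna", "p_protein")
}
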