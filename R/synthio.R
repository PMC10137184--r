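#' Specify a synthetic two-class expression cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' The defaults mirror a training design of 87 tumors and 22 normal lung
#' tissues with 22 matched tumor/normal pairs, 20 planted markers at a
#' 4-fold (2 log2-unit) effect, and unit log2 noise.
#'
#' @param n_features Number of features (miRNA probes) to simulate.
#' @param n_tumor,n_normal Number of tumor and normal samples.
#' @param n_paired Number of matched tumor/normal pairs
#'   (`<= min(n_tumor, n_normal)`).
#' @param n_planted_up,n_planted_down Number of features planted with higher
#'   (lower) mean expression in tumors.
#' @param planted_log2fc Planted effect size in log2 units (> 0); 1 means a
#'   2-fold, 2 a 4-fold change.
#' @param noise_sd Gaussian noise standard deviation on the log2 scale (> 0).
#' @param seed Integer seed; the generator is deterministic given the
#'   simulation spec.
#' @return A `mirdx_sim_spec` list.
#' @export
#' @examples
#' sim_spec(n_features = 50, n_tumor = 10, n_normal = 10, n_paired = 5)
sim_spec <- function(n_features = 200, n_tumor = 87, n_normal = 22,
                     n_paired = 22, n_planted_up = 10, n_planted_down = 10,
                     planted_log2fc = 2, noise_sd = 1, seed = 1L) {
  spec <- list(
    n_features = as.integer(n_features), n_tumor = as.integer(n_tumor),
    n_normal = as.integer(n_normal), n_paired = as.integer(n_paired),
    n_planted_up = as.integer(n_planted_up),
    n_planted_down = as.integer(n_planted_down),
    planted_log2fc = planted_log2fc, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  counts <- spec[c("n_features", "n_tumor", "n_normal", "n_paired",
                   "n_planted_up", "n_planted_down")]
  bad <- names(counts)[vapply(counts, function(x) is.na(x) || x < 0, logical(1))]
  if (length(bad) > 0) {
    stop_mirdx(sprintf("counts must be >= 0; violated by: %s",
                       paste(bad, collapse = ", ")), class = "mirdx_spec_error")
  }
  if (spec$n_paired > min(spec$n_tumor, spec$n_normal)) {
    stop_mirdx("n_paired must be <= min(n_tumor, n_normal)",
               class = "mirdx_spec_error")
  }
  if (spec$n_planted_up + spec$n_planted_down > spec$n_features) {
    stop_mirdx("n_planted_up + n_planted_down must be <= n_features",
               class = "mirdx_spec_error")
  }
  if (!is.finite(spec$planted_log2fc) || spec$planted_log2fc <= 0) {
    stop_mirdx("planted_log2fc must be > 0", class = "mirdx_spec_error")
  }
  if (!is.finite(spec$noise_sd) || spec$noise_sd <= 0) {
    stop_mirdx("noise_sd must be > 0", class = "mirdx_spec_error")
  }
  structure(spec, class = "mirdx_sim_spec")
}

#' Generate a synthetic tumor/normal log2 expression cohort
#'
#' Simulates a features-by-samples log2 expression matrix in which planted-up
#' features have tumor mean equal to the normal mean plus `planted_log2fc`
#' (planted-down the negation) and all other features have equal class means.
#' Noise is i.i.d. Gaussian on the log2 scale; matched pairs additionally
#' share a sample-level Gaussian random intercept (sd = `noise_sd / 2`) so
#' paired analyses gain power, as in matched-tissue designs.
#'
#' @param spec A [sim_spec()] object.
#' @param baseline Optional per-feature baseline log2 means (length
#'   `n_features`). Passing the `baseline` of a previously generated cohort
#'   emulates an independent validation cohort measured on the same
#'   features (per-feature mean expression is a property of the biology
#'   shared across cohorts); `NULL` draws fresh baselines.
#' @return A `mirdx_cohort` list with elements `expression` (matrix),
#'   `metadata` (tibble: `sample_id`, `class_label`, `pair_id`, `histology`),
#'   `truth` (tibble: `feature_id`, `direction` of the planted effect), and
#'   `baseline`.
#' @export
#' @examples
#' cohort <- gen_expression_cohort(sim_spec(n_features = 40, n_tumor = 12,
#'                                          n_normal = 8, n_paired = 4))
#' dim(cohort$expression)
gen_expression_cohort <- function(spec, baseline = NULL) {
  if (!inherits(spec, "mirdx_sim_spec")) spec <- do.call(sim_spec, spec)
  set.seed(spec$seed)
  p <- spec$n_features
  n <- spec$n_tumor + spec$n_normal
  feature_ids <- sprintf("mir-%03d", seq_len(p))
  sample_ids <- c(sprintf("T%03d", seq_len(spec$n_tumor)),
                  sprintf("N%03d", seq_len(spec$n_normal)))
  class_label <- rep(c("tumor", "normal"), c(spec$n_tumor, spec$n_normal))

  if (is.null(baseline)) {
    baseline <- rnorm(p, mean = 7, sd = 2)
  } else if (length(baseline) != p) {
    stop_mirdx("baseline must have length n_features")
  }
  delta <- numeric(p)
  up_idx <- seq_len(spec$n_planted_up)
  down_idx <- spec$n_planted_up + seq_len(spec$n_planted_down)
  delta[up_idx] <- spec$planted_log2fc
  delta[down_idx] <- -spec$planted_log2fc

  mu <- matrix(baseline, nrow = p, ncol = n)
  mu[, class_label == "tumor"] <- mu[, class_label == "tumor"] + delta

  x <- mu + matrix(rnorm(p * n, sd = spec$noise_sd), nrow = p)

  pair_id <- rep(NA_character_, n)
  if (spec$n_paired > 0) {
    pid <- sprintf("P%03d", seq_len(spec$n_paired))
    tumor_pos <- which(class_label == "tumor")[seq_len(spec$n_paired)]
    normal_pos <- which(class_label == "normal")[seq_len(spec$n_paired)]
    pair_id[tumor_pos] <- pid
    pair_id[normal_pos] <- pid
    # shared per-pair intercept: same shift on both partners, all features
    b <- rnorm(spec$n_paired, sd = spec$noise_sd / 2)
    x[, tumor_pos] <- sweep(x[, tumor_pos, drop = FALSE], 2, b, "+")
    x[, normal_pos] <- sweep(x[, normal_pos, drop = FALSE], 2, b, "+")
  }

  # histology for tumor samples: mostly NSCLC with small SCLC/carcinoid arms
  histology <- ifelse(class_label == "normal", "normal", "NSCLC")
  tumor_pos_all <- which(class_label == "tumor")
  n_sclc <- min(3L, max(0L, spec$n_tumor - 4L))
  n_carc <- min(2L, max(0L, spec$n_tumor - 4L - n_sclc))
  if (n_sclc > 0) histology[tumor_pos_all[spec$n_tumor - seq_len(n_sclc) + 1L]] <- "SCLC"
  if (n_carc > 0) histology[tumor_pos_all[spec$n_tumor - n_sclc - seq_len(n_carc) + 1L]] <- "carcinoid"

  dimnames(x) <- list(feature_ids, sample_ids)
  truth <- tibble(
    feature_id = feature_ids[c(up_idx, down_idx)],
    direction = rep(c("up", "down"), c(spec$n_planted_up, spec$n_planted_down))
  )
  structure(list(
    expression = x,
    metadata = tibble(sample_id = sample_ids, class_label = class_label,
                      pair_id = pair_id, histology = histology),
    truth = truth,
    baseline = baseline,
    spec = spec
  ), class = "mirdx_cohort")
}

#' Attach proportional-hazards survival outcomes to a cohort
#'
#' Draws event times from an exponential proportional-hazards model with
#' linear predictor `log_hr_per_unit` times the (centered) expression of the
#' driver features, summed over drivers. Censoring is independent uniform
#' administrative censoring with the horizon solved numerically so the
#' expected censored fraction matches `censor_rate`. Times are in months.
#'
#' @param cohort A `mirdx_cohort` (or any list with `expression` and
#'   `metadata`).
#' @param driver_features Feature ids whose expression drives the hazard.
#' @param log_hr_per_unit Log hazard ratio per log2-expression unit; a
#'   scalar shared by all drivers or a vector with one coefficient per
#'   driver (signs may differ, e.g. hazardous and protective drivers).
#' @param censor_rate Target fraction of censored subjects in `[0, 1)`.
#' @param seed Integer seed.
#' @param median_months Baseline median survival in months (default 30).
#' @return The cohort metadata tibble augmented with `time_months` and
#'   `event` columns.
#' @export
gen_survival <- function(cohort, driver_features = character(),
                         log_hr_per_unit = 0, censor_rate = 0.3, seed = 1L,
                         median_months = 30) {
  x <- cohort$expression
  meta <- cohort$metadata
  if (is.null(x) || ncol(x) == 0) stop_mirdx("empty cohort")
  missing_drv <- setdiff(driver_features, rownames(x))
  if (length(missing_drv) > 0) {
    stop_mirdx(sprintf("driver feature(s) not in cohort: %s",
                       paste(missing_drv, collapse = ", ")))
  }
  set.seed(derive_seed(seed, "survival"))
  lp <- rep(0, ncol(x))
  if (length(driver_features) > 0 && any(log_hr_per_unit != 0)) {
    coef <- rep_len(log_hr_per_unit, length(driver_features))
    drv <- x[driver_features, , drop = FALSE]
    drv <- drv - rowMeans(drv)
    lp <- colSums(coef * drv)
  }
  lambda0 <- log(2) / median_months
  rate <- lambda0 * exp(lp)
  t_event <- rexp(ncol(x), rate = rate)
  t_event <- pmax(t_event, 1e-6)
  if (censor_rate <= 0) {
    time <- t_event
    event <- rep(TRUE, ncol(x))
  } else {
    # P(censored) for C ~ U(0, tau), T ~ Exp(r): mean_i (1 - exp(-r_i tau)) / (r_i tau)
    pc <- function(tau) mean((1 - exp(-rate * tau)) / (rate * tau)) - censor_rate
    tau <- uniroot(pc, lower = 1e-6, upper = 1e6)$root
    cens <- runif(ncol(x), 0, tau)
    event <- t_event <= cens
    time <- pmin(t_event, cens)
  }
  meta$time_months <- time
  meta$event <- event
  meta
}

#' Generate a synthetic pharmacogenomic panel with linked genes
#'
#' Simulates per-(cell line, drug) log-scale drug-response values
#' (`ln_IC50`; lower = more sensitive) together with matched mRNA and
#' protein expression layers. Genes named in `linked_genes` have expression
#' aligned with the response to their drug: `direction = "sensitive"` genes
#' are higher-expressed in sensitive (low-IC50) lines, `"resistant"` genes
#' in resistant lines. mRNA and protein layers for a gene are correlated
#' (about 0.85); the protein layer is mean-centered per gene.
#'
#' @param n_lines,n_drugs Panel dimensions (drug names `drug01`, ...).
#' @param linked_genes Named list: `gene_id = list(drug = "drug01",
#'   direction = "sensitive"|"resistant")`.
#' @param n_genes Total number of genes (unlinked genes fill the remainder).
#' @param effect Expression shift (in SDs) per SD of drug response.
#' @param response_cor Correlation between drugs induced by a shared
#'   per-line general-sensitivity factor (log-IC50 panels are dominated by
#'   broad multidrug sensitivity differences between lines; default 0.85).
#' @param seed Integer seed.
#' @return A list with `panel` (long tibble: `cell_line`, `drug`, `measure`,
#'   `value`, `source`), `mrna` and `protein` expression matrices, and
#'   `linked` (tibble of the planted links).
#' @export
gen_pharmaco_panel <- function(n_lines = 94, n_drugs = 21,
                               linked_genes = list(), n_genes = 20,
                               effect = 1.5, response_cor = 0.85, seed = 1L) {
  if (n_drugs < 1) stop_mirdx("n_drugs must be >= 1")
  set.seed(derive_seed(seed, "pharmaco"))
  lines <- sprintf("LINE%03d", seq_len(n_lines))
  drugs <- sprintf("drug%02d", seq_len(n_drugs))
  general <- rnorm(n_lines)   # shared multidrug sensitivity of each line
  resp <- sqrt(response_cor) * matrix(general, nrow = n_lines, ncol = n_drugs) +
    sqrt(1 - response_cor) * matrix(rnorm(n_lines * n_drugs), nrow = n_lines)
  dimnames(resp) <- list(lines, drugs)

  linked <- tibble(
    gene_id = names(linked_genes),
    drug = vapply(linked_genes, function(g) g$drug, character(1)),
    direction = vapply(linked_genes, function(g) g$direction, character(1))
  )
  if (nrow(linked) > 0) {
    bad <- setdiff(linked$drug, drugs)
    if (length(bad) > 0) {
      stop_mirdx(sprintf("linked drug(s) not in panel: %s", paste(bad, collapse = ", ")))
    }
    if (!all(linked$direction %in% c("sensitive", "resistant"))) {
      stop_mirdx("linked direction must be 'sensitive' or 'resistant'")
    }
  }
  n_genes <- max(n_genes, nrow(linked))
  gene_ids <- union(linked$gene_id,
                    sprintf("GENE%03d", seq_len(n_genes)))[seq_len(n_genes)]

  mrna <- matrix(rnorm(n_genes * n_lines, mean = 5, sd = 1), nrow = n_genes,
                 dimnames = list(gene_ids, lines))
  # unlinked genes: protein tracks mRNA loosely (cor ~ 0.4, typical of
  # steady-state mRNA-protein coupling across cell lines)
  protein <- 0.4 * (mrna - 5) +
    matrix(rnorm(n_genes * n_lines, sd = sqrt(1 - 0.4^2)), nrow = n_genes)
  for (i in seq_len(nrow(linked))) {
    g <- linked$gene_id[i]
    z <- scale(resp[, linked$drug[i]])[, 1]
    # sensitive genes high where response value (ln_IC50) is low
    sgn <- if (linked$direction[i] == "sensitive") -1 else 1
    mrna[g, ] <- 5 + sgn * effect * z + rnorm(n_lines, sd = 0.5)
    # protein shares the response-linked component (cross-layer cor ~ 0.9)
    protein[g, ] <- sgn * effect * z + rnorm(n_lines, sd = 0.5)
  }
  protein <- protein - rowMeans(protein)
  dimnames(protein) <- dimnames(mrna)

  panel <- tibble(
    cell_line = rep(lines, times = n_drugs),
    drug = rep(drugs, each = n_lines),
    measure = "ln_IC50",
    value = as.vector(resp),
    source = "synthetic"
  )
  list(panel = panel, mrna = mrna, protein = protein, linked = linked)
}

#' Generate a synthetic dependency screen with anchor genes
#'
#' Simulates a gene-by-line knockout/knockdown effect matrix in which
#' essential anchor genes center near -1 and non-essential anchors near 0 on
#' the true scale, then applies a per-line affine distortion (random gain
#' and offset) so that anchor-based renormalization is non-trivial.
#' `dependent_ids` genes show a true effect of -1 in a random
#' `fraction_affected` subset of lines and 0 elsewhere.
#'
#' @param n_genes,n_lines Screen dimensions (query genes beyond the anchors).
#' @param essential_ids,nonessential_ids Anchor gene ids (disjoint; generated
#'   as `ESS*`/`NON*` when `NULL`).
#' @param n_essential,n_nonessential Anchor set sizes when ids are generated.
#' @param dependent_ids Query gene ids planted as proliferation-dependent.
#' @param fraction_affected Fraction of lines in which a dependent gene has a
#'   true effect.
#' @param noise_sd Gaussian noise on the true effect scale.
#' @param assay Label, `"CRISPR"` or `"RNAi"`.
#' @param seed Integer seed.
#' @return A `mirdx_depscreen` list: `assay`, `raw` matrix,
#'   `essential_ids`, `nonessential_ids`, `truth` (tibble of planted
#'   dependent genes with affected lines).
#' @export
gen_dependency_screen <- function(n_genes = 20, n_lines = 50,
                                  essential_ids = NULL, nonessential_ids = NULL,
                                  n_essential = 30, n_nonessential = 30,
                                  dependent_ids = character(),
                                  fraction_affected = 0.8, noise_sd = 0.15,
                                  assay = c("CRISPR", "RNAi"), seed = 1L) {
  assay <- match.arg(assay)
  set.seed(derive_seed(seed, paste0("depscreen-", assay)))
  if (is.null(essential_ids)) essential_ids <- sprintf("ESS%03d", seq_len(n_essential))
  if (is.null(nonessential_ids)) nonessential_ids <- sprintf("NON%03d", seq_len(n_nonessential))
  if (length(intersect(essential_ids, nonessential_ids)) > 0) {
    stop_mirdx("essential and non-essential anchor sets overlap")
  }
  query_ids <- union(dependent_ids, sprintf("Q%03d", seq_len(n_genes)))[seq_len(max(n_genes, length(dependent_ids)))]
  genes <- c(essential_ids, nonessential_ids, query_ids)
  lines <- sprintf("LINE%03d", seq_len(n_lines))

  true_eff <- matrix(0, nrow = length(genes), ncol = n_lines,
                     dimnames = list(genes, lines))
  true_eff[essential_ids, ] <- -1
  affected <- list()
  for (g in dependent_ids) {
    k <- sample(n_lines, round(fraction_affected * n_lines))
    true_eff[g, k] <- -1
    affected[[g]] <- lines[sort(k)]
  }
  noise <- matrix(rnorm(length(genes) * n_lines, sd = noise_sd),
                  nrow = length(genes))
  gain <- runif(n_lines, 0.7, 1.4)
  offset <- rnorm(n_lines, sd = 0.3)
  raw <- sweep(sweep(true_eff + noise, 2, gain, "*"), 2, offset, "+")

  structure(list(
    assay = assay, raw = raw,
    essential_ids = essential_ids, nonessential_ids = nonessential_ids,
    truth = tibble(gene_id = names(affected),
                   n_affected = vapply(affected, length, integer(1)),
                   fraction_affected = vapply(affected, length, integer(1)) / n_lines)
  ), class = "mirdx_depscreen")
}
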