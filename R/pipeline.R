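#' Configuration for the end-to-end synthetic pipeline
#'
#' Collects the knobs of [run_pipeline()]. All randomness flows from the
#' single `seed` through per-stage derived seeds, so stages are
#' independently reproducible and the full report bundle is deterministic.
#'
#' @param seed Master integer seed.
#' @param sim A [sim_spec()] for the training cohort; the validation cohort
#'   reuses it with a different derived seed.
#' @param thresholds A [marker_thresholds()] object.
#' @param paired_design Design used for the matched-pair analysis arm
#'   (`"paired"` or `"unpaired"`).
#' @param survival `NULL` to skip the survival stages, else a list with
#'   `n_subjects`, `log_hr_per_unit`, `censor_rate`.
#' @param pharmaco `NULL` to skip, else a list with `n_lines`, `n_drugs`,
#'   `n_genes`.
#' @param dependency `NULL` to skip, else a list with `n_lines`,
#'   `fraction_affected`.
#' @param n_hazardous,n_protective,n_null_genes Gene-panel composition for
#'   the prognostic/proliferation stages.
#' @param concordance Cohort-concordance policy for miRNA categorization.
#' @param out_dir Optional directory for stage outputs (TSV/GRP/JSON).
#' @return A `mirdx_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_spec(seed = seed),
                            thresholds = marker_thresholds(),
                            paired_design = "paired",
                            survival = list(n_subjects = 150,
                                            log_hr_per_unit = 0.8,
                                            censor_rate = 0.3),
                            pharmaco = list(n_lines = 94, n_drugs = 21,
                                            n_genes = 20),
                            dependency = list(n_lines = 50,
                                              fraction_affected = 0.8),
                            n_hazardous = 5, n_protective = 5,
                            n_null_genes = 10,
                            concordance = "all",
                            out_dir = NULL) {
  structure(list(seed = as.integer(seed), sim = sim, thresholds = thresholds,
                 paired_design = paired_design, survival = survival,
                 pharmaco = pharmaco, dependency = dependency,
                 n_hazardous = n_hazardous, n_protective = n_protective,
                 n_null_genes = n_null_genes, concordance = concordance,
                 out_dir = out_dir),
            class = "mirdx_config")
}

# Generate a tumor-only mRNA cohort with planted hazardous (up) and
# protective (down) genes, plus survival linked to them.
.gene_survival_cohort <- function(gene_ids_h, gene_ids_p, n_null, n_subjects,
                                  log_hr, censor_rate, seed, cohort_label) {
  n_genes <- length(gene_ids_h) + length(gene_ids_p) + n_null
  spec <- sim_spec(n_features = n_genes, n_tumor = n_subjects, n_normal = 0,
                   n_paired = 0, n_planted_up = length(gene_ids_h),
                   n_planted_down = length(gene_ids_p), planted_log2fc = 1.5,
                   noise_sd = 1, seed = seed)
  cohort <- gen_expression_cohort(spec)
  ids <- c(gene_ids_h, gene_ids_p, sprintf("NUL%02d", seq_len(n_null)))
  rownames(cohort$expression) <- ids
  cohort$truth$feature_id <- ids[seq_len(nrow(cohort$truth))]
  drivers <- c(gene_ids_h, gene_ids_p)
  meta <- gen_survival(cohort, driver_features = drivers,
                       log_hr_per_unit = c(rep(log_hr, length(gene_ids_h)),
                                           rep(-log_hr, length(gene_ids_p))),
                       censor_rate = censor_rate, seed = seed + 7L)
  list(expression = cohort$expression, metadata = meta, label = cohort_label)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> markers -> cluster -> classify -> survival ->
#' prognostic genes -> pharmaco -> dependency -> signature lists, each
#' stage feeding the next, and returns the aggregated report bundle.
#' Stages whose configuration is `NULL` are skipped with an explicit
#' notice; a failing stage halts the run naming the stage.
#'
#' @param config A [pipeline_config()] object.
#' @return A named list of per-stage results plus `notices` and `meta`
#'   (seed, config hash, package version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "mirdx_config"))
  notices <- character(0)
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mirdx(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)))
    })
  }

  ## simulate ----
  train <- stage("simulate", {
    spec <- config$sim; spec$seed <- derive_seed(config$seed, "train")
    gen_expression_cohort(spec)
  })
  valid <- stage("simulate", {
    spec <- config$sim; spec$seed <- derive_seed(config$seed, "validation")
    gen_expression_cohort(spec, baseline = train$baseline)
  })

  ## markers ----
  report$markers <- stage("markers", {
    stats_unpaired <- diff_stats(train$expression, train$metadata, "unpaired",
                                 config$thresholds,
                                 seed = derive_seed(config$seed, "sam1"))
    paired_meta <- train$metadata[!is.na(train$metadata$pair_id), ]
    stats_paired <- diff_stats(train$expression[, paired_meta$sample_id, drop = FALSE],
                               paired_meta, config$paired_design,
                               config$thresholds,
                               seed = derive_seed(config$seed, "sam2"))
    set_a <- select_markers(stats_unpaired, config$thresholds, "unpaired_cohort")
    set_b <- select_markers(stats_paired, config$thresholds, "paired_cohort")
    markers <- union_marker_sets(set_a, set_b)
    list(stats_unpaired = stats_unpaired, stats_paired = stats_paired,
         set_unpaired = set_a, set_paired = set_b, markers = markers,
         truth = train$truth)
  })
  markers <- report$markers$markers

  ## cluster ----
  report$cluster <- stage("cluster", {
    cl <- hcluster_two(train$expression, markers)
    list(assignment = cl$assignment,
         report = evaluate_clusters(cl, train$metadata))
  })

  ## classify ----
  report$classify <- stage("classify", {
    model <- fit_centroids(train$expression, train$metadata, markers)
    preds <- classify_cohort(valid$expression, model)
    list(model = model, predictions = preds,
         report = evaluate_predictions(preds, valid$metadata))
  })

  ## survival: per-miRNA categorization across three cohorts ----
  if (is.null(config$survival)) {
    notices <- c(notices, "survival stage skipped: no survival configuration")
  } else {
    report$survival <- stage("survival", {
      sv <- config$survival
      drivers_up <- intersect(train$truth$feature_id[train$truth$direction == "up"],
                              markers$feature_id)
      drivers_down <- intersect(train$truth$feature_id[train$truth$direction == "down"],
                                markers$feature_id)
      cohorts <- purrr::map(c(LUAD = "LUAD", LUSC = "LUSC"), function(lbl) {
        spec <- config$sim
        spec$n_tumor <- sv$n_subjects; spec$n_normal <- 0L; spec$n_paired <- 0L
        spec$seed <- derive_seed(config$seed, paste0("surv-", lbl))
        co <- gen_expression_cohort(spec)
        meta <- gen_survival(co, driver_features = c(drivers_up, drivers_down),
                             log_hr_per_unit = c(rep(sv$log_hr_per_unit, length(drivers_up)),
                                                 rep(-sv$log_hr_per_unit, length(drivers_down))),
                             censor_rate = sv$censor_rate,
                             seed = derive_seed(config$seed, paste0("survt-", lbl)))
        list(expression = co$expression, metadata = meta)
      })
      pooled <- list(
        expression = cbind(cohorts$LUAD$expression,
                           `colnames<-`(cohorts$LUSC$expression,
                                        paste0("L2_", colnames(cohorts$LUSC$expression)))),
        metadata = bind_rows(cohorts$LUAD$metadata,
                             cohorts$LUSC$metadata %>%
                               mutate(sample_id = paste0("L2_", .data$sample_id)))
      )
      all_cohorts <- c(cohorts, list(NSCLC = pooled))
      summaries <- purrr::map(names(all_cohorts), function(lbl) {
        co <- all_cohorts[[lbl]]
        purrr::map(markers$feature_id, function(f) {
          s <- tryCatch(
            optimal_cutoff(co$expression[f, ], co$metadata$time_months,
                           co$metadata$event, grid_policy = "quantile",
                           n_grid = 25),
            error = function(e) tibble(cutoff = NA_real_, n_high = NA_integer_,
                                       n_low = NA_integer_, logrank_chi2 = NA_real_,
                                       logrank_p = NA_real_, hr = NA_real_,
                                       hr_lo = NA_real_, hr_hi = NA_real_,
                                       n_candidates = 0L))
          mutate(s, feature_id = f, cohort = lbl)
        }) %>% bind_rows()
      }) %>% bind_rows()
      categories <- purrr::map(markers$feature_id, function(f) {
        ev <- summaries %>% filter(.data$feature_id == f) %>%
          select("cohort", "hr", p = "logrank_p")
        dirn <- markers$direction[markers$feature_id == f]
        categorize_mirna(ev, dirn, concordance = config$concordance) %>%
          mutate(mirna_id = f, tumor_direction = dirn)
      }) %>% bind_rows()
      list(summaries = summaries, categories = categories)
    })
  }

  ## prognostic genes + dependency + signatures ----
  gene_ids_h <- sprintf("HZG%02d", seq_len(config$n_hazardous))
  gene_ids_p <- sprintf("PRG%02d", seq_len(config$n_protective))
  if (is.null(config$survival)) {
    notices <- c(notices,
                 "prognostic-gene and signature stages skipped: no survival configuration")
  } else {
    report$prognostic <- stage("prognostic", {
      sv <- config$survival
      cohorts <- purrr::map(
        c(Xu = "Xu", LUAD = "LUAD", LUSC = "LUSC"),
        function(lbl) .gene_survival_cohort(
          gene_ids_h, gene_ids_p, config$n_null_genes, sv$n_subjects,
          sv$log_hr_per_unit, sv$censor_rate,
          derive_seed(config$seed, paste0("gene-", lbl)), lbl)
      )
      pooled <- list(
        expression = cbind(cohorts$LUAD$expression,
                           `colnames<-`(cohorts$LUSC$expression,
                                        paste0("L2_", colnames(cohorts$LUSC$expression)))),
        metadata = bind_rows(cohorts$LUAD$metadata,
                             cohorts$LUSC$metadata %>%
                               mutate(sample_id = paste0("L2_", .data$sample_id))),
        label = "NSCLC")
      # evidence 1: tumor-vs-normal differential expression (Xu-style cohort)
      de_spec <- sim_spec(
        n_features = length(gene_ids_h) + length(gene_ids_p) + config$n_null_genes,
        n_tumor = 51, n_normal = 49, n_paired = 0,
        n_planted_up = length(gene_ids_h), n_planted_down = length(gene_ids_p),
        planted_log2fc = 1.5, noise_sd = 1,
        seed = derive_seed(config$seed, "gene-de"))
      de_cohort <- gen_expression_cohort(de_spec)
      all_gene_ids <- c(gene_ids_h, gene_ids_p,
                        sprintf("NUL%02d", seq_len(config$n_null_genes)))
      rownames(de_cohort$expression) <- all_gene_ids
      de_stats <- two_group_stats(de_cohort$expression, de_cohort$metadata)
      de_ev <- ifelse(de_stats$t_p < 0.05 & de_stats$mean_log2_diff > 0, "hazardous",
                      ifelse(de_stats$t_p < 0.05 & de_stats$mean_log2_diff < 0,
                             "protective", "none"))
      names(de_ev) <- de_stats$feature_id
      surv_cohorts <- c(cohorts, list(NSCLC = pooled))
      surv_ev <- purrr::map(surv_cohorts, function(co) {
        vapply(all_gene_ids, function(g) {
          s <- tryCatch(optimal_cutoff(co$expression[g, ],
                                       co$metadata$time_months,
                                       co$metadata$event,
                                       grid_policy = "quantile", n_grid = 25),
                        error = function(e) NULL)
          if (is.null(s) || is.na(s$hr) || s$logrank_p >= 0.05) "none"
          else if (s$hr > 1) "hazardous" else "protective"
        }, character(1))
      })
      calls <- purrr::map(all_gene_ids, function(g) {
        ev <- c(de_ev[g], vapply(surv_ev, `[[`, character(1), g))
        prognostic_gene_call(ev) %>% mutate(gene_id = g)
      }) %>% bind_rows() %>% select("gene_id", "category", "n_supporting")
      calls
    })
  }

  if (is.null(config$dependency)) {
    notices <- c(notices, "dependency stage skipped: no dependency configuration")
  } else {
    report$dependency <- stage("dependency", {
      dp <- config$dependency
      screens <- purrr::map(c(CRISPR = "CRISPR", RNAi = "RNAi"), function(a) {
        normalize_dependency(gen_dependency_screen(
          n_genes = config$n_hazardous + config$n_protective + config$n_null_genes,
          n_lines = dp$n_lines,
          dependent_ids = gene_ids_h,
          fraction_affected = dp$fraction_affected,
          assay = a, seed = derive_seed(config$seed, paste0("dep-", a))))
      })
      # profile the named gene panel
      all_gene_ids <- c(gene_ids_h, gene_ids_p,
                        sprintf("NUL%02d", seq_len(config$n_null_genes)))
      for (a in names(screens)) {
        rn <- rownames(screens[[a]]$raw)
        qi <- setdiff(rn, c(screens[[a]]$essential_ids, screens[[a]]$nonessential_ids))
        rownames(screens[[a]]$raw)[match(qi, rn)] <- all_gene_ids[seq_along(qi)]
        rownames(screens[[a]]$normalized) <- rownames(screens[[a]]$raw)
      }
      profile <- proliferation_profile(screens$CRISPR, screens$RNAi)
      list(screens = screens, profile = profile)
    })
  }

  if (is.null(config$pharmaco)) {
    notices <- c(notices, "pharmaco stage skipped: no pharmaco configuration")
  } else {
    report$pharmaco <- stage("pharmaco", {
      ph <- config$pharmaco
      linked <- list()
      linked[[gene_ids_p[1]]] <- list(drug = "drug01", direction = "sensitive")
      linked[[gene_ids_h[1]]] <- list(drug = "drug02", direction = "resistant")
      panel <- gen_pharmaco_panel(n_lines = ph$n_lines, n_drugs = ph$n_drugs,
                                  linked_genes = linked, n_genes = ph$n_genes,
                                  seed = derive_seed(config$seed, "pharm"))
      cat_panel <- categorize_lines(panel$panel)
      drugs <- unique(cat_panel$drug)
      calls <- purrr::map(drugs, function(d) {
        bind_rows(gene_drug_call(panel$mrna, cat_panel, d, layer = "mRNA"),
                  gene_drug_call(panel$protein, cat_panel, d, layer = "protein"))
      }) %>% bind_rows()
      pans <- pan_call(calls, layers_required = c("mRNA", "protein"),
                       n_drugs_expected = ph$n_drugs)
      list(panel = cat_panel, calls = calls, pan = pans, linked = panel$linked)
    })
  }

  if (!is.null(config$survival) && !is.null(config$dependency)) {
    report$signatures <- stage("signature", {
      build_cmap_lists(report$prognostic, report$dependency$profile)
    })
  } else {
    notices <- c(notices, "signature stage skipped: requires survival and dependency stages")
  }

  report$notices <- notices
  report$meta <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    package_version = as.character(utils::packageVersion("mirdx"))
  )

  if (!is.null(config$out_dir)) .write_pipeline_outputs(report, config)
  report
}

# Write the main stage outputs with a metadata header comment.
.write_pipeline_outputs <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# mirdx %s | seed %d | config %s",
                 report$meta$package_version, report$meta$seed,
                 report$meta$config_hash)
  write_tsv_with_header <- function(df, path) {
    writeLines(hdr, path)
    suppressWarnings(readr::write_tsv(df, path, append = TRUE, col_names = TRUE))
  }
  write_tsv_with_header(report$markers$markers,
                        file.path(config$out_dir, "markers.tsv"))
  write_tsv_with_header(report$cluster$assignment,
                        file.path(config$out_dir, "cluster_assignment.tsv"))
  if (!is.null(report$survival)) {
    write_tsv_with_header(report$survival$categories,
                          file.path(config$out_dir, "mirna_categories.tsv"))
  }
  if (!is.null(report$pharmaco)) {
    write_tsv_with_header(report$pharmaco$pan,
                          file.path(config$out_dir, "pan_calls.tsv"))
  }
  if (!is.null(report$signatures)) {
    write_gene_lists(report$signatures$list1, config$out_dir)
    write_gene_lists(report$signatures$list2, config$out_dir)
  }
  invisible(config$out_dir)
}
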