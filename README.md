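# mirdx

Discovery and translational analysis of microRNA diagnostic biomarkers
for lung cancer, as a tested, reproducible R pipeline.

Bulk miRNA profiling can separate lung tumors from normal lung tissue,
and the miRNAs that do so point at target genes with prognostic,
drug-response, and proliferation relevance. `mirdx` implements that whole
chain for tumor/normal expression cohorts:

* **Marker selection** — per-feature fold change, classical pooled
  t-tests (unpaired or paired), and a SAM-style moderated statistic
  *d* = Δmean / (*s* + *s₀*) with permutation-estimated q-values;
  markers pass at FC > 2 or < 0.5, p < 0.05, and q < 0.05, and marker
  sets from different analysis arms are merged by direction-consistent
  union.
* **Diagnosis** — unsupervised two-group clustering (Manhattan distance,
  Ward linkage) and a nearest-centroid classifier (Pearson correlation
  with tumor and normal centroids), both scored by confusion reports
  (sensitivity, specificity, accuracy).
* **Prognosis** — Kaplan–Meier / log-rank / univariate Cox summaries at
  the smallest-p expression cutoff, oncogene vs tumor-suppressor
  categorization of miRNAs across cohorts, and hazardous/protective
  calls for target genes from five evidence categories.
* **Therapy response** — tertile-based cell-line sensitivity
  categorization, per-drug sensitive/resistant gene calls,
  pansensitive/panresistant summaries over a 21-drug panel with
  mRNA–protein concordance, and radiotherapy-response association.
* **Proliferation** — CRISPR/RNAi dependency-score renormalization that
  pins essential-gene medians to −1 and non-essential to 0 per cell
  line, with significance at a strict −0.5 threshold.
* **Signatures** — up/down gene lists for connectivity-map-style queries
  (plain GRP files) and filtering of connectivity results
  (score > 0.9, p ≤ 0.05).

A seeded synthetic-data module (`sim_spec()`, `gen_expression_cohort()`,
`gen_survival()`, `gen_pharmaco_panel()`, `gen_dependency_screen()`)
generates cohorts with the statistical structure these analyses assume,
so the full pipeline runs and is tested without any external data. See
the methods vignette (`vignettes/mirdx-methods.Rmd`) for the models,
assumptions, and design choices.

## Worked example

```r
library(mirdx)

# a training cohort shaped like the motivating design:
# 87 tumors vs 22 normals, 22 matched pairs, 4-fold planted markers
cohort <- gen_expression_cohort(sim_spec(seed = 1))

stats   <- diff_stats(cohort$expression, cohort$metadata, "unpaired",
                      marker_thresholds(), seed = 1)
markers <- select_markers(stats)
nrow(markers)
#> [1] 20

cl <- hcluster_two(cohort$expression, markers)
evaluate_clusters(cl, cohort$metadata)
#> # A tibble: 1 × 7
#>      tp    fn    tn    fp sensitivity specificity accuracy
#>   <int> <int> <int> <int>       <dbl>       <dbl>    <dbl>
#> 1    87     0    22     0           1           1        1

# nearest-centroid transfer to an independent validation cohort
model <- fit_centroids(cohort$expression, cohort$metadata, markers)
valid <- gen_expression_cohort(sim_spec(seed = 2), baseline = cohort$baseline)
preds <- classify_cohort(valid$expression, model)
head(preds, 3)
#> # A tibble: 3 × 6
#>   sample_id r_tumor r_normal predicted n_features_used flag
#>   <chr>       <dbl>    <dbl> <chr>               <int> <chr>
#> 1 T001        0.938    0.654 tumor                  20 <NA>
#> 2 T002        0.919    0.566 tumor                  20 <NA>
#> 3 T003        0.911    0.662 tumor                  20 <NA>

evaluate_predictions(preds, valid$metadata)
#> # A tibble: 1 × 7
#>      tp    fn    tn    fp sensitivity specificity accuracy
#>   <int> <int> <int> <int>       <dbl>       <dbl>    <dbl>
#> 1    87     0    22     0           1           1        1
```

All 20 planted markers are recovered and both classifiers are perfect at
these planted effect sizes (4-fold, unit log2 noise) — real cohorts sit
closer to the published accuracies in the low-to-mid 90s. The full chain
(survival categorization, pan-calls, dependency profiling, signature
lists) runs from one seed via:

```r
report <- run_pipeline(pipeline_config(seed = 1))
report$signatures$list1$down   # hazardous proliferation genes, list 1
```

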