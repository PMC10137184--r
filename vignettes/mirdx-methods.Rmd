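---
title: "Methods: miRNA diagnostic markers and downstream translational calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA diagnostic markers and downstream translational calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdx)
library(dplyr)
```

## Scope

`mirdx` implements a complete discovery-to-translation workflow for
microRNA diagnostic biomarkers in lung cancer expression cohorts:

1. differential-expression marker selection (fold change + t-test + SAM
   permutation FDR),
2. unsupervised two-group hierarchical clustering and nearest-centroid
   classification with confusion-matrix evaluation,
3. survival-based categorization of miRNAs as putative oncogenes or tumor
   suppressors and of their target genes as hazardous or protective,
4. drug-response calling (per-drug sensitive/resistant/neutral gene calls,
   pansensitive/panresistant summaries with mRNA–protein concordance,
   radiotherapy-response association),
5. dependency-screen normalization and proliferation-gene profiling,
6. construction of up/down gene signature lists for connectivity queries.

Because the cohorts that motivated this design are external microarray,
RNA-seq, and cell-line resources, the package ships a first-class
synthetic-data module that generates cohorts with the statistical
structure those analyses assume. Every stage is exercised and tested
end-to-end on those synthetic cohorts.

## Differential-expression statistics

For a log2 expression matrix with tumor and normal groups the package
computes, per feature:

* the **fold change** $2^{\bar x_T - \bar x_N}$, i.e. the ratio of
  geometric means — the data are log2, so the difference of group means is
  the natural effect scale;
* a **classical pooled-variance t-test** (two-sided), or a one-sample
  t-test on within-pair differences for the paired design;
* the **SAM relative difference** $d_i = (\bar x_{T,i} - \bar x_{N,i}) /
  (s_i + s_0)$, where $s_i$ is the pooled standard error of the mean
  difference and $s_0$ is a fudge factor that stabilizes features with
  small variance. $s_0$ is fixed at the 5th percentile of the per-feature
  $s_i$ distribution, computed once from the observed data and reused for
  permutations, which keeps $d$ exactly antisymmetric under group-label
  exchange.

**Permutation q-values.** Null statistics $d^*$ are generated by
permuting group labels (unpaired) or flipping the signs of pair
differences (paired). The per-feature q-value is

$$q_i = \mathrm{median}_b\,\#\{j : |d^*_{jb}| \ge |d_i|\} \,/\,
        \#\{j : |d_j| \ge |d_i|\},$$

capped at 1 and made non-increasing in $|d_i|$ by a running-maximum pass
in decreasing-$|d|$ order. When the permutation space holds at most
10,000 elements (label assignments or sign patterns) it is enumerated
exhaustively, making q-values exactly reproducible; otherwise a seeded
sample of `n_permutations` (default 1000) is drawn. Counting uses a
relative tolerance of $10^{-9}$ so that structural ties (the identity
permutation reproduces each observed $d_i$) survive floating-point
round-off; the test suite checks exact agreement (within $10^{-9}$) with
a brute-force enumeration oracle on small cohorts.

**Marker gates.** A feature is a diagnostic marker when fold change
exceeds 2 (or falls below 0.5), the t-test p-value is below 0.05, and the
SAM q-value is below 0.05; all three gates are exposed in
`marker_thresholds()`. Selection is monotone in every threshold. Marker
sets from different analysis arms (full cohort unpaired; matched-pair
subset) are merged by `union_marker_sets()`, which merges provenance and
drops features whose direction conflicts between arms. Blood-sample
analyses use the same machinery without the SAM gate (a t-test-only
table simply omits the `sam_q` column).

## Clustering and nearest-centroid classification

Samples are clustered on the marker submatrix with Manhattan distance
and Ward's linkage applied through the Lance–Williams recurrence
directly on the dissimilarities (`hclust` method `"ward.D"`). That
variant is the one that pairs coherently with a non-Euclidean metric;
the tree is cut into exactly two clusters, and each cluster is labeled
with the majority true class of its members (ties labeled tumor). The
confusion report (sensitivity, specificity, accuracy; tumor = positive
class) is produced by `evaluate_clusters()` / `report_from_counts()`.

The supervised classifier computes per-class centroids (per-feature
arithmetic means over all training samples with that label, including
any samples the unsupervised clustering would misplace) and assigns a
new profile to the class whose centroid it has the larger Pearson
correlation with, computed over the intersected feature set. Design
choices: ties predict tumor with a flag (a screening rule that favors
sensitivity; exact ties have measure zero on real data); fewer than
three shared features is refused rather than guessed; zero-variance
profiles return a flagged `NA` prediction. Pearson invariance under
affine transforms of a profile is property-tested.

## Survival machinery

Kaplan–Meier curves, two-group log-rank tests, and univariate Cox fits
on a binary covariate (Breslow tie handling, Wald intervals) are thin
wrappers over the `survival` package; the test suite verifies them
against hand-computed product-limit tables and
observed-minus-expected log-rank arithmetic.

`optimal_cutoff()` implements smallest-p dichotomization: it scans
candidate log2-expression cutoffs, keeps both groups at ≥ 10% of the
cohort, runs a log-rank test at each, and reports the summary at the
p-minimizing cutoff with the hazard ratio from the Cox fit at that
cutoff. **No multiple-testing correction is applied to the scan**, so
the minimum p is anti-conservative by construction; this mirrors the
published selection procedure, is documented rather than "fixed", and
is demonstrated by a null-simulation test (far more than 5% of null
scans reach p < 0.05). The candidate grid is configurable
(`grid_policy = "all"` scans every admissible unique value;
`"quantile"` uses an equally spaced quantile grid — the pipeline uses a
25-point grid for speed). A minimum cohort of 20 subjects is required.

A miRNA is categorized **oncogenic** when every required cohort (LUAD,
LUSC, and the pooled NSCLC cohort) yields HR > 1 at p < 0.05 from the
optimal-cutoff dichotomy *and* the miRNA is over-expressed in tumors;
**suppressive** is the mirror. The all-cohorts-required reading of
"concordant" is the default; a majority policy is config-selectable.
Target genes are called **hazardous**/**protective** when at least two
of five evidence categories (tumor-vs-normal differential expression
plus univariate survival in four cohorts) agree in direction with no
contradicting category; the 3^5 evidence truth table is enumerated in
tests and the two calls are mutually exclusive by construction.

## Drug response, radiotherapy, and dependency screens

Cell lines are categorized per (drug, source, measure) stratum by
**tertiles** of the response value (lower third sensitive for IC50-type
measures, upper third resistant, middle excluded; ties broken
deterministically by cell-line id; all-tied or < 6-line strata are
wholly excluded). The tertile rule is a deterministic, scale-free
stand-in for the categorization of the original screens and is
config-replaceable by fixed thresholds.

Per drug, a gene/miRNA is **sensitive** (resp. **resistant**) when its
expression is significantly higher (two-sample t-test, p < 0.05) in
sensitive (resp. resistant) lines; several strata for one drug are
evaluated separately and opposite calls veto to neutral. An id is
**pansensitive** over the 21-drug panel when, within every required
layer, it has at least one sensitive call and no resistant call for any
drug; genes require the mRNA and protein layers to agree independently,
miRNAs use their own layer. The literal "lack of resistance to all
drugs" reading would make every all-neutral gene pansensitive, so the
≥ 1-sensitive-call floor is imposed; the pan-call truth table is
enumerated in tests (mutual exclusivity; removing a drug never turns
pansensitive into panresistant).

**Radiotherapy association** compares expression between long-survival
(> 58 months) and short-survival (< 20 months) stage III/IV patients who
received radiotherapy; both intervals are open, so boundary patients are
excluded.

**Dependency screens** are renormalized per cell line by the unique
affine map sending the median raw effect of essential anchor genes to
−1 and of non-essential anchors to 0; medians are affine-equivariant, so
the anchor invariants hold exactly (asserted to $10^{-9}$). A normalized
score strictly below −0.5 is a significant knockout effect (a score of
exactly −0.5 is not). Genes are profiled by the fraction of lines
affected per assay: `both_major` (> 50% in both CRISPR and RNAi),
`either_major` (> 50% in at least one), `none_significant` (no affected
line in either), else `other`.

## Signature lists

`build_cmap_lists()` combines prognostic calls with proliferation
profiles into two up/down list pairs: list 1 up = protective genes
affected in < 50% of lines in both assays, list 1 down = hazardous genes
affected in > 50% in both; list 2 up = protective genes with no affected
line in either assay, list 2 down = hazardous genes affected in > 50% in
at least one. Genes with a `neither` prognostic call never enter a list;
up and down lists are disjoint by construction. Lists are written as
plain one-symbol-per-line GRP files; connectivity results from an
external query are filtered at score > 0.9 (strict) and p ≤ 0.05
(inclusive).

## The synthetic-data module

The generators define the study conditions under which the pipeline is
tested; their defaults were chosen once, to match the published designs
or — where unpublished — standard conventions in this field:

* **Expression cohorts** (`gen_expression_cohort()`): 87 tumor vs 22
  normal samples with 22 matched pairs; 200 features with 10 planted up
  and 10 planted down at 2 log2 units (4-fold); i.i.d. Gaussian noise
  with SD 1 on the log2 scale (arrays were quantile-normalized and
  log-transformed; Gaussian is the simplest matching assumption; the
  source arrays publish no per-miRNA variance estimates, so unit SD is a
  synthetic convention). Per-feature baselines are drawn N(7, 4) and can
  be reused across cohorts to emulate an independent validation cohort on
  the same platform biology. Matched pairs share a sample-level Gaussian
  intercept (SD = noise/2) so paired analyses gain power.
* **Survival** (`gen_survival()`): exponential proportional hazards with
  baseline median 30 months; linear predictor = coefficient × centered
  driver expression (coefficients may differ in sign across drivers, so
  hazardous and protective drivers can coexist); censoring is independent
  uniform-administrative with the horizon solved numerically to hit the
  requested censoring fraction — this keeps the log-rank null exact.
* **Drug panels** (`gen_pharmaco_panel()`): ln(IC50)-style responses with
  a strong per-line general-sensitivity factor (inter-drug correlation
  0.85). This factor is essential, not cosmetic: with independent drug
  responses, 21 tests at α = 0.05 put the probability that a null gene
  collects at least one sensitive and no resistant call near its
  maximum, and no procedure faithful to the published thresholds would
  keep false pan-calls rare. Real log-IC50 panels are dominated by broad
  multidrug sensitivity differences between lines, which collapses the
  effective multiplicity; under that structure unlinked genes are called
  `neither` in ≳ 90% of seeds while planted linked genes are recovered
  essentially always. Unlinked genes' protein values track mRNA with
  correlation 0.4 (typical steady-state coupling); linked genes share the
  response component across layers (correlation ≈ 0.9, above the 0.7
  design floor). The protein layer is mean-centered per gene.
* **Dependency screens** (`gen_dependency_screen()`): essential anchors
  at true effect −1, non-essential at 0, dependent genes at −1 in an
  exact planted fraction of lines; per-line random gain (0.7–1.4) and
  offset make the anchor renormalization non-trivial; noise SD 0.15.

What the generators deliberately do **not** emulate: probe chemistry and
detection thresholds, quantile-normalization internals, platform batch
effects, correlated miRNA families, non-proportional hazards, and
dose-response curve shapes (IC50/EC50 values are treated as given).
Passing tests therefore demonstrate correctness of the statistical
machinery and the end-to-end plumbing under the assumed generative
structure, not performance on real cohorts.

## Pipeline, problem sizes, and determinism

`run_pipeline(pipeline_config(seed = ...))` executes simulate → markers
→ cluster → classify → survival → prognostic genes → pharmaco →
dependency → signatures, each stage feeding the next; stages whose
configuration is `NULL` are skipped with an explicit notice. All
randomness flows from the single master seed through per-stage derived
seeds, so stages are independently reproducible and two runs with the
same configuration produce byte-identical report bundles (asserted in
tests). Output files carry a header with package version, seed, and a
configuration hash.

Default problem sizes — 200 features × 109 samples for the expression
cohorts, 150 subjects per survival cohort with a 25-point quantile
cutoff grid, a 94-line × 21-drug panel, and 50-line dependency screens —
were chosen so a full pipeline run completes in seconds while keeping
every test (planted-marker recovery, HR recovery within 2 SE,
pan-call recovery) comfortably powered.

## Known limitations

* The optimal-cutoff scan is intentionally anti-conservative (see
  above); its p-values should be read as selection scores, not calibrated
  error rates.
* The tertile sensitivity categorization is a stand-in for the original
  screens' unpublished rule; conclusions that depend on the exact
  sensitive/resistant boundary should be checked under the fixed-threshold
  method as well.
* Nearest-centroid transfer across platforms assumes shared per-feature
  baselines; strong platform shifts would need renormalization upstream.
* The connectivity scoring itself is external: the package builds query
  lists and filters result tables, nothing more.
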