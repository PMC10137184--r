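Package: mirdx
Title: miRNA Diagnostic Marker Discovery and Translational Analysis for
    Lung Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for microRNA
    diagnostic-marker discovery in tumor versus normal expression cohorts
    and its downstream translational analyses. Implements SAM-style
    permutation statistics with fold-change and t-test gates for marker
    selection, unsupervised Ward/Manhattan two-group clustering and
    nearest-centroid classification with confusion-matrix evaluation,
    optimal-cutoff survival dichotomization with Kaplan-Meier/log-rank and
    univariate Cox summaries for oncogene/suppressor categorization,
    pansensitive/panresistant drug-response calling with mRNA-protein
    concordance, CRISPR/RNAi dependency-score normalization against
    essential and non-essential anchor genes, and construction of up/down
    gene signature lists for connectivity queries. A seeded synthetic-data
    module generates cohorts with the statistical structure the analyses
    assume, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
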