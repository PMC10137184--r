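test_that("two-group t statistics match hand computation and trivial cases", {
  x <- rbind(a = c(1, 2, 3, 3, 4, 5),       # t = -2.449, p ~ 0.0705
             b = c(1, 2, 3, 1, 2, 3),       # identical groups
             c = c(3, 3.1, 2.9, 1, 1.1, 0.9))  # log2 means 3 vs 1 -> FC = 4
  colnames(x) <- c("T1", "T2", "T3", "N1", "N2", "N3")
  md <- toy_metadata(x)
  st <- two_group_stats(x, md)
  expect_equal(st$t_stat[1], -2.449, tolerance = 1e-3)
  expect_equal(st$t_p[1], 0.0705, tolerance = 1e-3)
  expect_equal(st$fold_change[2], 1)
  expect_equal(st$t_p[2], 1)
  expect_equal(st$fold_change[3], 2^st$mean_log2_diff[3])
  expect_equal(st$fold_change[3], 4)
})

test_that("paired design uses within-pair differences and validates pairs", {
  x <- make_toy_matrix(n_features = 4, tumor = 3, normal = 3, shift_first = 2)
  md <- toy_metadata(x)
  md$pair_id <- c("p1", "p2", "p3", "p1", "p2", "p3")
  stp <- two_group_stats(x, md, design = "paired")
  expect_equal(stp$df[1], 2)
  expect_identical(unique(stp$design), "paired")
  md_bad <- md; md_bad$pair_id[4] <- "p9"
  expect_error(two_group_stats(x, md_bad, design = "paired"), "p1")
  expect_error(two_group_stats(x[, 1:3], md[1:3, ]), ">= 2 samples")
})

test_that("SAM degenerate and symmetry contracts hold", {
  x <- make_toy_matrix(n_features = 6, tumor = 3, normal = 3, seed = 1)
  # equal group means everywhere: mirror tumor values into normal columns
  x[, 4:6] <- x[, 1:3]
  md <- toy_metadata(x)
  th <- marker_thresholds(n_permutations = 100)
  s <- sam_stats(x, md, thresholds = th)
  expect_true(all(s$sam_d == 0))
  expect_true(all(s$sam_q == 1))
  # label swap negates d, leaves q unchanged (exhaustive permutations)
  y <- make_toy_matrix(n_features = 8, tumor = 4, normal = 4, seed = 7,
                       shift_first = 3)
  mdy <- toy_metadata(y)
  mdy_sw <- mdy; mdy_sw$class_label <- ifelse(mdy$class_label == "tumor",
                                              "normal", "tumor")
  s1 <- sam_stats(y, mdy, thresholds = th)
  s2 <- sam_stats(y, mdy_sw, thresholds = th)
  expect_true(all(s1$exhaustive))
  expect_equal(s1$sam_d, -s2$sam_d)
  expect_equal(s1$sam_q, s2$sam_q)
  expect_error(sam_stats(y, mdy, thresholds = marker_thresholds(n_permutations = 5)),
               "n_permutations")
})

test_that("SAM q-values equal the exhaustive-permutation oracle", {
  for (seed in 1:3) {
    x <- make_toy_matrix(n_features = 12, tumor = 4, normal = 4, seed = seed,
                         shift_first = 2.5)
    md <- toy_metadata(x)
    got <- sam_stats(x, md, thresholds = marker_thresholds(n_permutations = 100))
    ora <- sam_oracle(x, colnames(x)[1:4], colnames(x)[5:8])
    expect_true(all(got$exhaustive))
    expect_lt(max(abs(got$sam_d - ora$d)), 1e-9)
    expect_lt(max(abs(got$sam_q - ora$q)), 1e-9)
  }
})

test_that("marker gates apply fold-change, p, and FDR thresholds", {
  stats <- tibble::tibble(
    feature_id = c("keep_up", "fc_gate", "fdr_gate", "keep_down", "p_gate"),
    fold_change = c(2.5, 1.8, 3.0, 0.3, 4.0),
    mean_log2_diff = log2(c(2.5, 1.8, 3.0, 0.3, 4.0)),
    t_p = c(0.01, 0.001, 0.04, 0.002, 0.2),
    sam_q = c(0.01, 0.001, 0.06, 0.01, 0.01)
  )
  got <- select_markers(stats)
  expect_identical(got$feature_id, c("keep_up", "keep_down"))
  expect_identical(got$direction, c("up", "down"))
  # without a sam_q column (t-test-only analysis) the FDR gate is skipped
  got2 <- select_markers(stats[setdiff(names(stats), "sam_q")])
  expect_true("fdr_gate" %in% got2$feature_id)
})

test_that("marker selection is monotone in every threshold", {
  set.seed(99)
  stats <- tibble::tibble(
    feature_id = sprintf("f%02d", 1:60),
    mean_log2_diff = rnorm(60, sd = 1.5),
    t_p = runif(60), sam_q = runif(60)
  )
  stats$fold_change <- 2^stats$mean_log2_diff
  base <- select_markers(stats, marker_thresholds())
  relaxed <- list(
    marker_thresholds(fc_up = 1.5, fc_down = 0.5),
    marker_thresholds(fc_up = 2, fc_down = 0.7),
    marker_thresholds(alpha = 0.2),
    marker_thresholds(fdr = 0.2)
  )
  for (th in relaxed) {
    expect_true(all(base$feature_id %in% select_markers(stats, th)$feature_id))
  }
})

test_that("marker-set union reproduces printed set arithmetic and properties", {
  ids_a <- sprintf("m%02d", 1:66)
  ids_b <- c(sprintf("m%02d", 1:51), sprintf("x%02d", 1:7))   # overlap 51
  a <- tibble::tibble(feature_id = ids_a, direction = "up",
                      provenance = "unpaired_cohort")
  b <- tibble::tibble(feature_id = ids_b, direction = "up",
                      provenance = "paired_cohort")
  u <- union_marker_sets(a, b)
  expect_equal(nrow(u), 73)
  expect_equal(sum(u$provenance == "paired_cohort,unpaired_cohort"), 51)
  expect_identical(union_marker_sets(a, a)$feature_id, a$feature_id)
  dis <- union_marker_sets(a[1:3, ], b[52:55, ])
  expect_equal(nrow(dis), 7)
  # inclusion-exclusion for direction-consistent inputs
  expect_equal(nrow(u), nrow(a) + nrow(b) - 51)
  # conflicting direction is excluded with a warning
  b_conf <- b; b_conf$direction[1] <- "down"
  expect_warning(u2 <- union_marker_sets(a, b_conf), "conflicting")
  expect_false(ids_b[1] %in% u2$feature_id)
  expect_equal(nrow(u2), 72)
})

test_that("histology profiles flag consistency and degenerate subgroups", {
  set.seed(5)
  n <- c(NSCLC = 10, SCLC = 4, carcinoid = 2, normal = 8)
  labels <- rep(names(n), n)
  ids <- sprintf("s%02d", seq_along(labels))
  x <- matrix(rnorm(2 * length(ids), mean = 5, sd = 0.4), nrow = 2,
              dimnames = list(c("up_all", "noisy"), ids))
  x["up_all", labels != "normal"] <- x["up_all", labels != "normal"] + 3
  x["noisy", labels == "carcinoid"] <- c(2, 12)   # tiny, high-variance group
  md <- tibble::tibble(sample_id = ids,
                       class_label = ifelse(labels == "normal", "normal", "tumor"),
                       histology = labels)
  prof <- histology_profile(x, md, c("up_all", "noisy"))
  expect_equal(nrow(prof), 6)
  sm <- histology_summary(prof)
  expect_identical(sm$pattern[sm$feature_id == "up_all"],
                   "consistently over-expressed")
  noisy_carc <- prof[prof$feature_id == "noisy" & prof$histology == "carcinoid", ]
  expect_false(noisy_carc$significant)
  # absent histology omitted with warning; missing normals are an error
  expect_warning(histology_profile(x, md[md$histology != "SCLC", ], "up_all"),
                 "SCLC")
  expect_error(histology_profile(x, md[md$histology != "normal", ], "up_all"),
               "normal")
})
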