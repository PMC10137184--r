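test_that("Kaplan-Meier estimator matches hand-computed product-limit tables", {
  # all censored: curve stays at 1
  km0 <- km_curve(c(3, 6, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(km0$surv == 1))
  # two subjects, events at 1 and 2
  km2 <- km_curve(c(1, 2), c(TRUE, TRUE))
  expect_equal(km2$surv, c(0.5, 0))
  # six-subject worksheet: times 5, 8, 8, 12, 16+, 20
  km6 <- km_curve(c(5, 8, 8, 12, 16, 20), c(1, 1, 1, 1, 0, 1))
  expect_equal(km6$surv[km6$time == 5], 5 / 6)
  expect_equal(km6$surv[km6$time == 8], 0.5)
  expect_equal(km6$surv[km6$time == 12], 1 / 3, tolerance = 1e-12)
  expect_equal(km6$surv[km6$time == 20], 0)
  expect_true(all(diff(km6$surv) <= 0))
  expect_error(km_curve(numeric(0), logical(0)), "empty")
})

test_that("log-rank matches the observed-minus-expected oracle", {
  # toy 3-vs-3 all-event data, frozen hand value
  lr <- logrank(c(1, 3, 5, 2, 4, 6), rep(TRUE, 6), rep(c("a", "b"), each = 3))
  expect_equal(lr$chi2, 0.4848763, tolerance = 1e-6)
  expect_equal(lr$chi2,
               oe_logrank_oracle(c(1, 3, 5), c(1, 1, 1), c(2, 4, 6), c(1, 1, 1)),
               tolerance = 1e-9)
  # identical groups: chi2 = 0, p = 1
  lr0 <- logrank(rep(c(2, 4, 7), 2), rep(TRUE, 6), rep(c("a", "b"), 3))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # label swap leaves chi2 unchanged
  g <- rep(c("a", "b"), each = 4)
  tt <- c(1, 2, 3, 9, 4, 5, 6, 7)
  expect_equal(logrank(tt, rep(TRUE, 8), g)$chi2,
               logrank(tt, rep(TRUE, 8), rev(g))$chi2, tolerance = 1e-9)
  expect_error(logrank(tt, rep(TRUE, 8), rep("a", 8)), "two")
  # oracle agreement on random censored data
  set.seed(12)
  for (i in 1:5) {
    n <- 30
    tm <- round(rexp(n, 0.1), 2); ev <- rbinom(n, 1, 0.8)
    grp <- rep(c("a", "b"), each = n / 2)
    expect_equal(logrank(tm, ev, grp)$chi2,
                 oe_logrank_oracle(tm[grp == "a"], ev[grp == "a"],
                                   tm[grp == "b"], ev[grp == "b"]),
                 tolerance = 1e-8)
  }
})

test_that("binary Cox fits obey coding symmetry and degenerate contracts", {
  tm <- rep(c(2, 4, 7, 9), 2); ev <- rep(TRUE, 8)
  g <- rep(c("a", "b"), each = 4)   # identical survival in both groups
  fit <- cox_binary(tm, ev, g)
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  set.seed(4)
  tm2 <- rexp(40, 0.1); g2 <- rep(c("a", "b"), 20)
  f1 <- cox_binary(tm2, rep(TRUE, 40), factor(g2, levels = c("a", "b")))
  f2 <- cox_binary(tm2, rep(TRUE, 40), factor(g2, levels = c("b", "a")))
  expect_equal(f1$hr, 1 / f2$hr, tolerance = 1e-8)
  expect_error(cox_binary(tm, rep(FALSE, 8), g), "no events")
})

test_that("log-rank and Cox p-values rank datasets consistently", {
  set.seed(8)
  ps <- t(vapply(1:60, function(i) {
    n <- 40
    g <- rep(c(0, 1), each = n / 2)
    beta <- runif(1, 0, 1.2)
    tm <- rexp(n, 0.05 * exp(beta * g))
    c(logrank(tm, rep(TRUE, n), g)$p,
      cox_binary(tm, rep(TRUE, n), factor(g))$p)
  }, numeric(2)))
  expect_gt(cor(ps[, 1], ps[, 2], method = "spearman"), 0.9)
})

test_that("optimal cutoff recovers a planted dichotomy", {
  set.seed(31)
  recovered <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 120
    expr <- rnorm(n, 6, 1)
    grp_high <- expr > 6
    tm <- rexp(n, 0.02 * ifelse(grp_high, 3, 1))
    s_out <- optimal_cutoff(expr, tm, rep(TRUE, n))
    s_out$cutoff
  }, numeric(1))
  expect_lt(abs(median(recovered) - 6), 0.35)
  # the recovered dichotomy carries hr > 1 for the high group
  set.seed(2)
  n <- 150; expr <- rnorm(n, 6, 1)
  tm <- rexp(n, 0.02 * ifelse(expr > 6, 3, 1))
  s_out <- optimal_cutoff(expr, tm, rep(TRUE, n))
  expect_gt(s_out$hr, 1.5)
  expect_equal(s_out$n_high + s_out$n_low, n)
})

test_that("optimal cutoff refuses degenerate inputs", {
  expect_error(optimal_cutoff(rnorm(10), rexp(10), rep(TRUE, 10)), ">= 20")
  expect_error(optimal_cutoff(rep(1, 30), rexp(30), rep(TRUE, 30)),
               "admissible")
})

test_that("null min-p scans are anti-conservative, as documented", {
  minps <- vapply(1:30, function(s) {
    set.seed(s + 500)
    n <- 60
    optimal_cutoff(rnorm(n), rexp(n, 0.05), rep(TRUE, n))$logrank_p
  }, numeric(1))
  # far more than the nominal 5% of null scans reach p < 0.05
  expect_gt(mean(minps < 0.05), 0.15)
})

test_that("miRNA categorization requires concordant significant cohorts", {
  onc <- tibble::tibble(cohort = c("LUAD", "LUSC", "NSCLC"),
                        hr = c(1.6, 1.4, 1.5), p = c(0.01, 0.02, 0.001))
  expect_identical(categorize_mirna(onc, "up")$category, "oncogenic")
  sup <- tibble::tibble(cohort = c("LUAD", "LUSC", "NSCLC"),
                        hr = c(0.5, 0.6, 0.55), p = c(0.01, 0.02, 0.001))
  expect_identical(categorize_mirna(sup, "down")$category, "suppressive")
  # direction contradiction: up in tumors but protective hazard
  expect_identical(categorize_mirna(sup, "up")$category, "neither")
  # one non-significant cohort breaks the all-required policy
  onc2 <- onc; onc2$p[2] <- 0.2
  expect_identical(categorize_mirna(onc2, "up")$category, "neither")
  expect_identical(categorize_mirna(onc2, "up", concordance = "majority")$category,
                   "oncogenic")
  miss <- categorize_mirna(onc[1:2, ], "up")
  expect_identical(miss$category, "neither")
  expect_identical(miss$flag, "insufficient evidence")
})

test_that("prognostic gene calls match the truth-table oracle on all 3^5 inputs", {
  levels <- c("hazardous", "protective", "none")
  grid <- expand.grid(rep(list(levels), 5), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    ev <- unlist(grid[i, ], use.names = FALSE)
    got <- prognostic_gene_call(ev)$category
    expect_identical(got, prognostic_oracle(ev))
  }
  # mutual exclusivity is structural: no evidence vector yields both calls
  calls <- apply(grid, 1, function(ev) prognostic_gene_call(ev)$category)
  expect_true(all(calls %in% c("hazardous", "protective", "neither")))
  expect_identical(prognostic_gene_call(c("hazardous", "hazardous", NA, NA, NA))$category,
                   "hazardous")
  expect_identical(prognostic_gene_call(c("hazardous", rep("none", 4)))$category,
                   "neither")
  expect_identical(prognostic_gene_call(c("hazardous", "hazardous", "protective",
                                          "none", "none"))$category, "neither")
})
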