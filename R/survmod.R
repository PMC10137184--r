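#' Kaplan-Meier product-limit curve
#'
#' Thin wrapper over [survival::survfit()] returning the step function as a
#' tidy table. The estimator starts at 1, is right-continuous and
#' non-increasing.
#'
#' @param times Follow-up times (>= 0), in months.
#' @param events Logical (or 0/1) event indicators.
#' @return A `mirdx_km` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) stop_mirdx("empty survival input")
  if (any(times < 0)) stop_mirdx("times must be >= 0")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, surv = fit$surv)
  class(out) <- c("mirdx_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank statistic with a 1-df chi-square p-value,
#' via [survival::survdiff()].
#'
#' @param times,events Survival outcome vectors.
#' @param group Two-level grouping vector.
#' @return One-row tibble: `chi2`, `p`, `n1`, `n2`.
#' @export
logrank <- function(times, events, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2) stop_mirdx("log-rank requires exactly two non-empty groups")
  fit <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ g)
  tibble(chi2 = unname(fit$chisq), p = pchisq(fit$chisq, df = 1, lower.tail = FALSE),
         n1 = unname(fit$n[1]), n2 = unname(fit$n[2]))
}

#' Univariate Cox fit on a binary covariate
#'
#' Partial-likelihood fit (Breslow ties) of a single binary covariate, with
#' Wald confidence interval and p-value. The hazard ratio is for the second
#' factor level versus the first (e.g. high versus low expression).
#'
#' @param times,events Survival outcome vectors.
#' @param group Two-level grouping; the HR is level 2 vs level 1.
#' @return One-row tibble: `hr`, `hr_lo`, `hr_hi`, `p`.
#' @export
cox_binary <- function(times, events, group) {
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2) stop_mirdx("cox_binary requires exactly two non-empty groups")
  if (sum(events) == 0) stop_mirdx("no events: hazard ratio unidentifiable")
  fit <- survival::coxph(survival::Surv(times, as.integer(events)) ~ g,
                         ties = "breslow")
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  tibble(hr = exp(beta), hr_lo = exp(beta - 1.96 * se),
         hr_hi = exp(beta + 1.96 * se),
         p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Optimal-cutoff survival dichotomization
#'
#' Scans candidate log2-expression cutoffs (the unique observed values that
#' leave at least `min_group_frac` of the cohort on each side), runs a
#' log-rank test at each, and returns the summary at the p-minimizing
#' cutoff, with the hazard ratio (high vs low) from [cox_binary()] at that
#' cutoff. The minimum p over the scan is anti-conservative by construction
#' (no multiple-testing correction is applied, matching the smallest-p
#' selection procedure); `n_candidates` is reported so downstream readers
#' can see the size of the scan.
#'
#' @param expression Per-sample expression values (log2).
#' @param times,events Survival outcome vectors, aligned with `expression`.
#' @param grid_policy `"all"` (default) scans every admissible unique
#'   expression value; `"quantile"` scans `n_grid` equally spaced quantiles
#'   of the admissible range (a coarser, faster grid for large cohorts).
#' @param n_grid Number of candidate cutoffs under the quantile policy.
#' @param min_group_frac Minimum fraction of the cohort in each group
#'   (default 0.10).
#' @param min_n Minimum cohort size (default 20).
#' @return One-row tibble: `cutoff`, `n_high`, `n_low`, `logrank_chi2`,
#'   `logrank_p`, `hr`, `hr_lo`, `hr_hi`, `n_candidates`.
#' @export
optimal_cutoff <- function(expression, times, events,
                           grid_policy = c("all", "quantile"), n_grid = 50,
                           min_group_frac = 0.10, min_n = 20) {
  grid_policy <- match.arg(grid_policy)
  n <- length(expression)
  stopifnot(length(times) == n, length(events) == n)
  keep <- !is.na(expression) & !is.na(times) & !is.na(events)
  expression <- expression[keep]; times <- times[keep]; events <- events[keep]
  n <- length(expression)
  if (n < min_n) stop_mirdx(sprintf("need >= %d subjects with survival data", min_n))
  cuts <- sort(unique(expression))
  if (grid_policy == "quantile" && length(cuts) > n_grid) {
    cuts <- sort(unique(quantile(expression, probs = seq(0, 1, length.out = n_grid),
                                 type = 7, names = FALSE)))
  }
  min_k <- ceiling(min_group_frac * n)
  admissible <- vapply(cuts, function(cc) {
    nh <- sum(expression > cc)
    nh >= min_k && (n - nh) >= min_k
  }, logical(1))
  cuts <- cuts[admissible]
  if (length(cuts) == 0) stop_mirdx("no admissible cutoff (constant or near-constant expression)")
  scans <- purrr::map(cuts, function(cc) {
    lr <- logrank(times, events, expression > cc)
    tibble(cutoff = cc, chi2 = lr$chi2, p = lr$p)
  }) %>% bind_rows()
  best <- scans[which.min(scans$p), ]
  grp <- factor(ifelse(expression > best$cutoff, "high", "low"),
                levels = c("low", "high"))
  cox <- cox_binary(times, events, grp)
  tibble(cutoff = best$cutoff,
         n_high = sum(expression > best$cutoff),
         n_low = sum(expression <= best$cutoff),
         logrank_chi2 = best$chi2, logrank_p = best$p,
         hr = cox$hr, hr_lo = cox$hr_lo, hr_hi = cox$hr_hi,
         n_candidates = nrow(scans))
}

#' Categorize a miRNA as oncogenic, suppressive, or neither
#'
#' A miRNA is called oncogenic when, in every required cohort, the
#' optimal-cutoff dichotomy gives hazard ratio > 1 with p < 0.05 and the
#' miRNA is over-expressed in tumors; suppressive is the mirror case
#' (HR < 1 everywhere significant, under-expressed in tumors). Anything
#' else — including missing cohort evidence — is neither.
#'
#' @param evidence Tibble with one row per cohort: `cohort`, `hr`, `p`.
#' @param tumor_direction `"up"` or `"down"`: the miRNA's direction in
#'   tumors versus normal tissue.
#' @param required_cohorts Cohort ids that must all concur (default LUAD,
#'   LUSC and the pooled NSCLC cohort).
#' @param concordance `"all"` (default) requires every cohort to concur;
#'   `"majority"` requires more than half.
#' @param alpha Significance level for each cohort's p-value.
#' @return One-row tibble: `category`, `n_cohorts`, `flag`.
#' @export
categorize_mirna <- function(evidence, tumor_direction,
                             required_cohorts = c("LUAD", "LUSC", "NSCLC"),
                             concordance = c("all", "majority"),
                             alpha = 0.05) {
  concordance <- match.arg(concordance)
  evidence <- as_tibble(evidence)
  ev <- evidence[match(required_cohorts, evidence$cohort), ]
  if (any(is.na(ev$hr)) || any(is.na(ev$p))) {
    return(tibble(category = "neither", n_cohorts = sum(!is.na(ev$hr)),
                  flag = "insufficient evidence"))
  }
  need <- if (concordance == "all") length(required_cohorts) else
    floor(length(required_cohorts) / 2) + 1
  onc <- sum(ev$hr > 1 & ev$p < alpha) >= need && tumor_direction == "up"
  sup <- sum(ev$hr < 1 & ev$p < alpha) >= need && tumor_direction == "down"
  tibble(category = if (onc) "oncogenic" else if (sup) "suppressive" else "neither",
         n_cohorts = nrow(ev), flag = NA_character_)
}

#' Prognostic gene call from five evidence categories
#'
#' A gene is hazardous when at least two of the five evidence categories
#' (tumor-vs-normal differential expression plus univariate survival in
#' four cohorts) point in the hazardous direction and none points in the
#' protective direction; protective is the mirror; any contradiction or
#' fewer than two supporting categories gives neither.
#'
#' @param evidence Character vector (length <= 5) with entries
#'   `"hazardous"`, `"protective"`, or `"none"`/`NA` per category.
#' @return One-row tibble: `category`, `n_supporting`.
#' @export
prognostic_gene_call <- function(evidence) {
  ev <- evidence[!is.na(evidence)]
  n_h <- sum(ev == "hazardous"); n_p <- sum(ev == "protective")
  category <- if (n_h >= 2 && n_p == 0) "hazardous"
  else if (n_p >= 2 && n_h == 0) "protective"
  else "neither"
  tibble(category = category, n_supporting = max(n_h, n_p))
}

#' Kaplan-Meier step plot
#'
#' @param object A `mirdx_km` tibble from [km_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mirdx_km
#' @export
autoplot.mirdx_km <- function(object, ...) {
  steps <- bind_rows(tibble(time = 0, surv = 1),
                     tibble(time = object$time, surv = object$surv))
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability") +
    ggplot2::theme_minimal()
}
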