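# Statistical procedure: QC filtering, normality-gated paired tests,
# linear models of index vs. covariates, and age-stratified percentile
# reference intervals.

#' Standardized test-result record
#' @param test_name One of `paired_t`, `wilcoxon_signed_rank`, `ols_t`,
#'   `anova_F`.
#' @param estimate Point estimate.
#' @param ci_lo,ci_hi 95% confidence bounds (NA when undefined).
#' @param p_value Two-sided p-value.
#' @param n Sample size used.
#' @return One-row data.frame of class `stat_result`.
#' @export
stat_result <- function(test_name, estimate, ci_lo = NA_real_,
                        ci_hi = NA_real_, p_value = NA_real_, n = NA_integer_) {
  if (!test_name %in% c("paired_t", "wilcoxon_signed_rank", "ols_t", "anova_F"))
    stop_param("unknown test_name: ", test_name)
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop_param("p_value outside [0, 1]")
  out <- data.frame(test_name = test_name, estimate = estimate,
                    ci_lo = ci_lo, ci_hi = ci_hi, p_value = p_value, n = n)
  class(out) <- c("stat_result", class(out))
  out
}

#' Remove donors failing the hypochromic-RBC screen
#'
#' Donors with >= 5% hypochromic red cells (a sign of iron deficiency) are
#' removed and reported.
#'
#' @param cohort data.frame with a `hypochromic_pct` column.
#' @param threshold Exclusion threshold (percent).
#' @return List with `cohort` (surviving rows) and `flags` (data.frame of
#'   removed donors with the reason).
#' @export
qc_filter <- function(cohort, threshold = 5) {
  if (!"hypochromic_pct" %in% names(cohort))
    stop_format("qc_filter: cohort lacks a hypochromic_pct column")
  drop <- !is.na(cohort$hypochromic_pct) & cohort$hypochromic_pct >= threshold
  flags <- if (any(drop)) {
    data.frame(donor_id = if (!is.null(cohort$donor_id)) cohort$donor_id[drop]
               else which(drop),
               hypochromic_pct = cohort$hypochromic_pct[drop],
               reason = "HYPOCHROMIC_GE_5PCT")
  } else {
    data.frame(donor_id = character(0), hypochromic_pct = numeric(0),
               reason = character(0))
  }
  list(cohort = cohort[!drop, , drop = FALSE], flags = flags)
}

#' Choose between paired t and Wilcoxon signed-rank by a Shapiro-Wilk gate
#'
#' The Shapiro-Wilk test is applied to the paired differences `x - y`; if
#' its p-value is at least `alpha` the parametric paired t-test is chosen,
#' otherwise the Wilcoxon signed-rank test. Constant differences make the
#' gate undecidable and fall back to the rank test with a warning.
#'
#' @param x,y Paired numeric vectors (equal length >= 4).
#' @param alpha Gate level.
#' @return `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @export
choose_paired_test <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop_param("x and y must be paired (equal length)")
  if (length(x) < 4)
    stop_param("insufficient data: need at least 4 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    warning("constant paired differences: normality gate undecidable, using wilcoxon_signed_rank")
    return("wilcoxon_signed_rank")
  }
  if (stats::shapiro.test(d)$p.value >= alpha) "paired_t" else "wilcoxon_signed_rank"
}

#' Normality-gated paired comparison
#'
#' Runs the test selected by [choose_paired_test()] on the pairs, oriented
#' as `x - y`. The estimate is the mean difference for the t-test and the
#' Hodges-Lehmann median difference for the signed-rank test.
#'
#' @param x,y Paired numeric vectors.
#' @param alpha Shapiro-Wilk gate level.
#' @param force Optionally force `"paired_t"` or `"wilcoxon_signed_rank"`,
#'   bypassing the gate.
#' @return A [stat_result()] row.
#' @export
paired_compare <- function(x, y, alpha = 0.05, force = NULL) {
  d <- x - y
  if (all(d == 0)) {
    return(stat_result("wilcoxon_signed_rank", estimate = 0, ci_lo = 0,
                       ci_hi = 0, p_value = 1, n = length(d)))
  }
  if (stats::sd(d) == 0) {
    # exactly constant nonzero shift: the t statistic degenerates; report
    # the exact shift with the sign-test p-value (2 / 2^n, all signs equal)
    test <- force %||% suppressWarnings(choose_paired_test(x, y, alpha))
    return(stat_result(test, estimate = d[1], ci_lo = d[1], ci_hi = d[1],
                       p_value = if (test == "paired_t") 0
                                 else min(1, 2 / 2^length(d)),
                       n = length(d)))
  }
  test <- force %||% choose_paired_test(x, y, alpha)
  if (test == "paired_t") {
    tt <- stats::t.test(x, y, paired = TRUE)
    stat_result("paired_t", estimate = unname(tt$estimate),
                ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
                p_value = tt$p.value, n = length(d))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              conf.int = TRUE))
    stat_result("wilcoxon_signed_rank", estimate = unname(wt$estimate),
                ci_lo = wt$conf.int[1], ci_hi = wt$conf.int[2],
                p_value = wt$p.value, n = length(d))
  }
}

#' Linear model of a Lorrca index on donor covariates
#'
#' Ordinary least squares of the index on the covariates (main effects
#' only; `gender` is coded as a two-level factor), with per-coefficient
#' t-tests and the overall ANOVA F-test.
#'
#' @param cohort data.frame holding the index and covariate columns.
#' @param index_name Column to model (e.g. `"o_hyper"`).
#' @param covariates Character vector of covariate columns.
#' @return List with `coefficients` (data.frame, one [stat_result()] row
#'   per model coefficient, intercept excluded), `model_f` (the overall F
#'   as a `stat_result`), and `fit` (the underlying `lm`).
#' @export
fit_index_model <- function(cohort, index_name, covariates = c("age", "gender")) {
  missing_cols <- setdiff(c(index_name, covariates), names(cohort))
  if (length(missing_cols))
    stop_format("fit_index_model: missing columns: ",
                paste(missing_cols, collapse = ", "))
  if (nrow(cohort) <= length(covariates) + 2)
    stop_param("too few rows for the requested model")
  dat <- cohort[, c(index_name, covariates), drop = FALSE]
  if ("gender" %in% covariates) dat$gender <- factor(dat$gender)
  form <- stats::as.formula(paste(index_name, "~",
                                  paste(covariates, collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  if (fit$rank < length(coef(fit)) || anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_param("collinear covariates: ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  ci <- stats::confint(fit)
  keep <- rownames(ct) != "(Intercept)"
  coefs <- do.call(rbind, lapply(rownames(ct)[keep], function(nm) {
    r <- stat_result("ols_t", estimate = ct[nm, "Estimate"],
                     ci_lo = ci[nm, 1], ci_hi = ci[nm, 2],
                     p_value = ct[nm, "Pr(>|t|)"], n = nrow(dat))
    r$term <- nm
    r
  }))
  fstat <- sm$fstatistic
  model_f <- stat_result("anova_F", estimate = unname(fstat[1]),
                         p_value = unname(stats::pf(fstat[1], fstat[2],
                                                    fstat[3], lower.tail = FALSE)),
                         n = nrow(dat))
  list(coefficients = coefs, model_f = model_f, fit = fit)
}

#' Percentile reference intervals by stratum
#'
#' Central reference intervals per stratum from linear-interpolation
#' quantiles with index `h = (n - 1) q + 1` (R's default type-7 rule,
#' pinned so results are reproducible across implementations). Strata with
#' fewer than `min_n` values get undefined bounds and a `LOW_N` flag.
#'
#' @param values Numeric vector of index values.
#' @param strata Stratum label per value (e.g. age decade).
#' @param lo_q,hi_q Quantile levels of the interval.
#' @param min_n Minimum stratum size for defined bounds.
#' @return data.frame with one row per stratum: `stratum`, `lo`, `hi`, `n`,
#'   `method`, `flag`.
#' @export
reference_interval <- function(values, strata, lo_q = 0.025, hi_q = 0.975,
                               min_n = 20) {
  if (length(values) != length(strata))
    stop_param("values and strata must align")
  if (any(!is.finite(values))) stop_param("values must be finite")
  labs <- unique(as.character(strata))
  out <- do.call(rbind, lapply(labs, function(s) {
    v <- values[as.character(strata) == s]
    if (length(v) < min_n) {
      data.frame(stratum = s, lo = NA_real_, hi = NA_real_, n = length(v),
                 method = "percentile", flag = "LOW_N")
    } else {
      q <- stats::quantile(v, c(lo_q, hi_q), type = 7, names = FALSE)
      data.frame(stratum = s, lo = q[1], hi = q[2], n = length(v),
                 method = "percentile", flag = "")
    }
  }))
  rownames(out) <- NULL
  out
}
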