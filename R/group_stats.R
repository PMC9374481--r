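# Group statistics: per-group outlier exclusion, pooled-variance t tests
# with Cohen's d and JZS Bayes factors, linear regression with partial
# eta-squared, and the cohort-level report that assembles every contrast.

#' Per-group outlier exclusion
#'
#' Within each group, values more than `k` sample SDs from the group mean
#' are excluded (single pass).  Degenerate groups (SD = 0) exclude nothing;
#' missing values are excluded.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector of group labels.
#' @param k SD multiplier (default 2.5).
#' @return Logical inclusion mask.
#' @export
exclude_outliers <- function(values, groups, k = 2.5) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  for (g in unique(groups)) {
    idx <- which(groups == g & keep)
    if (length(idx) < 3) stop("need at least 3 non-missing values per group")
    m <- mean(values[idx])
    s <- stats::sd(values[idx])
    if (s > 0) keep[idx] <- abs(values[idx] - m) <= k * s
  }
  keep
}

#' Pooled-variance two-sample t test
#'
#' Student's t with df = n1 + n2 - 2 and a two-sided p value.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return A list: `t`, `df`, `p`, `n1`, `n2`.
#' @export
student_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group")
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), n1 = n1, n2 = n2)
}

#' Cohen's d from a two-sample t statistic
#'
#' d = |t| * sqrt(1/n1 + 1/n2).
#'
#' @param t t statistic.
#' @param n1,n2 Group sizes.
#' @return Effect size d (>= 0).
#' @export
cohen_d_from_t <- function(t, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  abs(t) * sqrt(1 / n1 + 1 / n2)
}

#' JZS Bayes factor for a two-sample t test
#'
#' Default Bayesian two-sample test: the standardized effect size carries a
#' zero-centred Cauchy prior (scale 0.707 by default), and the Bayes factor
#' is the ratio of prior-marginalized to null likelihoods of the observed t
#' statistic, evaluated by adaptive quadrature over the effect-size prior:
#' BF10 = integral of T_df(t | ncp = delta * sqrt(n1 n2 / (n1 + n2))) *
#' Cauchy(delta; 0, scale) d delta / T_df(t | 0).  Returns BF01 = 1 / BF10,
#' so values above 1 favor the null.
#'
#' @param t Observed t statistic.
#' @param n1,n2 Group sizes.
#' @param cauchy_scale Cauchy prior scale (default 0.707).
#' @return BF01 (> 0).
#' @export
jzs_bf01 <- function(t, n1, n2, cauchy_scale = 0.707) {
  stopifnot(n1 >= 2, n2 >= 2, cauchy_scale > 0)
  df <- n1 + n2 - 2
  neff <- sqrt(n1 * n2 / (n1 + n2))
  integrand <- function(delta) {
    suppressWarnings(stats::dt(t, df, ncp = delta * neff)) *
      stats::dcauchy(delta, 0, cauchy_scale)
  }
  m1 <- tryCatch({
    lo <- stats::integrate(integrand, -Inf, 0, rel.tol = 1e-9)
    hi <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-9)
    if (lo$message != "OK" || hi$message != "OK") {
      stop(sprintf("quadrature did not converge (%s / %s)",
                   lo$message, hi$message))
    }
    lo$value + hi$value
  }, error = function(e) stop("JZS quadrature failed: ", conditionMessage(e)))
  m0 <- stats::dt(t, df)
  m0 / m1
}

#' Simple linear regression with F test and partial eta-squared
#'
#' Ordinary least squares of `y` on `x` with intercept; reports
#' F = (R^2/df1) / ((1-R^2)/df2) with df1 = 1, df2 = n - 2, the two-sided
#' p value, partial eta-squared F*df1 / (F*df1 + df2), and a best-effort
#' JZS regression Bayes factor (Zellner-Siow prior, scale sqrt(2)/4).
#'
#' @param y Response vector.
#' @param x Predictor vector (non-constant, n >= 3).
#' @return A list: `f`, `df1`, `df2`, `p`, `r_squared`, `eta2p`, `slope`,
#'   `intercept`, `bf01`, `n`.
#' @export
regress <- function(y, x) {
  ok <- stats::complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  df1 <- 1; df2 <- n - 2
  f <- (r2 / df1) / ((1 - r2) / df2)
  # a perfect fit has F = Inf; the effect-size ratio still converges to 1
  eta2p <- if (is.finite(f)) f * df1 / (f * df1 + df2) else 1
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       r_squared = r2,
       eta2p = eta2p,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       bf01 = jzs_bf01_regression(r2, n),
       n = n)
}

# Best-effort JZS linear-model Bayes factor (Liang et al. g-prior with
# Zellner-Siow mixing, default scale sqrt(2)/4); the exact convention behind
# published regression BF01 values varies across software, so this is
# reported as supporting information only.
jzs_bf01_regression <- function(r2, n, p = 1, scale = sqrt(2) / 4) {
  integrand <- function(g) {
    (1 + g)^((n - 1 - p) / 2) * (1 + g * (1 - r2))^(-(n - 1) / 2) *
      sqrt(n * scale^2 / 2) / gamma(0.5) * g^(-1.5) *
      exp(-n * scale^2 / (2 * g))
  }
  bf10 <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-8)$value,
    error = function(e) NA_real_)
  1 / bf10
}

# One group contrast: exclusion, pooled t, d, BF01.
contrast_row <- function(metric, values, groups, k = 2.5) {
  keep <- exclude_outliers(values, groups, k)
  a <- values[keep & groups == "ADS"]
  b <- values[keep & groups == "HC"]
  tt <- student_t(a, b)
  data.frame(metric = metric, t = tt$t, df = tt$df, p = tt$p,
             cohen_d = cohen_d_from_t(tt$t, tt$n1, tt$n2),
             bf01 = jzs_bf01(tt$t, tt$n1, tt$n2),
             n_ads = tt$n1, n_hc = tt$n2,
             mean_ads = mean(a), mean_hc = mean(b),
             n_excluded = sum(!keep))
}

#' Cohort-level statistical report
#'
#' Runs the full statistics layer on a cohort metrics table: per-metric
#' outlier exclusion (2.5 SD within group) followed by pooled-variance t
#' tests with Cohen's d and JZS BF01 for every entrainment and baseline
#' metric; linear regressions of the cognitive score on absolute and
#' relative entrainment amplitude within the ADS group; and, when
#' per-frequency columns (`pf_<freq>`) are present, a per-frequency group
#' contrast table.
#'
#' @param metrics Data frame with columns `subject`, `group` and the metric
#'   columns (`rel_amp`, `abs_amp`, `itpl`, `cv`, `base_full`,
#'   `base_aperiodic`, `base_periodic`, `r_squared`; missing metric columns
#'   raise an error).
#' @param covariates Data frame with `subject` and `score` (MMSE-like).
#' @param outlier_k SD multiplier for exclusion.
#' @return A list of class `cohort_report`: `contrasts`, `regressions`,
#'   `per_freq` (or NULL).
#' @export
cohort_report <- function(metrics, covariates = NULL, outlier_k = 2.5) {
  wanted <- c("rel_amp", "abs_amp", "itpl", "cv",
              "base_full", "base_aperiodic", "base_periodic", "r_squared")
  missing_cols <- setdiff(c("subject", "group", wanted), names(metrics))
  if (length(missing_cols)) {
    stop("missing metric column(s): ", paste(missing_cols, collapse = ", "))
  }
  groups <- metrics$group
  contrasts <- do.call(rbind, lapply(wanted, function(m) {
    contrast_row(m, metrics[[m]], groups, outlier_k)
  }))

  regressions <- NULL
  if (!is.null(covariates)) {
    merged <- merge(metrics, covariates, by = "subject")
    ads <- merged[merged$group == "ADS", ]
    regressions <- do.call(rbind, lapply(c("abs_amp", "rel_amp"), function(m) {
      keep <- abs(ads[[m]] - mean(ads[[m]])) <=
        outlier_k * stats::sd(ads[[m]])
      r <- regress(ads$score[keep], ads[[m]][keep])
      data.frame(predictor = m, f = r$f, df1 = r$df1, df2 = r$df2, p = r$p,
                 eta2p = r$eta2p, slope = r$slope, bf01 = r$bf01, n = r$n)
    }))
  }

  per_freq <- NULL
  pf_cols <- grep("^pf_", names(metrics), value = TRUE)
  if (length(pf_cols)) {
    per_freq <- do.call(rbind, lapply(pf_cols, function(cl) {
      row <- contrast_row(cl, metrics[[cl]], groups, outlier_k)
      row$freq <- as.numeric(sub("^pf_", "", cl))
      row
    }))
  }
  structure(list(contrasts = contrasts, regressions = regressions,
                 per_freq = per_freq),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort_report\n\nGroup contrasts (ADS vs HC):\n")
  print(cbind(x$contrasts[, c("metric", "n_ads", "n_hc")],
              round(x$contrasts[, c("t", "p", "cohen_d", "bf01")], 3)))
  if (!is.null(x$regressions)) {
    cat("\nRegressions of cognitive score (ADS):\n")
    print(cbind(x$regressions[, c("predictor", "n")],
                round(x$regressions[, c("f", "p", "eta2p", "slope", "bf01")], 3)))
  }
  invisible(x)
}
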