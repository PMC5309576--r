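#' Paired difference sample for method comparison
#'
#' Pairs of reference (gold standard, e.g. pneumotachograph) and test
#' (e.g. displacement sensor) values for one parameter, with the
#' difference taken test minus reference. A `subject` grouping key marks
#' breath-level data for the repeated-measures analyses.
#'
#' @param reference,test Paired numeric vectors of equal length.
#' @param subject Optional grouping key (one entry per pair).
#' @param parameter,session Labels carried through to results.
#' @return An object of class `diff_sample`.
#' @export
diff_sample <- function(reference, test, subject = NULL,
                        parameter = "", session = "") {
  if (length(reference) != length(test))
    stop("reference and test must have equal length")
  d <- test - reference
  if (!all(is.finite(d))) stop("differences must be finite")
  if (!is.null(subject) && length(subject) != length(d))
    stop("subject must have one entry per pair")
  structure(list(reference = reference, test = test, d = d,
                 subject = if (is.null(subject)) NULL else as.character(subject),
                 parameter = parameter, session = session),
            class = "diff_sample")
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Bias is the mean of the test-minus-reference differences; the limits of
#' agreement are `bias +/- multiplier * SD` of the differences (sample SD,
#' n - 1 denominator; multiplier 1.96 for 95% limits). The Pearson
#' correlation between reference and test is reported alongside, and the
#' plot data put the reference on the x-axis (the gold standard is taken
#' as truth, not averaged with the test device).
#'
#' @param sample A [diff_sample] with at least 2 pairs.
#' @param multiplier LOA multiplier (default 1.96).
#' @return An object of class `ba_result` with fields `bias`, `sd`,
#'   `loa_lower`, `loa_upper`, `n`, `pearson_r`, `se_limit` (delta-method
#'   standard error of each limit), and the sample.
#' @examples
#' s <- diff_sample(c(10, 20, 30), c(9, 20, 31))
#' bland_altman(s)
#' @export
bland_altman <- function(sample, multiplier = 1.96) {
  stopifnot(inherits(sample, "diff_sample"))
  d <- sample$d
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  r <- if (stats::sd(sample$reference) == 0 || stats::sd(sample$test) == 0)
    NA_real_ else stats::cor(sample$reference, sample$test)
  # delta method: Var(L) = Var(bias) + mult^2 * Var(SD), Var(SD) ~ s^2/(2n)
  se_limit <- sqrt(s^2 / n + multiplier^2 * s^2 / (2 * n))
  structure(list(bias = bias, sd = s,
                 loa_lower = bias - multiplier * s,
                 loa_upper = bias + multiplier * s,
                 n = n, m_eff = n, pearson_r = r,
                 multiplier = multiplier,
                 var_bias = s^2 / n, var_sd = s^2 / (2 * n),
                 se_limit = se_limit,
                 parameter = sample$parameter, session = sample$session,
                 sample = sample),
            class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("<ba_result> %s%s: bias %.4g, 95%% LOA [%.4g, %.4g], n = %d, r = %.3f\n",
              x$parameter, if (nzchar(x$session)) paste0(" (", x$session, ")") else "",
              x$bias, x$loa_lower, x$loa_upper, x$n,
              if (is.na(x$pearson_r)) NA else x$pearson_r))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences (test minus reference) against the reference value, with
#' the bias and limits of agreement drawn as horizontal lines.
#'
#' @param x A `ba_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ba_result <- function(x, ...) {
  graphics::plot(x$sample$reference, x$sample$d,
                 xlab = paste("reference", x$parameter),
                 ylab = "difference (test - reference)", ...)
  graphics::abline(h = c(x$loa_lower, x$bias, x$loa_upper),
                   lty = c(2, 1, 2), col = c("red", "blue", "red"))
  invisible(x)
}

#' Percentage differences and their Bland-Altman summary
#'
#' Percentage difference per pair is `100 * (test - reference) /
#' reference`, on the printed percent scale.
#'
#' @param sample A [diff_sample]; every reference value must be non-zero.
#' @param multiplier LOA multiplier.
#' @return List with `percent` (per-pair percentages) and `ba` (a
#'   `ba_result` on the percentage scale).
#' @examples
#' percent_diff(diff_sample(c(2, 2), c(2.2, 2)))$percent  # 10, 0
#' @export
percent_diff <- function(sample, multiplier = 1.96) {
  stopifnot(inherits(sample, "diff_sample"))
  if (any(sample$reference == 0))
    stop("percentage difference undefined for a zero reference value")
  pct <- 100 * (sample$test - sample$reference) / sample$reference
  ps <- diff_sample(rep(0, length(pct)), pct, subject = sample$subject,
                    parameter = paste0(sample$parameter, " (%)"),
                    session = sample$session)
  list(percent = pct, ba = bland_altman(ps, multiplier = multiplier))
}

#' Repeated-measures limits of agreement with random subject effects
#'
#' For breath-level differences nested in subjects, the one-way
#' random-effects decomposition splits the difference variance into a
#' between-subject component and a within-subject component, estimated by
#' the unbalanced-aware ANOVA method of moments (a negative
#' between-subject estimate is truncated to zero). The bias is the
#' generalized-least-squares grand mean, each subject mean weighted by
#' `1 / (sigma2_b + sigma2_w / n_i)`, and the limits of agreement are
#' `bias +/- multiplier * sqrt(sigma2_b + sigma2_w)`.
#'
#' Standard errors use the delta method with an effective sample size
#' `m = N / deff`, `deff = 1 + (nbar - 1) * ICC`, accounting for the
#' within-subject correlation of breath-level differences.
#'
#' A single subject cannot support the decomposition; the function then
#' falls back to [bland_altman()] with a warning. If every subject
#' contributes exactly one difference the result reduces to the simple
#' Bland-Altman limits exactly.
#'
#' @param sample A [diff_sample] with a `subject` grouping.
#' @param multiplier LOA multiplier.
#' @return An object of class `rm_result` with `bias`, `sigma2_between`,
#'   `sigma2_within`, `sd_total`, `loa_lower`, `loa_upper`, `n_subjects`,
#'   `n_breaths`, `se_limit`.
#' @export
loa_repeated <- function(sample, multiplier = 1.96) {
  stopifnot(inherits(sample, "diff_sample"))
  if (is.null(sample$subject)) stop("sample must carry a subject grouping")
  d <- sample$d
  g <- factor(sample$subject)
  k <- nlevels(g)
  if (k < 2L) {
    warning("single subject: falling back to simple Bland-Altman")
    return(bland_altman(sample, multiplier = multiplier))
  }
  ni <- as.numeric(table(g))
  N <- length(d)
  mi <- tapply(d, g, mean)
  grand <- mean(d)
  if (all(ni == 1)) {
    s2b <- stats::var(d); s2w <- 0
  } else {
    ssw <- sum((d - mi[g])^2)
    msw <- ssw / (N - k)
    ssb <- sum(ni * (mi - grand)^2)
    msb <- ssb / (k - 1)
    n0 <- (N - sum(ni^2) / N) / (k - 1)
    s2w <- msw
    s2b <- max(0, (msb - msw) / n0)
  }
  w <- 1 / (s2b + s2w / ni)
  bias <- sum(w * mi) / sum(w)
  sd_tot <- sqrt(s2b + s2w)
  var_bias <- 1 / sum(w)
  icc <- if (s2b + s2w > 0) s2b / (s2b + s2w) else 0
  deff <- 1 + (N / k - 1) * icc
  m_eff <- N / deff
  var_sd <- (s2b + s2w) / (2 * m_eff)
  se_limit <- sqrt(var_bias + multiplier^2 * var_sd)
  structure(list(bias = bias, sigma2_between = s2b, sigma2_within = s2w,
                 sd_total = sd_tot,
                 loa_lower = bias - multiplier * sd_tot,
                 loa_upper = bias + multiplier * sd_tot,
                 n_subjects = k, n_breaths = N, n = N, m_eff = m_eff,
                 multiplier = multiplier,
                 var_bias = var_bias, var_sd = var_sd, se_limit = se_limit,
                 parameter = sample$parameter, session = sample$session),
            class = "rm_result")
}

#' @export
print.rm_result <- function(x, ...) {
  cat(sprintf(paste0("<rm_result> %s%s: bias %.4g, 95%% LOA [%.4g, %.4g] ",
                     "(sigma_b %.3g, sigma_w %.3g; %d subjects, %d breaths)\n"),
              x$parameter, if (nzchar(x$session)) paste0(" (", x$session, ")") else "",
              x$bias, x$loa_lower, x$loa_upper,
              sqrt(x$sigma2_between), sqrt(x$sigma2_within),
              x$n_subjects, x$n_breaths))
  invisible(x)
}

# Shared accessor: limits and their SEs from a fitted ba_result/rm_result.
fitted_limits <- function(g) {
  if (!inherits(g, c("ba_result", "rm_result")))
    stop("expected a fitted ba_result or rm_result")
  list(lower = g$loa_lower, upper = g$loa_upper,
       se = g$se_limit, var_bias = g$var_bias, var_sd = g$var_sd,
       mult = g$multiplier)
}

#' Wald test of limits-of-agreement equality between two groups
#'
#' Compares the fitted lower and upper limits of two independent groups
#' (e.g. two measurement sessions). For each limit
#' `L = bias +/- multiplier * SD`, the delta-method variance is
#' `Var(bias) + multiplier^2 * Var(SD)` with `Var(SD) ~ sigma^2 / (2 m)`
#' for effective sample size `m`; the statistic is
#' `z = (L1 - L2) / sqrt(SE1^2 + SE2^2)` with a two-sided normal p-value,
#' reported as a `[lower, upper]` pair. A joint 2-df chi-square statistic
#' testing both limits simultaneously (accounting for the covariance of
#' the two limits within each group) is also returned.
#'
#' @param g1,g2 Fitted `ba_result` or `rm_result` objects.
#' @param alpha Significance level (information only; default 0.05).
#' @return An object of class `wald_result` with `p_lower`, `p_upper`,
#'   `z_lower`, `z_upper`, per-group limit standard errors, `chisq_joint`,
#'   `p_joint`, and `alpha`.
#' @export
wald_loa_equality <- function(g1, g2, alpha = 0.05) {
  f1 <- fitted_limits(g1); f2 <- fitted_limits(g2)
  if (f1$se == 0 && f2$se == 0)
    stop("degenerate zero-variance groups: limits have no standard error")
  se_pool <- sqrt(f1$se^2 + f2$se^2)
  z_lower <- (f1$lower - f2$lower) / se_pool
  z_upper <- (f1$upper - f2$upper) / se_pool
  p_lower <- 2 * stats::pnorm(-abs(z_lower))
  p_upper <- 2 * stats::pnorm(-abs(z_upper))
  # joint test: covariance of (L-, L+) within a group is Var(b) - m^2 Var(SD)
  cov_g <- function(f) {
    v <- f$var_bias + f$mult^2 * f$var_sd
    cv <- f$var_bias - f$mult^2 * f$var_sd
    matrix(c(v, cv, cv, v), 2, 2)
  }
  dl <- c(f1$lower - f2$lower, f1$upper - f2$upper)
  V <- cov_g(f1) + cov_g(f2)
  chisq <- tryCatch(as.numeric(t(dl) %*% solve(V, dl)),
                    error = function(e) NA_real_)
  structure(list(p_lower = p_lower, p_upper = p_upper,
                 z_lower = z_lower, z_upper = z_upper,
                 se_limit_1 = f1$se, se_limit_2 = f2$se,
                 chisq_joint = chisq,
                 p_joint = if (is.na(chisq)) NA_real_ else
                   stats::pchisq(chisq, df = 2, lower.tail = FALSE),
                 alpha = alpha),
            class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("<wald_result> p [lower, upper] = [%.3g, %.3g]; joint chi2(2) p = %.3g\n",
              x$p_lower, x$p_upper, x$p_joint))
  invisible(x)
}

#' Minimum detectable change in a limit of agreement
#'
#' Post hoc power analysis: the smallest shift of a limit of agreement
#' between two groups detectable with the stated power at level `alpha`,
#' `Delta_min = (z[1 - alpha/2] + z[power]) * sqrt(SE1^2 + SE2^2)`.
#' With a single fitted group, an equally precise replication is assumed
#' (`SE2 = SE1`).
#'
#' @param g1 Fitted `ba_result` or `rm_result`.
#' @param g2 Optional second fitted group.
#' @param power Target power in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Minimum detectable limit change (same units as the parameter).
#' @export
detectable_loa_change <- function(g1, g2 = NULL, power = 0.8, alpha = 0.05) {
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop("power and alpha must lie in (0, 1)")
  f1 <- fitted_limits(g1)
  se2 <- if (is.null(g2)) f1$se else fitted_limits(g2)$se
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) *
    sqrt(f1$se^2 + se2^2)
}

#' Distribution diagnostics for a difference sample
#'
#' Pearson kurtosis (population moments, normal = 3), a normality summary
#' (Anderson-Darling p-value and the mean absolute deviation of the
#' standardized sample quantiles from normal quantiles), and, when all
#' paired values are positive, the same diagnostics recomputed on the
#' differences of log-transformed pairs. Peaked difference distributions
#' (kurtosis well above 3) make classical limits of agreement
#' conservative: the limits tend to be further apart than the true 95%
#' band, not closer.
#'
#' @param sample A [diff_sample] with at least 4 non-constant differences.
#' @return An object of class `diagnostics` with `kurtosis`, `ad_p`,
#'   `qq_dev`, `log_retested` (flag), and `log` (the same three numbers
#'   after log transform, or `NULL`).
#' @export
distribution_diagnostics <- function(sample) {
  stopifnot(inherits(sample, "diff_sample"))
  d <- sample$d
  if (length(d) < 4L) stop("need at least 4 differences")
  if (stats::sd(d) == 0) stop("constant sample: diagnostics undefined")
  one <- function(x) {
    m2 <- mean((x - mean(x))^2)
    m4 <- mean((x - mean(x))^4)
    z <- sort((x - mean(x)) / stats::sd(x))
    q <- stats::qnorm(stats::ppoints(length(x)))
    ad <- if (length(x) >= 8)
      tryCatch(nortest::ad.test(x)$p.value, error = function(e) NA_real_)
    else NA_real_
    list(kurtosis = m4 / m2^2, ad_p = ad, qq_dev = mean(abs(z - q)))
  }
  base <- one(d)
  can_log <- all(sample$reference > 0) && all(sample$test > 0)
  lg <- if (can_log) one(log(sample$test) - log(sample$reference)) else NULL
  structure(c(base, list(log_retested = can_log, log = lg)),
            class = "diagnostics")
}

#' @export
print.diagnostics <- function(x, ...) {
  cat(sprintf("<diagnostics> kurtosis %.2f (normal = 3), AD p = %.3g, QQ dev %.3g%s\n",
              x$kurtosis, x$ad_p, x$qq_dev,
              if (x$log_retested)
                sprintf("; after log: kurtosis %.2f", x$log$kurtosis)
              else "; log transform skipped (non-positive values)"))
  invisible(x)
}
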