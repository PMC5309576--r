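test_that("diff_sample takes test-minus-reference and validates inputs", {
  s <- diff_sample(c(1, 2, 3), c(1.5, 1.5, 3.5))
  expect_equal(s$d, c(0.5, -0.5, 0.5))
  expect_error(diff_sample(1:3, 1:4), "equal length")
  expect_error(diff_sample(c(1, 2), c(NA, 2)), "finite")
  expect_error(diff_sample(1:3, 4:6, subject = "a"), "one entry per pair")
})

test_that("bland_altman reproduces hand-computed bias and limits", {
  d <- c(0.1, -0.3, 0.2, 0.4, -0.2, 0)
  ba <- bland_altman(diff_sample(numeric(6), d))
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd, sd(d))
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))
  expect_equal(ba$se_limit, sqrt(sd(d)^2 / 6 + 1.96^2 * sd(d)^2 / 12))
  ba90 <- bland_altman(diff_sample(numeric(6), d), multiplier = 1.645)
  expect_equal(ba90$loa_upper, mean(d) + 1.645 * sd(d))
  expect_error(bland_altman(diff_sample(0, 1)), "at least 2 pairs")
})

test_that("percent differences are on the printed percent scale", {
  out <- percent_diff(diff_sample(c(2, 2, 4), c(2.2, 2, 5)))
  expect_equal(out$percent, c(10, 0, 25))
  expect_equal(out$ba$bias, mean(c(10, 0, 25)))
  expect_error(percent_diff(diff_sample(c(0, 1), c(1, 1))),
               "zero reference")
})

test_that("repeated-measures limits reduce to Bland-Altman for singletons", {
  set.seed(10)
  d <- rnorm(25, 0.2, 0.5)
  s <- diff_sample(numeric(25), d, subject = paste0("s", 1:25))
  rm_fit <- loa_repeated(s)
  ba_fit <- bland_altman(diff_sample(numeric(25), d))
  expect_equal(rm_fit$bias, ba_fit$bias, tolerance = 1e-9)
  expect_equal(rm_fit$loa_lower, ba_fit$loa_lower, tolerance = 1e-9)
  expect_equal(rm_fit$loa_upper, ba_fit$loa_upper, tolerance = 1e-9)
  expect_equal(rm_fit$sigma2_within, 0)
})

test_that("repeated-measures variance components match a manual ANOVA", {
  set.seed(11)
  k <- 12
  ni <- sample(4:9, k, replace = TRUE)
  subj <- rep(paste0("s", seq_len(k)), ni)
  d <- rep(rnorm(k, 0, 0.4), ni) + rnorm(sum(ni), 0.1, 0.2)
  s <- diff_sample(numeric(sum(ni)), d, subject = subj)
  fit <- loa_repeated(s)
  # manual one-way ANOVA method of moments (group sizes in factor order)
  g <- factor(subj)
  ni_g <- as.numeric(table(g))
  mi <- tapply(d, g, mean)
  msw <- sum((d - mi[g])^2) / (sum(ni) - k)
  msb <- sum(ni_g * (mi - mean(d))^2) / (k - 1)
  n0 <- (sum(ni) - sum(ni^2) / sum(ni)) / (k - 1)
  expect_equal(fit$sigma2_within, msw, tolerance = 1e-9)
  expect_equal(fit$sigma2_between, max(0, (msb - msw) / n0),
               tolerance = 1e-9)
  expect_equal(fit$sd_total,
               sqrt(fit$sigma2_between + fit$sigma2_within))
  expect_equal(fit$loa_upper, fit$bias + 1.96 * fit$sd_total)
})

test_that("a single subject falls back to simple Bland-Altman", {
  s <- diff_sample(numeric(5), rnorm(5), subject = rep("s1", 5))
  expect_warning(fit <- loa_repeated(s), "single subject")
  expect_s3_class(fit, "ba_result")
})

test_that("Wald test is null for identical groups and flags separated ones", {
  set.seed(12)
  b1 <- bland_altman(diff_sample(numeric(50), rnorm(50)))
  w_self <- wald_loa_equality(b1, b1)
  expect_equal(w_self$p_lower, 1)
  expect_equal(w_self$p_upper, 1)
  expect_equal(w_self$p_joint, 1)
  b2 <- bland_altman(diff_sample(numeric(50), rnorm(50, mean = 3)))
  w_sep <- wald_loa_equality(b1, b2)
  expect_lt(w_sep$p_joint, 0.001)
  expect_lt(w_sep$p_upper, 0.001)
})

test_that("detectable_loa_change implements the power formula", {
  set.seed(13)
  b1 <- bland_altman(diff_sample(numeric(40), rnorm(40)))
  expect_equal(detectable_loa_change(b1),
               (qnorm(0.975) + qnorm(0.8)) * sqrt(2) * b1$se_limit)
  b2 <- bland_altman(diff_sample(numeric(80), rnorm(80)))
  expect_equal(detectable_loa_change(b1, b2),
               (qnorm(0.975) + qnorm(0.8)) *
                 sqrt(b1$se_limit^2 + b2$se_limit^2))
  # more power demands a larger detectable change
  expect_gt(detectable_loa_change(b1, power = 0.9),
            detectable_loa_change(b1, power = 0.8))
  expect_error(detectable_loa_change(b1, power = 1.2), "power and alpha")
})

test_that("distribution diagnostics separate normal from peaked samples", {
  set.seed(14)
  s_norm <- diff_sample(numeric(400), rnorm(400))
  d_norm <- distribution_diagnostics(s_norm)
  expect_lt(abs(d_norm$kurtosis - 3), 0.6)
  expect_gt(d_norm$ad_p, 0.01)
  expect_false(d_norm$log_retested)  # reference not positive

  # multiplicative errors: peaked on the raw scale, normal after log
  ref <- exp(rnorm(400, 1, 0.1))
  tst <- ref * exp(rnorm(400, 0, 0.5))
  d_log <- distribution_diagnostics(diff_sample(ref, tst))
  expect_true(d_log$log_retested)
  expect_gt(d_log$kurtosis, 3.5)
  expect_lt(abs(d_log$log$kurtosis - 3), 1)
})
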