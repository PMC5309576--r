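test_that("timing indices satisfy their defining arithmetic exactly", {
  m <- breath_markers(data.frame(insp_start = c(0, 4.5),
                                 exp_start = c(1.5, 6),
                                 exp_end = c(4.5, 9.5)))
  ti <- timing_indices(m)
  expect_equal(ti$tI, c(1.5, 1.5))
  expect_equal(ti$tE, c(3, 3.5))
  expect_equal(ti$tTot, ti$tI + ti$tE)
  expect_equal(ti$RR, 60 / ti$tTot)
  expect_equal(ti$RR[1], 60 / 4.5)
  expect_equal(ti$tI_over_tE, ti$tI / ti$tE)
  expect_equal(ti$tI_over_tTot, ti$tI / ti$tTot)
})

test_that("IE50 equals 1 for a symmetric sinusoidal breath", {
  tt <- seq(0, 4, by = 0.001)
  level <- resp_trace(0.5 - 0.5 * cos(2 * pi * tt / 4), fs = 1000)
  rate <- resp_trace(0.5 * (2 * pi / 4) * sin(2 * pi * tt / 4), fs = 1000)
  m <- breath_markers(data.frame(insp_start = 0, exp_start = 2,
                                 exp_end = 4))
  out <- ie50(level, rate, m)
  expect_equal(out$IE50, 1, tolerance = 1e-6)
  expect_equal(out$TIF50, out$TEF50, tolerance = 1e-9)
  expect_true(is.na(out$ie50_flag))
})

test_that("IE50 equals 2 for the 2:1 triangular breath closed form", {
  # inspiration 1 s at slope 1, expiration 2 s at slope -1/2
  tt <- seq(0, 3, by = 0.001)
  level_v <- ifelse(tt <= 1, tt, 1 - (tt - 1) / 2)
  rate_v <- ifelse(tt <= 1, 1, -1 / 2)
  level <- resp_trace(level_v, fs = 1000)
  rate <- resp_trace(rate_v, fs = 1000)
  m <- breath_markers(data.frame(insp_start = 0, exp_start = 1,
                                 exp_end = 3))
  out <- ie50(level, rate, m)
  expect_equal(out$TIF50, 1, tolerance = 1e-6)
  expect_equal(out$TEF50, 0.5, tolerance = 1e-6)
  expect_equal(out$IE50, 2, tolerance = 1e-6)
})

test_that("IE50 is invariant to scaling and offsetting the level trace", {
  tt <- seq(0, 4, by = 0.001)
  base <- 0.5 - 0.5 * cos(2 * pi * tt / 4) +
    0.05 * sin(2 * pi * tt / 2 + 0.4)
  rate_v <- c(diff(base) * 1000, 0)
  m <- breath_markers(data.frame(insp_start = 0, exp_start = 2,
                                 exp_end = 4))
  a <- ie50(resp_trace(base, fs = 1000), resp_trace(rate_v, fs = 1000), m)
  b <- ie50(resp_trace(3.5 * base + 2, fs = 1000),
            resp_trace(3.5 * rate_v, fs = 1000), m)
  expect_equal(a$IE50, b$IE50, tolerance = 1e-9)
})

test_that("a zero-excursion breath is flagged, not an error", {
  tt <- seq(0, 3, by = 0.01)
  level <- resp_trace(rep(1, length(tt)), fs = 100)
  rate <- resp_trace(rep(0, length(tt)), fs = 100)
  m <- breath_markers(data.frame(insp_start = 0, exp_start = 1,
                                 exp_end = 3))
  out <- ie50(level, rate, m)
  expect_true(is.na(out$IE50))
  expect_equal(out$ie50_flag, "zero_excursion")
})

test_that("breath_parameters combines timing and IE50 with key columns", {
  tt <- seq(0, 4, by = 0.001)
  level <- resp_trace(0.5 - 0.5 * cos(2 * pi * tt / 4), fs = 1000)
  rate <- resp_trace(0.5 * (2 * pi / 4) * sin(2 * pi * tt / 4), fs = 1000)
  m <- breath_markers(data.frame(insp_start = 0, exp_start = 2,
                                 exp_end = 4))
  p <- breath_parameters(level, rate, m, subject = "S01", device = "PNT",
                         session = "REST1")
  expect_s3_class(p, "breath_parameters")
  expect_equal(p$subject, "S01")
  expect_equal(p$device, "PNT")
  expect_equal(p$session, "REST1")
  expect_equal(p$tTot, 4)
  expect_equal(p$IE50, 1, tolerance = 1e-6)
  expect_error(
    breath_parameters(level, resp_trace(rate$values, fs = 500), m),
    "share a time base")
})

test_that("average_subject takes per-breath means of the ratio parameters", {
  p <- data.frame(subject = "S01", device = "PNT", session = "REST1",
                  breath_id = 1:2, tI = c(1, 2), tE = c(2, 2),
                  tTot = c(3, 4), RR = c(20, 15),
                  tI_over_tE = c(0.5, 1), tI_over_tTot = c(1 / 3, 0.5),
                  TIF50 = c(1, 1), TEF50 = c(1, 1), IE50 = c(1, NA),
                  ie50_flag = c(NA, "undefined"))
  av <- average_subject(p)
  expect_equal(nrow(av), 1L)
  expect_equal(av$tI, 1.5)
  expect_equal(av$tI_over_tE, 0.75)  # mean of ratios, not ratio of means
  expect_equal(av$IE50, 1)           # flagged breath dropped from IE50 only
  expect_equal(av$n_breaths, 2L)
})

test_that("rr_ttot_tolerance implements the exact discrepancy arithmetic", {
  expect_equal(rr_ttot_tolerance(20, 2), abs(60 / 20 - 60 / 22))
  expect_equal(rr_ttot_tolerance(50, 2), abs(60 / 50 - 60 / 52))
  expect_error(rr_ttot_tolerance(2, -3), "positive")
})
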