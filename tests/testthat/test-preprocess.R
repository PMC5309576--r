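test_that("resampling a 0.25 Hz sine keeps its extrema in place", {
  # every extremum of sin(2*pi*t/4) sampled at 30 Hz from t = 0 falls
  # exactly on an input knot, so the resampled extrema must not move
  tt <- seq(0, 44, by = 1 / 30)
  tr <- resp_trace(sin(2 * pi * 0.25 * tt), fs = 30)
  rs <- resample_trace(tr, 100)
  expect_equal(rs$fs, 100)
  y <- rs$values
  tt_out <- trace_times(rs)
  idx <- which(diff(sign(diff(y))) != 0) + 1L
  t_found <- tt_out[idx]
  t_true <- seq(1, 43, by = 2)  # analytic extrema of the sine
  for (t0 in t_true) expect_lt(min(abs(t_found - t0)), 5e-3)
})

test_that("resampling preserves the sample range (no overshoot)", {
  set.seed(4)
  tt <- seq(0, 20, by = 1 / 30)
  y <- sin(2 * pi * 0.3 * tt) + 0.3 * sin(2 * pi * 1.1 * tt + 1)
  rs <- resample_trace(resp_trace(y, fs = 30), 100)
  expect_lte(max(rs$values), max(y) + 1e-12)
  expect_gte(min(rs$values), min(y) - 1e-12)
})

test_that("extremum-shift battery reports both reference frames consistently", {
  res <- resampling_extremum_shift(n_waveforms = 5, seed = 2)
  expect_length(res$shifts_ms, 5L)
  expect_length(res$moves_ms, 5L)
  expect_equal(res$max_shift_ms, max(res$shifts_ms))
  expect_equal(res$max_move_ms, max(res$moves_ms))
  expect_true(all(is.finite(res$shifts_ms)) && all(res$shifts_ms >= 0))
  # movement relative to the input grid cannot exceed the offset from the
  # analytic extrema by more than one input sample
  expect_lte(res$max_move_ms, res$max_shift_ms + 1000 / 30)
})

test_that("alignment filter magnitude meets ripple and attenuation specs", {
  filt <- design_alignment_filter(100)
  # pass band: deviation from peak within the 0.5 dB design ripple
  f_pass <- seq(0.1, 8, length.out = 200)
  mag <- filter_magnitude(filt, f_pass)
  ripple_db <- 20 * log10(max(mag) / min(mag))
  expect_lte(ripple_db, 0.5 + 0.05)
  # stop bands: at least 50 dB below the pass-band peak
  expect_gte(stopband_attenuation(filt), 50)
  # response decays towards DC and Nyquist
  expect_lt(filter_magnitude(filt, 0.001), 0.01 * max(mag))
  expect_lt(filter_magnitude(filt, 49), 0.01 * max(mag))
})

test_that("filter design rejects invalid specifications", {
  expect_error(design_alignment_filter(10), "fs must exceed 20")
  expect_error(design_alignment_filter(100, low = 5, high = 1),
               "pass-band edges")
  expect_error(design_alignment_filter(100, order = 0), "order")
})

test_that("zero-phase filtering does not shift a pass-band peak", {
  filt <- design_alignment_filter(100)
  tt <- seq(0, 60, by = 0.01)
  # Gaussian-modulated 0.3 Hz tone: a unique dominant peak near t = 30 s
  # (a plain sine has equal-height peaks, so argmax would be ambiguous)
  tr <- resp_trace(sin(2 * pi * 0.3 * (tt - 30)) *
                     exp(-((tt - 30) / 8)^2), fs = 100)
  out <- bandpass_zero_phase(tr, filt)
  sel <- tt > 20 & tt < 40
  t_in <- tt[sel][which.max(tr$values[sel])]
  t_out <- tt[sel][which.max(out$values[sel])]
  expect_lte(abs(t_in - t_out), 0.01 + 1e-9)
  # 0.3 Hz is in the pass band: amplitude preserved within the two-pass
  # ripple (0.5 dB per pass, so at most ~1 dB down forward-backward)
  amp <- max(abs(out$values[sel])) / max(abs(tr$values[sel]))
  expect_gt(amp, 10^(-1.2 / 20))
  expect_lt(amp, 1.01)
})

test_that("estimate_lag recovers a known integer-sample lag exactly", {
  set.seed(6)
  tt <- seq(0, 45, by = 0.01)
  base <- sin(2 * pi * 0.25 * tt) + 0.2 * sin(2 * pi * 0.7 * tt + 0.3)
  for (lag_s in c(-0.73, 0, 0.5, 1.24)) {
    k <- round(lag_s * 100)
    shifted <- c(rep(0, max(k, 0)), base)[1:length(base)]
    if (k < 0) shifted <- c(base[(-k + 1):length(base)], rep(0, -k))
    a <- resp_trace(base, fs = 100)
    b <- resp_trace(0.8 * shifted + 0.1, fs = 100)  # gain + offset
    est <- estimate_lag(a, b, max_lag = 3)
    expect_equal(est$lag, lag_s, tolerance = 1e-9)
    expect_false(est$flagged)
  }
})

test_that("align_and_truncate aligns by the lag and matches lengths", {
  a <- resp_trace(1:100, fs = 10, t0 = 0)
  b <- resp_trace(101:220, fs = 10, t0 = 0)
  out <- align_and_truncate(a, b, lag = 0.5)  # 5 samples
  expect_equal(length(out$a), length(out$b))
  expect_equal(out$b$values[1], 106)
  expect_equal(out$a$values[1], 1)
  expect_equal(out$a$t0, out$b$t0)
  expect_error(align_and_truncate(a, b, lag = 1000), "no overlap")
  expect_error(align_and_truncate(a, resp_trace(1:50, fs = 5), 0),
               "share a sampling rate")
})
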