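test_that("detect_extrema finds alternating extrema of a clean sine", {
  tt <- seq(0, 20, by = 0.01)
  tr <- resp_trace(-cos(2 * pi * 0.25 * tt), fs = 100)
  cand <- detect_extrema(tr)
  expect_true(all(cand$type[c(TRUE, FALSE)] == cand$type[1]))
  expect_true(all(abs(diff(match(cand$type, c("trough", "peak")))) == 1))
  # troughs of -cos at multiples of 4 s, peaks at 2, 6, 10, ...
  for (r in seq_len(nrow(cand))) {
    t_true <- if (cand$type[r] == "peak")
      seq(2, 20, by = 4) else seq(0, 20, by = 4)
    expect_lte(min(abs(cand$time[r] - t_true)), 0.01 + 1e-9)
  }
  expect_equal(attr(cand, "t_range"), c(0, 20), tolerance = 1e-9)
  expect_error(detect_extrema(resp_trace(1:50, fs = 100)),
               "at least 1 s")
})

test_that("screen_breaths assembles trough-peak-trough breaths in order", {
  cand <- make_candidates(time = c(0, 1.5, 4, 5.5, 8),
                          value = c(0, 1, 0.05, 1.05, 0.02),
                          type = c("trough", "peak", "trough", "peak",
                                   "trough"),
                          t_range = c(-1, 9))
  mk <- screen_breaths(cand)
  expect_s3_class(mk, "breath_markers")
  expect_equal(nrow(mk), 2L)
  expect_equal(mk$insp_start, c(0, 4))
  expect_equal(mk$exp_start, c(1.5, 5.5))
  expect_equal(mk$exp_end, c(4, 8))
  expect_true(all(mk$insp_start < mk$exp_start & mk$exp_start < mk$exp_end))
})

test_that("breaths violating the duration rule are removed and logged", {
  cand <- make_candidates(
    time = c(0, 1.5, 4, 4.15, 4.3, 8, 9.5, 12),
    value = c(0, 1, 0, 1, 0, 0.02, 1.02, 0.01),
    type = c("trough", "peak", "trough", "peak", "trough", "trough",
             "peak", "trough"),
    t_range = c(-1, 13))
  # the 4 -> 4.3 s breath has tTot = 0.3 < 0.5 s at full amplitude;
  # the duplicated troughs at 4.3 and 8 collapse is not expected here, so
  # feed a strictly alternating variant instead
  cand <- cand[-6, ]
  mk <- screen_breaths(cand)
  ex <- attr(mk, "excluded")
  expect_true("tTot below minimum" %in% ex$reason)
  expect_false(any(mk$exp_end - mk$insp_start < 0.5))
})

test_that("low-prominence chatter is pruned without losing true breaths", {
  # a clean three-breath train with a small noise wiggle on one limb
  time <- c(0, 2, 4, 6, 6.4, 6.6, 8, 10, 12)
  value <- c(0, 1, 0.02, 1.02, 0.60, 0.63, 0.01, 1.01, 0.03)
  type <- c("trough", "peak", "trough", "peak", "trough", "peak",
            "trough", "peak", "trough")
  mk <- screen_breaths(make_candidates(time, value, type,
                                       t_range = c(-1, 13)))
  expect_equal(nrow(mk), 3L)
  ex <- attr(mk, "excluded")
  expect_true("low-prominence extremum pair pruned" %in% ex$reason)
})

test_that("markers too close to the trace edges are rejected", {
  cand <- make_candidates(time = c(0.05, 1.5, 4, 5.5, 8),
                          value = c(0, 1, 0.05, 1.05, 0.02),
                          type = c("trough", "peak", "trough", "peak",
                                   "trough"),
                          t_range = c(0, 9))
  mk <- screen_breaths(cand)
  ex <- attr(mk, "excluded")
  expect_true("marker too close to epoch edge" %in% ex$reason)
  expect_equal(nrow(mk), 1L)  # the second breath is clear of both edges
  guard <- screening_rules()$edge_guard
  expect_true(all(mk$insp_start >= guard & mk$exp_end <= 9 - guard))
})

test_that("a breath whose expiration never returns to baseline is rejected", {
  cand <- make_candidates(time = c(1, 2.5, 5, 6.5, 9),
                          value = c(0, 2, 1.4, 3.4, 1.5),
                          type = c("trough", "peak", "trough", "peak",
                                   "trough"),
                          t_range = c(-5, 20))
  # first breath recovers only 0.6 of its 2.0 excursion (< 0.75 fraction)
  mk <- screen_breaths(cand)
  ex <- attr(mk, "excluded")
  expect_true("incomplete expiratory return" %in% ex$reason)
  expect_equal(nrow(mk), 1L)
  expect_equal(mk$insp_start, 5)
})

test_that("non-alternating candidates are refused", {
  cand <- make_candidates(time = c(0, 1, 2),
                          value = c(0, 0.1, 1),
                          type = c("trough", "trough", "peak"))
  expect_error(screen_breaths(cand), "alternate")
})

test_that("screening_rules validates its arguments", {
  expect_error(screening_rules(min_tTot = 3, max_tTot = 2), "min_tTot")
  expect_error(screening_rules(min_amplitude_fraction = 1.5),
               "min_amplitude_fraction")
  expect_error(screening_rules(edge_guard = -1), "edge_guard")
  expect_error(screening_rules(min_return_fraction = 1), "min_return")
})

test_that("artifact breaths are screened out without losing real breaths", {
  cfg <- clean_config(seed = 31, artifact_rate = 0.3, epoch_length = 60)
  rec <- render_waveforms(simulate_breath_train(cfg))
  pr <- process_recording(rec, lead_in = 0)
  b <- rec$truth$breaths
  expect_gt(sum(b$artifact), 0)  # the draw does contain artifacts
  starts_true <- b$insp_start[!b$artifact]
  # a breath marker adjacent to a pruned artifact may sit anywhere in
  # the flat junction the artifact occupied (its tI + tE = 0.6 s span)
  art_tol <- 0.6 + 0.05
  for (mk in list(pr$markers_pnt, pr$markers_slp)) {
    # every screened breath corresponds to a true non-artifact breath:
    # no cough-spike artifact survives screening
    for (s in mk$insp_start)
      expect_lte(min(abs(starts_true - s)), art_tol)
    # nothing artifact-short survives either
    expect_true(all(mk$exp_end - mk$insp_start >=
                      screening_rules()$min_tTot))
    expect_lte(nrow(mk), length(starts_true))
  }
  # every true non-artifact breath in the epoch interior is recovered on
  # both devices; breaths whose closing trough abuts the truncated trace
  # end (within an artifact-train length of it) are excluded from the
  # claim, since an artifact run touching the edge merges into the guard
  interior <- which(!b$artifact & b$insp_start >= 0.7 &
                      b$exp_end <= 60 - pr$lag_used - 2)
  for (i in interior) {
    s <- b$insp_start[i]
    # strict match unless the preceding breath was an artifact
    tol <- if (i > 1 && b$artifact[i - 1]) art_tol else 0.05
    expect_lte(min(abs(pr$markers_pnt$insp_start - s)), tol)
    expect_lte(min(abs(pr$markers_slp$insp_start - s)), tol)
  }
})

test_that("screened count matches ground truth in at least 95% of subjects", {
  # seeds preregistered as 2001-2040; deterministic given the seeds
  guard <- screening_rules()$edge_guard
  ok_pnt <- logical(40)
  ok_slp <- logical(40)
  for (i in 1:40) {
    cfg <- sim_config(seed = 2000 + i, epoch_length = 60)
    rec <- render_waveforms(simulate_breath_train(cfg))
    pr <- process_recording(rec, lead_in = 15, analysis_window = 45)
    w0 <- 15 + guard
    w1 <- 60 - pr$lag_used - guard
    b <- rec$truth$breaths
    n_true <- sum(!b$artifact & b$insp_start >= w0 & b$exp_end <= w1)
    ok_pnt[i] <- nrow(pr$markers_pnt) == n_true
    ok_slp[i] <- nrow(pr$markers_slp) == n_true
  }
  expect_gte(mean(ok_pnt), 0.95)
  expect_gte(mean(ok_slp), 0.95)
})

test_that("breath_markers validates marker ordering", {
  expect_error(breath_markers(data.frame(insp_start = 1, exp_start = 0.5,
                                         exp_end = 2)),
               "insp_start < exp_start < exp_end")
  expect_error(breath_markers(data.frame(insp_start = c(0, 1),
                                         exp_start = c(0.5, 1.5),
                                         exp_end = c(2, 3))),
               "non-overlapping")
})
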