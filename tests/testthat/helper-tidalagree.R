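# Shared helpers for the test suite.

# A simulation configuration with every stochastic ingredient switched
# off: deterministic breath timings, no measurement noise, no drift, no
# artifacts. Used wherever an analytic expectation must hold exactly.
clean_config <- function(...) {
  defaults <- list(cv_timing = 0, noise_sd_pnt = 0, noise_sd_slp = 0,
                   drift_amplitude = 0, artifact_rate = 0)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Worst-case absolute offset (seconds) between each true marker time and
# the nearest detected marker of the same role, over true breaths lying
# inside [w0, w1].
max_marker_error <- function(markers, truth, w0, w1) {
  true_b <- truth$breaths[!truth$breaths$artifact &
                            truth$breaths$insp_start >= w0 &
                            truth$breaths$exp_end <= w1, ]
  errs <- c()
  for (role in c("insp_start", "exp_start", "exp_end")) {
    for (t_true in true_b[[role]]) {
      errs <- c(errs, min(abs(markers[[role]] - t_true)))
    }
  }
  if (length(errs)) max(errs) else NA_real_
}

# Exhaustive-search oracle for the inter-device lag: evaluates the
# Pearson correlation at every integer-sample shift within max_lag and
# returns the argmax in seconds. Independent re-implementation used to
# cross-check estimate_lag().
oracle_lag <- function(a, b, max_lag) {
  fs <- a$fs
  L <- round(max_lag * fs)
  xa <- a$values; xb <- b$values
  na <- length(xa); nb <- length(xb)
  best_k <- 0L; best_r <- -Inf
  for (k in (-L):L) {
    if (k >= 0) { ia <- 1:(min(na, nb - k)); ib <- ia + k }
    else        { ib <- 1:(min(nb, na + k)); ia <- ib - k }
    if (length(ia) < 10L) next
    r <- suppressWarnings(stats::cor(xa[ia], xb[ib]))
    if (is.finite(r) && r > best_r) { best_r <- r; best_k <- k }
  }
  best_k / fs
}

# Candidate extremum table with the attributes detect_extrema() attaches,
# for driving screen_breaths() directly in unit tests.
make_candidates <- function(time, value, type, t_range = range(time)) {
  structure(data.frame(time = time, value = value, type = type),
            t_range = t_range)
}
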