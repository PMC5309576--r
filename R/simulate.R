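#' @name synthetic-breaths
#' @title Synthetic paired recordings with known ground truth
#'
#' @description
#' The generator builds an epoch of tidal breathing in two stages. First,
#' [simulate_breath_train()] draws per-breath inspiratory and expiratory
#' durations from gamma distributions with configured means and coefficient
#' of variation, accumulating marker times from `t = 0` until the epoch is
#' covered, and flags artifact breaths. Second, [render_waveforms()] turns
#' those markers into continuous signals: each breath's volume is built from
#' a rising inspiratory limb and falling expiratory limb of warped
#' half-cosine shape, with the warp exponent solved per breath so that the
#' ratio of inspiratory to expiratory flow at the 50% volume crossing
#' (IE50) equals the configured target exactly; flow is the analytic time
#' derivative. The displacement channel is a gain-scaled copy of volume with
#' slow sinusoidal baseline drift, independent noise, and an inter-device
#' time offset, sampled at its own (lower) rate.
NULL

# Limb shape s(u; p) = (1 - cos(pi * u^p)) / 2 on u in [0, 1]:
# rises 0 -> 1, zero slope at both ends for p > 1/2, and crosses 1/2 at
# u = 0.5^(1/p) where the slope is (pi/2) * g(p) with g(p) = p * 2^(1/p - 1).
limb_shape <- function(u, p) (1 - cos(pi * u^p)) / 2

limb_slope <- function(u, p) {
  # du of limb_shape; u^(p-1) is guarded at u = 0 (limit is 0 for p > 1/2)
  out <- (pi / 2) * sin(pi * u^p) * p * u^(p - 1)
  out[u <= 0] <- 0
  out
}

limb_gain <- function(p) p * 2^(1 / p - 1)

#' Solve the limb warp exponents that realize a target IE50
#'
#' For a breath with inspiratory duration `tI`, expiratory duration `tE`
#' and warped half-cosine limbs, the flow ratio at the 50% volume crossing
#' is `IE50 = g(pI) * tE / (g(pE) * tI)` with `g(p) = p * 2^(1/p - 1)`.
#' The warp is placed on whichever limb keeps both exponents on the
#' monotone branch `p >= log(2)` (where limbs stay smooth with zero
#' end-slope).
#'
#' @param tI,tE Limb durations in seconds.
#' @param ie50 Target flow ratio (> 0).
#' @return Numeric `c(pI, pE)` of limb exponents.
#' @keywords internal
solve_limb_warp <- function(tI, tE, ie50) {
  rho <- ie50 * tI / tE            # required g(pI) / g(pE)
  if (abs(rho - 1) < 1e-12) return(c(1, 1))
  target <- max(rho, 1 / rho)
  if (target > limb_gain(200)) {
    warning("target IE50 unattainably extreme for this breath; clamping warp")
    target <- limb_gain(200)
  }
  p <- stats::uniroot(function(p) limb_gain(p) - target,
                      lower = log(2), upper = 200, tol = 1e-12)$root
  if (rho > 1) c(p, 1) else c(1, p)
}

#' Simulate a ground-truth breath train
#'
#' Draws per-breath inspiratory and expiratory durations independently from
#' gamma distributions with means `mean_tI` / `mean_tE` and coefficient of
#' variation `cv_timing` (`cv_timing = 0` gives constant durations), flags
#' each breath as an artifact with probability `artifact_rate` (artifacts
#' become brief low-amplitude oscillations when rendered), and accumulates
#' markers from `t = 0` until the epoch is covered. Deterministic given the
#' seed.
#'
#' @param config A [sim_config].
#' @param seed Optional seed overriding `config$seed`.
#' @return An object of class `ground_truth`: a list with a per-breath
#'   data frame `breaths` (markers, true parameters, amplitude, artifact
#'   flag), the true `inter_device_offset`, and the `config` used.
#' @examples
#' truth <- simulate_breath_train(sim_config(cv_timing = 0, seed = 1))
#' head(truth$breaths)
#' @export
simulate_breath_train <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  art_tI <- 0.3; art_tE <- 0.3; art_amp_frac <- 0.1

  with_seed(seed, {
    tI <- tE <- amp <- numeric(0); artifact <- logical(0)
    total <- 0
    while (total < config$epoch_length) {
      is_art <- stats::runif(1) < config$artifact_rate
      if (is_art) {
        ti <- art_tI; te <- art_tE; a <- art_amp_frac * config$tidal_amplitude
      } else if (config$cv_timing == 0) {
        ti <- config$mean_tI; te <- config$mean_tE; a <- config$tidal_amplitude
      } else {
        shape <- 1 / config$cv_timing^2
        ti <- stats::rgamma(1, shape = shape, scale = config$mean_tI / shape)
        te <- stats::rgamma(1, shape = shape, scale = config$mean_tE / shape)
        a <- config$tidal_amplitude
      }
      tI <- c(tI, ti); tE <- c(tE, te); amp <- c(amp, a)
      artifact <- c(artifact, is_art)
      total <- total + ti + te
    }
    tTot <- tI + tE
    insp_start <- cumsum(c(0, tTot[-length(tTot)]))
    breaths <- data.frame(
      breath_id = seq_along(tI),
      insp_start = insp_start,
      exp_start = insp_start + tI,
      exp_end = insp_start + tTot,
      tI = tI, tE = tE, tTot = tTot,
      RR = 60 / tTot,
      tI_over_tE = tI / tE,
      tI_over_tTot = tI / tTot,
      IE50 = ifelse(artifact, NA_real_, config$target_IE50),
      amplitude = amp,
      artifact = artifact
    )
    structure(list(breaths = breaths,
                   inter_device_offset = config$inter_device_offset,
                   config = config),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  b <- x$breaths
  cat(sprintf("<ground_truth> %d breaths (%d artifact) over %.1f s, offset %.2f s\n",
              nrow(b), sum(b$artifact), max(b$exp_end), x$inter_device_offset))
  invisible(x)
}

# Analytic volume and flow of a breath train as functions of time.
# Returns list(vol, flow); both evaluate to 0 outside the train's span.
breath_train_funs <- function(truth) {
  b <- truth$breaths
  warp <- t(mapply(function(ti, te, ie, art) {
    if (art) c(1, 1) else solve_limb_warp(ti, te, ie)
  }, b$tI, b$tE, ifelse(is.na(b$IE50), 1, b$IE50), b$artifact))
  eval_at <- function(t, deriv) {
    out <- numeric(length(t))
    idx <- findInterval(t, b$insp_start)
    ok <- idx >= 1 & t < max(b$exp_end)
    for (k in unique(idx[ok])) {
      sel <- ok & idx == k
      tk <- t[sel] - b$insp_start[k]
      insp <- tk < b$tI[k]
      u <- ifelse(insp, tk / b$tI[k], (tk - b$tI[k]) / b$tE[k])
      u <- pmin(pmax(u, 0), 1)
      p <- ifelse(insp, warp[k, 1], warp[k, 2])
      a <- b$amplitude[k]
      if (deriv) {
        rate <- a * limb_slope(u, p) / ifelse(insp, b$tI[k], b$tE[k])
        out[sel] <- ifelse(insp, rate, -rate)
      } else {
        out[sel] <- ifelse(insp, a * limb_shape(u, p), a * (1 - limb_shape(u, p)))
      }
    }
    out
  }
  list(vol = function(t) eval_at(t, deriv = FALSE),
       flow = function(t) eval_at(t, deriv = TRUE))
}

#' Render a ground-truth breath train into device signals
#'
#' Produces the paired recording implied by the markers: PNT flow (the
#' analytic limb derivative plus measurement noise) sampled at `fs_pnt`,
#' PNT volume as the running trapezoidal integral of that measured flow
#' (a pneumotachograph derives volume by digitally integrating its noisy
#' flow signal, so the two channels are conserved by construction), and
#' an SLP displacement trace equal to `slp_gain` times volume plus
#' sinusoidal baseline drift and independent noise, sampled at `fs_slp`
#' and delayed by `inter_device_offset`.
#'
#' @param truth A [ground_truth] from [simulate_breath_train()].
#' @param config A [sim_config]; defaults to the one stored in `truth`.
#' @param seed Optional seed for the noise/drift draws (defaults to
#'   `config$seed + 1` so timing and noise streams are decoupled).
#' @return An object of class `paired_recording`: list with [resp_trace]s
#'   `pnt_flow`, `pnt_volume`, `slp`, plus `truth` and `config`.
#' @examples
#' cfg <- sim_config(epoch_length = 20, seed = 2)
#' rec <- render_waveforms(simulate_breath_train(cfg), cfg)
#' rec$pnt_volume
#' @export
render_waveforms <- function(truth, config = truth$config, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  validate_sim_config(config)
  b <- truth$breaths
  if (any(diff(as.vector(t(b[, c("insp_start", "exp_start", "exp_end")]))) < -1e-9))
    stop("ground-truth markers must be increasing")
  seed <- if (is.null(seed)) config$seed + 1L else as.integer(seed)
  funs <- breath_train_funs(truth)
  T_end <- config$epoch_length
  t_pnt <- seq(0, T_end, by = 1 / config$fs_pnt)
  t_slp <- seq(0, T_end, by = 1 / config$fs_slp)

  with_seed(seed, {
    flow0 <- funs$flow(t_pnt)
    e_f <- stats::rnorm(length(t_pnt), sd = config$noise_sd_pnt)
    flow_meas <- flow0 + e_f
    # the device derives volume by digitally integrating the measured flow,
    # so the rendered volume is the running trapezoidal integral of the
    # rendered (noisy) flow: the two channels are conserved by construction
    dt <- 1 / config$fs_pnt
    vol_meas <- c(0, cumsum((flow_meas[-1] + flow_meas[-length(flow_meas)]) / 2) * dt)
    phase <- stats::runif(1, 0, 2 * pi)
    tt <- t_slp - truth$inter_device_offset
    tt <- pmin(pmax(tt, 0), T_end)   # hold the resting level outside the span
    slp <- config$slp_gain * funs$vol(tt) +
      config$drift_amplitude * sin(2 * pi * t_slp / config$drift_period + phase) +
      stats::rnorm(length(t_slp), sd = config$noise_sd_slp)
    structure(list(
      pnt_flow = resp_trace(flow_meas, config$fs_pnt, label = "pnt_flow",
                            units = "vol/s"),
      pnt_volume = resp_trace(vol_meas, config$fs_pnt, label = "pnt_volume",
                              units = "vol"),
      slp = resp_trace(slp, config$fs_slp, label = "slp", units = "a.u."),
      truth = truth, config = config
    ), class = "paired_recording")
  })
}

#' @export
print.paired_recording <- function(x, ...) {
  cat(sprintf("<paired_recording> %d true breaths; PNT %g Hz, SLP %g Hz, %.1f s\n",
              nrow(x$truth$breaths), x$config$fs_pnt, x$config$fs_slp,
              x$config$epoch_length))
  invisible(x)
}

#' Simulate a cohort of paired recordings
#'
#' Per-subject configurations are jittered multiplicatively (lognormal,
#' coefficient of variation `subject_cv`) around the base configuration in
#' breath timing, IE50, displacement gain and inter-device offset, giving
#' between-subject variation; each subject then gets an independent
#' sub-seed derived from the master seed by counter, so the cohort is
#' reproducible as a whole.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config Base [sim_config].
#' @param seed Master seed (defaults to `config$seed`).
#' @param subject_cv Between-subject lognormal coefficient of variation
#'   (0 makes all subjects share the base configuration).
#' @param jitter Optional pre-drawn `n_subjects x 5` matrix of subject
#'   multipliers (tI, tE, IE50, gain, offset), so the same simulated
#'   subjects can be re-measured across sessions.
#' @return List of [paired_recording]s with a `subject` field (`"S01"`, ...).
#' @export
make_cohort <- function(n_subjects, config, seed = NULL, subject_cv = 0.15,
                        jitter = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    stop("n_subjects must be >= 1")
  n_subjects <- as.integer(n_subjects)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  jit <- if (!is.null(jitter)) {
    stopifnot(is.matrix(jitter), nrow(jitter) == n_subjects, ncol(jitter) == 5)
    jitter
  } else with_seed(seed, {
    matrix(exp(stats::rnorm(5 * n_subjects, mean = 0, sd = subject_cv)),
           nrow = n_subjects, ncol = 5)
  })
  lapply(seq_len(n_subjects), function(i) {
    cfg <- config
    cfg$mean_tI <- config$mean_tI * jit[i, 1]
    cfg$mean_tE <- config$mean_tE * jit[i, 2]
    cfg$target_IE50 <- config$target_IE50 * jit[i, 3]
    cfg$slp_gain <- config$slp_gain * jit[i, 4]
    cfg$inter_device_offset <- config$inter_device_offset * jit[i, 5]
    cfg$seed <- as.integer((seed * 1009 + i) %% 2147483647)
    rec <- render_waveforms(simulate_breath_train(cfg), cfg)
    rec$subject <- sprintf("S%02d", i)
    rec
  })
}

#' Write a paired recording to CSV traces plus a JSON sidecar
#'
#' Writes `<stem>_pnt_flow.csv`, `<stem>_pnt_volume.csv`, `<stem>_slp.csv`
#' (two-column `time_s,value`) and `<stem>_truth.json` holding the
#' ground-truth breath table and the simulation configuration.
#'
#' @param rec A [paired_recording].
#' @param dir Output directory (created if missing).
#' @param stem File-name stem, e.g. the subject id.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir, stem = rec$subject %||% "recording") {
  stopifnot(inherits(rec, "paired_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("pnt_flow", "pnt_volume", "slp"))
    write_trace_csv(rec[[nm]], file.path(dir, paste0(stem, "_", nm, ".csv")))
  sidecar <- list(truth = rec$truth$breaths,
                  inter_device_offset = rec$truth$inter_device_offset,
                  config = unclass(rec$config),
                  subject = rec$subject %||% stem)
  jsonlite::write_json(sidecar, file.path(dir, paste0(stem, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a paired recording written by [write_recording()]
#'
#' @param dir Directory containing the files.
#' @param stem File-name stem used when writing.
#' @return A [paired_recording].
#' @export
read_recording <- function(dir, stem) {
  paths <- file.path(dir, paste0(stem, "_", c("pnt_flow", "pnt_volume", "slp"),
                                 ".csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing trace file: ", missing[1])
  side_path <- file.path(dir, paste0(stem, "_truth.json"))
  if (!file.exists(side_path)) stop("missing sidecar file: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  cfg <- do.call(sim_config, side$config)
  truth <- structure(list(breaths = as.data.frame(side$truth),
                          inter_device_offset = side$inter_device_offset,
                          config = cfg), class = "ground_truth")
  structure(list(
    pnt_flow = read_trace_csv(paths[1], label = "pnt_flow", units = "vol/s"),
    pnt_volume = read_trace_csv(paths[2], label = "pnt_volume", units = "vol"),
    slp = read_trace_csv(paths[3], label = "slp", units = "a.u."),
    truth = truth, config = cfg, subject = side$subject
  ), class = "paired_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
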