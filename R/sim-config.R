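#' Simulation settings for a paired two-device recording
#'
#' Bundles everything the synthetic-data generator needs to emulate one
#' epoch of simultaneous pneumotachograph (PNT) and structured light
#' plethysmography (SLP) tidal breathing. Defaults describe a resting
#' adult: median inspiratory/expiratory times near 1.7/2.5 s (about
#' 14 breaths per minute), a mildly asymmetric flow-volume loop
#' (IE50 = 1.2), device rates of 100 Hz (PNT) and 30 Hz (SLP), a small
#' manual-start synchronization offset, and baseline drift on the
#' displacement channel slower than the 0.05 Hz analysis band edge.
#'
#' @param epoch_length Recording duration in seconds.
#' @param mean_tI,mean_tE Mean inspiratory / expiratory durations (s).
#' @param cv_timing Coefficient of variation of the per-breath gamma
#'   timing draws (dimensionless, >= 0; 0 gives perfectly regular breaths).
#' @param target_IE50 Ratio of inspiratory to expiratory flow at 50% of
#'   tidal volume that each rendered breath attains analytically (> 0).
#' @param tidal_amplitude Tidal volume excursion in arbitrary volume units.
#' @param slp_gain Dimensionless gain of the displacement channel relative
#'   to volume (SLP is uncalibrated; only shape matters downstream).
#' @param noise_sd_pnt,noise_sd_slp Additive white-noise standard
#'   deviations: flow units for PNT, displacement units for SLP.
#' @param drift_amplitude,drift_period Sinusoidal baseline drift on the
#'   SLP channel (signal units, s).
#' @param inter_device_offset Unknown start-time offset between the two
#'   devices in seconds; positive means the SLP trace is delayed.
#' @param fs_pnt,fs_slp Device sampling rates in Hz; `fs_pnt > fs_slp > 0`.
#' @param artifact_rate Per-breath probability of an artifact (a brief,
#'   low-amplitude oscillation replacing a normal breath), in `[0, 1)`.
#' @param seed Integer seed making every draw reproducible.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(epoch_length = 45, seed = 7)
#' cfg
#' @export
sim_config <- function(epoch_length = 45,
                       mean_tI = 1.7,
                       mean_tE = 2.5,
                       cv_timing = 0.1,
                       target_IE50 = 1.2,
                       tidal_amplitude = 1,
                       slp_gain = 0.8,
                       noise_sd_pnt = 0.02,
                       noise_sd_slp = 0.03,
                       drift_amplitude = 0.1,
                       drift_period = 30,
                       inter_device_offset = 0.5,
                       fs_pnt = 100,
                       fs_slp = 30,
                       artifact_rate = 0.05,
                       seed = 1L) {
  cfg <- list(epoch_length = epoch_length, mean_tI = mean_tI, mean_tE = mean_tE,
              cv_timing = cv_timing, target_IE50 = target_IE50,
              tidal_amplitude = tidal_amplitude, slp_gain = slp_gain,
              noise_sd_pnt = noise_sd_pnt, noise_sd_slp = noise_sd_slp,
              drift_amplitude = drift_amplitude, drift_period = drift_period,
              inter_device_offset = inter_device_offset,
              fs_pnt = fs_pnt, fs_slp = fs_slp,
              artifact_rate = artifact_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$epoch_length) || cfg$epoch_length <= 0)
    stop("epoch_length must be a positive number")
  if (!num1(cfg$mean_tI) || cfg$mean_tI <= 0) stop("mean_tI must be > 0")
  if (!num1(cfg$mean_tE) || cfg$mean_tE <= 0) stop("mean_tE must be > 0")
  if (!num1(cfg$cv_timing) || cfg$cv_timing < 0) stop("cv_timing must be >= 0")
  if (!num1(cfg$target_IE50) || cfg$target_IE50 <= 0) stop("target_IE50 must be > 0")
  if (!num1(cfg$tidal_amplitude) || cfg$tidal_amplitude <= 0)
    stop("tidal_amplitude must be > 0")
  if (!num1(cfg$fs_pnt) || !num1(cfg$fs_slp) ||
      !(cfg$fs_pnt > cfg$fs_slp && cfg$fs_slp > 0))
    stop("sampling rates must satisfy fs_pnt > fs_slp > 0")
  if (!num1(cfg$artifact_rate) || cfg$artifact_rate < 0 || cfg$artifact_rate >= 1)
    stop("artifact_rate must be in [0, 1)")
  if (!num1(cfg$noise_sd_pnt) || cfg$noise_sd_pnt < 0 ||
      !num1(cfg$noise_sd_slp) || cfg$noise_sd_slp < 0)
    stop("noise standard deviations must be >= 0")
  if (!num1(cfg$drift_amplitude) || cfg$drift_amplitude < 0 ||
      !num1(cfg$drift_period) || cfg$drift_period <= 0)
    stop("drift_amplitude must be >= 0 and drift_period > 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %g s epoch, tI/tE = %.2f/%.2f s (cv %.2f), IE50 = %.2f\n",
    "  PNT %g Hz (noise %.3g), SLP %g Hz (gain %.2f, noise %.3g, drift %.2f/%g s)\n",
    "  offset %.2f s, artifact rate %.2f, seed %d\n"),
    x$epoch_length, x$mean_tI, x$mean_tE, x$cv_timing, x$target_IE50,
    x$fs_pnt, x$noise_sd_pnt, x$fs_slp, x$slp_gain, x$noise_sd_slp,
    x$drift_amplitude, x$drift_period,
    x$inter_device_offset, x$artifact_rate, x$seed))
  invisible(x)
}

# Run code with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
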