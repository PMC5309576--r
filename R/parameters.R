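#' Per-breath timing indices from markers
#'
#' For each breath: `tI` = expiratory start minus inspiratory start,
#' `tE` = expiratory end minus expiratory start, `tTot = tI + tE`,
#' `RR = 60 / tTot` (breaths per minute), plus the ratios `tI/tE` and the
#' duty cycle `tI/tTot`. The identities `tI + tE = tTot` and
#' `RR * tTot = 60` hold to machine precision by construction.
#'
#' @param markers A [breath_markers].
#' @return Data frame with one row per breath: `breath_id`, `tI`, `tE`,
#'   `tTot`, `RR`, `tI_over_tE`, `tI_over_tTot`.
#' @examples
#' m <- breath_markers(data.frame(insp_start = 0, exp_start = 1.5,
#'                                exp_end = 4.5))
#' timing_indices(m)  # tI 1.5, tE 3, tTot 4.5, RR 13.33
#' @export
timing_indices <- function(markers) {
  stopifnot(inherits(markers, "breath_markers"))
  tI <- markers$exp_start - markers$insp_start
  tE <- markers$exp_end - markers$exp_start
  tTot <- tI + tE
  data.frame(breath_id = markers$breath_id,
             tI = tI, tE = tE, tTot = tTot, RR = 60 / tTot,
             tI_over_tE = tI / tE, tI_over_tTot = tI / tTot)
}

# |rate| at the times where `level` crosses `target` within [t_lo, t_hi].
# Crossing times are found by linear interpolation between samples, and
# the rate is linearly interpolated at each crossing. Multiple crossings
# (a non-monotone limb) are combined as a time-weighted mean, each
# crossing weighted by the span of the limb it accounts for.
limb_rate_at_level <- function(level, rate, t_lo, t_hi, target) {
  tt <- trace_times(level)
  sel <- which(tt >= t_lo & tt <= t_hi)
  if (length(sel) < 2L) return(list(value = NA_real_, n_crossings = 0L))
  t <- tt[sel]; y <- level$values[sel]
  dy <- y - target
  cross <- which(dy[-1] * dy[-length(dy)] < 0)
  t_cross <- t[cross] + (t[cross + 1] - t[cross]) *
    (0 - dy[cross]) / (dy[cross + 1] - dy[cross])
  exact <- t[dy == 0]
  t_cross <- sort(c(t_cross, exact))
  if (!length(t_cross)) return(list(value = NA_real_, n_crossings = 0L))
  r <- abs(trace_at(rate, t_cross))
  if (length(t_cross) == 1L)
    return(list(value = r, n_crossings = 1L))
  # weights: half-distance to neighbouring crossings, limb edges closing
  bounds <- c(t_lo, (t_cross[-1] + t_cross[-length(t_cross)]) / 2, t_hi)
  wgt <- diff(bounds)
  list(value = sum(r * wgt) / sum(wgt), n_crossings = length(t_cross))
}

#' Per-breath IE50 from a level trace and its rate trace
#'
#' IE50 is the ratio of inspiratory to expiratory flow (or displacement
#' rate) at 50% of the breath's excursion: `IE50 = TIF50 / TEF50`. The
#' tidal excursion is the level at expiratory start minus the level at
#' inspiratory start; `TIF50` is `|rate|` where the inspiratory limb
#' crosses the midpoint level and `TEF50` where the expiratory limb does.
#' If a limb crosses the midpoint more than once, the time-weighted mean
#' `|rate|` over the crossings is used and the breath is flagged. A breath
#' with zero excursion gets a missing IE50 and a flag (its timing indices
#' are unaffected).
#'
#' For a pneumotachograph the level is volume and the rate is flow; for a
#' displacement sensor the level is displacement and the rate its central
#' difference derivative ([derivative_trace()]).
#'
#' @param level,rate [resp_trace]s on a common time base.
#' @param markers A [breath_markers].
#' @return Data frame with columns `breath_id`, `TIF50`, `TEF50`, `IE50`,
#'   `ie50_flag` (`NA`, `"multiple_crossings"` or `"zero_excursion"`).
#' @export
ie50 <- function(level, rate, markers) {
  stopifnot(inherits(level, "resp_trace"), inherits(rate, "resp_trace"),
            inherits(markers, "breath_markers"))
  if (abs(level$fs - rate$fs) > 1e-6 * level$fs ||
      abs(level$t0 - rate$t0) > 1e-6)
    stop("level and rate traces must share a time base")
  out <- data.frame(breath_id = markers$breath_id,
                    TIF50 = NA_real_, TEF50 = NA_real_, IE50 = NA_real_,
                    ie50_flag = NA_character_)
  for (k in seq_len(nrow(markers))) {
    v0 <- trace_at(level, markers$insp_start[k])
    v1 <- trace_at(level, markers$exp_start[k])
    excursion <- v1 - v0
    if (excursion == 0) { out$ie50_flag[k] <- "zero_excursion"; next }
    mid <- v0 + excursion / 2
    insp <- limb_rate_at_level(level, rate, markers$insp_start[k],
                               markers$exp_start[k], mid)
    expi <- limb_rate_at_level(level, rate, markers$exp_start[k],
                               markers$exp_end[k], mid)
    out$TIF50[k] <- insp$value
    out$TEF50[k] <- expi$value
    if (is.na(insp$value) || is.na(expi$value) || expi$value == 0) {
      out$ie50_flag[k] <- "undefined"
      next
    }
    out$IE50[k] <- insp$value / expi$value
    if (insp$n_crossings > 1L || expi$n_crossings > 1L)
      out$ie50_flag[k] <- "multiple_crossings"
  }
  out
}

#' All seven per-breath tidal parameters
#'
#' Convenience wrapper combining [timing_indices()] and [ie50()] into one
#' table, annotated with subject/device/session keys.
#'
#' @param level,rate [resp_trace]s on a common time base.
#' @param markers A [breath_markers].
#' @param subject,device,session Key columns added to every row.
#' @return Data frame of class `breath_parameters`, one row per breath.
#' @export
breath_parameters <- function(level, rate, markers,
                              subject = "", device = "", session = "") {
  tim <- timing_indices(markers)
  ie <- ie50(level, rate, markers)
  out <- cbind(subject = subject, device = device, session = session,
               merge(tim, ie, by = "breath_id"))
  class(out) <- c("breath_parameters", "data.frame")
  out
}

#' Per-subject epoch averages of the tidal parameters
#'
#' Unweighted arithmetic mean of each parameter over the breaths of an
#' epoch. Ratio parameters are averaged as per-breath ratios (the mean of
#' `tI/tE`, not the ratio of mean `tI` to mean `tE`), and missing IE50
#' values (flagged breaths) are dropped from the IE50 mean only.
#'
#' @param params A `breath_parameters` data frame (or any data frame with
#'   the parameter columns plus `subject`, `device`, `session`).
#' @return Data frame with one row per subject x device x session and the
#'   mean of each of the seven parameters plus `n_breaths`.
#' @export
average_subject <- function(params) {
  stopifnot(is.data.frame(params))
  if (nrow(params) == 0L) stop("no breaths to average")
  cols <- c("tI", "tE", "tTot", "RR", "tI_over_tE", "tI_over_tTot", "IE50")
  stopifnot(all(cols %in% names(params)))
  key <- interaction(params$subject, params$device, params$session, drop = TRUE)
  rows <- lapply(split(params, key), function(g) {
    means <- vapply(cols, function(cl) mean(g[[cl]], na.rm = TRUE), 0)
    cbind(data.frame(subject = g$subject[1], device = g$device[1],
                     session = g$session[1], n_breaths = nrow(g)),
          as.data.frame(as.list(means)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Breath-time tolerance implied by a respiratory-rate tolerance
#'
#' Since `RR = 60 / tTot`, a discrepancy `delta_rr` at rate `rr` implies a
#' total-breath-time discrepancy `|60/rr - 60/(rr + delta_rr)|`. A
#' clinical tolerance of +/- 2 breaths per minute therefore translates
#' into under 0.3 s at 20 brpm but under 0.05 s at 50 brpm: agreement
#' bands on RR and tTot must be judged jointly.
#'
#' @param rr Respiratory rate in breaths per minute (> 0).
#' @param delta_rr Rate discrepancy in breaths per minute.
#' @return Implied absolute tTot discrepancy in seconds.
#' @examples
#' rr_ttot_tolerance(20, 2)  # 0.2727 s
#' rr_ttot_tolerance(50, 2)  # 0.0462 s
#' @export
rr_ttot_tolerance <- function(rr, delta_rr) {
  if (any(rr <= 0) || any(rr + delta_rr <= 0))
    stop("rates must remain positive")
  abs(60 / rr - 60 / (rr + delta_rr))
}
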