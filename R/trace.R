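#' Uniformly sampled device signal
#'
#' A `resp_trace` holds one uniformly sampled signal from a respiratory
#' measurement device: flow or integrated volume from a pneumotachograph,
#' or a thoraco-abdominal wall displacement trace. Sampling is implied by
#' the rate `fs` and start time `t0`; sample `k` (1-based) sits at
#' `t0 + (k - 1) / fs`.
#'
#' @param values Numeric vector of samples; must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param label Short description of what the signal is
#'   (e.g. `"pnt_flow"`, `"pnt_volume"`, `"slp"`).
#' @param units Signal units as a string (informational).
#' @return An object of class `resp_trace`.
#' @examples
#' tr <- resp_trace(sin(2 * pi * 0.25 * seq(0, 10, by = 0.01)), fs = 100)
#' tr
#' @export
resp_trace <- function(values, fs, t0 = 0, label = "", units = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("trace must contain at least one sample")
  if (!all(is.finite(values))) stop("trace values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  structure(
    list(values = values, fs = fs, t0 = as.numeric(t0),
         label = as.character(label), units = as.character(units)),
    class = "resp_trace"
  )
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("<resp_trace> %s%s: %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
              x$label, if (nzchar(x$units)) paste0(" (", x$units, ")") else "",
              length(x$values), x$fs, x$t0, trace_end(x)))
  invisible(x)
}

#' @export
length.resp_trace <- function(x) length(x$values)

#' Sample times of a trace
#'
#' @param trace A [resp_trace].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "resp_trace"))
  trace$t0 + (seq_along(trace$values) - 1) / trace$fs
}

#' Time of the last sample of a trace
#' @param trace A [resp_trace].
#' @return Last sample time in seconds.
#' @export
trace_end <- function(trace) {
  trace$t0 + (length(trace$values) - 1) / trace$fs
}

#' Crop a trace to a time window
#'
#' Keeps samples with times in `[t_start, t_end]` (inclusive, up to a
#' half-sample tolerance on the boundaries).
#'
#' @param trace A [resp_trace].
#' @param t_start,t_end Window boundaries in seconds.
#' @return A [resp_trace] covering the requested window.
#' @export
crop_trace <- function(trace, t_start, t_end) {
  stopifnot(inherits(trace, "resp_trace"))
  if (t_end <= t_start) stop("t_end must exceed t_start")
  tt <- trace_times(trace)
  tol <- 0.5 / trace$fs
  keep <- which(tt >= t_start - tol & tt <= t_end + tol)
  if (length(keep) < 1L) stop("crop window does not overlap the trace")
  resp_trace(trace$values[keep], trace$fs, t0 = tt[keep[1]],
             label = trace$label, units = trace$units)
}

#' First derivative of a trace by central differences
#'
#' Interior samples use the symmetric two-sided difference
#' `(x[k+1] - x[k-1]) * fs / 2`; the end points use one-sided differences.
#' Used to obtain a displacement-rate trace from a displacement trace.
#'
#' @param trace A [resp_trace] with at least 3 samples.
#' @return A [resp_trace] of the derivative, same rate and time base.
#' @export
derivative_trace <- function(trace) {
  stopifnot(inherits(trace, "resp_trace"))
  x <- trace$values
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * trace$fs
  d[n] <- (x[n] - x[n - 1]) * trace$fs
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * trace$fs / 2
  resp_trace(d, trace$fs, t0 = trace$t0,
             label = paste0(trace$label, "_rate"),
             units = if (nzchar(trace$units)) paste0(trace$units, "/s") else "")
}

#' Linear interpolation of a trace at arbitrary times
#'
#' @param trace A [resp_trace].
#' @param t Times in seconds (must lie within the trace span).
#' @return Interpolated values.
#' @keywords internal
trace_at <- function(trace, t) {
  stats::approx(trace_times(trace), trace$values, xout = t, rule = 2)$y
}

#' Write a trace to a two-column CSV file
#'
#' The format is `time_s,value` with a header row, the interchange format
#' used for all recordings in this package.
#'
#' @param trace A [resp_trace].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "resp_trace"))
  df <- data.frame(time_s = trace_times(trace), value = trace$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace from a two-column CSV file
#'
#' Expects columns `time_s` and `value`, uniform sampling. Non-uniform
#' time stamps (a gap or jitter beyond 1% of the sampling interval) are
#' rejected with an error naming the file.
#'
#' @param path CSV file path.
#' @param label,units Metadata to attach to the trace.
#' @return A [resp_trace].
#' @export
read_trace_csv <- function(path, label = "", units = "") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop(sprintf("'%s': expected columns time_s,value", path))
  tt <- df$time_s
  if (length(tt) < 2L) stop(sprintf("'%s': too few samples", path))
  dt <- diff(tt)
  if (any(dt <= 0) || max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt))
    stop(sprintf("'%s': time stamps are not uniformly spaced", path))
  resp_trace(df$value, fs = 1 / stats::median(dt), t0 = tt[1],
             label = label, units = units)
}
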