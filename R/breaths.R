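#' Detect candidate peaks and troughs of a respiratory trace
#'
#' Estimates the first derivative by central differences, smooths the
#' derivative (only the derivative - the trace values themselves are never
#' smoothed, so marker values stay faithful to the unfiltered signal) with
#' a moving average of width `derivative_smoothing`, and takes its zero
#' crossings as candidate extrema. Each crossing is refined to the most
#' extreme raw sample in its neighbourhood, and consecutive extrema of the
#' same type are collapsed to the more extreme one so the output strictly
#' alternates trough/peak. Detection is invariant to positive rescaling of
#' the trace.
#'
#' @param trace A [resp_trace] at least 1 s long.
#' @param derivative_smoothing Moving-average window applied to the
#'   derivative, in seconds.
#' @return A data frame with columns `time`, `value`, `type`
#'   (`"trough"`/`"peak"`), ordered in time and alternating; zero rows for
#'   a constant trace.
#' @export
detect_extrema <- function(trace, derivative_smoothing = 0.2) {
  stopifnot(inherits(trace, "resp_trace"))
  x <- trace$values
  n <- length(x)
  if ((n - 1) / trace$fs < 1) stop("trace must be at least 1 s long")
  empty <- data.frame(time = numeric(0), value = numeric(0),
                      type = character(0))
  if (max(x) == min(x)) return(empty)
  d <- derivative_trace(trace)$values
  w <- max(1L, as.integer(round(derivative_smoothing * trace$fs)))
  if (w %% 2 == 0) w <- w + 1L  # symmetric window: no phase shift
  if (w > 1L) {
    raw <- d
    d <- as.numeric(stats::filter(d, rep(1 / w, w), sides = 2))
    d[is.na(d)] <- raw[is.na(d)]  # keep the raw derivative at the edges
  }
  s <- sign(d)
  flips <- which(s[-1] * s[-n] < 0 | (s[-n] != 0 & s[-1] == 0))
  if (!length(flips)) return(empty)
  half <- max(1L, (w - 1L) %/% 2L)
  cand <- lapply(flips, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + 1L + half)
    seg <- x[lo:hi]
    if (d[i] > 0) {                       # rising -> falling: peak
      j <- lo + which.max(seg) - 1L
      list(idx = j, type = "peak")
    } else {
      j <- lo + which.min(seg) - 1L
      list(idx = j, type = "trough")
    }
  })
  idx <- vapply(cand, `[[`, 0L, "idx")
  type <- vapply(cand, `[[`, "", "type")
  keep <- !duplicated(idx)
  idx <- idx[keep]; type <- type[keep]
  ord <- order(idx); idx <- idx[ord]; type <- type[ord]
  # collapse runs of same-type extrema to the most extreme member
  out_idx <- integer(0); out_type <- character(0)
  i <- 1L
  while (i <= length(idx)) {
    j <- i
    while (j < length(idx) && type[j + 1] == type[i]) j <- j + 1L
    run <- idx[i:j]
    best <- if (type[i] == "peak") run[which.max(x[run])] else run[which.min(x[run])]
    out_idx <- c(out_idx, best); out_type <- c(out_type, type[i])
    i <- j + 1L
  }
  tt <- trace_times(trace)
  out <- data.frame(time = tt[out_idx], value = x[out_idx], type = out_type)
  attr(out, "t_range") <- c(tt[1], tt[n])
  out
}

#' Screening rules for artifact breath exclusion
#'
#' A programmatic replacement for by-eye exclusion of artifactual breaths:
#' a candidate breath is rejected if its total duration falls outside
#' `[min_tTot, max_tTot]` or if its inspiratory excursion is below
#' `min_amplitude_fraction` of the median excursion across candidates.
#'
#' @param min_tTot,max_tTot Allowed breath duration range in seconds.
#' @param min_amplitude_fraction Minimum excursion as a fraction of the
#'   median candidate excursion, in (0, 1).
#' @param edge_guard Breaths with a marker closer than this (seconds) to
#'   either end of the analyzed trace are rejected: an extremum that close
#'   to the edge cannot be confirmed (the signal might continue past the
#'   cut, so a noise dip at the boundary would masquerade as a marker).
#'   Applied only when the candidates carry the trace span (as those from
#'   [detect_extrema()] do).
#' @param min_return_fraction Minimum expiratory excursion (peak value
#'   minus expiratory-end value) as a fraction of the inspiratory
#'   excursion (peak value minus inspiratory-start value). A breath whose
#'   expiration does not come back down - typically the last breath of an
#'   epoch cut mid-expiration, whose "trough" is a noise dip on the
#'   falling limb - is rejected as incomplete.
#' @param enforce_alternation Require strictly alternating candidates
#'   (error rather than silently reorder if violated).
#' @return An object of class `screening_rules`.
#' @export
screening_rules <- function(min_tTot = 0.5, max_tTot = 15,
                            min_amplitude_fraction = 0.25,
                            edge_guard = 0.2,
                            min_return_fraction = 0.75,
                            enforce_alternation = TRUE) {
  if (min_tTot <= 0 || max_tTot <= min_tTot)
    stop("need 0 < min_tTot < max_tTot")
  if (min_amplitude_fraction <= 0 || min_amplitude_fraction >= 1)
    stop("min_amplitude_fraction must be in (0, 1)")
  if (edge_guard < 0) stop("edge_guard must be non-negative")
  if (min_return_fraction < 0 || min_return_fraction >= 1)
    stop("min_return_fraction must be in [0, 1)")
  structure(list(min_tTot = min_tTot, max_tTot = max_tTot,
                 min_amplitude_fraction = min_amplitude_fraction,
                 edge_guard = edge_guard,
                 min_return_fraction = min_return_fraction,
                 enforce_alternation = isTRUE(enforce_alternation)),
            class = "screening_rules")
}

#' Assemble and screen breaths from alternating extrema
#'
#' Applies the amplitude rule in two stages. First, low-prominence
#' adjacent trough/peak pairs - noise chatter whose swing is below
#' `min_amplitude_fraction` of the typical candidate swing (the 95th
#' percentile of adjacent swings, recomputed as pairs are removed) - are
#' pruned iteratively, smallest swing first. Pruning a pair preserves
#' alternation and re-joins the surrounding real markers, so a wiggle in
#' the middle of a limb cannot split a breath in two. Second, candidate
#' breaths are assembled trough -> peak -> trough (inspiratory start,
#' expiratory start, expiratory end; contiguous breaths share markers) and
#' those violating the duration, amplitude, or epoch-edge
#' [screening_rules()] are removed. Breaths truncated at the epoch edges
#' never appear, because a breath requires all three markers; breaths
#' whose markers fall inside the `edge_guard` zone are additionally
#' rejected because an extremum that close to the cut cannot be told from
#' a noise dip at the boundary. Every removal is recorded with its reason.
#'
#' @param candidates Data frame from [detect_extrema()].
#' @param rules A [screening_rules()].
#' @return An object of class `breath_markers`: a data frame with columns
#'   `breath_id`, `insp_start`, `exp_start`, `exp_end`, plus an
#'   `excluded` attribute logging removed breaths and reasons. Zero rows
#'   (with a warning) if nothing survives.
#' @export
screen_breaths <- function(candidates, rules = screening_rules()) {
  stopifnot(is.data.frame(candidates), inherits(rules, "screening_rules"))
  t_range <- attr(candidates, "t_range")
  empty <- breath_markers(data.frame(insp_start = numeric(0),
                                     exp_start = numeric(0),
                                     exp_end = numeric(0)))
  if (nrow(candidates) < 3L) {
    if (nrow(candidates) > 0L) warning("no complete breath among candidates")
    return(empty)
  }
  if (rules$enforce_alternation &&
      any(candidates$type[-1] == candidates$type[-nrow(candidates)]))
    stop("candidate extrema must alternate trough/peak")
  # stage 1: iteratively prune low-prominence adjacent pairs (noise chatter)
  pruned <- data.frame(insp_start = numeric(0), reason = character(0))
  more_extreme <- function(cand, i, j) {
    # does row i beat row j as a representative of their shared type?
    if (cand$type[i] == "peak") cand$value[i] > cand$value[j]
    else cand$value[i] < cand$value[j]
  }
  while (nrow(candidates) >= 2L) {
    swing <- abs(diff(candidates$value))
    thr <- rules$min_amplitude_fraction *
      stats::quantile(swing, 0.95, names = FALSE)
    i <- which.min(swing)
    if (swing[i] >= thr) break
    pruned <- rbind(pruned, data.frame(
      insp_start = candidates$time[i],
      reason = "low-prominence extremum pair pruned"))
    if (i == 1L || i + 1L == nrow(candidates)) {
      # at the sequence edge, drop only the outermost member (deleting the
      # whole pair could discard a real extremum that has no same-type
      # neighbour to merge into); single removal preserves alternation
      candidates <- candidates[-(if (i == 1L) 1L else nrow(candidates)), ,
                               drop = FALSE]
    } else {
      # a deleted member replaces its same-type neighbour when more extreme,
      # so chatter clusters around a real extremum collapse to the envelope
      if (more_extreme(candidates, i + 1L, i - 1L))
        candidates[i - 1L, ] <- candidates[i + 1L, ]
      if (more_extreme(candidates, i, i + 2L))
        candidates[i + 2L, ] <- candidates[i, ]
      candidates <- candidates[-c(i, i + 1L), , drop = FALSE]
    }
  }
  if (nrow(candidates) < 3L) {
    warning("no complete breath among candidates")
    attr(empty, "excluded") <- pruned
    return(empty)
  }
  tr <- which(candidates$type == "trough")
  breaths <- list(); excl <- list()
  for (i in tr) {
    if (i + 2L > nrow(candidates)) break
    if (candidates$type[i + 1] != "peak" || candidates$type[i + 2] != "trough")
      next
    breaths[[length(breaths) + 1L]] <- data.frame(
      insp_start = candidates$time[i],
      exp_start = candidates$time[i + 1],
      exp_end = candidates$time[i + 2],
      amplitude = candidates$value[i + 1] - candidates$value[i],
      return_amp = candidates$value[i + 1] - candidates$value[i + 2]
    )
  }
  if (!length(breaths)) {
    warning("no complete breath among candidates")
    return(empty)
  }
  b <- do.call(rbind, breaths)
  med_amp <- stats::median(b$amplitude)
  tTot <- b$exp_end - b$insp_start
  reason <- rep(NA_character_, nrow(b))
  reason[tTot < rules$min_tTot] <- "tTot below minimum"
  reason[tTot > rules$max_tTot] <- "tTot above maximum"
  low_amp <- b$amplitude < rules$min_amplitude_fraction * med_amp
  reason[is.na(reason) & low_amp] <- "amplitude below fraction of median"
  ret_frac <- rules$min_return_fraction %||% 0
  incomplete <- b$return_amp < ret_frac * b$amplitude
  reason[is.na(reason) & incomplete] <- "incomplete expiratory return"
  guard <- rules$edge_guard %||% 0
  if (!is.null(t_range) && guard > 0) {
    at_edge <- b$insp_start < t_range[1] + guard |
      b$exp_end > t_range[2] - guard
    reason[is.na(reason) & at_edge] <- "marker too close to epoch edge"
  }
  keep <- is.na(reason)
  if (!any(keep)) warning("all candidate breaths were screened out")
  out <- breath_markers(b[keep, c("insp_start", "exp_start", "exp_end"),
                          drop = FALSE])
  attr(out, "excluded") <- rbind(pruned, data.frame(
    insp_start = b$insp_start[!keep], reason = reason[!keep]))
  out
}

#' Per-breath marker table
#'
#' Validates and wraps a table of inspiratory-start / expiratory-start /
#' expiratory-end times. Markers must satisfy
#' `insp_start < exp_start < exp_end` within each breath and breaths must
#' be time-ordered and non-overlapping.
#'
#' @param df Data frame with columns `insp_start`, `exp_start`, `exp_end`
#'   in seconds.
#' @return An object of class `breath_markers` (a data frame with a
#'   `breath_id` column added).
#' @export
breath_markers <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("insp_start", "exp_start", "exp_end") %in% names(df)))
  df <- df[, c("insp_start", "exp_start", "exp_end"), drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df)) {
    if (any(!(df$insp_start < df$exp_start & df$exp_start < df$exp_end)))
      stop("markers must satisfy insp_start < exp_start < exp_end")
    if (nrow(df) > 1 && any(df$insp_start[-1] < df$exp_end[-nrow(df)] - 1e-9))
      stop("breaths must be time-ordered and non-overlapping")
  }
  df <- cbind(breath_id = seq_len(nrow(df)), df)
  class(df) <- c("breath_markers", "data.frame")
  df
}

#' @export
print.breath_markers <- function(x, ...) {
  cat(sprintf("<breath_markers> %d breaths", nrow(x)))
  ex <- attr(x, "excluded")
  if (!is.null(ex) && nrow(ex)) cat(sprintf(" (%d excluded)", nrow(ex)))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Establish a one-to-one breath correspondence between devices
#'
#' Greedy nearest matching on inspiratory start times: candidate pairs are
#' considered in order of increasing time difference and accepted while
#' within `tolerance` and while neither breath is already matched.
#' Matching by proximity rather than ordinal index survives a breath
#' missed by one device. Unmatched breaths are reported and excluded from
#' paired analyses.
#'
#' @param a,b [breath_markers] from two aligned, truncated traces.
#' @param tolerance Maximum inspiratory-start discrepancy in seconds.
#' @return An object of class `breath_pairing`: data frame `pairs` with
#'   columns `a`, `b` (breath ids) and `delta` (start-time difference),
#'   plus `unpaired_a`, `unpaired_b`.
#' @export
pair_breaths <- function(a, b, tolerance = 0.5) {
  stopifnot(inherits(a, "breath_markers"), inherits(b, "breath_markers"))
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(structure(list(pairs = data.frame(a = integer(0), b = integer(0),
                                             delta = numeric(0)),
                          unpaired_a = a$breath_id, unpaired_b = b$breath_id),
                     class = "breath_pairing"))
  }
  d <- abs(outer(a$insp_start, b$insp_start, "-"))
  ord <- order(d)
  used_a <- rep(FALSE, nrow(a)); used_b <- rep(FALSE, nrow(b))
  pa <- pb <- integer(0); pd <- numeric(0)
  for (k in ord) {
    if (d[k] > tolerance) break
    i <- (k - 1) %% nrow(a) + 1
    j <- (k - 1) %/% nrow(a) + 1
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    pa <- c(pa, i); pb <- c(pb, j); pd <- c(pd, d[k])
  }
  ord2 <- order(pa)
  structure(list(pairs = data.frame(a = pa[ord2], b = pb[ord2],
                                    delta = pd[ord2]),
                 unpaired_a = a$breath_id[!used_a],
                 unpaired_b = b$breath_id[!used_b]),
            class = "breath_pairing")
}

#' @export
print.breath_pairing <- function(x, ...) {
  cat(sprintf("<breath_pairing> %d pairs; %d/%d unpaired (A/B)\n",
              nrow(x$pairs), length(x$unpaired_a), length(x$unpaired_b)))
  invisible(x)
}
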