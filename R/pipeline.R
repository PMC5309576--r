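#' Configuration of an end-to-end agreement study
#'
#' Bundles the cohort specification, measurement sessions, preprocessing
#' and screening options, and the analysis settings for [run_study()].
#' Sessions mirror a repeatability protocol: two resting sessions and one
#' elevated-rate session measured after exercise. Each session entry is a
#' list of [sim_config()] field overrides applied on top of the base
#' configuration; the default elevated session shortens breaths to a
#' median rate near 45 breaths per minute with a near-symmetric loop.
#'
#' @param cohort A base [sim_config()] for simulation, or a directory path
#'   containing a cohort written by [write_cohort()] (then `sessions` is
#'   ignored and the directory is analyzed as a single session).
#' @param n_subjects Number of simulated subjects.
#' @param sessions Named list of per-session [sim_config()] overrides.
#' @param subject_cv Between-subject variation passed to [make_cohort()].
#' @param lead_in Familiarization period in seconds, ignored by analysis.
#' @param analysis_window Analyzed epoch length in seconds.
#' @param rules [screening_rules()] for artifact breath exclusion.
#' @param derivative_smoothing Detection smoothing window in seconds.
#' @param pair_tolerance Breath pairing tolerance in seconds.
#' @param max_lag Alignment search half-window in seconds.
#' @param lag_override Optional named list `subject -> lag (s)` replacing
#'   the automatic estimate (the programmatic analogue of fixing one
#'   pair's synchronization by eye).
#' @param alpha,power Significance level and target power for the session
#'   comparisons.
#' @param multiplier LOA multiplier (1.96 for 95% limits).
#' @param seed Master seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort = sim_config(),
                         n_subjects = 21,
                         sessions = list(
                           REST1 = list(),
                           REST2 = list(),
                           POST_CST = list(mean_tI = 0.66, mean_tE = 0.73,
                                           target_IE50 = 1.0)),
                         subject_cv = 0.15,
                         lead_in = 15,
                         analysis_window = 45,
                         rules = screening_rules(),
                         derivative_smoothing = 0.2,
                         pair_tolerance = 0.5,
                         max_lag = 5,
                         lag_override = NULL,
                         alpha = 0.05,
                         power = 0.8,
                         multiplier = 1.96,
                         seed = 1L) {
  if (!inherits(cohort, "sim_config") &&
      !(is.character(cohort) && length(cohort) == 1L))
    stop("cohort must be a sim_config or a directory path")
  if (length(sessions) < 1L || is.null(names(sessions)))
    stop("sessions must be a non-empty named list")
  structure(list(cohort = cohort, n_subjects = as.integer(n_subjects),
                 sessions = sessions, subject_cv = subject_cv,
                 lead_in = lead_in, analysis_window = analysis_window,
                 rules = rules, derivative_smoothing = derivative_smoothing,
                 pair_tolerance = pair_tolerance, max_lag = max_lag,
                 lag_override = lag_override, alpha = alpha, power = power,
                 multiplier = multiplier, seed = as.integer(seed)),
            class = "study_config")
}

#' Preprocess and extract breaths from one paired recording
#'
#' Runs the per-subject pipeline: resample the displacement trace to the
#' PNT rate with the shape-preserving interpolant, band-pass filter copies
#' of both level traces, estimate the inter-device lag from the peak of
#' their normalized cross-correlation, align and truncate the unfiltered
#' traces, restrict to the analysis window, detect and screen breaths on
#' each device, pair them one-to-one, and compute the seven per-breath
#' parameters per device.
#'
#' @param rec A [paired_recording].
#' @param filt Optional pre-designed [design_alignment_filter()] at the
#'   PNT rate (designed on the fly if `NULL`).
#' @param lead_in,analysis_window Epoch policy in seconds; `NULL` window
#'   analyzes everything after `lead_in`.
#' @param rules [screening_rules()].
#' @param derivative_smoothing,pair_tolerance,max_lag,lag_override As in
#'   [study_config()] (scalar `lag_override` here).
#' @return List with `params_pnt`, `params_slp` (breath parameter tables),
#'   `markers_pnt`, `markers_slp`, `pairing`, `alignment`, `lag_used`.
#' @export
process_recording <- function(rec, filt = NULL, lead_in = 0,
                              analysis_window = NULL,
                              rules = screening_rules(),
                              derivative_smoothing = 0.2,
                              pair_tolerance = 0.5, max_lag = 5,
                              lag_override = NULL) {
  stopifnot(inherits(rec, "paired_recording"))
  fs <- rec$pnt_volume$fs
  if (is.null(filt)) filt <- design_alignment_filter(fs)
  slp_r <- resample_trace(rec$slp, fs)
  vol_f <- bandpass_zero_phase(rec$pnt_volume, filt)
  slp_f <- bandpass_zero_phase(slp_r, filt)
  al <- estimate_lag(vol_f, slp_f, max_lag = max_lag)
  lag_used <- if (!is.null(lag_override)) {
    al$method <- "manual"
    as.numeric(lag_override)
  } else al$lag
  ali_v <- align_and_truncate(rec$pnt_volume, slp_r, lag_used)
  ali_f <- align_and_truncate(rec$pnt_flow, slp_r, lag_used)
  vol <- ali_v$a; slp <- ali_v$b; flow <- ali_f$a
  t_start <- vol$t0 + lead_in
  t_stop <- if (is.null(analysis_window)) trace_end(vol)
            else min(t_start + analysis_window, trace_end(vol))
  vol <- crop_trace(vol, t_start, t_stop)
  slp <- crop_trace(slp, t_start, t_stop)
  flow <- crop_trace(flow, t_start, t_stop)
  m_pnt <- screen_breaths(detect_extrema(vol, derivative_smoothing), rules)
  m_slp <- screen_breaths(detect_extrema(slp, derivative_smoothing), rules)
  pairing <- pair_breaths(m_pnt, m_slp, tolerance = pair_tolerance)
  subject <- rec$subject %||% ""
  list(params_pnt = breath_parameters(vol, flow, m_pnt, subject = subject,
                                      device = "PNT"),
       params_slp = breath_parameters(slp, derivative_trace(slp), m_slp,
                                      subject = subject, device = "SLP"),
       markers_pnt = m_pnt, markers_slp = m_slp,
       pairing = pairing, alignment = al, lag_used = lag_used)
}

param_cols <- c("tI", "tE", "tTot", "RR", "tI_over_tE", "tI_over_tTot", "IE50")

# Assemble breath-level and subject-averaged diff samples per parameter
# from the per-subject pipeline outputs of one session.
session_diff_samples <- function(processed, session) {
  breath <- lapply(param_cols, function(pc) {
    ref <- tst <- numeric(0); subj <- character(0)
    for (pr in processed) {
      p <- pr$pairing$pairs
      if (!nrow(p)) next
      x <- pr$params_pnt[[pc]][match(p$a, pr$params_pnt$breath_id)]
      y <- pr$params_slp[[pc]][match(p$b, pr$params_slp$breath_id)]
      ok <- is.finite(x) & is.finite(y)
      ref <- c(ref, x[ok]); tst <- c(tst, y[ok])
      subj <- c(subj, rep(pr$params_pnt$subject[1], sum(ok)))
    }
    diff_sample(ref, tst, subject = subj, parameter = pc, session = session)
  })
  averaged <- lapply(param_cols, function(pc) {
    ref <- tst <- numeric(0); subj <- character(0)
    for (pr in processed) {
      if (!nrow(pr$params_pnt) || !nrow(pr$params_slp)) next
      x <- mean(pr$params_pnt[[pc]], na.rm = TRUE)
      y <- mean(pr$params_slp[[pc]], na.rm = TRUE)
      if (!is.finite(x) || !is.finite(y)) next
      ref <- c(ref, x); tst <- c(tst, y)
      subj <- c(subj, pr$params_pnt$subject[1])
    }
    diff_sample(ref, tst, subject = subj, parameter = pc, session = session)
  })
  names(breath) <- names(averaged) <- param_cols
  list(breath = breath, averaged = averaged)
}

pool_diff_samples <- function(s1, s2, session) {
  diff_sample(c(s1$reference, s2$reference), c(s1$test, s2$test),
              subject = c(s1$subject, s2$subject),
              parameter = s1$parameter, session = session)
}

fit_row <- function(fit, level) {
  data.frame(session = fit$session, parameter = fit$parameter, level = level,
             bias = fit$bias,
             sd = (fit$sd_total %||% fit$sd),
             loa_lower = fit$loa_lower, loa_upper = fit$loa_upper,
             se_limit = fit$se_limit, n = fit$n,
             pearson_r = fit$pearson_r %||% NA_real_)
}

#' Run a complete simulated agreement study
#'
#' Simulates (or reads) a cohort for each measurement session, runs the
#' per-subject pipeline ([process_recording()]), and assembles the
#' agreement analyses: per-parameter Bland-Altman fits of the averaged
#' parameters, repeated-measures fits of the breath-by-breath parameters,
#' percentage differences, session comparisons (first vs second rest
#' session and pooled rest vs post-exercise) with Wald tests of limit
#' equality and minimum detectable limit changes at the configured power,
#' plus distribution diagnostics. Deterministic given the configuration
#' and seed.
#'
#' @param config A [study_config()].
#' @return A list (class `study_report`) with `breath_table`,
#'   `subject_summary`, `agreement`, `percent`, `comparisons`,
#'   `diagnostics`, `exclusions`, `fits` and `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  simulate <- inherits(config$cohort, "sim_config")
  session_names <- if (simulate) names(config$sessions) else "SESSION1"

  # subject multipliers drawn once so all sessions measure the same cohort
  jitter <- if (simulate)
    with_seed(config$seed, {
      matrix(exp(stats::rnorm(5 * config$n_subjects, 0, config$subject_cv)),
             nrow = config$n_subjects, ncol = 5)
    })
  filt <- NULL
  processed <- list(); samples <- list()
  breath_rows <- list(); summary_rows <- list(); excl_rows <- list()

  for (j in seq_along(session_names)) {
    sn <- session_names[j]
    cohort <- if (simulate) {
      base <- config$cohort
      over <- config$sessions[[sn]]
      cfg <- do.call(sim_config, utils::modifyList(
        unclass(base)[names(formals(sim_config))],
        c(over, list(epoch_length = config$lead_in + config$analysis_window))))
      make_cohort(config$n_subjects, cfg,
                  seed = (config$seed * 31 + j) %% 2147483647,
                  subject_cv = config$subject_cv, jitter = jitter)
    } else read_cohort(config$cohort)
    if (is.null(filt)) filt <- design_alignment_filter(cohort[[1]]$pnt_volume$fs)
    pr <- lapply(cohort, function(rec) {
      lo <- config$lag_override[[rec$subject %||% ""]]
      process_recording(rec, filt = filt, lead_in = config$lead_in,
                        analysis_window = config$analysis_window,
                        rules = config$rules,
                        derivative_smoothing = config$derivative_smoothing,
                        pair_tolerance = config$pair_tolerance,
                        max_lag = config$max_lag, lag_override = lo)
    })
    processed[[sn]] <- pr
    samples[[sn]] <- session_diff_samples(pr, sn)
    for (p in pr) {
      breath_rows[[length(breath_rows) + 1L]] <-
        cbind(session = sn, rbind(as.data.frame(p$params_pnt),
                                  as.data.frame(p$params_slp)))
      both <- rbind(p$params_pnt, p$params_slp)
      if (nrow(both)) {
        av <- average_subject(both)
        av$session <- sn
        summary_rows[[length(summary_rows) + 1L]] <-
          av[c("session", setdiff(names(av), "session"))]
      }
      for (side in c("markers_pnt", "markers_slp")) {
        ex <- attr(p[[side]], "excluded")
        if (!is.null(ex) && nrow(ex))
          excl_rows[[length(excl_rows) + 1L]] <- cbind(
            session = sn, subject = p$params_pnt$subject[1] %||% "",
            device = if (side == "markers_pnt") "PNT" else "SLP", ex)
      }
    }
  }

  # pooled rest sessions, when both rest sessions are present
  rest <- intersect(c("REST1", "REST2"), session_names)
  if (length(rest) == 2L) {
    samples$COMBINED_REST <- list(
      breath = lapply(param_cols, function(pc) pool_diff_samples(
        samples$REST1$breath[[pc]], samples$REST2$breath[[pc]],
        "COMBINED_REST")),
      averaged = lapply(param_cols, function(pc) pool_diff_samples(
        samples$REST1$averaged[[pc]], samples$REST2$averaged[[pc]],
        "COMBINED_REST")))
    names(samples$COMBINED_REST$breath) <- param_cols
    names(samples$COMBINED_REST$averaged) <- param_cols
  }

  fits <- list(); agree_rows <- list(); pct_rows <- list(); diag_rows <- list()
  for (sn in names(samples)) {
    for (pc in param_cols) {
      sb <- samples[[sn]]$breath[[pc]]
      sa <- samples[[sn]]$averaged[[pc]]
      if (length(sb$d) >= 2L && length(unique(sb$subject)) >= 2L) {
        fb <- loa_repeated(sb, multiplier = config$multiplier)
        fits[[sn]]$breath[[pc]] <- fb
        agree_rows[[length(agree_rows) + 1L]] <- fit_row(fb, "breath")
      }
      if (length(sa$d) >= 2L) {
        fa <- bland_altman(sa, multiplier = config$multiplier)
        fits[[sn]]$averaged[[pc]] <- fa
        agree_rows[[length(agree_rows) + 1L]] <- fit_row(fa, "averaged")
        if (all(sa$reference != 0)) {
          pb <- percent_diff(sa, multiplier = config$multiplier)$ba
          pct_rows[[length(pct_rows) + 1L]] <- data.frame(
            session = sn, parameter = pc, level = "averaged",
            bias_pct = pb$bias, loa_lower_pct = pb$loa_lower,
            loa_upper_pct = pb$loa_upper)
        }
      }
      if (length(sb$d) >= 2L && all(sb$reference != 0)) {
        pb <- percent_diff(sb, multiplier = config$multiplier)$ba
        pct_rows[[length(pct_rows) + 1L]] <- data.frame(
          session = sn, parameter = pc, level = "breath",
          bias_pct = pb$bias, loa_lower_pct = pb$loa_lower,
          loa_upper_pct = pb$loa_upper)
      }
      if (length(sb$d) >= 4L && stats::sd(sb$d) > 0) {
        dg <- distribution_diagnostics(sb)
        diag_rows[[length(diag_rows) + 1L]] <- data.frame(
          session = sn, parameter = pc, level = "breath",
          kurtosis = dg$kurtosis, ad_p = dg$ad_p, qq_dev = dg$qq_dev,
          log_retested = dg$log_retested,
          kurtosis_log = if (dg$log_retested) dg$log$kurtosis else NA_real_)
      }
    }
  }

  comparisons <- list(
    c("REST1", "REST2"),
    c("COMBINED_REST", "POST_CST"))
  comp_rows <- list()
  for (cmp in comparisons) {
    if (!all(cmp %in% names(fits))) next
    for (lvl in c("breath", "averaged")) {
      for (pc in param_cols) {
        g1 <- fits[[cmp[1]]][[lvl]][[pc]]
        g2 <- fits[[cmp[2]]][[lvl]][[pc]]
        if (is.null(g1) || is.null(g2)) next
        wt <- tryCatch(wald_loa_equality(g1, g2, alpha = config$alpha),
                       error = function(e) NULL)
        if (is.null(wt)) next
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          comparison = paste(cmp, collapse = " vs "), parameter = pc,
          level = lvl, p_lower = wt$p_lower, p_upper = wt$p_upper,
          p_joint = wt$p_joint,
          delta_min = detectable_loa_change(g1, g2, power = config$power,
                                            alpha = config$alpha))
      }
    }
  }

  cfg_file <- tempfile()
  saveRDS(config, cfg_file)
  manifest <- list(seed = config$seed,
                   n_subjects = config$n_subjects,
                   sessions = session_names,
                   analysis_window = config$analysis_window,
                   lead_in = config$lead_in,
                   package_version = as.character(utils::packageVersion("tidalagree")),
                   config_md5 = unname(tools::md5sum(cfg_file)))
  unlink(cfg_file)

  bind <- function(rows) if (length(rows)) {
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  } else data.frame()
  structure(list(
    breath_table = bind(breath_rows),
    subject_summary = bind(summary_rows),
    agreement = bind(agree_rows),
    percent = bind(pct_rows),
    comparisons = bind(comp_rows),
    diagnostics = bind(diag_rows),
    exclusions = bind(excl_rows),
    fits = fits, samples = samples, manifest = manifest
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> sessions: %s; %d breath rows, %d agreement fits\n",
              paste(x$manifest$sessions, collapse = ", "),
              nrow(x$breath_table), nrow(x$agreement)))
  invisible(x)
}

#' Write a cohort of paired recordings to a directory
#'
#' One set of CSV traces + JSON sidecar per subject
#' (see [write_recording()]) plus a `manifest.json` listing the subjects.
#'
#' @param cohort List of [paired_recording]s (e.g. from [make_cohort()]).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stems <- vapply(seq_along(cohort), function(i)
    cohort[[i]]$subject %||% sprintf("S%02d", i), "")
  for (i in seq_along(cohort)) write_recording(cohort[[i]], dir, stems[i])
  jsonlite::write_json(list(subjects = stems), file.path(dir, "manifest.json"),
                       auto_unbox = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json` and the per-subject
#'   files; a missing trace is reported with the offending file name.
#' @return List of [paired_recording]s.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing cohort manifest: ", mf)
  stems <- unlist(jsonlite::read_json(mf, simplifyVector = TRUE)$subjects)
  lapply(stems, function(s) read_recording(dir, s))
}
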