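#' Extract trimmed measurement windows from an annotated trace
#'
#' Splits a phase-annotated trace into its sealed measurement periods and
#' trims `exclusion` seconds from each side of every period, discarding the
#' interval right after flushing while the recirculation loop mixes and the
#' interval just before the next flush. Windows are half-open in time and
#' windows whose trimmed span falls below `min_window` are dropped with a
#' warning.
#'
#' @param trace A phase-annotated `o2_trace`.
#' @param exclusion Seconds removed from each end of every measurement
#'   period (default 60).
#' @param min_window Minimum retained window span in seconds (default 120).
#' @return A tibble with one row per retained window: `period_index`,
#'   `t_start`, `t_end`, `t_mid_s` and a `samples` list-column of
#'   (`time_s`, `o2_mgL`) tibbles.
#' @export
extract_windows <- function(trace, exclusion = 60, min_window = 120) {
  if (all(trace$phase == "unknown")) {
    abort_shoalmet("trace is not phase-annotated; run annotate_phases() first.",
                   "shoalmet_invalid_trace")
  }
  runs <- rle(trace$phase)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values == "measure"
  out <- vector("list", sum(keep))
  dropped <- 0L
  k <- 0L
  for (r in which(keep)) {
    idx <- starts[r]:ends[r]
    p_start <- trace$time_s[starts[r]]
    p_end_excl <- if (ends[r] < nrow(trace)) {
      trace$time_s[ends[r] + 1L] # first sample of the following flush
    } else {
      trace$time_s[ends[r]] + (trace$time_s[ends[r]] - trace$time_s[ends[r] - 1L])
    }
    w_start <- p_start + exclusion
    w_end <- p_end_excl - exclusion
    if (w_end - w_start < min_window) {
      dropped <- dropped + 1L
      next
    }
    sel <- idx[trace$time_s[idx] >= w_start & trace$time_s[idx] < w_end]
    k <- k + 1L
    out[[k]] <- tibble::tibble(
      period_index = k, # reindexed below once drops are known
      t_start = w_start,
      t_end = w_end,
      t_mid_s = (w_start + w_end) / 2,
      samples = list(tibble::tibble(time_s = trace$time_s[sel],
                                    o2_mgL = trace$o2_mgL[sel]))
    )
  }
  if (dropped > 0) {
    warning(sprintf("%d measurement period(s) shorter than %g s after trimming were dropped.",
                    dropped, min_window), call. = FALSE)
  }
  res <- dplyr::bind_rows(out[seq_len(k)])
  if (k > 0) res$period_index <- seq_len(k)
  res
}

#' Least-squares oxygen-uptake slope of one window
#'
#' Ordinary least-squares regression of oxygen concentration on time within a
#' measurement window, the per-period rate estimate at the heart of
#' intermittent-flow respirometry. The slope is rescaled to mg O2 L^-1 h^-1
#' and r^2 is the squared Pearson correlation of the fit; a window with zero
#' oxygen variance has no rate information and is assigned r^2 = 0 (QC fail).
#'
#' @param samples Tibble with `time_s` and `o2_mgL` (at least 3 rows).
#' @param qc_threshold Minimum r^2 for `qc_pass` (default 0.97).
#' @return One-row tibble: `slope_mgL_h`, `intercept_mgL`, `r_squared`,
#'   `n_samples`, `qc_pass`.
#' @examples
#' s <- tibble::tibble(time_s = 0:20 * 2, o2_mgL = 8 - 0.5 * (0:20 * 2) / 3600)
#' fit_slope(s)
#' @export
fit_slope <- function(samples, qc_threshold = 0.97) {
  if (nrow(samples) < 3) {
    abort_shoalmet("need at least 3 samples to fit a slope.",
                   "shoalmet_insufficient_data")
  }
  t_h <- samples$time_s / 3600
  if (stats::var(t_h) == 0) {
    abort_shoalmet("all timestamps identical; slope is undefined.",
                   "shoalmet_singular_fit")
  }
  if (stats::var(samples$o2_mgL) == 0) {
    return(tibble::tibble(
      slope_mgL_h = 0, intercept_mgL = samples$o2_mgL[1],
      r_squared = 0, n_samples = nrow(samples), qc_pass = FALSE
    ))
  }
  fit <- stats::lm(o2_mgL ~ t_h, data = data.frame(t_h = t_h,
                                                   o2_mgL = samples$o2_mgL))
  r2 <- stats::cor(t_h, samples$o2_mgL)^2
  tibble::tibble(
    slope_mgL_h = unname(stats::coef(fit)[2]),
    intercept_mgL = unname(stats::coef(fit)[1]),
    r_squared = r2,
    n_samples = nrow(samples),
    qc_pass = r2 > qc_threshold
  )
}

#' Fit all measurement-window slopes of a trace
#'
#' Convenience wrapper: [extract_windows()] then [fit_slope()] per window.
#'
#' @inheritParams extract_windows
#' @inheritParams fit_slope
#' @return A tibble of per-period slope estimates with window timing columns.
#' @export
fit_period_slopes <- function(trace, exclusion = 60, min_window = 120,
                              qc_threshold = 0.97) {
  win <- extract_windows(trace, exclusion = exclusion, min_window = min_window)
  if (nrow(win) == 0) {
    abort_shoalmet("no usable measurement windows in trace.",
                   "shoalmet_insufficient_data")
  }
  fits <- purrr::map(win$samples, fit_slope, qc_threshold = qc_threshold)
  dplyr::bind_cols(
    win[c("period_index", "t_start", "t_end", "t_mid_s")],
    dplyr::bind_rows(fits)
  )
}

#' Convert oxygen-depletion slopes to oxygen-uptake rates
#'
#' MO2 = -slope x V_eff, with consumption positive: a declining oxygen trace
#' (negative slope, mg L^-1 h^-1) over an effective water volume V_eff
#' (litres) gives the whole-animal uptake in mg O2 h^-1. V_eff is the inner
#' chamber volume minus the fish's body volume (see [effective_volume()]).
#'
#' @param slopes A tibble of slope estimates (from [fit_period_slopes()] or
#'   [fit_slope()]).
#' @param chamber A [chamber_spec()].
#' @param fish_mass Fish wet mass, grams.
#' @param subtract_body_volume Subtract body volume from the chamber volume?
#' @return `slopes` with an added `mo2` column (mg O2 h^-1).
#' @examples
#' est <- tibble::tibble(slope_mgL_h = -0.5)
#' slope_to_mo2(est, chamber_spec(), fish_mass = 1.84)$mo2
#' @export
slope_to_mo2 <- function(slopes, chamber, fish_mass,
                         subtract_body_volume = TRUE) {
  v_eff <- effective_volume(chamber, fish_mass, subtract_body_volume)
  slopes$mo2 <- -slopes$slope_mgL_h * v_eff
  slopes
}

#' Fit the background-respiration model from empty-chamber trials
#'
#' Bacterial respiration is measured in the empty chamber for a few
#' measurement periods before and after each trial. Each background trace is
#' reduced to the mean oxygen uptake over its windows (full inner volume, no
#' fish), giving the rate at trial start (`rate_pre`) and trial end
#' (`rate_post`); in between the background is assumed to rise linearly.
#' Negative fitted rates are clamped to zero with a warning.
#'
#' @param pre_trace,post_trace Phase-annotated `o2_trace`s from the empty
#'   chamber before and after the trial.
#' @param chamber A [chamber_spec()].
#' @inheritParams extract_windows
#' @return A `background_model` list: `rate_pre`, `rate_post` (mg O2 h^-1).
#' @export
fit_background <- function(pre_trace, post_trace, chamber,
                           exclusion = 60, min_window = 120) {
  one <- function(trace, label) {
    win <- extract_windows(trace, exclusion = exclusion, min_window = min_window)
    if (nrow(win) < 1) {
      abort_shoalmet(
        sprintf("%s background trace has no usable measurement window.", label),
        "shoalmet_insufficient_background"
      )
    }
    fits <- dplyr::bind_rows(purrr::map(win$samples, fit_slope, qc_threshold = 0))
    mean(-fits$slope_mgL_h * chamber$inner_volume)
  }
  rate_pre <- one(pre_trace, "pre")
  rate_post <- one(post_trace, "post")
  if (rate_pre < 0 || rate_post < 0) {
    warning("negative fitted background rate clamped to 0.", call. = FALSE)
  }
  structure(
    list(rate_pre = max(0, rate_pre), rate_post = max(0, rate_post)),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> %.4g -> %.4g mg O2/h (linear in time)\n",
              x$rate_pre, x$rate_post))
  invisible(x)
}

#' Subtract time-interpolated background respiration
#'
#' Subtracts the bacterial contribution from each per-period uptake estimate,
#' interpolating the background linearly from `rate_pre` at `trial_start` to
#' `rate_post` at `trial_end` and evaluating it at each window's midpoint.
#' Corrected values are floored at zero (a fish cannot produce oxygen); the
#' number of floored periods is recorded in the `n_floored` attribute.
#'
#' @param slopes Tibble with `mo2` and `t_mid_s` columns.
#' @param background A [fit_background()] model.
#' @param trial_start,trial_end Trial time span in seconds.
#' @return `slopes` with `mo2_raw`, `mo2` replaced by the corrected rate, and
#'   a `corrected` flag.
#' @export
correct_background <- function(slopes, background, trial_start, trial_end) {
  if (trial_end <= trial_start) {
    abort_shoalmet("`trial_end` must exceed `trial_start`.",
                   "shoalmet_invalid_interval")
  }
  t <- slopes$t_mid_s
  if (any(t < trial_start | t > trial_end)) {
    abort_shoalmet("window midpoints must lie within [trial_start, trial_end].",
                   "shoalmet_invalid_interval")
  }
  frac <- (t - trial_start) / (trial_end - trial_start)
  bg <- background$rate_pre + (background$rate_post - background$rate_pre) * frac
  corrected <- slopes$mo2 - bg
  n_floored <- sum(corrected < 0)
  if (n_floored > 0) {
    warning(sprintf("%d corrected MO2 value(s) below 0 floored.", n_floored),
            call. = FALSE)
  }
  slopes$mo2_raw <- slopes$mo2
  slopes$mo2 <- pmax(0, corrected)
  slopes$corrected <- TRUE
  attr(slopes, "n_floored") <- n_floored
  slopes
}

#' Process one trial: trace to background-corrected MO2 series
#'
#' Full per-trial pipeline: trim measurement windows, fit per-period
#' least-squares slopes, convert to oxygen uptake over the effective volume,
#' and subtract the linearly interpolated background fitted from the pre- and
#' post-trial empty-chamber runs.
#'
#' @param trace Phase-annotated `o2_trace` of the fish trial.
#' @param pre_trace,post_trace Empty-chamber background traces.
#' @param chamber A [chamber_spec()]; defaults to the trace's chamber.
#' @param fish_mass Fish wet mass, grams.
#' @inheritParams extract_windows
#' @inheritParams fit_slope
#' @inheritParams slope_to_mo2
#' @return Tibble with one row per measurement period: window timing, slope,
#'   `r_squared`, `qc_pass`, `mo2_raw` and corrected `mo2`.
#' @export
process_trial <- function(trace, pre_trace, post_trace, fish_mass,
                          chamber = trace_chamber(trace),
                          exclusion = 60, min_window = 120,
                          qc_threshold = 0.97, subtract_body_volume = TRUE) {
  slopes <- fit_period_slopes(trace, exclusion = exclusion,
                              min_window = min_window,
                              qc_threshold = qc_threshold)
  slopes <- slope_to_mo2(slopes, chamber, fish_mass,
                         subtract_body_volume = subtract_body_volume)
  bg <- fit_background(pre_trace, post_trace, chamber,
                       exclusion = exclusion, min_window = min_window)
  dt <- chamber$sample_interval
  correct_background(slopes, bg,
                     trial_start = min(trace$time_s),
                     trial_end = max(trace$time_s) + dt)
}
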