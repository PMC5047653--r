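#' Minimum metabolic rate (lowest-decile MO2)
#'
#' MR_min is the standard-metabolic-rate proxy for intermittent-flow data:
#' the lowest 10th percentile of the per-period oxygen-uptake estimates over
#' the whole trial. The default estimator averages all values at or below the
#' empirical 10th percentile (at least one value is always included), which
#' is robust to single-period noise; `method = "quantile"` returns the
#' percentile point estimate instead.
#'
#' @param mo2 Numeric vector of QC-passing per-period MO2 values
#'   (mg O2 h^-1); at least 10 are required.
#' @param method `"decile_mean"` (default) or `"quantile"`.
#' @param probs Percentile defining "lowest" (default 0.10).
#' @return MR_min in mg O2 h^-1.
#' @examples
#' mr_min(1:10) # lowest decile is {1}
#' @export
mr_min <- function(mo2, method = c("decile_mean", "quantile"), probs = 0.10) {
  method <- match.arg(method)
  mo2 <- mo2[!is.na(mo2)]
  if (length(mo2) < 10) {
    abort_shoalmet(
      sprintf("MR_min needs at least 10 MO2 values; got %d.", length(mo2)),
      "shoalmet_insufficient_data"
    )
  }
  thr <- unname(stats::quantile(mo2, probs = probs, type = 7))
  if (method == "quantile") return(thr)
  low <- mo2[mo2 <= thr]
  if (length(low) == 0) low <- min(mo2)
  mean(low)
}

#' Routine metabolic rate
#'
#' Mean oxygen uptake of the undisturbed animal after a settling exclusion:
#' the arithmetic mean of per-period MO2 values whose window midpoint falls
#' after `settle_cutoff` hours from trial start, discarding the initial
#' handling-stress phase.
#'
#' @param mo2 Per-period MO2 values (mg O2 h^-1).
#' @param t_mid_h Window midpoints, hours from trial start.
#' @param settle_cutoff Hours excluded from the start (default 5).
#' @return RMR in mg O2 h^-1.
#' @export
rmr <- function(mo2, t_mid_h, settle_cutoff = 5) {
  stopifnot(length(mo2) == length(t_mid_h))
  keep <- !is.na(mo2) & t_mid_h > settle_cutoff
  if (!any(keep)) {
    abort_shoalmet(
      sprintf("no MO2 values after the %g h settling cutoff.", settle_cutoff),
      "shoalmet_insufficient_data"
    )
  }
  mean(mo2[keep])
}

#' Initial stress response
#'
#' The elevation of the very first post-transfer rate estimate above the
#' trial's minimum metabolic rate: first-period MO2 minus MR_min. It indexes
#' the handling/isolation stress reaction. If the first period failed QC the
#' ISR is reported missing rather than imputed from a later period.
#'
#' @param first_mo2 MO2 of the first measurement period (mg O2 h^-1), or `NA`
#'   if that period failed QC.
#' @param mr_min_value The trial's MR_min.
#' @return ISR in mg O2 h^-1 (`NA` if the first period is unusable).
#' @export
isr <- function(first_mo2, mr_min_value) {
  if (is.na(first_mo2)) return(NA_real_)
  first_mo2 - mr_min_value
}

#' Time for oxygen uptake to stabilise
#'
#' Detects when the declining post-handling metabolic rate settles: the
#' earliest window midpoint t* such that every rolling mean of `k`
#' consecutive periods from t* onwards stays within a fraction `delta` of
#' the trial's final reference level (the mean MO2 over the last `ref_window`
#' hours). If no such point exists the last midpoint is returned flagged
#' unstabilised.
#'
#' @param t_mid_h Window midpoints, hours from trial start (needs to span at
#'   least 3 h).
#' @param mo2 Per-period MO2 values.
#' @param k Rolling-window length in periods (default 3).
#' @param delta Relative tolerance around the reference level (default 0.10).
#' @param ref_window Hours at the trial end defining the reference level
#'   (default 3).
#' @return A list: `time_h` and logical `stabilized`.
#' @export
stabilization_time <- function(t_mid_h, mo2, k = 3, delta = 0.10,
                               ref_window = 3) {
  stopifnot(length(mo2) == length(t_mid_h))
  ok <- !is.na(mo2)
  t_mid_h <- t_mid_h[ok]
  mo2 <- mo2[ok]
  n <- length(mo2)
  if (n < k || diff(range(t_mid_h)) < 3) {
    abort_shoalmet("need at least 3 h of MO2 data to assess stabilization.",
                   "shoalmet_insufficient_data")
  }
  t_end <- t_mid_h[n]
  ref <- mean(mo2[t_mid_h >= t_end - ref_window])
  roll <- stats::filter(mo2, rep(1 / k, k), sides = 1)
  roll <- roll[k:n] # mean of periods (i-k+1)..i, aligned to start index below
  within <- abs(roll - ref) <= delta * abs(ref)
  # ok from window-start i onward <=> all rolling windows starting >= i pass
  ok_from <- rev(cumprod(rev(within))) > 0
  idx <- which(ok_from)
  if (length(idx) == 0) {
    return(list(time_h = t_mid_h[n], stabilized = FALSE))
  }
  list(time_h = t_mid_h[idx[1]], stabilized = TRUE)
}

#' Summarise one processed trial into its metabolic metrics
#'
#' Computes MR_min, RMR, ISR and stabilization time from a processed
#' per-period MO2 tibble (see [process_trial()]). Periods failing QC are
#' excluded from all metrics but counted; MR_min is taken over the whole
#' trial while RMR excludes the first `settle_cutoff` hours.
#'
#' @param slopes Tibble with `t_mid_s`, `mo2`, `qc_pass` (and optionally
#'   `period_index`).
#' @param fish_id,testing Trial identifiers carried into the output.
#' @param settle_cutoff RMR settling exclusion, hours (default 5).
#' @param mr_min_method Passed to [mr_min()].
#' @param isr_use_corrected Use the background-corrected first slope for ISR
#'   (default) or the raw one (requires an `mo2_raw` column).
#' @return One-row tibble: identifiers, `mr_min`, `rmr`, `isr`,
#'   `stabilization_h`, `stabilized`, `n_periods_total`, `n_periods_used`.
#' @export
summarize_trial <- function(slopes, fish_id = NA_character_,
                            testing = NA_character_, settle_cutoff = 5,
                            mr_min_method = "decile_mean",
                            isr_use_corrected = TRUE) {
  used <- slopes[slopes$qc_pass, , drop = FALSE]
  mrm <- mr_min(used$mo2, method = mr_min_method)
  rmr_val <- rmr(used$mo2, used$t_mid_s / 3600, settle_cutoff = settle_cutoff)
  first_row <- slopes[which.min(slopes$t_mid_s), , drop = FALSE]
  first_mo2 <- if (!first_row$qc_pass) {
    NA_real_
  } else if (isr_use_corrected || is.null(slopes$mo2_raw)) {
    first_row$mo2
  } else {
    first_row$mo2_raw
  }
  stab <- stabilization_time(used$t_mid_s / 3600, used$mo2)
  tibble::tibble(
    fish_id = fish_id,
    testing = testing,
    mr_min = mrm,
    rmr = rmr_val,
    isr = isr(first_mo2, mrm),
    stabilization_h = stab$time_h,
    stabilized = stab$stabilized,
    n_periods_total = nrow(slopes),
    n_periods_used = nrow(used)
  )
}
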