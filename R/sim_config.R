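#' Simulation configuration (generator ground truth)
#'
#' All parameters of the synthetic respirometry generator. The defaults are
#' the package's calibrated cohort preset: 8 fish per holding treatment with
#' wet mass 1.84 +/- 0.11 g and standard length 3.69 +/- 0.085 cm, overnight
#' trials of 11.5 h, a handling-stress component that decays until oxygen
#' uptake stabilises around 4.6 h (solitary testing), a shoal-testing effect
#' that lowers the metabolic floor by 25.9 percent on average (individual
#' effects spanning 5-60 percent), and background (bacterial) respiration
#' rising linearly through the night.
#'
#' The shoal-testing effect is drawn per fish from a Beta distribution
#' rescaled to `shoal_effect_range`, parameterised by its mean
#' (`shoal_effect_mean`) and concentration (`shoal_effect_conc`, the Beta
#' a+b on the rescaled support; larger is tighter). Setting
#' `shoal_effect_range` to a degenerate interval fixes the effect exactly,
#' which is how zero-effect null cohorts are produced.
#'
#' @param n_fish_per_treatment Fish per holding treatment (total cohort is
#'   twice this).
#' @param mass_mean,mass_sd Wet mass distribution, grams.
#' @param length_mean,length_sd Standard length distribution, cm.
#' @param baseline_mo2_ref Metabolic floor (minimum MO2) of a solitary-tested
#'   fish at `reference_mass`, mg O2 h^-1.
#' @param baseline_mass_exponent Allometric scaling exponent b in
#'   floor ~ mass^b.
#' @param reference_mass Reference mass for `baseline_mo2_ref`, grams.
#' @param shoal_effect_mean Mean fractional reduction of the floor under
#'   shoal testing.
#' @param shoal_effect_range Support of the per-fish effect (fractions).
#' @param shoal_effect_conc Beta concentration of the effect distribution.
#' @param stress_amplitude Initial handling-stress elevation of MO2 above the
#'   floor, mg O2 h^-1, decaying exponentially.
#' @param stress_tau Stress decay time constant, hours.
#' @param activity_noise_sd SD of the per-measurement-period activity
#'   fluctuation added to MO2, mg O2 h^-1 (one draw per period; biological
#'   noise, distinct from instrument noise).
#' @param background_rate_start,background_rate_end Bacterial respiration at
#'   trial start and end, mg O2 h^-1 (linear in between).
#' @param optode_noise_sd Per-sample optode noise SD, mg L^-1.
#' @param trial_duration Overnight trial length, hours (at least 6 so the 5 h
#'   settling exclusion leaves usable periods).
#' @param flush_tau Time constant of the exponential re-oxygenation during
#'   flushing, seconds; the default (25 s) restores >99.9 percent saturation
#'   within a 3 min flush.
#' @param subtract_body_volume Subtract fish body volume from the chamber
#'   volume in the mass balance (see [effective_volume()]).
#' @param solitary_k_drop_mean,solitary_k_drop_sd Fractional week-0-to-1 loss
#'   of body mass (hence Fulton's K) for solitary-held fish.
#' @param shoal_k_drift_sd SD of the neutral week-to-week mass drift for
#'   shoal-held fish (mean 0).
#' @param mr_noise_cv Coefficient of variation of measured metabolic summaries
#'   in the summary-level simulator [simulate_metric_cohort()] (used for
#'   inference calibration, not for trace simulation).
#' @param seed Integer RNG seed; identical configs give bit-identical output.
#' @return A `sim_config` object (validated list).
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$shoal_effect_mean
#' @export
sim_config <- function(n_fish_per_treatment = 8,
                       mass_mean = 1.84, mass_sd = 0.11,
                       length_mean = 3.69, length_sd = 0.085,
                       baseline_mo2_ref = 0.42,
                       baseline_mass_exponent = 0.89,
                       reference_mass = 1.84,
                       shoal_effect_mean = 0.259,
                       shoal_effect_range = c(0.05, 0.60),
                       shoal_effect_conc = 10,
                       stress_amplitude = 0.20,
                       stress_tau = 2.95,
                       activity_noise_sd = 0.01,
                       background_rate_start = 0.005,
                       background_rate_end = 0.020,
                       optode_noise_sd = 0.005,
                       trial_duration = 11.5,
                       flush_tau = 25,
                       subtract_body_volume = TRUE,
                       solitary_k_drop_mean = 0.05,
                       solitary_k_drop_sd = 0.015,
                       shoal_k_drift_sd = 0.01,
                       mr_noise_cv = 0.03,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$trial_duration < 6) {
    abort_shoalmet("`trial_duration` must be at least 6 h.",
                   "shoalmet_invalid_spec")
  }
  if (cfg$stress_tau <= 0) {
    abort_shoalmet("`stress_tau` must be positive.", "shoalmet_invalid_spec")
  }
  r <- cfg$shoal_effect_range
  if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] ||
      r[1] < 0 || r[2] >= 1) {
    abort_shoalmet("`shoal_effect_range` must lie within [0, 1).",
                   "shoalmet_invalid_spec")
  }
  if (r[1] != r[2] &&
      (cfg$shoal_effect_mean <= r[1] || cfg$shoal_effect_mean >= r[2])) {
    abort_shoalmet("`shoal_effect_mean` must lie inside `shoal_effect_range`.",
                   "shoalmet_invalid_spec")
  }
  for (f in c("mass_mean", "length_mean", "baseline_mo2_ref",
              "reference_mass", "flush_tau")) {
    if (cfg[[f]] <= 0) {
      abort_shoalmet(sprintf("`%s` must be positive.", f),
                     "shoalmet_invalid_spec")
    }
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d fish/treatment, floor %.3g mg O2/h @ %.2f g ",
           "(b=%.2f), shoal effect mean %.3f in [%.2f, %.2f], ",
           "trial %.1f h, seed %d\n"),
    x$n_fish_per_treatment, x$baseline_mo2_ref, x$reference_mass,
    x$baseline_mass_exponent, x$shoal_effect_mean,
    x$shoal_effect_range[1], x$shoal_effect_range[2],
    x$trial_duration, x$seed
  ))
  invisible(x)
}

# Per-fish shoal effects: Beta on [0, 1] rescaled to the configured support,
# with the configured mean and concentration. Degenerate support => constant.
draw_shoal_effects <- function(n, config) {
  r <- config$shoal_effect_range
  if (r[1] == r[2]) return(rep(r[1], n))
  mu <- (config$shoal_effect_mean - r[1]) / (r[2] - r[1])
  a <- mu * config$shoal_effect_conc
  b <- (1 - mu) * config$shoal_effect_conc
  r[1] + (r[2] - r[1]) * stats::rbeta(n, a, b)
}

#' Read or write a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
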