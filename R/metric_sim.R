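#' Summary-level cohort simulator for inference calibration
#'
#' Draws per-fish metabolic summaries directly from the generator's
#' distributional assumptions, skipping trace synthesis: each fish gets an
#' allometric metabolic floor, a per-condition shoal effect, and a
#' multiplicative log-normal measurement error with coefficient of variation
#' `config$mr_noise_cv`. This is the cheap harness for studying the
#' statistical properties of the comparison machinery (type-I error, power)
#' over many replicate cohorts; it shares its truth parameters with
#' [simulate_cohort()] but none of its oxygen dynamics.
#'
#' @param config A [sim_config()]; set `shoal_effect_range = c(0, 0)` for a
#'   null (zero-effect) cohort.
#' @param seed Overrides `config$seed` when given.
#' @return Tibble with one row per fish x testing condition: `fish_id`,
#'   `holding`, `testing`, `mass_g`, `true_effect`, `mr_min`.
#' @examples
#' simulate_metric_cohort(sim_config(seed = 3))
#' @export
simulate_metric_cohort <- function(config = sim_config(), seed = NULL) {
  n <- 2L * config$n_fish_per_treatment
  with_seed(seed %||% config$seed, {
    mass <- pmax(0.25 * config$mass_mean,
                 stats::rnorm(n, config$mass_mean, config$mass_sd))
    effect <- draw_shoal_effects(n, config)
    floor_sol <- config$baseline_mo2_ref *
      (mass / config$reference_mass)^config$baseline_mass_exponent
    out <- tibble::tibble(
      fish_id = rep(sprintf("F%02d", seq_len(n)), each = 2),
      holding = rep(rep(c("shoal", "solitary"),
                        each = config$n_fish_per_treatment), each = 2),
      testing = rep(c("solitary", "shoal"), n),
      mass_g = rep(mass, each = 2),
      true_effect = rep(effect, each = 2)
    )
    true_val <- ifelse(out$testing == "shoal",
                       rep(floor_sol, each = 2) * (1 - out$true_effect),
                       rep(floor_sol, each = 2))
    out$mr_min <- true_val *
      exp(stats::rnorm(nrow(out), 0, config$mr_noise_cv))
    out
  })
}
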