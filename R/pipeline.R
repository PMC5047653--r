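#' Process every trial of a simulated (or assembled) cohort
#'
#' Runs the full per-trial pipeline — window trimming, least-squares slopes,
#' volume conversion, background correction, metabolic summaries — over a
#' cohort, returning one row of metrics per fish and testing condition.
#'
#' @param sim A [simulate_cohort()] result, or any list with a `trials`
#'   tibble holding `fish_id`, `holding`, `testing`, `mass_g` and
#'   list-columns `trace`, `pre`, `post`, plus a `chamber`.
#' @inheritParams process_trial
#' @inheritParams summarize_trial
#' @return Tibble: `fish_id`, `holding`, `testing`, `mass_g`, `mr_min`,
#'   `rmr`, `isr`, `stabilization_h`, `stabilized`, period counts.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(sim_config(n_fish_per_treatment = 2,
#'                                   trial_duration = 6, seed = 5))
#' process_cohort(sim)
#' }
#' @export
process_cohort <- function(sim, exclusion = 60, min_window = 120,
                           qc_threshold = 0.97, settle_cutoff = 5,
                           subtract_body_volume = TRUE) {
  trials <- sim$trials
  rows <- purrr::pmap(
    list(trials$trace, trials$pre, trials$post, trials$mass_g,
         trials$fish_id, trials$testing),
    function(trace, pre, post, mass, id, testing) {
      slopes <- process_trial(trace, pre, post, mass, chamber = sim$chamber,
                              exclusion = exclusion, min_window = min_window,
                              qc_threshold = qc_threshold,
                              subtract_body_volume = subtract_body_volume)
      summarize_trial(slopes, fish_id = id, testing = testing,
                      settle_cutoff = settle_cutoff)
    }
  )
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(out,
                   trials[c("fish_id", "testing", "holding", "mass_g")],
                   by = c("fish_id", "testing")) |>
    dplyr::relocate("holding", "mass_g", .after = "testing")
}

#' Recover the shoaling effect from a simulated cohort
#'
#' End-to-end parameter recovery: simulate a cohort, push every trace through
#' the slope pipeline and metrics, and compare paired solitary- versus
#' shoal-testing MR_min with the sign-flip permutation test. The comparison's
#' mean per-fish percent reduction estimates the generator's mean shoal
#' effect.
#'
#' @param config A [sim_config()].
#' @param chamber A [chamber_spec()].
#' @param metric Metric to compare (default `"mr_min"`).
#' @param n_perm,perm_seed Permutation settings (see
#'   [paired_permutation_test()]).
#' @return A list: `summaries` (per-trial metrics), `comparison` (the
#'   `shoal_perm`), `truth` (generator ground truth).
#' @export
recover_shoal_effect <- function(config = sim_config(),
                                 chamber = chamber_spec(),
                                 metric = "mr_min", n_perm = 10000,
                                 perm_seed = 1L) {
  sim <- simulate_cohort(config, chamber)
  summaries <- process_cohort(sim)
  comparison <- compare_conditions(summaries, metric = metric,
                                   n_perm = n_perm, seed = perm_seed)
  list(summaries = summaries, comparison = comparison, truth = sim$truth)
}

#' Cohort report tables
#'
#' Assembles the analysis outputs a study report needs: group means and
#' s.e.m. per metric and testing condition, mass-corrected variants, the
#' permutation comparison per metric, the body-condition trajectory, and a QC
#' section (periods used, r^2 floor, stabilization flags). The delegated
#' mixed-model comparison is included per metric; note its repeated-measures
#' structure is a random intercept only (no autocorrelation correction).
#'
#' @param summaries Per-trial metrics from [process_cohort()].
#' @param morphometrics Fish x week mass/length tibble (optional).
#' @param reference_mass Mass standard for [mass_correct()], grams.
#' @param metrics Metric columns to compare.
#' @param n_perm,seed Permutation settings.
#' @return A list of tibbles/objects: `group_means`, `comparisons`,
#'   `mixed_models`, `condition` (or NULL), `qc`.
#' @export
cohort_report <- function(summaries, morphometrics = NULL,
                          reference_mass = 1.84,
                          metrics = c("mr_min", "rmr", "isr"),
                          n_perm = 10000, seed = 1L) {
  metrics <- intersect(metrics, names(summaries))
  long <- summaries |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  long <- long |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(value_mc = safe_mass_correct(.data$value, .data$mass_g,
                                               reference_mass)) |>
    dplyr::ungroup()
  group_means <- long |>
    dplyr::group_by(.data$metric, .data$testing) |>
    dplyr::summarise(
      mean = mean(.data$value), sem = sem(.data$value),
      mean_mass_corrected = mean(.data$value_mc),
      sem_mass_corrected = sem(.data$value_mc),
      n = dplyr::n(), .groups = "drop"
    )
  comparisons <- purrr::map(
    rlang::set_names(metrics),
    function(m) compare_conditions(summaries, metric = m,
                                   n_perm = n_perm, seed = seed)
  )
  mixed_models <- purrr::map(
    rlang::set_names(metrics),
    function(m) suppressWarnings(mixed_model_compare(summaries, response = m))
  )
  condition <- if (!is.null(morphometrics)) {
    condition_trajectory(morphometrics)
  }
  qc <- summaries |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      periods_total = sum(.data$n_periods_total),
      periods_used = sum(.data$n_periods_used),
      trials_unstabilized = sum(!.data$stabilized)
    )
  list(group_means = group_means, comparisons = comparisons,
       mixed_models = mixed_models, condition = condition, qc = qc)
}

# Mass correction that degrades to a no-op where the log-log fit is
# undefined (e.g. a non-positive ISR value in the cohort).
safe_mass_correct <- function(values, mass_g, reference_mass) {
  tryCatch(mass_correct(values, mass_g, reference_mass = reference_mass),
           error = function(e) values)
}
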