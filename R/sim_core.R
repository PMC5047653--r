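#' Simulate one intermittent-flow respirometry trial
#'
#' Generates the dissolved-oxygen trace of a single fish sealed in the inner
#' chamber of a dual-chamber respirometer, alternating measurement and flush
#' phases for the configured trial duration. During sealed measurement phases
#' oxygen declines by the mass balance
#' \deqn{d[O_2]/dt = -(\dot{M}O_{2,fish}(t) + B(t)) / V_{eff},}
#' where the fish's oxygen uptake is a metabolic floor plus an exponentially
#' decaying handling-stress component and a per-period activity fluctuation
#' (truncated so uptake stays non-negative), and \eqn{B(t)} is bacterial
#' background respiration rising linearly through the trial. During flush
#' phases oxygen relaxes exponentially back towards full air saturation.
#' Per-sample optode noise is added last. Under shoal testing the floor is
#' multiplied by \eqn{1 - e} with \eqn{e} the fish's shoal effect.
#'
#' @param chamber A [chamber_spec()].
#' @param fish One fish: a list or one-row data frame with at least `fish_id`
#'   and `mass_g`.
#' @param condition Testing condition, `"solitary"` or `"shoal"`.
#' @param config A [sim_config()]; `config$seed` fixes all randomness, so
#'   identical inputs give bit-identical traces.
#' @param shoal_effect Optional fixed fractional reduction for this fish;
#'   drawn from the configured effect distribution when `NULL`.
#' @return A list with `trace` (an `o2_trace` tibble: `time_s`, `o2_mgL`,
#'   `o2_percent_sat`, `phase`) and `truth` (one-row tibble of generator
#'   ground truth: floor, effect, background endpoints, stabilization time).
#' @examples
#' tr <- simulate_trial(chamber_spec(),
#'                      list(fish_id = "F01", mass_g = 1.84),
#'                      "solitary", sim_config(trial_duration = 6, seed = 1))
#' head(tr$trace)
#' @export
simulate_trial <- function(chamber, fish, condition = c("solitary", "shoal"),
                           config = sim_config(), shoal_effect = NULL) {
  condition <- match.arg(condition)
  mass <- as.numeric(fish$mass_g)
  v_eff <- effective_volume(chamber, mass, config$subtract_body_volume)
  total_s <- config$trial_duration * 3600
  cycle_s <- chamber$measure_duration + chamber$flush_duration
  n_cycles <- floor(total_s / cycle_s)

  with_seed(config$seed, {
    if (is.null(shoal_effect)) shoal_effect <- draw_shoal_effects(1, config)
    floor_sol <- config$baseline_mo2_ref *
      (mass / config$reference_mass)^config$baseline_mass_exponent
    floor_val <- if (condition == "shoal") {
      floor_sol * (1 - shoal_effect)
    } else {
      floor_sol
    }
    eps <- stats::rnorm(n_cycles, 0, config$activity_noise_sd)
    bg_span <- config$background_rate_end - config$background_rate_start
    mo2_fun <- function(t, j) {
      stress <- config$stress_amplitude * exp(-(t / 3600) / config$stress_tau)
      bg <- config$background_rate_start + bg_span * t / total_s
      pmax(0, floor_val + stress + eps[j]) + bg
    }
    raw <- sim_trace_engine(chamber, config, n_cycles, v_eff, mo2_fun)
    o2 <- add_optode_noise(raw$o2_true, config)
    trace <- new_o2_trace(
      tibble::tibble(
        time_s = raw$time_s,
        o2_mgL = o2,
        o2_percent_sat = 100 * o2 / chamber$o2_full_saturation,
        phase = raw$phase
      ),
      chamber = chamber,
      fish_id = as.character(fish$fish_id %||% NA_character_),
      testing = condition
    )
    t_mid_h <- ((seq_len(n_cycles) - 1) * cycle_s +
                  chamber$measure_duration / 2) / 3600
    noiseless <- floor_val +
      config$stress_amplitude * exp(-t_mid_h / config$stress_tau)
    stab <- stabilization_time(t_mid_h, noiseless)
    truth <- tibble::tibble(
      fish_id = as.character(fish$fish_id %||% NA_character_),
      testing = condition,
      mass_g = mass,
      true_floor = floor_val,
      true_floor_solitary = floor_sol,
      true_shoal_effect = shoal_effect,
      background_start = config$background_rate_start,
      background_end = config$background_rate_end,
      true_stabilization_h = stab$time_h
    )
    list(trace = trace, truth = truth)
  })
}

# Shared oxygen-dynamics engine: trapezoidal integration of the consumption
# rate during sealed phases, exponential re-saturation during flushes.
sim_trace_engine <- function(chamber, config, n_cycles, v_eff, mo2_fun) {
  dt <- chamber$sample_interval
  n_m <- floor(chamber$measure_duration / dt)
  n_f <- floor(chamber$flush_duration / dt)
  sat <- chamber$o2_full_saturation
  cycle_s <- chamber$measure_duration + chamber$flush_duration
  times <- o2 <- vector("list", n_cycles)
  phase <- rep.int(rep(c("measure", "flush"), c(n_m, n_f)), n_cycles)
  o2_cur <- sat
  for (j in seq_len(n_cycles)) {
    t0 <- (j - 1) * cycle_s
    t_m <- t0 + (seq_len(n_m) - 1) * dt
    rate <- mo2_fun(t_m, j) / v_eff / 3600 # mg L^-1 s^-1
    o2_m <- o2_cur - c(0, cumsum((rate[-1] + rate[-n_m]) / 2 * dt))
    o2_seal_end <- o2_m[n_m] - rate[n_m] * dt
    t_f <- t0 + chamber$measure_duration + (seq_len(n_f) - 1) * dt
    o2_f <- sat - (sat - o2_seal_end) * exp(-(seq_len(n_f) * dt) / config$flush_tau)
    o2_cur <- o2_f[n_f]
    times[[j]] <- c(t_m, t_f)
    o2[[j]] <- c(o2_m, o2_f)
  }
  o2 <- unlist(o2)
  if (any(o2 < 0)) {
    abort_shoalmet(
      "physically impossible configuration: oxygen would be fully depleted within a measurement period.",
      "shoalmet_impossible_config"
    )
  }
  list(time_s = unlist(times), o2_true = o2, phase = phase)
}

add_optode_noise <- function(o2_true, config) {
  if (config$optode_noise_sd == 0) return(o2_true)
  pmax(0, o2_true + stats::rnorm(length(o2_true), 0, config$optode_noise_sd))
}

#' Simulate an empty-chamber background trial
#'
#' Three measurement periods with only bacterial respiration consuming oxygen,
#' run before (`when = "pre"`, consumption at `background_rate_start`) or
#' after a trial (`when = "post"`, at `background_rate_end`). The empty
#' chamber uses the full inner volume.
#'
#' @inheritParams simulate_trial
#' @param when `"pre"` or `"post"`.
#' @param n_periods Number of measurement periods (default 3).
#' @return An `o2_trace` tibble.
#' @export
simulate_background_trial <- function(chamber, config = sim_config(),
                                      when = c("pre", "post"), n_periods = 3) {
  when <- match.arg(when)
  rate <- if (when == "pre") config$background_rate_start else config$background_rate_end
  with_seed(config$seed, {
    raw <- sim_trace_engine(chamber, config, n_periods, chamber$inner_volume,
                            function(t, j) rep(rate, length(t)))
    o2 <- add_optode_noise(raw$o2_true, config)
    new_o2_trace(
      tibble::tibble(
        time_s = raw$time_s,
        o2_mgL = o2,
        o2_percent_sat = 100 * o2 / chamber$o2_full_saturation,
        phase = raw$phase
      ),
      chamber = chamber,
      fish_id = NA_character_,
      testing = NA_character_,
      trial_type = paste0("background_", when)
    )
  })
}

#' Simulate a full paired-testing cohort
#'
#' Draws a cohort of fish (half held in shoals, half in isolation), gives each
#' fish one solitary-testing and one shoal-testing overnight trial with
#' pre/post empty-chamber background trials, and records generator ground
#' truth for parameter-recovery checks. Morphometrics (wet mass, standard
#' length) are recorded at weeks 0, 1 and 2 of the holding period; solitary
#' fish lose condition between weeks 0 and 1 while shoal-held fish drift
#' neutrally.
#'
#' @param config A [sim_config()].
#' @param chamber A [chamber_spec()].
#' @return A `cohort_sim` list: `fish` (metadata tibble), `trials` (tibble
#'   with list-columns `trace`, `pre`, `post`), `truth` (one row per fish and
#'   testing condition), `morphometrics` (fish x week mass/length), plus the
#'   `config` and `chamber` used.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(sim_config(n_fish_per_treatment = 2,
#'                                   trial_duration = 6, seed = 2))
#' sim$truth
#' }
#' @export
simulate_cohort <- function(config = sim_config(), chamber = chamber_spec()) {
  n <- 2L * config$n_fish_per_treatment
  with_seed(config$seed, {
    fish <- tibble::tibble(
      fish_id = sprintf("F%02d", seq_len(n)),
      holding = rep(c("shoal", "solitary"), each = config$n_fish_per_treatment),
      mass_g = pmax(0.25 * config$mass_mean,
                    stats::rnorm(n, config$mass_mean, config$mass_sd)),
      length_cm = pmax(0.25 * config$length_mean,
                       stats::rnorm(n, config$length_mean, config$length_sd))
    )
    effects <- draw_shoal_effects(n, config)
    morpho <- cohort_morphometrics(fish, config)
    seeds <- matrix(sample.int(.Machine$integer.max - 1L, n * 6L),
                    nrow = n, ncol = 6L)
    rows <- vector("list", 2L * n)
    truths <- vector("list", 2L * n)
    k <- 0L
    for (i in seq_len(n)) {
      for (ci in 1:2) {
        cond <- c("solitary", "shoal")[ci]
        k <- k + 1L
        cfg_t <- config
        cfg_t$seed <- seeds[i, 3L * (ci - 1L) + 1L]
        res <- simulate_trial(chamber, fish[i, ], cond, cfg_t,
                              shoal_effect = effects[i])
        cfg_pre <- config; cfg_pre$seed <- seeds[i, 3L * (ci - 1L) + 2L]
        cfg_post <- config; cfg_post$seed <- seeds[i, 3L * (ci - 1L) + 3L]
        rows[[k]] <- tibble::tibble(
          fish_id = fish$fish_id[i],
          holding = fish$holding[i],
          testing = cond,
          mass_g = fish$mass_g[i],
          trace = list(res$trace),
          pre = list(simulate_background_trial(chamber, cfg_pre, "pre")),
          post = list(simulate_background_trial(chamber, cfg_post, "post"))
        )
        truths[[k]] <- res$truth
      }
    }
    structure(
      list(
        fish = fish,
        trials = dplyr::bind_rows(rows),
        truth = dplyr::bind_rows(truths),
        morphometrics = morpho,
        config = config,
        chamber = chamber
      ),
      class = "cohort_sim"
    )
  })
}

# Weeks 0/1/2 mass and length per fish. Solitary-held fish lose a configured
# fraction of mass between weeks 0 and 1 (the body-condition signal); both
# treatments drift neutrally otherwise. Lengths are held fixed: standard
# length barely changes over two weeks at this size.
cohort_morphometrics <- function(fish, config) {
  n <- nrow(fish)
  drop1 <- ifelse(fish$holding == "solitary",
                  pmax(0, stats::rnorm(n, config$solitary_k_drop_mean,
                                       config$solitary_k_drop_sd)),
                  stats::rnorm(n, 0, config$shoal_k_drift_sd))
  drift2 <- stats::rnorm(n, 0, config$shoal_k_drift_sd)
  m0 <- fish$mass_g
  m1 <- m0 * (1 - drop1)
  m2 <- m1 * (1 + drift2)
  tibble::tibble(
    fish_id = rep(fish$fish_id, 3),
    holding = rep(fish$holding, 3),
    week = rep(0:2, each = n),
    mass_g = c(m0, m1, m2),
    length_cm = rep(fish$length_cm, 3)
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<cohort_sim> %d fish (%d/treatment), %d fish trials + %d background trials, seed %d\n",
    nrow(x$fish), x$config$n_fish_per_treatment, nrow(x$trials),
    2L * nrow(x$trials), x$config$seed
  ))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes one trace CSV per fish trial (`trial_<fish>_<testing>.csv`) and per
#' background trial, plus `fish.csv`, `morphometrics.csv`, `truth.csv` and
#' `config.yaml`, into `dir`.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(sim$trials))) {
    stem <- sprintf("%s_%s", sim$trials$fish_id[i], sim$trials$testing[i])
    write_trace(sim$trials$trace[[i]], file.path(dir, sprintf("trial_%s.csv", stem)))
    write_trace(sim$trials$pre[[i]], file.path(dir, sprintf("bg_pre_%s.csv", stem)))
    write_trace(sim$trials$post[[i]], file.path(dir, sprintf("bg_post_%s.csv", stem)))
  }
  readr::write_csv(sim$fish, file.path(dir, "fish.csv"))
  readr::write_csv(sim$morphometrics, file.path(dir, "morphometrics.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  write_sim_config(sim$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
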