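test_that("noiseless constant-rate trials deplete oxygen exactly linearly", {
  ch <- chamber_spec()
  cfg <- noiseless_config(seed = 1)
  fish <- default_fish()
  res <- simulate_trial(ch, fish, "solitary", cfg)
  v_eff <- effective_volume(ch, fish$mass_g)
  floor_val <- res$truth$true_floor
  expected_slope <- -floor_val / v_eff # mg L^-1 h^-1

  sl <- fit_period_slopes(res$trace, exclusion = 0)
  expect_equal(sl$slope_mgL_h, rep(expected_slope, nrow(sl)), tolerance = 1e-9)
  expect_true(all(sl$r_squared > 1 - 1e-12))

  # oxygen conservation: V_eff x per-period drop equals integrated uptake
  m <- res$trace[res$trace$phase == "measure", ]
  first_period <- m[m$time_s < ch$measure_duration, ]
  span_h <- (max(first_period$time_s) - min(first_period$time_s)) / 3600
  drop <- first_period$o2_mgL[1] - first_period$o2_mgL[nrow(first_period)]
  expect_equal(drop * v_eff, floor_val * span_h, tolerance = 1e-9)
})

test_that("identical seeds reproduce trials and cohorts bit-exactly", {
  ch <- chamber_spec()
  cfg <- short_config(seed = 11)
  a <- simulate_trial(ch, default_fish(), "shoal", cfg)
  b <- simulate_trial(ch, default_fish(), "shoal", cfg)
  expect_identical(a, b)

  cfg2 <- short_config(seed = 12, n_fish_per_treatment = 2)
  expect_identical(simulate_cohort(cfg2), simulate_cohort(cfg2))
})

test_that("default trials keep oxygen above 80% air saturation across seeds", {
  ch <- chamber_spec()
  for (s in 1:5) {
    cond <- if (s %% 2 == 1) "solitary" else "shoal"
    tr <- simulate_trial(ch, default_fish(), cond, sim_config(seed = s))$trace
    expect_gt(min(tr$o2_percent_sat), 80)
  }
})

test_that("configurations that would fully deplete oxygen are rejected", {
  ch <- chamber_spec()
  greedy <- sim_config(baseline_mo2_ref = 30, stress_amplitude = 0,
                       optode_noise_sd = 0, activity_noise_sd = 0, seed = 1)
  expect_error(simulate_trial(ch, default_fish(), "solitary", greedy),
               class = "shoalmet_impossible_config")
})

test_that("background trials consume at the configured endpoint rate only", {
  ch <- chamber_spec()
  cfg0 <- noiseless_config(seed = 2)
  flat <- simulate_background_trial(ch, cfg0, "pre")
  sl0 <- fit_period_slopes(flat, qc_threshold = 0)
  expect_equal(sl0$slope_mgL_h, rep(0, 3), tolerance = 1e-12)

  cfg <- sim_config(background_rate_start = 0.002, background_rate_end = 0.010,
                    seed = 3)
  post <- simulate_background_trial(ch, cfg, "post")
  slp <- fit_period_slopes(post, qc_threshold = 0)
  # three 7-min windows against per-sample optode noise: ~3 sigma band
  expect_equal(mean(slp$slope_mgL_h), -0.010 / ch$inner_volume,
               tolerance = 0.2)

  pre <- simulate_background_trial(ch, cfg, "pre")
  slq <- fit_period_slopes(pre, qc_threshold = 0)
  expect_lt(mean(abs(slq$slope_mgL_h)), mean(abs(slp$slope_mgL_h)))
})

test_that("a default cohort has the right shape and calibrated truth", {
  sim <- simulate_cohort(sim_config(seed = 4))
  expect_equal(nrow(sim$fish), 16)
  expect_equal(nrow(sim$trials), 32)
  # two background runs accompany every fish trial
  expect_equal(sum(lengths(sim$trials$pre) > 0) +
                 sum(lengths(sim$trials$post) > 0), 64)
  expect_equal(nrow(sim$truth), 32)

  # effect ordering: shoal floor = solitary floor x (1 - effect), per fish
  tw <- tidyr::pivot_wider(sim$truth[c("fish_id", "testing", "true_floor")],
                           names_from = "testing", values_from = "true_floor")
  eff <- sim$truth$true_shoal_effect[sim$truth$testing == "solitary"]
  expect_equal(tw$shoal, tw$solitary * (1 - eff), tolerance = 1e-12)
  expect_true(all(tw$shoal <= tw$solitary))
  expect_true(all(eff >= 0.05 & eff <= 0.60))
  # cohort mean effect near its calibrated value (16 draws, sd ~ 0.08)
  expect_equal(mean(eff), 0.259, tolerance = 0.25)
})

test_that("a zero-effect configuration gives equal floors across conditions", {
  cfg <- short_config(seed = 5, n_fish_per_treatment = 2,
                      shoal_effect_mean = 0, shoal_effect_range = c(0, 0))
  sim <- simulate_cohort(cfg)
  tw <- tidyr::pivot_wider(sim$truth[c("fish_id", "testing", "true_floor")],
                           names_from = "testing", values_from = "true_floor")
  expect_equal(tw$shoal, tw$solitary, tolerance = 1e-12)
})

test_that("simulated cohorts round-trip through plain-text files", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(short_config(seed = 6, n_fish_per_treatment = 1))
  write_cohort(sim, dir)
  expect_true(file.exists(file.path(dir, "trial_F01_solitary.csv")))
  back <- read_trace(file.path(dir, "trial_F01_solitary.csv"), sim$chamber)
  orig <- sim$trials$trace[[1]]
  expect_equal(back$time_s, orig$time_s)
  expect_equal(back$o2_mgL, orig$o2_mgL)
  expect_equal(back$phase, orig$phase)
  cfg2 <- read_sim_config(file.path(dir, "config.yaml"))
  expect_equal(cfg2$baseline_mo2_ref, sim$config$baseline_mo2_ref)
})
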