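test_that("window trimming removes one minute from each end of each period", {
  tr <- make_linear_trace(c(-0.4, -0.4, -0.4))
  win <- extract_windows(tr, exclusion = 60)
  expect_equal(nrow(win), 3)
  expect_equal(win$t_start, c(60, 780, 1500))
  expect_equal(win$t_end, c(480, 1200, 1920))
  s1 <- win$samples[[1]]
  expect_true(all(s1$time_s >= 60 & s1$time_s < 480))
  expect_equal(win$t_mid_s[1], 270)

  full <- extract_windows(tr, exclusion = 0)
  expect_equal(nrow(full$samples[[1]]), 270) # full 9-min period at 2 s
})

test_that("periods too short to survive trimming are dropped with a warning", {
  ch <- chamber_spec()
  t <- seq(0, 298, by = 2) # 100 s measure + flush tail
  phase <- ifelse(t < 100, "measure", "flush")
  tr <- new_o2_trace(tibble::tibble(time_s = t, o2_mgL = 7, phase = phase), ch)
  expect_warning(win <- extract_windows(tr, exclusion = 60, min_window = 120),
                 "dropped")
  expect_equal(nrow(win), 0)
})

test_that("fit_slope reproduces exact lines and handles degenerate windows", {
  t <- seq(0, 40, by = 2)
  line <- tibble::tibble(time_s = t, o2_mgL = 8.0 - 0.5 * t / 3600)
  est <- fit_slope(line)
  expect_equal(est$slope_mgL_h, -0.5, tolerance = 1e-10)
  expect_equal(est$intercept_mgL, 8.0, tolerance = 1e-10)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  expect_true(est$qc_pass)

  flat <- tibble::tibble(time_s = t, o2_mgL = 7.5)
  est0 <- fit_slope(flat)
  expect_equal(est0$slope_mgL_h, 0)
  expect_equal(est0$r_squared, 0)
  expect_false(est0$qc_pass)

  same_t <- tibble::tibble(time_s = rep(3, 5), o2_mgL = 1:5)
  expect_error(fit_slope(same_t), class = "shoalmet_singular_fit")
  expect_error(fit_slope(line[1:2, ]), class = "shoalmet_insufficient_data")
})

test_that("fit_slope agrees with the closed-form OLS oracle on noisy windows", {
  set.seed(42)
  # fixed 21-sample noisy window
  t <- seq(0, 40, by = 2)
  y <- 8.1 - 2.3 * t / 3600 + rnorm(21, 0, 0.01)
  est <- fit_slope(tibble::tibble(time_s = t, o2_mgL = y))
  oracle <- ols_oracle(t / 3600, y)
  expect_equal(est$slope_mgL_h, oracle$slope, tolerance = 1e-10)
  expect_equal(est$intercept_mgL, oracle$intercept, tolerance = 1e-10)
  expect_equal(est$r_squared, oracle$r2, tolerance = 1e-10)

  # property: random small windows
  for (i in 1:25) {
    n <- sample(3:40, 1)
    t <- sort(runif(n, 0, 600))
    y <- runif(1, 5, 9) + runif(1, -3, 3) * t / 3600 + rnorm(n, 0, 0.05)
    est <- fit_slope(tibble::tibble(time_s = t, o2_mgL = y))
    oracle <- ols_oracle(t / 3600, y)
    expect_equal(est$slope_mgL_h, oracle$slope, tolerance = 1e-10)
    # r^2 compared absolutely: near-zero r^2 makes relative error meaningless
    expect_lt(abs(est$r_squared - oracle$r2), 1e-9)
  }
})

test_that("slope-to-MO2 conversion uses the effective chamber volume", {
  ch <- chamber_spec()
  est <- tibble::tibble(slope_mgL_h = -0.5)
  expect_equal(slope_to_mo2(est, ch, fish_mass = 1.84)$mo2,
               0.5 * (0.100 - 0.00184), tolerance = 1e-12)
  expect_equal(slope_to_mo2(est, ch, fish_mass = 1.84,
                            subtract_body_volume = FALSE)$mo2,
               0.0500, tolerance = 1e-12)
  expect_equal(slope_to_mo2(tibble::tibble(slope_mgL_h = 0), ch, 1.84)$mo2, 0)
  expect_error(slope_to_mo2(est, ch, fish_mass = 120),
               class = "shoalmet_impossible_geometry")
})

test_that("background model averages empty-chamber windows and clamps negatives", {
  ch <- chamber_spec()
  flat <- make_linear_trace(c(0, 0, 0))
  bg0 <- fit_background(flat, flat, ch)
  expect_equal(bg0$rate_pre, 0)
  expect_equal(bg0$rate_post, 0)

  # per-period MO2 of {0.001, 0.002, 0.003} mg/h over the 0.1 L chamber
  pre <- make_linear_trace(-c(0.001, 0.002, 0.003) / ch$inner_volume)
  bg <- fit_background(pre, flat, ch)
  expect_equal(bg$rate_pre, 0.002, tolerance = 1e-9)

  rising <- make_linear_trace(c(0.05, 0.05, 0.05)) # oxygen increasing
  expect_warning(bgn <- fit_background(rising, flat, ch), "clamped")
  expect_equal(bgn$rate_pre, 0)

  # recovery of simulated rates within optode-noise tolerance
  cfg <- sim_config(background_rate_start = 0.004, background_rate_end = 0.012,
                    seed = 31)
  bg2 <- fit_background(simulate_background_trial(ch, cfg, "pre"),
                        simulate_background_trial(ch, cfg, "post"), ch)
  expect_equal(bg2$rate_pre, 0.004, tolerance = 0.25)
  expect_equal(bg2$rate_post, 0.012, tolerance = 0.1)
})

test_that("background correction interpolates linearly in time", {
  slopes <- tibble::tibble(t_mid_s = c(0, 1800, 3600), mo2 = c(1, 1, 1))
  bg0 <- structure(list(rate_pre = 0, rate_post = 0), class = "background_model")
  out0 <- correct_background(slopes, bg0, 0, 3600)
  expect_equal(out0$mo2, slopes$mo2)

  bg <- structure(list(rate_pre = 0, rate_post = 0.010),
                  class = "background_model")
  out <- correct_background(slopes, bg, 0, 3600)
  expect_equal(out$mo2[2], 1 - 0.005, tolerance = 1e-12)
  # monotone: corrected never exceeds raw for non-negative rates
  expect_true(all(out$mo2 <= out$mo2_raw))

  expect_error(correct_background(slopes, bg, 3600, 0),
               class = "shoalmet_invalid_interval")
  expect_error(correct_background(slopes, bg, 100, 3600),
               class = "shoalmet_invalid_interval")
})

test_that("background correction pulls overnight MO2 toward the true floor", {
  ch <- chamber_spec()
  better <- logical(20)
  for (s in 1:20) {
    cfg <- short_config(seed = 100 + s)
    res <- simulate_trial(ch, default_fish(), "solitary", cfg)
    sl <- process_trial(res$trace,
                        simulate_background_trial(ch, cfg, "pre"),
                        simulate_background_trial(ch, cfg, "post"),
                        default_fish()$mass_g, chamber = ch)
    late <- sl$t_mid_s / 3600 > 4 # stress has mostly decayed
    err_corr <- abs(mean(sl$mo2[late]) - res$truth$true_floor)
    err_raw <- abs(mean(sl$mo2_raw[late]) - res$truth$true_floor)
    better[s] <- err_corr < err_raw
  }
  expect_true(mean(better) >= 0.8)
})

test_that("a noiseless trial is recovered end-to-end to within 0.1%", {
  ch <- chamber_spec()
  cfg <- sim_config(optode_noise_sd = 0, activity_noise_sd = 0, seed = 7)
  res <- simulate_trial(ch, default_fish(), "solitary", cfg)
  sl <- process_trial(res$trace,
                      simulate_background_trial(ch, cfg, "pre"),
                      simulate_background_trial(ch, cfg, "post"),
                      default_fish()$mass_g, chamber = ch)
  truth <- res$truth$true_floor +
    cfg$stress_amplitude * exp(-(sl$t_mid_s / 3600) / cfg$stress_tau)
  expect_lt(max(abs(sl$mo2 - truth) / truth), 0.001)
})
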