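# Shared fixtures: small chambers/configs for speed, independent oracles.

default_fish <- function(mass = 1.84) list(fish_id = "F01", mass_g = mass)

# Short (6 h) trial config for unit tests; full-length runs live in the
# acceptance suite.
short_config <- function(...) {
  sim_config(trial_duration = 6, ...)
}

noiseless_config <- function(...) {
  sim_config(optode_noise_sd = 0, activity_noise_sd = 0,
             background_rate_start = 0, background_rate_end = 0,
             stress_amplitude = 0, ...)
}

# Independent closed-form OLS via the textbook sum formulas.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = 1 - ss_res / ss_tot)
}

# Brute-force lowest-decile oracle: sort and slice.
mr_min_oracle <- function(x) {
  sx <- sort(x)
  k <- max(1L, floor((length(x) - 1) * 0.1 + 1))
  mean(sx[seq_len(k)])
}

# Hand-built three-period trace with an exact per-period depletion slope
# (mg L^-1 h^-1, negative for consumption), phases annotated.
make_linear_trace <- function(slopes_mgL_h, chamber = chamber_spec(),
                              o2_start = chamber$o2_full_saturation) {
  dt <- chamber$sample_interval
  cyc <- chamber$measure_duration + chamber$flush_duration
  rows <- lapply(seq_along(slopes_mgL_h), function(j) {
    t0 <- (j - 1) * cyc
    t_m <- t0 + seq(0, chamber$measure_duration - dt, by = dt)
    t_f <- t0 + seq(chamber$measure_duration, cyc - dt, by = dt)
    data.frame(
      time_s = c(t_m, t_f),
      o2_mgL = c(o2_start + slopes_mgL_h[j] * (t_m - t0) / 3600,
                 rep(o2_start, length(t_f))),
      phase = rep(c("measure", "flush"), c(length(t_m), length(t_f)))
    )
  })
  new_o2_trace(do.call(rbind, rows), chamber)
}
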