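test_that("Fulton's K follows 100 M / L^3", {
  expect_equal(fultons_k(1, 1), 100)
  expect_equal(fultons_k(1.84, 3.69), 100 * 1.84 / 3.69^3, tolerance = 1e-12)
  expect_equal(round(fultons_k(1.84, 3.69), 3), 3.662)
  expect_equal(fultons_k(0.5, 2), 6.25)
  expect_error(fultons_k(0, 3), class = "shoalmet_domain_error")
  expect_error(fultons_k(1, -2), class = "shoalmet_domain_error")
})

test_that("mass correction standardises values to the reference mass", {
  v <- c(0.4, 0.5, 0.45, 0.61)
  # all fish at the reference mass: correction must be the identity
  expect_equal(mass_correct(v, rep(1.84, 4)), v, tolerance = 1e-12)

  # exact power law collapses onto a single value at the reference mass
  m <- c(1.2, 1.6, 2.0, 2.6)
  a <- 0.23; b <- 0.83
  expect_equal(mass_correct(a * m^b, m, reference_mass = 1.84),
               rep(a * 1.84^b, 4), tolerance = 1e-10)

  # 8-pair fixture versus an independent two-pass closed-form computation
  set.seed(9)
  m8 <- runif(8, 1.4, 2.4)
  v8 <- 0.3 * m8^0.9 * exp(rnorm(8, 0, 0.08))
  o <- ols_oracle(log(m8), log(v8))
  expected <- exp(o$intercept + o$slope * log(1.84) +
                    (log(v8) - o$intercept - o$slope * log(m8)))
  expect_equal(mass_correct(v8, m8), expected, tolerance = 1e-10)

  # geometric mean is preserved when the reference is the geometric-mean mass
  gm <- exp(mean(log(m8)))
  corrected <- mass_correct(v8, m8, reference_mass = gm)
  expect_equal(exp(mean(log(corrected))), exp(mean(log(v8))),
               tolerance = 1e-10)

  expect_warning(out <- mass_correct(v8, rep(2, 8)), "no-op")
  expect_equal(out, v8)
  expect_error(mass_correct(c(1, 2), c(1, 2)),
               class = "shoalmet_insufficient_data")
  expect_error(mass_correct(c(-1, 1, 2), c(1, 2, 3)),
               class = "shoalmet_domain_error")
})

test_that("condition trajectories summarise K by treatment and week", {
  morpho <- tibble::tibble(
    fish_id = rep(c("A", "B"), each = 3),
    holding = rep(c("shoal", "solitary"), each = 3),
    week = rep(0:2, 2),
    mass_g = c(rep(1.8, 3), 1.8, 1.6, 1.6),
    length_cm = 3.6
  )
  traj <- condition_trajectory(morpho)
  # constant-K fish has zero deltas
  expect_equal(traj$deltas$delta_k[traj$deltas$fish_id == "A"], c(0, 0))
  expect_lt(traj$deltas$delta_k[traj$deltas$fish_id == "B" &
                                  traj$deltas$week_to == 1], 0)
  # single fish per group: s.e.m. undefined
  expect_true(all(is.na(traj$by_week$sem_k)))

  sim <- simulate_cohort(short_config(seed = 13))
  traj2 <- condition_trajectory(sim$morphometrics)
  d01 <- dplyr::filter(traj2$deltas, week_to == 1)
  mean_sol <- mean(d01$delta_k[d01$holding == "solitary"])
  mean_sho <- mean(d01$delta_k[d01$holding == "shoal"])
  k_bar <- mean(fultons_k(sim$fish$mass_g, sim$fish$length_cm))
  expect_lt(mean_sol, -0.02 * k_bar) # solitary fish lose condition
  expect_lt(abs(mean_sho), 0.02 * k_bar) # shoal-held fish hold steady

  expect_warning(condition_trajectory(morpho[morpho$week != 1, ]), "partial")
})

test_that("paired sign-flip permutation p-values are exact for small n", {
  # identical pairs: no signal
  expect_equal(paired_permutation_test(1:5, 1:5)$p_value, 1)

  # n = 8, all differences the same sign: only the two extreme flips tie
  a <- c(5.2, 6.1, 4.8, 5.9, 6.3, 5.5, 5.0, 6.0)
  b <- a - c(0.4, 0.2, 0.5, 0.3, 0.6, 0.2, 0.3, 0.5)
  res <- paired_permutation_test(a, b)
  expect_equal(res$p_value, 2 / 256)
  expect_equal(res$method, "exact")

  # pairing invariance: shuffling fish order leaves p unchanged
  ord <- c(3, 1, 8, 5, 2, 7, 4, 6)
  expect_equal(paired_permutation_test(a[ord], b[ord])$p_value, res$p_value)

  # percent reduction is per fish, then averaged
  expect_equal(res$mean_pct_reduction, mean(100 * (a - b) / a))
})

test_that("Monte-Carlo permutation converges to the enumerated p-value", {
  a <- c(2.0, 2.3, 1.9, 2.6, 2.1, 2.4)
  b <- c(1.8, 2.4, 1.6, 2.2, 2.2, 2.0)
  p_exact <- paired_permutation_test(a, b, exact = TRUE)$p_value
  p_mc <- paired_permutation_test(a, b, exact = FALSE, n_perm = 40000,
                                  seed = 5)$p_value
  expect_equal(p_mc, p_exact, tolerance = 0.1)
  expect_gt(p_mc, 0)
})

test_that("condition comparisons pivot paired testing conditions correctly", {
  d <- simulate_metric_cohort(sim_config(seed = 17))
  cmp <- compare_conditions(d, metric = "mr_min", seed = 1)
  expect_equal(cmp$n, 16)
  expect_lt(cmp$p_value, 0.05) # default effect is large and paired
  td <- tidy(cmp)
  expect_equal(td$mean_pct_reduction, cmp$mean_pct_reduction)
  expect_equal(td$metric, "mr_min")
})

test_that("the mixed model recovers treatment structure and degrades gracefully", {
  d <- simulate_metric_cohort(sim_config(seed = 19))
  mm <- suppressWarnings(mixed_model_compare(d, "mr_min"))
  co <- tidy(mm)
  expect_lt(co$estimate[co$term == "testingshoal"], 0) # shoal lowers MO2
  ft <- tidy(mm, "ftests")
  expect_true(all(c("holding", "testing", "mass_g") %in% ft$term))
  expect_lt(ft$p_value[ft$term == "testing"], 0.05)

  # constant response: testing effect is estimated as exactly zero
  d0 <- d
  d0$mr_min <- 1
  mm0 <- suppressWarnings(mixed_model_compare(d0, "mr_min"))
  co0 <- tidy(mm0)
  expect_equal(co0$estimate[co0$term == "testingshoal"], 0, tolerance = 1e-10)
  expect_type(glance(mm0)$fallback, "logical")
})
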