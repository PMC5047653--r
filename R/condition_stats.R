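#' Fulton's K condition factor
#'
#' K = 100 x M / L^3 with wet mass M in grams and standard length L in cm, a
#' dimensionless index of plumpness for fish of similar shape.
#'
#' @param mass_g Wet mass, grams (positive).
#' @param length_cm Standard length, cm (positive).
#' @return Condition factor (vectorised).
#' @examples
#' fultons_k(1.84, 3.69)
#' @export
fultons_k <- function(mass_g, length_cm) {
  if (any(mass_g <= 0 | length_cm <= 0, na.rm = TRUE)) {
    abort_shoalmet("mass and length must be positive.", "shoalmet_domain_error")
  }
  100 * mass_g / length_cm^3
}

#' Allometric mass correction by log-log residuals
#'
#' Removes body-size differences from a metabolic metric by regressing
#' log(value) on log(mass) across the cohort (one pooled OLS fit) and
#' rebuilding each fish's value at a common reference mass: corrected_i =
#' exp(fitted value at log(reference mass) + residual_i). Output order
#' matches input. With zero mass variance the regression is undefined and
#' the values are returned unchanged with a warning.
#'
#' @param values Positive metric values (e.g. MR_min per fish).
#' @param mass_g Positive wet masses, same length (at least 3).
#' @param reference_mass Mass all values are standardised to, grams
#'   (default 1.84, a typical cohort mean for small damselfish).
#' @return Corrected values, same order and units as `values`.
#' @examples
#' mass_correct(c(0.4, 0.5, 0.6), c(1.5, 1.9, 2.3))
#' @export
mass_correct <- function(values, mass_g, reference_mass = 1.84) {
  if (length(values) != length(mass_g)) {
    abort_shoalmet("`values` and `mass_g` must have equal length.",
                   "shoalmet_domain_error")
  }
  if (length(values) < 3) {
    abort_shoalmet("mass correction needs at least 3 fish.",
                   "shoalmet_insufficient_data")
  }
  if (any(values <= 0 | mass_g <= 0)) {
    abort_shoalmet("values and masses must be positive.",
                   "shoalmet_domain_error")
  }
  lm_dat <- data.frame(lv = log(values), lm_ = log(mass_g))
  if (stats::var(lm_dat$lm_) == 0) {
    # no size signal to remove; exact identity when already at the reference
    if (any(mass_g != reference_mass)) {
      warning("zero mass variance; mass correction is a no-op.", call. = FALSE)
    }
    return(values)
  }
  fit <- stats::lm(lv ~ lm_, data = lm_dat)
  fitted_ref <- unname(stats::predict(fit,
                                      newdata = data.frame(lm_ = log(reference_mass))))
  unname(exp(fitted_ref + stats::residuals(fit)))
}

#' Body-condition trajectory by holding treatment
#'
#' Per-treatment mean and standard error of Fulton's K at each measured week,
#' plus the per-fish week-to-week change in K. A missing week yields a
#' partial result flagged in the `complete` attribute.
#'
#' @param morphometrics Tibble with `fish_id`, `holding`, `week`, `mass_g`,
#'   `length_cm` (weeks 0 and 1 expected).
#' @return A list of tibbles: `by_week` (holding, week, mean_k, sem_k, n) and
#'   `deltas` (fish_id, holding, week_from, week_to, delta_k).
#' @export
condition_trajectory <- function(morphometrics) {
  m <- dplyr::mutate(morphometrics, k = fultons_k(.data$mass_g, .data$length_cm))
  by_week <- m |>
    dplyr::group_by(.data$holding, .data$week) |>
    dplyr::summarise(mean_k = mean(.data$k), sem_k = sem(.data$k),
                     n = dplyr::n(), .groups = "drop")
  deltas <- m |>
    dplyr::arrange(.data$fish_id, .data$week) |>
    dplyr::group_by(.data$fish_id, .data$holding) |>
    dplyr::mutate(week_from = dplyr::lag(.data$week),
                  delta_k = .data$k - dplyr::lag(.data$k)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$delta_k)) |>
    dplyr::select("fish_id", "holding", "week_from", week_to = "week", "delta_k")
  complete <- all(c(0, 1) %in% unique(m$week))
  if (!complete) {
    warning("weeks 0 and 1 not both present; trajectory is partial.",
            call. = FALSE)
  }
  structure(list(by_week = by_week, deltas = deltas), complete = complete)
}

#' Paired sign-flip permutation test
#'
#' Self-contained inference for paired designs (each fish measured under both
#' testing conditions): under the null of no condition effect the sign of
#' each within-fish difference is exchangeable, so the mean difference is
#' referred to the distribution obtained by flipping signs. All 2^n flips
#' are enumerated exactly for n <= 12; larger samples use seeded Monte Carlo
#' (with the identity flip counted, keeping p > 0). The two-sided p-value
#' compares |mean difference| against the flip distribution.
#'
#' @param values_a,values_b Paired measurements per fish, same order (e.g.
#'   solitary and shoal testing). n >= 2.
#' @param n_perm Monte-Carlo draws when not enumerating (default 10000).
#' @param seed Seed for the Monte-Carlo path.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default enumerates when n <= 12.
#' @return A `shoal_perm` object: observed mean difference, two-sided
#'   `p_value`, per-fish percent reductions and their mean, group means and
#'   s.e.m., method details.
#' @examples
#' paired_permutation_test(c(5, 6, 7, 8), c(4, 5, 6, 7))
#' @export
paired_permutation_test <- function(values_a, values_b, n_perm = 10000,
                                    seed = NULL, exact = NULL) {
  if (length(values_a) != length(values_b) || length(values_a) < 2) {
    abort_shoalmet("need equal-length paired samples with n >= 2.",
                   "shoalmet_domain_error")
  }
  d <- values_a - values_b
  n <- length(d)
  obs <- mean(d)
  tol <- 1e-12 * max(1, abs(obs))
  if (all(d == 0)) {
    p <- 1
    method <- "degenerate"
  } else if (exact %||% (n <= 12)) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm_means <- as.vector(signs %*% d) / n
    p <- mean(abs(perm_means) >= abs(obs) - tol)
    method <- "exact"
  } else {
    p <- with_seed(seed %||% 1L, {
      hits <- sum(vapply(seq_len(n_perm), function(i) {
        abs(mean(d * sample(c(-1, 1), n, replace = TRUE))) >= abs(obs) - tol
      }, logical(1)))
      (1 + hits) / (1 + n_perm)
    })
    method <- "monte_carlo"
  }
  pct <- 100 * (values_a - values_b) / values_a
  structure(
    list(
      estimate = obs,
      p_value = p,
      n = n,
      mean_a = mean(values_a), mean_b = mean(values_b),
      sem_a = sem(values_a), sem_b = sem(values_b),
      pct_reduction = pct,
      mean_pct_reduction = mean(pct),
      method = method,
      n_perm = if (method == "monte_carlo") n_perm else 2^n,
      seed = if (method == "monte_carlo") (seed %||% 1L) else NA_integer_
    ),
    class = "shoal_perm"
  )
}

#' @export
print.shoal_perm <- function(x, ...) {
  cat(sprintf(
    "Paired sign-flip permutation test (%s, %d flips)\n  mean difference %.4g, mean reduction %.1f%%, p = %.4g (n = %d pairs)\n",
    x$method, x$n_perm, x$estimate, x$mean_pct_reduction, x$p_value, x$n
  ))
  invisible(x)
}

#' Compare paired testing conditions on one metabolic metric
#'
#' Pivots a per-fish-by-condition summary table to paired solitary/shoal
#' columns and runs the sign-flip permutation test, reporting the mean
#' per-fish percent reduction 100 x (solitary - shoal) / solitary.
#'
#' @param summaries Tibble with `fish_id`, `testing` and the metric column
#'   (e.g. from [process_cohort()]).
#' @param metric Metric column name (default `"mr_min"`).
#' @inheritParams paired_permutation_test
#' @return A `shoal_perm` comparison (solitary as group a, shoal as group b)
#'   with the metric name attached.
#' @export
compare_conditions <- function(summaries, metric = "mr_min", n_perm = 10000,
                               seed = NULL) {
  wide <- summaries |>
    dplyr::select("fish_id", "testing", dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "testing", values_from = dplyr::all_of(metric)) |>
    dplyr::filter(!is.na(.data$solitary) & !is.na(.data$shoal))
  res <- paired_permutation_test(wide$solitary, wide$shoal,
                                 n_perm = n_perm, seed = seed)
  res$metric <- metric
  res
}

#' Linear mixed-model comparison of treatments
#'
#' The conventional inference path for this design: a linear mixed model with
#' holding treatment and testing condition as fixed effects, body mass as a
#' covariate, and a per-individual random intercept for the repeated
#' measures, delegated to `lmer` with Satterthwaite F tests. This
#' complements, and is cross-checkable against, the bespoke permutation test
#' in [paired_permutation_test()]. A singular or failed random-effect fit
#' falls back to fixed-effects-only OLS, flagged in the result.
#'
#' @param data Tibble with one row per fish x testing condition.
#' @param response Response column name (e.g. `"mr_min"`).
#' @param fixed_effects Character vector of fixed-effect columns
#'   (default `c("holding", "testing")`).
#' @param covariate Optional numeric covariate column (default `"mass_g"`;
#'   `NULL` to omit).
#' @param random Grouping column for the random intercept (default
#'   `"fish_id"`).
#' @return A `shoal_mmc` object wrapping the fit with tidy coefficient and
#'   F-test tables.
#' @export
mixed_model_compare <- function(data, response,
                                fixed_effects = c("holding", "testing"),
                                covariate = "mass_g", random = "fish_id") {
  # solitary is the biological baseline; make it the reference level so the
  # testing/holding coefficients read as the effect of shoal exposure
  for (col in fixed_effects) {
    if (is.character(data[[col]]) &&
        all(data[[col]] %in% c("solitary", "shoal"))) {
      data[[col]] <- factor(data[[col]], levels = c("solitary", "shoal"))
    }
  }
  terms <- c(fixed_effects, covariate)
  fml <- stats::as.formula(paste(
    response, "~", paste(terms, collapse = " + "),
    "+ (1 |", random, ")"
  ))
  fit <- NULL
  fallback <- FALSE
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(fml, data = data)),
    error = function(e) NULL
  )
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) {
      warning("singular random-effect fit; reporting fixed-effects-only fallback.",
              call. = FALSE)
    }
    fallback <- TRUE
    fml_fe <- stats::as.formula(paste(response, "~",
                                      paste(terms, collapse = " + ")))
    fit_fe <- stats::lm(fml_fe, data = data)
    coefs <- summary(fit_fe)$coefficients
    coef_tbl <- tibble::tibble(
      term = rownames(coefs),
      estimate = unname(coefs[, 1]), std_error = unname(coefs[, 2]),
      statistic = unname(coefs[, 3]), p_value = unname(coefs[, 4])
    )
    an <- stats::anova(fit_fe)
    ftests <- tibble::tibble(
      term = rownames(an)[rownames(an) != "Residuals"],
      f_value = an$`F value`[rownames(an) != "Residuals"],
      p_value = an$`Pr(>F)`[rownames(an) != "Residuals"]
    )
    obj <- list(fit = fit_fe, coef = coef_tbl, ftests = ftests,
                response = response, fallback = TRUE)
  } else {
    coefs <- summary(fit)$coefficients
    coef_tbl <- tibble::tibble(
      term = rownames(coefs),
      estimate = unname(coefs[, "Estimate"]),
      std_error = unname(coefs[, "Std. Error"]),
      statistic = unname(coefs[, "t value"]),
      p_value = unname(coefs[, "Pr(>|t|)"])
    )
    an <- stats::anova(fit) # lmerTest Satterthwaite type III
    ftests <- tibble::tibble(
      term = rownames(an),
      f_value = an$`F value`,
      num_df = an$NumDF,
      den_df = an$DenDF,
      p_value = an$`Pr(>F)`
    )
    obj <- list(fit = fit, coef = coef_tbl, ftests = ftests,
                response = response, fallback = FALSE)
  }
  structure(obj, class = "shoal_mmc")
}

#' @export
print.shoal_mmc <- function(x, ...) {
  cat(sprintf("Linear mixed-model comparison of %s%s\n", x$response,
              if (x$fallback) " (fixed-effects fallback)" else ""))
  print(x$ftests)
  invisible(x)
}
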