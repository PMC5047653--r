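#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a paired permutation comparison
#'
#' @param x A `shoal_perm` from [paired_permutation_test()] or
#'   [compare_conditions()].
#' @param ... Unused.
#' @return One-row tibble: estimate (mean paired difference), group means,
#'   mean percent reduction, p-value, method.
#' @export
tidy.shoal_perm <- function(x, ...) {
  tibble::tibble(
    metric = x$metric %||% NA_character_,
    estimate = x$estimate,
    mean_solitary = x$mean_a,
    mean_shoal = x$mean_b,
    mean_pct_reduction = x$mean_pct_reduction,
    p_value = x$p_value,
    n_pairs = x$n,
    method = x$method
  )
}

#' @rdname tidy.shoal_perm
#' @export
glance.shoal_perm <- function(x, ...) {
  tibble::tibble(n_pairs = x$n, n_perm = x$n_perm, method = x$method,
                 p_value = x$p_value)
}

#' Tidy a mixed-model treatment comparison
#'
#' @param x A `shoal_mmc` from [mixed_model_compare()].
#' @param effects `"fixed"` (coefficients, default) or `"ftests"` (the
#'   F-table).
#' @param ... Unused.
#' @return A tibble of coefficients or F tests.
#' @export
tidy.shoal_mmc <- function(x, effects = c("fixed", "ftests"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$coef else x$ftests
}

#' @rdname tidy.shoal_mmc
#' @export
glance.shoal_mmc <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    fallback = x$fallback,
    n_obs = stats::nobs(x$fit)
  )
}
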