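#' Plot an oxygen trace
#'
#' Dissolved oxygen against time, coloured by cycle phase — the first visual
#' QC for any respirometry trial.
#'
#' @param trace An `o2_trace`.
#' @param max_points Thin the trace to roughly this many points (default
#'   5000) to keep plots light.
#' @return A ggplot.
#' @export
plot_trace <- function(trace, max_points = 5000) {
  d <- tibble::as_tibble(trace)
  if (nrow(d) > max_points) {
    d <- d[seq(1, nrow(d), length.out = max_points), ]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s / 3600, y = .data$o2_mgL,
                                  colour = .data$phase)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::labs(x = "Time (h)", y = expression(O[2] ~ (mg ~ L^-1)),
                  colour = "Phase") +
    ggplot2::theme_minimal()
}

#' @rdname plot_trace
#' @param object,... For `autoplot`: the trace and further arguments passed
#'   to `plot_trace()`.
#' @export
autoplot.o2_trace <- function(object, ...) plot_trace(object, ...)

#' Plot a per-period oxygen-uptake series
#'
#' Background-corrected MO2 against window midpoint, with QC failures marked
#' and the settling cutoff indicated.
#'
#' @param slopes Tibble from [process_trial()].
#' @param settle_cutoff Hours (drawn as a dashed line; default 5).
#' @return A ggplot.
#' @export
plot_mo2_series <- function(slopes, settle_cutoff = 5) {
  ggplot2::ggplot(slopes, ggplot2::aes(x = .data$t_mid_s / 3600, y = .data$mo2,
                                       shape = .data$qc_pass)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = settle_cutoff, linetype = "dashed") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(x = "Time (h)",
                  y = expression(dot(M) * O[2] ~ (mg ~ O[2] ~ h^-1)),
                  shape = expression(r^2 ~ QC)) +
    ggplot2::theme_minimal()
}

#' Plot paired solitary/shoal metric comparisons
#'
#' Per-fish paired lines with group means, the classic display for a paired
#' testing-condition contrast.
#'
#' @param summaries Tibble from [process_cohort()].
#' @param metric Metric column (default `"mr_min"`).
#' @return A ggplot.
#' @export
plot_comparison <- function(summaries, metric = "mr_min") {
  d <- summaries |>
    dplyr::mutate(testing = factor(.data$testing,
                                   levels = c("solitary", "shoal")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$testing, y = .data[[metric]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$fish_id), alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3,
                          colour = "red") +
    ggplot2::labs(x = "Testing condition", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot the body-condition trajectory
#'
#' Mean Fulton's K (+/- s.e.m.) per holding treatment across measurement
#' weeks.
#'
#' @param trajectory Result of [condition_trajectory()].
#' @return A ggplot.
#' @export
plot_condition_trajectory <- function(trajectory) {
  ggplot2::ggplot(trajectory$by_week,
                  ggplot2::aes(x = .data$week, y = .data$mean_k,
                               colour = .data$holding)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_k - .data$sem_k,
                                          ymax = .data$mean_k + .data$sem_k)) +
    ggplot2::labs(x = "Week", y = "Fulton's K", colour = "Holding") +
    ggplot2::theme_minimal()
}
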