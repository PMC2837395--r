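#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evolution run
#'
#' @param x An `evolution_run`.
#' @param ... Unused.
#' @return The per-step population summary tibble: population size, mean
#'   birth and mutation rates, mutator frequency, mean concentrations,
#'   stabilities and binding probabilities, and per-step event counts.
#' @export
tidy.evolution_run <- function(x, ...) x$time_series

#' One-row summary of an evolution run
#'
#' @param x An `evolution_run`.
#' @param ... Unused.
#' @return A one-row tibble: final time, population size, mean birth rate,
#'   mutator frequency, fitness class, extinction flag, calibrated b0 and
#'   G_ref.
#' @export
glance.evolution_run <- function(x, ...) {
  last <- x$time_series[nrow(x$time_series), ]
  tibble(
    t_end = x$meta$t_end, n = last$n, mean_b = last$mean_b,
    mutator_freq = last$mutator_freq,
    fitness_class = if (!is.na(last$mean_b) && last$mean_b > 0)
      fitness_class(min(last$mean_b, 1)) else NA_real_,
    extinct = x$meta$extinct, b0 = x$meta$b0, G_ref = x$meta$G_ref)
}

#' Plot an evolution run
#'
#' Stacked panels of population size, mean birth rate, mean MMR
#' concentration, and mutator frequency against time.
#'
#' @param object An `evolution_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evolution_run <- function(object, ...) {
  dat <- tidyr::pivot_longer(
    dplyr::select(object$time_series, "t", P = "n", b = "mean_b",
                  C4 = "mean_C4", freq = "mutator_freq"),
    -"t", names_to = "panel", values_to = "value")
  dat$panel <- factor(dat$panel, levels = c("P", "b", "C4", "freq"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "t", y = NULL) +
    ggplot2::theme_bw()
}

#' Plot a local fitness landscape
#'
#' Histogram of relative fitness changes per point mutation; the bar at
#' x = -1 collects lethal mutants.
#'
#' @param object A `landscape_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.landscape_histogram <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bins$bin_right[1] - object$bins$bin_left[1]) +
    ggplot2::labs(x = expression((b[mut] - b) / b), y = "mutants") +
    ggplot2::theme_bw()
}

#' Plot a competition experiment
#'
#' Fractional population of the high-fluctuation lineage over time, one
#' faint line per replicate plus the cross-replicate mean.
#'
#' @param traces Tibble returned by [run_competition()].
#' @return A ggplot object.
#' @export
plot_competition <- function(traces) {
  avg <- dplyr::summarise(dplyr::group_by(traces, .data$t),
                          fraction = mean(.data$fraction, na.rm = TRUE),
                          .groups = "drop")
  ggplot2::ggplot(traces, ggplot2::aes(x = .data$t, y = .data$fraction)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate), alpha = 0.25) +
    ggplot2::geom_line(data = avg, colour = "black", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "t", y = "fraction of fluctuating lineage") +
    ggplot2::theme_bw()
}

#' @importFrom rlang .data
NULL
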