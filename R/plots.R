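#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# long format shared by the plotting methods
.outputs_long <- function(yearly) {
  yearly |>
    dplyr::mutate(cum_cost_musd = .data$cum_cost_usd / 1e6) |>
    tidyr::pivot_longer(
      c("cum_tka_total", "cum_cost_musd"),
      names_to = "output", values_to = "value"
    ) |>
    dplyr::mutate(output = dplyr::recode(.data$output,
      cum_tka_total = "Cumulative patients in TKA",
      cum_cost_musd = "Cumulative gross cost (million $)"
    ))
}

#' Plot the yearly cumulative outputs of an experiment
#'
#' Draws the replication-averaged cumulative number of patients in TKA
#' (split into waiting-driven and post-transplant in the traditional
#' paradigm) and the cumulative gross cost, by calendar year.
#'
#' @param object A `menisim_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.menisim_experiment <- function(object, ...) {
  long <- .outputs_long(object$yearly)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~output, scales = "free_y") +
    ggplot2::labs(
      x = "Year",
      y = NULL,
      title = sprintf(
        "%s paradigm (scenario %s), mean of %d replications",
        object$config$paradigm, object$config$scenario,
        object$config$n_replications
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep across implant-quality scenarios
#'
#' Overlays the cumulative-TKA and cumulative-cost curves of every
#' scenario in the sweep, coloured by scenario.
#'
#' @param object A `menisim_sensitivity`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.menisim_sensitivity <- function(object, ...) {
  long <- .outputs_long(object$yearly)
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$year, y = .data$value,
      colour = .data$scenario, group = .data$scenario
    )
  ) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~output, scales = "free_y") +
    ggplot2::labs(
      x = "Year", y = NULL, colour = "Scenario",
      title = "Implant-quality sensitivity of the 3DP-enabled pathway"
    ) +
    ggplot2::theme_minimal()
}
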