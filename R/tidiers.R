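#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the yearly output series of an experiment
#'
#' @param x A `menisim_experiment`.
#' @param replications Return the per-replication series instead of the
#'   replication averages.
#' @param ... Unused.
#' @return A tibble with one row per year (`year`, `cum_tka_waiting`,
#'   `cum_tka_post`, `cum_tka_total`, `cum_cost_usd`, plus `se_` columns
#'   for the averaged series), or one row per replication-year.
#' @export
tidy.menisim_experiment <- function(x, replications = FALSE, ...) {
  if (replications) x$replications else x$yearly
}

#' One-row final-year summary of an experiment
#'
#' @param x A `menisim_experiment`.
#' @param ... Unused.
#' @return A one-row tibble: paradigm, scenario, final year, final-year
#'   cumulative TKA counts and gross cost (USD and million USD).
#' @export
glance.menisim_experiment <- function(x, ...) {
  last <- dplyr::slice_tail(x$yearly, n = 1L)
  tibble::tibble(
    paradigm = x$config$paradigm,
    scenario = x$config$scenario,
    n_patients = x$config$n_patients,
    n_replications = x$config$n_replications,
    final_year = last$year,
    cum_tka_waiting = last$cum_tka_waiting,
    cum_tka_post = last$cum_tka_post,
    cum_tka_total = last$cum_tka_total,
    cum_cost_usd = last$cum_cost_usd,
    cum_cost_musd = last$cum_cost_usd / 1e6
  )
}

#' Tidy the stacked yearly series of a sensitivity sweep
#'
#' @param x A `menisim_sensitivity`.
#' @param ... Unused.
#' @return A tibble with one row per scenario-year.
#' @export
tidy.menisim_sensitivity <- function(x, ...) {
  x$yearly
}

#' Final-year summary of every scenario in a sensitivity sweep
#'
#' @param x A `menisim_sensitivity`.
#' @param ... Unused.
#' @return A tibble with one row per scenario, ordered as run, with the
#'   scenario's scaling factor and final-year outputs.
#' @export
glance.menisim_sensitivity <- function(x, ...) {
  tab <- scenario_factors()
  purrr::imap(x$results, function(res, sc) {
    dplyr::mutate(
      glance(res),
      factor = tab$factor[match(sc, tab$scenario)],
      .after = "scenario"
    )
  }) |> dplyr::bind_rows()
}
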