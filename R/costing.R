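#' Cost of the traditional meniscus allograft within the transplantation fee
#'
#' The allograft component (USD) of the traditional transplantation cost;
#' in the 3D-printing-enabled pathway it is replaced by the implant cost.
#'
#' @export
allograft_cost <- 4750

#' Per-state and per-event cost table
#'
#' Costs (USD) charged during the simulation: nothing for a no-issue year,
#' an event cost each time a patient enters repair, reoperation or TKA, a
#' weekly charge per week spent waiting in the allograft queue, and the
#' transplantation procedure cost. Defaults are the traditional-paradigm
#' values; pass `paradigm = "3dp"` for the 3D-printing-enabled pathway,
#' where the transplantation cost swaps the allograft for the printed
#' implant (see [transplantation_cost_3dp()]) and no waiting cost can
#' arise because transplantation is immediate.
#'
#' @param paradigm `"traditional"` or `"3dp"`.
#' @param implant Implant cost used for the 3DP transplantation fee;
#'   defaults to the bill-of-materials total ([implant_cost()]).
#' @return A one-row tibble with columns `cost_ni`, `cost_r`, `cost_ro`,
#'   `cost_tka`, `cost_wait` and `cost_transplant`.
#' @export
#' @examples
#' cost_table()
#' cost_table("3dp")
cost_table <- function(paradigm = c("traditional", "3dp"),
                       implant = implant_cost()) {
  paradigm <- rlang::arg_match(paradigm)
  transplant <- if (paradigm == "traditional") {
    8875
  } else {
    transplantation_cost_3dp(8875, allograft_cost, implant)
  }
  tibble::tibble(
    cost_ni = 0, cost_r = 2760, cost_ro = 1770, cost_tka = 14167,
    cost_wait = 30, cost_transplant = transplant
  )
}

#' Bill of materials of a 3D-printed meniscus implant
#'
#' Itemized component costs for one patient-matched implant: stem cells,
#' culture medium, the collagen/alginate/PCL bio-ink, growth factor, the
#' ABS mould and overheads. Amounts are informative strings; costs are
#' USD per implant.
#'
#' @return A tibble with columns `item`, `amount` and `cost`.
#' @export
#' @examples
#' implant_bom()
#' implant_cost() # 3124
implant_bom <- function() {
  tibble::tribble(
    ~item, ~amount, ~cost,
    "Stem cell", "", 1000,
    "Cell culture", "500 mL", 213,
    "Human collagen-II", "22.5 mL", 805.5,
    "Alginate", "5 g", 0.7,
    "Polycaprolactone (PCL)", "1 g", 0.4,
    "TGF-beta I", "0.1 mg", 1076.5,
    "ABS", "63.5 g", 0.8,
    "Acetone", "10 mL", 0.1,
    "Others (container, beaker, machine, electricity, labor)", "", 27
  )
}

#' Total cost of the implant bill of materials
#'
#' @param bom A bill-of-materials tibble with a numeric `cost` column;
#'   defaults to [implant_bom()].
#' @return The summed item cost in USD.
#' @export
implant_cost <- function(bom = implant_bom()) {
  if (!is.data.frame(bom) || !"cost" %in% names(bom)) {
    rlang::abort("`bom` must be a data frame with a `cost` column")
  }
  if (any(bom$cost < 0)) rlang::abort("item costs must be non-negative")
  sum(bom$cost)
}

#' Transplantation cost of the 3D-printing-enabled pathway
#'
#' Obtained from the traditional transplantation cost by replacing its
#' allograft component with the 3D-printed implant cost; surgery, physical
#' therapy and procedure components are unchanged.
#'
#' @param traditional_transplant Traditional transplantation cost (USD).
#' @param allograft Allograft component of that cost (USD).
#' @param implant 3D-printed implant cost (USD).
#' @return `traditional_transplant - allograft + implant`, in USD.
#' @export
#' @examples
#' transplantation_cost_3dp(8875, 4750, 3124) # 7249
transplantation_cost_3dp <- function(traditional_transplant = 8875,
                                     allograft = allograft_cost,
                                     implant = implant_cost()) {
  v <- c(traditional_transplant, allograft, implant)
  if (!is.numeric(v) || length(v) != 3L || any(is.na(v)) || any(v < 0)) {
    rlang::abort("all cost components must be non-negative numbers")
  }
  if (allograft > traditional_transplant) {
    rlang::abort("the allograft component cannot exceed the transplantation cost")
  }
  traditional_transplant - allograft + implant
}

#' Accrue one patient's cost events
#'
#' Emits the timed cost events of a single patient: a weekly waiting
#' charge for every completed week in the allograft queue (timed-out
#' patients accrue the full threshold's worth), the transplantation fee at
#' the transplantation instant, the per-state event cost at each annual
#' check of the post-transplant trajectory (nothing for `NI`), and, for a
#' patient forced out of the queue, one TKA cost at the timeout instant
#' with no transplantation fee. Patient evaluation costs are negligible
#' and not modelled. Events falling after `horizon` weeks are dropped,
#' which is also how patients still waiting at the end of the observation
#' window are censored.
#'
#' @param disposition A one-row data frame with columns `arrival_week`,
#'   `outcome`, `event_week` (see [run_allocation()]); for the
#'   3DP pathway use outcome `"TRANSPLANTED"` with
#'   `event_week == arrival_week`.
#' @param trajectory The patient's post-transplant trajectory (columns
#'   `cycle`, `state`) for transplanted patients, `NULL` for timed-out
#'   ones; cycle `k` is charged at week `event_week + 52 k`.
#' @param costs A cost table from [cost_table()].
#' @param horizon Observation-window length in weeks.
#' @param weeks_per_year Cycle length in weeks (default 52).
#' @return A tibble of cost events: `week`, `item`, `cost`.
#' @export
#' @examples
#' d <- tibble::tibble(arrival_week = 0, outcome = "TIMED_OUT", event_week = 104)
#' accrue_patient_cost(d, NULL, cost_table(), horizon = 1040)
accrue_patient_cost <- function(disposition, trajectory, costs, horizon,
                                weeks_per_year = 52) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    rlang::abort("`horizon` must be a positive number of weeks")
  }
  stopifnot(nrow(disposition) == 1L)
  arrival <- disposition$arrival_week
  outcome <- disposition$outcome
  event <- disposition$event_week
  if (outcome == "TIMED_OUT" && !is.null(trajectory) && nrow(trajectory) > 0L) {
    rlang::abort("a timed-out patient has no post-transplant trajectory")
  }

  wait_weeks <- floor(event - arrival)
  ev <- list()
  if (wait_weeks >= 1) {
    ev$wait <- tibble::tibble(
      week = arrival + seq_len(wait_weeks), item = "waiting",
      cost = costs$cost_wait
    )
  }
  if (outcome == "TRANSPLANTED") {
    ev$transplant <- tibble::tibble(
      week = event, item = "transplantation", cost = costs$cost_transplant
    )
    if (!is.null(trajectory) && nrow(trajectory) > 0L) {
      tr <- dplyr::filter(trajectory, .data$cycle > 0L, .data$state != "NI")
      if (nrow(tr) > 0L) {
        state_cost <- c(
          R = costs$cost_r, RO = costs$cost_ro, TKA = costs$cost_tka
        )
        ev$post <- tibble::tibble(
          week = event + weeks_per_year * tr$cycle,
          item = paste0("state_", tr$state),
          cost = unname(state_cost[tr$state])
        )
      }
    }
  } else {
    ev$tka <- tibble::tibble(
      week = event, item = "waiting_tka", cost = costs$cost_tka
    )
  }
  out <- dplyr::bind_rows(ev)
  if (nrow(out) == 0L) {
    return(tibble::tibble(week = numeric(), item = character(), cost = numeric()))
  }
  dplyr::arrange(dplyr::filter(out, .data$week <= horizon), .data$week)
}
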