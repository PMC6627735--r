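#' Build a simulation configuration
#'
#' Collects every tunable of the pathway simulation with the defaults of
#' the study design: 1040 patients arriving over a 20-year (1040-week)
#' window with mean interarrival 1 week, a 104-week queue timeout in the
#' traditional paradigm, donor interarrival means drawn from 1-5 weeks, an
#' intermediate-entry cap of 2, and averages over 10 replications.
#'
#' @param paradigm `"traditional"` (allograft queue) or `"3dp"`
#'   (immediate patient-matched implant).
#' @param scenario Implant-quality scenario (see [scenario_factors()]);
#'   only meaningful for the 3DP paradigm, where it scales the transition
#'   matrix. The traditional paradigm always uses the original matrix.
#' @param n_patients Number of patients per replication.
#' @param horizon_years Length of the observation window in years.
#' @param weeks_per_year Annual-cycle length in weeks.
#' @param wait_threshold Queue timeout in weeks before TKA is forced.
#' @param patient_mean_interarrival Mean patient interarrival time (weeks).
#' @param donor_mean_range Range the per-gap donor interarrival mean is
#'   drawn from (weeks).
#' @param donor_mixing `"per_gap"` or `"per_stream"` donor-mean resampling
#'   (see [sample_donor_arrivals()]).
#' @param n_replications Number of independent replications averaged.
#' @param seed Master seed; replication substream seeds are derived from it
#'   deterministically so that runs sharing a master seed share patient
#'   arrival streams and per-patient transition draws (common random
#'   numbers across scenarios and paradigms).
#' @param cap Intermediate-state entry cap (third entry forces TKA).
#' @param count_reentry Whether an `R` to `RO` move counts as a new
#'   intermediate entry (see [simulate_post_transplant()]).
#' @param horizon_queue_policy What happens to patients still waiting when
#'   the window closes: `"censor"` (default; they accrue waiting cost to
#'   the horizon but no TKA is recorded) or `"force_tka"` (a waiting TKA is
#'   recorded at the horizon).
#' @param costs Optional cost table overriding [cost_table()] for the
#'   chosen paradigm (a one-row data frame or named list with fields
#'   `cost_ni`, `cost_r`, `cost_ro`, `cost_tka`, `cost_wait`,
#'   `cost_transplant`).
#' @param transition_matrix Optional base [transition_matrix()] replacing
#'   the built-in traditional one; the scenario's scaling factor is still
#'   applied to it in the 3DP paradigm.
#' @return A list of class `"menisim_config"`.
#' @export
#' @examples
#' simulation_config("3dp", scenario = "s5", seed = 7)
simulation_config <- function(paradigm = c("traditional", "3dp"),
                              scenario = "original",
                              n_patients = 1040,
                              horizon_years = 20,
                              weeks_per_year = 52,
                              wait_threshold = 104,
                              patient_mean_interarrival = 1,
                              donor_mean_range = c(1, 5),
                              donor_mixing = c("per_gap", "per_stream"),
                              n_replications = 10,
                              seed = 1,
                              cap = 2,
                              count_reentry = TRUE,
                              horizon_queue_policy = c("censor", "force_tka"),
                              costs = NULL,
                              transition_matrix = NULL) {
  paradigm <- rlang::arg_match(paradigm)
  donor_mixing <- rlang::arg_match(donor_mixing)
  horizon_queue_policy <- rlang::arg_match(horizon_queue_policy)
  scenario <- tolower(as.character(scenario))
  if (!scenario %in% scenario_factors()$scenario) {
    rlang::abort(sprintf("unknown scenario '%s'", scenario))
  }
  stopifnot(
    n_patients >= 1, horizon_years >= 1, n_replications >= 1,
    weeks_per_year > 0, wait_threshold > 0,
    wait_threshold <= horizon_years * weeks_per_year,
    patient_mean_interarrival > 0, cap >= 0
  )
  if (!is.null(costs)) {
    costs <- tibble::as_tibble(as.list(unlist(costs)))
    needed <- names(cost_table())
    if (!all(needed %in% names(costs))) {
      rlang::abort(paste("`costs` must provide:", paste(needed, collapse = ", ")))
    }
    costs <- costs[needed]
  }
  if (!is.null(transition_matrix)) {
    if (is.list(transition_matrix)) {
      # rows as a list, e.g. from a YAML/JSON config file
      transition_matrix <- do.call(rbind, lapply(transition_matrix, unlist))
    }
    transition_matrix <- menisim::transition_matrix(unclass(transition_matrix))
  }
  structure(
    list(
      paradigm = paradigm, scenario = scenario,
      n_patients = as.integer(n_patients),
      horizon_years = as.integer(horizon_years),
      weeks_per_year = weeks_per_year,
      wait_threshold = wait_threshold,
      patient_mean_interarrival = patient_mean_interarrival,
      donor_mean_range = donor_mean_range,
      donor_mixing = donor_mixing,
      n_replications = as.integer(n_replications),
      seed = as.integer(seed),
      cap = cap, count_reentry = isTRUE(count_reentry),
      horizon_queue_policy = horizon_queue_policy,
      costs = costs,
      transition_matrix = transition_matrix
    ),
    class = "menisim_config"
  )
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' The file's top-level keys mirror the arguments of
#' [simulation_config()]; `costs` may be a mapping of the six cost fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"menisim_config"`.
#' @export
read_simulation_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    rlang::abort(paste("unknown configuration keys:", paste(unknown, collapse = ", ")))
  }
  do.call(simulation_config, vals)
}

# cost table and transition matrix implied by a config
.config_costs <- function(config) {
  if (!is.null(config$costs)) config$costs else cost_table(config$paradigm)
}

.config_matrix <- function(config) {
  base <- config$transition_matrix
  if (is.null(base)) base <- traditional_transition_matrix()
  if (config$paradigm == "traditional") base else scenario_matrix(config$scenario, base)
}

# calendar year of an event week: year y covers weeks (52(y-1), 52y];
# events at week 0 belong to year 1
.event_year <- function(week, weeks_per_year) {
  pmax(1L, as.integer(ceiling(week / weeks_per_year)))
}

# cumulative per-year counts/sums of events at `week` with weight `value`
.cumulate <- function(week, value, horizon_years, weeks_per_year) {
  keep <- week <= horizon_years * weeks_per_year
  yr <- .event_year(week[keep], weeks_per_year)
  per_year <- vapply(
    seq_len(horizon_years),
    function(y) sum(value[keep][yr == y]), numeric(1)
  )
  cumsum(per_year)
}

#' Run one replication of a pathway simulation
#'
#' Generates the patient arrival stream; in the traditional paradigm also
#' generates the donor stream and resolves the first-come-first-served
#' allograft queue (in the 3DP paradigm every patient is transplanted at
#' arrival); simulates each transplanted patient's annual-cycle Markov
#' trajectory under the configured transition matrix and entry cap;
#' accrues waiting, transplantation and post-transplant costs; and bins
#' all events into calendar years.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed of this replication's random substream.
#' @param keep_details Attach per-patient dispositions and state-entry
#'   events (attribute `"details"`) for diagnostics and auditing.
#' @return A tibble with one row per calendar year: `year`,
#'   `cum_tka_waiting`, `cum_tka_post`, `cum_tka_total`, `cum_cost_usd`;
#'   all series are cumulative and non-decreasing.
#' @export
#' @examples
#' cfg <- simulation_config("3dp", n_patients = 50, n_replications = 1)
#' run_replication(cfg, seed = 1)
run_replication <- function(config, seed, keep_details = FALSE) {
  stopifnot(inherits(config, "menisim_config"))
  set.seed(as.integer(seed))
  wpy <- config$weeks_per_year
  horizon <- config$horizon_years * wpy
  costs <- .config_costs(config)
  tmat <- .config_matrix(config)

  patients <- sample_patient_arrivals(config$n_patients, config$patient_mean_interarrival)
  if (config$paradigm == "traditional") {
    donors <- sample_donor_arrivals(horizon, config$donor_mean_range, config$donor_mixing)
    disp <- run_allocation(patients, donors, config$wait_threshold)
  } else {
    disp <- tibble::tibble(
      patient_id = patients$patient_id,
      arrival_week = patients$arrival_week,
      outcome = "TRANSPLANTED",
      event_week = patients$arrival_week,
      waiting_weeks = 0
    )
  }

  # per-patient transition uniforms are drawn as a full block so that runs
  # sharing a seed share draws position-by-position (common random numbers)
  n <- nrow(disp)
  u <- matrix(stats::runif(n * config$horizon_years), nrow = n)

  transplanted <- disp$outcome == "TRANSPLANTED"
  n_cycles <- ifelse(
    transplanted,
    pmax(0, floor((horizon - disp$event_week) / wpy)),
    0
  )
  events <- .sim_cohort_events(
    tmat, as.integer(n_cycles), u,
    cap = config$cap, count_reentry = config$count_reentry
  )
  if (nrow(events) > 0L) {
    events$week <- disp$event_week[events$patient] + wpy * events$cycle
  } else {
    events <- tibble::tibble(
      patient = integer(), cycle = integer(), state = character(),
      forced = logical(), week = numeric()
    )
  }

  # --- cost events -------------------------------------------------------
  # waiting: one charge per completed week in queue (timed-out patients
  # accrue the full threshold); charges beyond the horizon are dropped
  wait_n <- as.integer(floor(disp$event_week - disp$arrival_week))
  wk_wait <- rep(disp$arrival_week, wait_n) + sequence(wait_n)
  cost_wait <- .cumulate(
    wk_wait, rep(costs$cost_wait, length(wk_wait)),
    config$horizon_years, wpy
  )
  # transplantation fees at the transplantation instant
  wk_tx <- disp$event_week[transplanted]
  cost_tx <- .cumulate(
    wk_tx, rep(costs$cost_transplant, length(wk_tx)),
    config$horizon_years, wpy
  )
  # timed-out patients: one TKA cost at the timeout instant
  timeout_week <- disp$event_week[disp$outcome == "TIMED_OUT"]
  if (config$horizon_queue_policy == "force_tka") {
    # still-waiting patients at the horizon are recorded as timed out there
    timeout_week <- pmin(timeout_week, horizon)
  }
  cost_wait_tka <- .cumulate(
    timeout_week, rep(costs$cost_tka, length(timeout_week)),
    config$horizon_years, wpy
  )
  # post-transplant state-entry costs
  state_cost <- c(R = costs$cost_r, RO = costs$cost_ro, TKA = costs$cost_tka)
  cost_post <- .cumulate(
    events$week, unname(state_cost[events$state]),
    config$horizon_years, wpy
  )

  # --- TKA counts --------------------------------------------------------
  tka_wait <- .cumulate(
    timeout_week, rep(1, length(timeout_week)),
    config$horizon_years, wpy
  )
  post_tka_week <- events$week[events$state == "TKA"]
  tka_post <- .cumulate(
    post_tka_week, rep(1, length(post_tka_week)),
    config$horizon_years, wpy
  )

  out <- tibble::tibble(
    year = seq_len(config$horizon_years),
    cum_tka_waiting = tka_wait,
    cum_tka_post = tka_post,
    cum_tka_total = tka_wait + tka_post,
    cum_cost_usd = cost_wait + cost_tx + cost_wait_tka + cost_post
  )
  if (keep_details) {
    attr(out, "details") <- list(dispositions = disp, state_events = events)
  }
  out
}

# replication substream seeds derived from the master seed
.replication_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a replicated pathway experiment
#'
#' Runs `n_replications` independent replications of [run_replication()]
#' with substream seeds derived deterministically from the master seed and
#' averages each yearly output series across replications (arithmetic
#' mean, the study's reporting convention), with standard errors attached
#' for diagnostics.
#'
#' @param config A [simulation_config()].
#' @return An object of class `"menisim_experiment"`: a list with
#'   `yearly` (averaged series plus `se_` columns), `replications` (the
#'   per-replication series, stacked with a `replication` column) and
#'   `config`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' cfg <- simulation_config("3dp", n_patients = 100, n_replications = 2)
#' run_experiment(cfg)
run_experiment <- function(config) {
  stopifnot(inherits(config, "menisim_config"))
  seeds <- .replication_seeds(config$seed, config$n_replications)
  reps <- purrr::map2(seq_along(seeds), seeds, function(i, s) {
    dplyr::mutate(run_replication(config, s), replication = i, .before = 1L)
  })
  reps <- dplyr::bind_rows(reps)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  yearly <- reps |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      dplyr::across(
        c("cum_tka_waiting", "cum_tka_post", "cum_tka_total", "cum_cost_usd"),
        list(mean = mean, se = se),
        .names = "{.fn}_{.col}"
      ),
      .groups = "drop"
    ) |>
    dplyr::rename_with(
      ~ sub("^mean_", "", .x),
      dplyr::starts_with("mean_")
    )
  structure(
    list(yearly = yearly, replications = reps, config = config),
    class = "menisim_experiment"
  )
}

#' Sensitivity sweep over implant-quality scenarios
#'
#' Runs [run_experiment()] once per scenario with a common master seed, so
#' every scenario sees identical patient arrival streams and per-patient
#' transition draws (common random numbers); differences between scenario
#' outputs then reflect the quality factors, not sampling noise.
#'
#' @param config A [simulation_config()] with `paradigm = "3dp"` (the
#'   scenario field is overridden per run).
#' @param scenarios Character vector of scenario ids; defaults to
#'   `original` plus all eight quality scenarios.
#' @return An object of class `"menisim_sensitivity"`: a list with
#'   `results` (one `menisim_experiment` per scenario), `yearly` (their
#'   averaged series stacked with `scenario` and `factor` columns) and
#'   `config`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' cfg <- simulation_config("3dp", n_patients = 100, n_replications = 2)
#' run_sensitivity(cfg, c("original", "s8"))
run_sensitivity <- function(config, scenarios = scenario_factors()$scenario) {
  stopifnot(inherits(config, "menisim_config"))
  if (config$paradigm != "3dp") {
    rlang::abort("sensitivity scenarios apply to the 3dp paradigm")
  }
  scenarios <- tolower(scenarios)
  tab <- scenario_factors()
  bad <- setdiff(scenarios, tab$scenario)
  if (length(bad) > 0L) {
    rlang::abort(paste("unknown scenarios:", paste(bad, collapse = ", ")))
  }
  results <- purrr::map(scenarios, function(sc) {
    cfg <- config
    cfg$scenario <- sc
    run_experiment(cfg)
  })
  names(results) <- scenarios
  yearly <- purrr::imap(results, function(res, sc) {
    dplyr::mutate(
      res$yearly,
      scenario = sc,
      factor = tab$factor[match(sc, tab$scenario)],
      .before = 1L
    )
  }) |> dplyr::bind_rows()
  structure(
    list(results = results, yearly = yearly, config = config),
    class = "menisim_sensitivity"
  )
}

#' @export
print.menisim_config <- function(x, ...) {
  cat(
    "Pathway simulation configuration\n",
    sprintf("  paradigm: %s (scenario %s)\n", x$paradigm, x$scenario),
    sprintf(
      "  %d patients, %d years, %d replications, seed %d\n",
      x$n_patients, x$horizon_years, x$n_replications, x$seed
    ),
    sep = ""
  )
  invisible(x)
}

#' @export
print.menisim_experiment <- function(x, ...) {
  g <- generics::glance(x)
  cat(sprintf(
    "Pathway experiment: %s (scenario %s), %d patients, %d reps\n",
    x$config$paradigm, x$config$scenario,
    x$config$n_patients, x$config$n_replications
  ))
  cat(sprintf(
    "Year %d: %.1f TKA (%.1f waiting + %.1f post), cost $%.2fM\n",
    g$final_year, g$cum_tka_total, g$cum_tka_waiting, g$cum_tka_post,
    g$cum_cost_musd
  ))
  invisible(x)
}

#' @export
print.menisim_sensitivity <- function(x, ...) {
  cat(sprintf(
    "Implant-quality sensitivity sweep (%d scenarios, seed %d)\n",
    length(x$results), x$config$seed
  ))
  print(generics::glance(x))
  invisible(x)
}
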