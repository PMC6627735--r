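#' Sample patient arrivals to the transplantation pathway
#'
#' Patients arrive with independent exponentially distributed interarrival
#' times (default mean 1 week), i.e. a Poisson arrival process. Times are
#' measured in weeks from the start of the simulation.
#'
#' @param n_patients Number of patients to generate.
#' @param mean_interarrival Mean interarrival time in weeks (> 0).
#' @return A tibble with columns `patient_id` and `arrival_week`, sorted by
#'   arrival (strictly increasing almost surely).
#' @export
#' @examples
#' set.seed(1)
#' sample_patient_arrivals(5)
sample_patient_arrivals <- function(n_patients, mean_interarrival = 1) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0) {
    rlang::abort("`n_patients` must be a non-negative count")
  }
  if (!is.numeric(mean_interarrival) || length(mean_interarrival) != 1L ||
    is.na(mean_interarrival) || mean_interarrival <= 0) {
    rlang::abort("`mean_interarrival` must be a positive number of weeks")
  }
  n <- as.integer(n_patients)
  tibble::tibble(
    patient_id = seq_len(n),
    arrival_week = cumsum(stats::rexp(n, rate = 1 / mean_interarrival))
  )
}

#' Sample donor (allograft) arrivals over a horizon
#'
#' Donor arrivals follow a mixed exponential renewal process: for each gap
#' a mean `m` is drawn uniformly from `donor_mean_range` (default 1 to 5
#' weeks) and the interarrival time is exponential with that mean, so the
#' marginal mean interarrival is the midpoint (3 weeks by default). With
#' `mixing = "per_stream"` a single mean is drawn once and reused for every
#' gap in the stream, an alternative reading of "the average interarrival
#' time being a random sample" kept for sensitivity checking.
#'
#' @param horizon Length of the observation window in weeks (> 0); all
#'   returned arrival times are `<= horizon`.
#' @param donor_mean_range Length-2 numeric range the per-gap mean is drawn
#'   from, in weeks.
#' @param mixing `"per_gap"` (default) redraws the mean for every
#'   interarrival; `"per_stream"` draws it once per stream.
#' @return A tibble with columns `donor_id` and `arrival_week`.
#' @export
#' @examples
#' set.seed(1)
#' sample_donor_arrivals(52)
sample_donor_arrivals <- function(horizon, donor_mean_range = c(1, 5),
                                  mixing = c("per_gap", "per_stream")) {
  if (!is.numeric(horizon) || length(horizon) != 1L || is.na(horizon) || horizon <= 0) {
    rlang::abort("`horizon` must be a positive number of weeks")
  }
  if (!is.numeric(donor_mean_range) || length(donor_mean_range) != 2L ||
    any(donor_mean_range <= 0) || diff(donor_mean_range) < 0) {
    rlang::abort("`donor_mean_range` must be an increasing positive range")
  }
  mixing <- rlang::arg_match(mixing)
  stream_mean <- stats::runif(1L, donor_mean_range[1L], donor_mean_range[2L])
  # draw in blocks sized from the marginal mean to avoid one rexp() call per gap
  times <- numeric(0)
  t_now <- 0
  block <- max(16L, ceiling(horizon / mean(donor_mean_range)) + 8L)
  while (t_now <= horizon) {
    m <- if (mixing == "per_gap") {
      stats::runif(block, donor_mean_range[1L], donor_mean_range[2L])
    } else {
      rep(stream_mean, block)
    }
    gaps <- stats::rexp(block, rate = 1 / m)
    times <- c(times, t_now + cumsum(gaps))
    t_now <- times[length(times)]
  }
  times <- times[times <= horizon]
  tibble::tibble(donor_id = seq_along(times), arrival_week = times)
}

#' Allocate donors to waiting patients (first come, first served)
#'
#' Resolves the traditional paradigm's allograft queue. Donors are taken in
#' arrival order and each is assigned to the longest-waiting patient
#' present in the queue at that moment; a donor arriving to an empty queue
#' is discarded (no allograft banking). A patient whose waiting time
#' reaches `threshold` weeks before receiving a donor leaves the queue and
#' is forced into TKA at exactly `arrival + threshold`; if a donor arrives
#' at that same instant the timeout wins. Every patient receives exactly
#' one disposition.
#'
#' @param patients Tibble of patient arrivals from
#'   [sample_patient_arrivals()] (columns `patient_id`, `arrival_week`).
#' @param donors Tibble of donor arrivals from [sample_donor_arrivals()]
#'   (column `arrival_week`).
#' @param threshold Waiting-time threshold in weeks (> 0) after which a
#'   patient is forced into TKA; default 104 weeks (2 years).
#' @return A tibble with one row per patient: `patient_id`, `arrival_week`,
#'   `outcome` (`"TRANSPLANTED"` or `"TIMED_OUT"`), `event_week` (the
#'   transplantation or timeout instant) and `waiting_weeks`
#'   (`event_week - arrival_week`).
#' @export
#' @examples
#' pats <- tibble::tibble(patient_id = 1:2, arrival_week = c(0, 1))
#' dons <- tibble::tibble(donor_id = 1L, arrival_week = 2)
#' run_allocation(pats, dons, threshold = 104)
run_allocation <- function(patients, donors, threshold = 104) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
    threshold <= 0) {
    rlang::abort("`threshold` must be a positive number of weeks")
  }
  arr <- patients$arrival_week
  ord <- order(arr)
  arr <- arr[ord]
  ids <- patients$patient_id[ord]
  n <- length(arr)
  donor_t <- sort(donors$arrival_week)

  outcome <- rep("TIMED_OUT", n)
  event <- arr + threshold
  head_i <- 1L # longest-waiting patient still in queue
  next_i <- 1L # next patient yet to arrive
  for (d in donor_t) {
    while (next_i <= n && arr[next_i] <= d) next_i <- next_i + 1L
    # drop patients whose timeout is at or before the donor instant
    while (head_i < next_i && arr[head_i] + threshold <= d) head_i <- head_i + 1L
    if (head_i < next_i) {
      outcome[head_i] <- "TRANSPLANTED"
      event[head_i] <- d
      head_i <- head_i + 1L
    }
  }
  tibble::tibble(
    patient_id = ids,
    arrival_week = arr,
    outcome = outcome,
    event_week = event,
    # timed-out patients wait exactly the threshold; avoid float residue
    waiting_weeks = ifelse(outcome == "TIMED_OUT", threshold, event - arr)
  )
}
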