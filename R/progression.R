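# state codes used internally: 1 = NI, 2 = R, 3 = RO, 4 = TKA
.state_code <- function(state) match(state, health_states)

# first three cumulative sums of each non-absorbing row; a uniform draw u
# maps to destination 1 + sum(u >= cum[s, ])
.row_cums <- function(matrix) {
  m <- unclass(matrix)
  t(apply(m[1:3, , drop = FALSE], 1L, function(r) cumsum(r)[1:3]))
}

#' Draw one annual state transition
#'
#' Samples the next health state from the current state's row of the
#' transition matrix. Stepping from `TKA` is a contract violation: the
#' state is absorbing and trajectories stop there.
#'
#' @param current Current state label, one of `"NI"`, `"R"`, `"RO"`.
#' @param matrix A `transition_matrix`.
#' @return The next state label.
#' @export
#' @examples
#' set.seed(1)
#' step_state("RO", traditional_transition_matrix()) # always "NI"
step_state <- function(current, matrix) {
  s <- .state_code(current)
  if (is.na(s) || s == 4L) {
    rlang::abort("`current` must be one of NI, R, RO (TKA is absorbing)")
  }
  m <- transition_matrix(unclass(matrix))
  cums <- cumsum(unclass(m)[s, ])[1:3]
  health_states[1L + sum(stats::runif(1L) >= cums)]
}

#' Simulate one patient's post-transplant trajectory
#'
#' Starts at `NI` immediately after surgery and applies one annual
#' transition per cycle. Every transition *into* an intermediate state
#' (`R` or `RO`, including an `R` to `RO` escalation) counts as a new
#' intermediate-state entry; when a sampled transition would be entry
#' number `cap + 1`, the destination is replaced by `TKA` (the "forced"
#' TKA of the entry-cap rule). The trajectory stops at `TKA` or after
#' `n_cycles` annual checks, whichever comes first.
#'
#' @param matrix A `transition_matrix`.
#' @param n_cycles Number of annual checks to simulate (>= 0).
#' @param cap Maximum number of intermediate-state entries allowed before
#'   TKA is forced (default 2, i.e. the third entry becomes TKA).
#' @param count_reentry Whether an `R` to `RO` transition counts as a new
#'   intermediate entry (default `TRUE`); with `FALSE` a direct move
#'   between the two intermediate states continues the same episode.
#' @return A tibble with one row per visited cycle: `cycle` (0 =
#'   immediately after surgery), `state`, `entries_used` (intermediate
#'   entries so far) and `forced_tka` (whether that row's TKA was forced
#'   by the cap).
#' @export
#' @examples
#' set.seed(1)
#' simulate_post_transplant(traditional_transition_matrix(), 10)
simulate_post_transplant <- function(matrix, n_cycles, cap = 2, count_reentry = TRUE) {
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 0) {
    rlang::abort("`n_cycles` must be a non-negative count")
  }
  m <- transition_matrix(unclass(matrix))
  cums <- .row_cums(m)
  state <- 1L
  entries <- 0L
  cyc <- 0L
  states <- integer(n_cycles + 1L)
  entry_trace <- integer(n_cycles + 1L)
  forced <- logical(n_cycles + 1L)
  states[1L] <- state
  for (k in seq_len(n_cycles)) {
    dest <- 1L + sum(stats::runif(1L) >= cums[state, ])
    if (dest %in% c(2L, 3L)) {
      new_entry <- count_reentry || !(state %in% c(2L, 3L))
      if (new_entry && entries + 1L > cap) {
        dest <- 4L
        forced[k + 1L] <- TRUE
      } else if (new_entry) {
        entries <- entries + 1L
      }
    }
    state <- dest
    cyc <- k
    states[k + 1L] <- state
    entry_trace[k + 1L] <- entries
    if (state == 4L) break
  }
  keep <- seq_len(cyc + 1L)
  tibble::tibble(
    cycle = keep - 1L,
    state = health_states[states[keep]],
    entries_used = entry_trace[keep],
    forced_tka = forced[keep]
  )
}

# Vectorized cohort progression used by the replication engine.
#
# u: n x max_cycles matrix of uniforms (row = patient, col = cycle);
# n_cycles: per-patient number of annual checks. Returns a tibble of the
# non-NI state entries (patient, cycle, state, forced) -- exactly the events
# that carry cost or count as TKA.
.sim_cohort_events <- function(matrix, n_cycles, u, cap = 2, count_reentry = TRUE) {
  n <- length(n_cycles)
  stopifnot(nrow(u) == n)
  cums <- .row_cums(transition_matrix(unclass(matrix)))
  state <- rep(1L, n)
  entries <- rep(0L, n)
  out <- vector("list", ncol(u))
  for (k in seq_len(ncol(u))) {
    idx <- which(state != 4L & n_cycles >= k)
    if (length(idx) == 0L) break
    s <- state[idx]
    uk <- u[idx, k]
    dest <- 1L + (uk >= cums[s, 1L]) + (uk >= cums[s, 2L]) + (uk >= cums[s, 3L])
    inter <- dest == 2L | dest == 3L
    new_entry <- inter & (count_reentry | !(s %in% c(2L, 3L)))
    force <- new_entry & (entries[idx] + 1L > cap)
    dest[force] <- 4L
    entries[idx] <- entries[idx] + as.integer(new_entry & !force)
    state[idx] <- dest
    ev <- dest != 1L
    if (any(ev)) {
      out[[k]] <- tibble::tibble(
        patient = idx[ev], cycle = k,
        state = health_states[dest[ev]], forced = force[ev]
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Exact TKA absorption probabilities under the entry-cap rule
#'
#' Analytic counterpart of [simulate_post_transplant()]: augments the
#' Markov chain with the number of intermediate-state entries used, so the
#' state space is (health state, entries) for entries `0..cap` plus
#' absorbing `TKA`, redirects the `(cap + 1)`-th intermediate entry to
#' `TKA`, and iterates the augmented kernel from the initial state
#' `(NI, 0)`. Useful as an exact oracle for Monte-Carlo output and for
#' expected cohort TKA fractions.
#'
#' @inheritParams simulate_post_transplant
#' @param cap Intermediate-entry cap; `Inf` disables the cap, reducing the
#'   computation to plain matrix powers of the unaugmented chain.
#' @return A tibble with columns `cycle` (`0..n_cycles`) and `p_tka`, the
#'   probability of being in `TKA` after that many annual checks;
#'   non-decreasing in `cycle`.
#' @export
#' @examples
#' tka_probability_by_cycle(traditional_transition_matrix(), 10)
tka_probability_by_cycle <- function(matrix, n_cycles, cap = 2, count_reentry = TRUE) {
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 0) {
    rlang::abort("`n_cycles` must be a non-negative count")
  }
  m <- unclass(transition_matrix(unclass(matrix)))
  if (!is.finite(cap)) {
    # plain chain: no forced transitions
    p <- c(1, 0, 0, 0)
    out <- numeric(n_cycles + 1L)
    for (k in seq_len(n_cycles)) {
      p <- as.vector(p %*% m)
      out[k + 1L] <- p[4L]
    }
    return(tibble::tibble(cycle = 0:n_cycles, p_tka = out))
  }
  cap <- as.integer(cap)
  # augmented transient states: (health s in 1..3, entries e in 0..cap)
  n_tr <- 3L * (cap + 1L)
  aidx <- function(s, e) (e * 3L) + s
  K <- matrix(0, n_tr, n_tr) # transient-to-transient
  a <- numeric(n_tr) # transient-to-TKA
  for (s in 1:3) {
    for (e in 0:cap) {
      i <- aidx(s, e)
      K[i, aidx(1L, e)] <- K[i, aidx(1L, e)] + m[s, 1L]
      for (d in 2:3) {
        new_entry <- count_reentry || !(s %in% c(2L, 3L))
        if (new_entry) {
          if (e + 1L > cap) {
            a[i] <- a[i] + m[s, d] # forced TKA
          } else {
            K[i, aidx(d, e + 1L)] <- K[i, aidx(d, e + 1L)] + m[s, d]
          }
        } else {
          K[i, aidx(d, e)] <- K[i, aidx(d, e)] + m[s, d]
        }
      }
      a[i] <- a[i] + m[s, 4L]
    }
  }
  p <- numeric(n_tr)
  p[aidx(1L, 0L)] <- 1
  p_tka <- 0
  out <- numeric(n_cycles + 1L)
  for (k in seq_len(n_cycles)) {
    p_tka <- p_tka + sum(p * a)
    p <- as.vector(p %*% K)
    out[k + 1L] <- p_tka
  }
  tibble::tibble(cycle = 0:n_cycles, p_tka = out)
}
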