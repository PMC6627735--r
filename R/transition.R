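#' Health states of the post-transplant Markov model
#'
#' The annual-cycle model tracks each transplanted patient through four
#' states: `NI` (no issue, the initial state right after surgery), `R`
#' (meniscal repair, a minor intervention), `RO` (reoperation for a
#' postoperative condition such as arthrofibrosis) and `TKA` (total knee
#' arthroplasty, the most severe outcome). `R` and `RO` are the
#' "intermediate" states; `TKA` is absorbing. In the traditional paradigm a
#' fifth, pre-transplant situation exists (waiting in the allograft queue),
#' represented by queue dispositions rather than a Markov state.
#'
#' @format A character vector of the four state labels in canonical order.
#' @export
health_states <- c("NI", "R", "RO", "TKA")

# row-stochasticity tolerance applied on construction
.row_sum_tol <- 1e-9

#' Construct and validate an annual transition matrix
#'
#' Builds a 4x4 row-stochastic transition kernel over the states
#' `NI, R, RO, TKA` (in that fixed order). The TKA row must be the
#' absorbing row `(0, 0, 0, 1)`.
#'
#' @param x A 4x4 numeric matrix of transition probabilities, rows = "from"
#'   state, columns = "to" state, in the order `NI, R, RO, TKA`.
#' @return The validated matrix with state dimnames and class
#'   `"transition_matrix"`.
#' @export
#' @examples
#' transition_matrix(traditional_transition_matrix())
transition_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || !all(dim(x) == c(4L, 4L))) {
    rlang::abort("a transition matrix must be a numeric 4x4 matrix")
  }
  if (any(x < 0) || any(x > 1)) {
    rlang::abort("transition probabilities must lie in [0, 1]")
  }
  if (any(abs(rowSums(x) - 1) > .row_sum_tol)) {
    rlang::abort("every row of a transition matrix must sum to 1")
  }
  if (!isTRUE(all.equal(unname(x[4L, ]), c(0, 0, 0, 1), tolerance = .row_sum_tol))) {
    rlang::abort("the TKA row must be absorbing: (0, 0, 0, 1)")
  }
  dimnames(x) <- list(from = health_states, to = health_states)
  class(x) <- c("transition_matrix", class(x))
  x
}

#' Annual transition matrix of traditional meniscus transplantation
#'
#' The probabilities used in the simulation of the traditional paradigm:
#' from `NI` a patient stays in `NI` with probability 0.82 and moves to
#' `R`/`RO`/`TKA` with probabilities 0.04/0.12/0.02; a repair succeeds
#' (returns to `NI`) with probability 0.80 and escalates to reoperation
#' with probability 0.20; a reoperation always succeeds; `TKA` is
#' absorbing.
#'
#' @return A `transition_matrix`.
#' @export
#' @examples
#' traditional_transition_matrix()
traditional_transition_matrix <- function() {
  transition_matrix(matrix(
    c(
      0.82, 0.04, 0.12, 0.02,
      0.80, 0.00, 0.20, 0.00,
      1.00, 0.00, 0.00, 0.00,
      0.00, 0.00, 0.00, 1.00
    ),
    nrow = 4L, byrow = TRUE
  ))
}

#' Scale the off-NI transition probabilities of a matrix
#'
#' Implant quality enters the model by scaling every transition into the
#' adverse states `R`, `RO` and `TKA` by a common positive factor, in every
#' non-absorbing row; the probability of returning to (or staying in) `NI`
#' is reset to the complement so each row still sums to 1. A factor of 1
#' returns the input unchanged; factors above 1 encode a worse implant,
#' below 1 a better one.
#'
#' @param base A `transition_matrix` to scale.
#' @param factor Positive scalar applied to the `R`, `RO` and `TKA` entries
#'   of the `NI`, `R` and `RO` rows.
#' @return The scaled `transition_matrix`.
#' @details A factor making any row's scaled off-NI mass exceed 1 is an
#'   error (the scenario would not define a probability distribution); it
#'   is never silently clipped.
#' @export
#' @examples
#' scale_transition_matrix(traditional_transition_matrix(), 1.5)
scale_transition_matrix <- function(base, factor) {
  base <- transition_matrix(unclass(base))
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) || factor <= 0) {
    rlang::abort("`factor` must be a single positive number")
  }
  out <- unclass(base)
  for (i in 1:3) {
    off <- out[i, 2:4] * factor
    mass <- sum(off)
    if (mass > 1 + .row_sum_tol) {
      rlang::abort(sprintf(
        "factor %.4f is infeasible: scaled off-NI mass %.4f in row %s exceeds 1",
        factor, mass, health_states[i]
      ))
    }
    out[i, 2:4] <- off
    out[i, 1L] <- 1 - min(mass, 1)
  }
  transition_matrix(out)
}

#' Combined quality factor of the three implant-quality aspects
#'
#' Implant quality is assessed along mechanical performance, shape fidelity
#' and biocompatibility; each aspect contributes a multiplicative factor on
#' the adverse transition probabilities, and their simultaneous effect is
#' the product of the three.
#'
#' @param mechanical,shape,biocompatibility Positive scale factors.
#' @return The product of the three factors.
#' @export
#' @examples
#' combined_factor(1.50, 0.95, 1.43) # worst case, ~2.0378
#' combined_factor(0.50, 0.90, 1.11) # best case, 0.4995
combined_factor <- function(mechanical, shape, biocompatibility) {
  f <- c(mechanical = mechanical, shape = shape, biocompatibility = biocompatibility)
  if (!is.numeric(f) || length(f) != 3L || any(is.na(f)) || any(f <= 0)) {
    rlang::abort("all three quality factors must be positive numbers")
  }
  unname(prod(f))
}

#' Implant-quality scenarios and their scaling factors
#'
#' The eight sensitivity scenarios vary one quality aspect at a time
#' (bad/good mechanical performance, shape fidelity, biocompatibility) or
#' combine all three; `original` leaves the traditional matrix unchanged
#' (an implant of allograft-equivalent quality).
#'
#' @return A tibble with columns `scenario`, `aspect`, `case` and `factor`.
#' @export
#' @examples
#' scenario_factors()
scenario_factors <- function() {
  tibble::tibble(
    scenario = c("original", paste0("s", 1:8)),
    aspect = c(
      "none", "mechanical", "mechanical", "shape", "shape",
      "biocompatibility", "biocompatibility", "combined", "combined"
    ),
    case = c("original", "bad", "good", "bad", "good", "bad", "good", "worst", "best"),
    factor = c(
      1.00,
      1.50, 0.50,
      0.95, 0.90,
      1.43, 1.11,
      combined_factor(1.50, 0.95, 1.43),
      combined_factor(0.50, 0.90, 1.11)
    )
  )
}

#' Transition matrix of a named implant-quality scenario
#'
#' @param scenario One of `"original"`, `"s1"` ... `"s8"` (see
#'   [scenario_factors()]), case-insensitive.
#' @param base The matrix to scale; defaults to the traditional one.
#' @return A `transition_matrix`.
#' @export
#' @examples
#' scenario_matrix("s5") # bad biocompatibility, factor 1.43
scenario_matrix <- function(scenario, base = traditional_transition_matrix()) {
  tab <- scenario_factors()
  id <- tolower(as.character(scenario))
  if (length(id) != 1L || !id %in% tab$scenario) {
    rlang::abort(sprintf(
      "unknown scenario '%s'; expected one of %s",
      paste(scenario, collapse = ","), paste(tab$scenario, collapse = ", ")
    ))
  }
  scale_transition_matrix(base, tab$factor[match(id, tab$scenario)])
}

#' Serialize a transition matrix to JSON
#'
#' Writes the plain representation `{"states": [...], "rows": [[...]]}`
#' with rows in the canonical `NI, R, RO, TKA` order.
#'
#' @param m A `transition_matrix`.
#' @return A JSON string.
#' @seealso [transition_from_json()]
#' @export
transition_to_json <- function(m) {
  m <- transition_matrix(unclass(m))
  jsonlite::toJSON(
    list(states = health_states, rows = unname(apply(unclass(m), 1L, c, simplify = FALSE))),
    auto_unbox = FALSE, digits = NA
  )
}

#' Deserialize a transition matrix from JSON
#'
#' @param json A JSON string or path to a JSON file produced by
#'   [transition_to_json()] (or hand-written in the same shape).
#' @return A `transition_matrix`.
#' @export
transition_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  if (!identical(as.character(obj$states), health_states)) {
    rlang::abort("serialized states must be NI, R, RO, TKA in order")
  }
  rows <- obj$rows
  if (is.list(rows)) rows <- do.call(rbind, rows)
  transition_matrix(rows)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Annual transition matrix (rows: from, cols: to)\n")
  print(round(unclass(x), 6))
  invisible(x)
}
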