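# Independent brute-force oracle: P(in TKA within `n_cycles` annual checks)
# by exhaustive enumeration of all state paths, applying the entry-cap rule
# (every transition into R or RO is an entry; entry cap + 1 becomes TKA).
# Deliberately recursive and unrelated to the package's augmented-kernel code.
brute_force_p_tka <- function(m, n_cycles, cap = 2) {
  m <- unclass(m)
  recur <- function(state, entries, depth) {
    if (depth == 0L) {
      return(0)
    }
    p <- 0
    for (dest in 1:4) {
      pr <- m[state, dest]
      if (pr == 0) next
      if (dest == 4L) {
        p <- p + pr
      } else if (dest %in% 2:3) {
        if (entries + 1L > cap) {
          p <- p + pr
        } else {
          p <- p + pr * recur(dest, entries + 1L, depth - 1L)
        }
      } else {
        p <- p + pr * recur(dest, entries, depth - 1L)
      }
    }
    p
  }
  recur(1L, 0L, n_cycles)
}

# a matrix that deterministically walks NI -> R -> RO -> (forced TKA)
deterministic_escalation_matrix <- function() {
  transition_matrix(matrix(
    c(
      0, 1, 0, 0,
      0, 0, 1, 0,
      0, 1, 0, 0,
      0, 0, 0, 1
    ),
    nrow = 4, byrow = TRUE
  ))
}

# a matrix where nothing ever happens after surgery
all_ni_matrix <- function() {
  transition_matrix(matrix(
    c(
      1, 0, 0, 0,
      1, 0, 0, 0,
      1, 0, 0, 0,
      0, 0, 0, 1
    ),
    nrow = 4, byrow = TRUE
  ))
}
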