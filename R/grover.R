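#' Grover diffusion operator
#'
#' Inversion about the average, `2|s><s| - I` with `|s>` the uniform state
#' over the register, up to a global phase.  Realized inside the H/X/CNOT/MCX
#' gate set as H on all qubits, X on all qubits, a multi-controlled Z
#' (H - MCX - H sandwich on the last qubit), X on all, H on all.  A width-1
#' register degenerates to H X (H X H) X H, i.e. minus Pauli-X, which is
#' `2|s><s| - I` up to phase.
#'
#' @param qubits Qubit indices of the diffused register.
#' @return A circuit fragment.
#' @export
build_diffuser <- function(qubits) {
  w <- length(qubits)
  stopifnot(w >= 1L)
  h_all <- lapply(qubits, function(q) gate("H", q))
  x_all <- lapply(qubits, function(q) gate("X", q))
  last <- qubits[w]
  phase <- if (w == 1L) {
    list(gate("H", last), gate("X", last), gate("H", last))
  } else {
    list(gate("H", last), gate("MCX", last, controls = qubits[-w]), gate("H", last))
  }
  c(h_all, x_all, phase, x_all, h_all)
}

#' Iteration schedules
#'
#' `outer_iterations()` gives the default outer Grover iteration count over S
#' text positions, `max(1, floor((pi/4) * sqrt(S)))`; the number of marked
#' positions is unknown at run time, so the schedule follows the standard
#' quarter-period count over the valid address space, clamped below at one.
#' `inner_iterations()` gives the inner loop count over m patterns,
#' `ceiling(pi * sqrt(m) / 4)`.  Both can be overridden per run via
#' [search_instance()].
#'
#' @param S Number of valid text positions, >= 1.
#' @return Integer iteration count, >= 1.
#' @examples
#' outer_iterations(3)   # 1
#' outer_iterations(64)  # 6
#' inner_iterations(16)  # 4
#' @export
outer_iterations <- function(S) {
  stopifnot(S >= 1)
  max(1L, as.integer(floor(pi / 4 * sqrt(S))))
}

#' @param m Number of patterns, >= 1.
#' @rdname outer_iterations
#' @export
inner_iterations <- function(m) {
  stopifnot(m >= 1)
  as.integer(ceiling(pi * sqrt(m) / 4))
}
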