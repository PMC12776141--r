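#' Phase-marking oracles
#'
#' Both matchers mark matching basis states by flipping their phase through
#' phase kickback: a multi-controlled X fires into a match qubit prepared in
#' `|->`, multiplying the satisfying branch by -1 while every register is
#' returned to its input state.
#'
#' `prepare_match_minus()` emits X then H, taking `|0>` to
#' `(|0> - |1>)/sqrt(2)`.
#'
#' @param match_qubit Qubit index of the match register.
#' @return A circuit fragment.
#' @export
prepare_match_minus <- function(match_qubit) {
  list(gate("X", match_qubit), gate("H", match_qubit))
}

#' Enumerate-m oracle
#'
#' For each pattern in turn: X on the data qubits where the encoded pattern
#' bit is 0, an MCX with all data qubits as controls and the match qubit as
#' target, then the X layer again.  With the match qubit in `|->` the net
#' effect is a -1 phase on any data word equal to an encoded pattern and
#' identity elsewhere; the data register is restored after every pattern.
#'
#' Duplicate patterns are rejected: marking the same word twice cancels the
#' phase and silently unmarks a true match.  When a pattern encodes to the
#' all-zero word (all-A) it collides with the word loaded by QRAM padding
#' states; pass the validity-flag qubit from [build_validity_flag()] as
#' `validity` to restrict that pattern's mark to valid addresses.
#'
#' @param patterns Character vector of distinct, equal-length k-mers.
#' @param data Qubit indices of the data register, width 2L.
#' @param match_qubit Match qubit index.
#' @param validity Optional validity-flag qubit added as a control for
#'   all-zero-encoding patterns.
#' @return A circuit fragment.
#' @export
build_enumerate_oracle <- function(patterns, data, match_qubit, validity = NULL) {
  m <- length(patterns)
  stopifnot(m >= 1L)
  patterns <- toupper(patterns)
  if (anyDuplicated(patterns)) {
    stop("duplicate patterns are rejected: a repeated mark cancels its own phase",
         call. = FALSE)
  }
  lens <- nchar(patterns)
  if (length(unique(lens)) != 1L) {
    stop("all patterns must have equal length", call. = FALSE)
  }
  stopifnot(length(data) == 2L * lens[1])
  ops <- list()
  for (p in patterns) {
    bits <- encode_kmer(p)
    zeros <- data[bits == 0L]
    conj <- lapply(zeros, function(q) gate("X", q))
    ctl <- data
    if (all(bits == 0L) && !is.null(validity)) ctl <- c(ctl, validity)
    ops <- c(ops, conj, list(gate("MCX", match_qubit, controls = ctl)), rev(conj))
  }
  ops
}

#' Bitwise-equality oracle
#'
#' Compares the data and pattern registers position by position.  For each
#' bit k: CNOT(data_k -> anc_k), CNOT(pattern_k -> anc_k), X(anc_k), turning
#' each ancilla into the XNOR of the two bits; an MCX over all 2L ancillas
#' (plus any validity controls) then fires into the match qubit, and the
#' XNOR layer is uncomputed so the ancillas end at `|0...0>`.  Net effect:
#' a -1 phase exactly when the two registers hold equal bit strings.
#'
#' @param L Pattern length; registers below must have width 2L.
#' @param data,pattern_data Qubit indices of the two compared registers.
#' @param ancilla Qubit indices of the equality ancillas, width 2L,
#'   initialized `|0...0>`.
#' @param match_qubit Match qubit index.
#' @param validity Optional vector of validity-flag qubits added as controls
#'   (used when QRAM padding makes the all-zero word ambiguous).
#' @return A circuit fragment.
#' @export
build_equality_oracle <- function(L, data, pattern_data, ancilla, match_qubit,
                                  validity = NULL) {
  w <- 2L * as.integer(L)
  if (length(ancilla) != w) {
    stop(sprintf("equality ancilla register must have width 2L = %d", w),
         call. = FALSE)
  }
  stopifnot(length(data) == w, length(pattern_data) == w)
  xnor <- unlist(lapply(seq_len(w), function(k) {
    list(gate("CNOT", ancilla[k], controls = data[k]),
         gate("CNOT", ancilla[k], controls = pattern_data[k]),
         gate("X", ancilla[k]))
  }), recursive = FALSE)
  mark <- gate("MCX", match_qubit, controls = c(ancilla, validity))
  c(xnor, list(mark), rev(xnor))
}
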