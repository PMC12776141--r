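#' Closed-form qubit and gate accounting
#'
#' Reproduces the arithmetic resource accounting for either matcher at
#' arbitrary problem size, without building a circuit.  For a text of n
#' bases and patterns of length L under linear addressing there are
#' S = n - L + 1 window positions; the index register needs
#' `max(1, ceiling(log2(S)))` qubits and the data register 2L.  The
#' enumerate-m variant adds 3 overhead ancillas (phase inversion, match
#' indication, intermediate computation); the nested variant additionally
#' needs a pattern-ID register, a 2L pattern-data register and 2L equality
#' ancillas.  QRAM substring loading costs one multi-controlled block per
#' (position, base), i.e. `S * L` MCX blocks; since each base spans two data
#' qubits the per-qubit bound `2 * S * L` is reported as a secondary field.
#'
#' @param n Text length in bases.
#' @param m Number of patterns.
#' @param L Pattern length, `1 <= L <= n`.
#' @param variant `"enumerate_m"` or `"nested_grover"`.
#' @return A `resource_estimate` with the per-register widths, total qubit
#'   count and MCX load counts.
#' @examples
#' resource_estimate(1000, 10, 20)  # 981 positions, 53 qubits, 19620 MCX
#' @export
resource_estimate <- function(n, m, L, variant = c("enumerate_m", "nested_grover")) {
  variant <- match.arg(variant)
  stopifnot(m >= 1, n >= 1)
  if (L < 1 || L > n) stop("pattern length L must satisfy 1 <= L <= n", call. = FALSE)
  S <- n - L + 1
  index_qubits <- max(1L, as.integer(ceiling(log2(S))))
  data_qubits <- 2L * as.integer(L)
  overhead <- 3L
  est <- list(variant = variant, n = n, m = m, L = as.integer(L), S = S,
              index_qubits = index_qubits,
              data_qubits = data_qubits,
              overhead_ancillas = overhead,
              mcx_load = S * L,
              mcx_load_per_qubit = 2 * S * L)
  if (variant == "nested_grover") {
    est$pattern_id_qubits <- max(1L, as.integer(ceiling(log2(m))))
    est$pattern_data_qubits <- data_qubits
    est$equality_ancillas <- data_qubits
    est$total_qubits <- index_qubits + data_qubits + est$pattern_id_qubits +
      est$pattern_data_qubits + est$equality_ancillas + overhead
  } else {
    est$total_qubits <- index_qubits + data_qubits + overhead
  }
  structure(est, class = "resource_estimate")
}

#' @export
print.resource_estimate <- function(x, ...) {
  cat(sprintf("<resource_estimate: %s, n = %s, m = %s, L = %d>\n",
              x$variant, format(x$n, big.mark = ","),
              format(x$m, big.mark = ","), x$L))
  cat(sprintf("  positions S            %s\n", format(x$S, big.mark = ",")))
  cat(sprintf("  index register         %d qubits\n", x$index_qubits))
  cat(sprintf("  data register          %d qubits\n", x$data_qubits))
  if (x$variant == "nested_grover") {
    cat(sprintf("  pattern-ID register    %d qubits\n", x$pattern_id_qubits))
    cat(sprintf("  pattern-data register  %d qubits\n", x$pattern_data_qubits))
    cat(sprintf("  equality ancillas      %d qubits\n", x$equality_ancillas))
  }
  cat(sprintf("  overhead ancillas      %d qubits\n", x$overhead_ancillas))
  cat(sprintf("  total                  %d qubits\n", x$total_qubits))
  cat(sprintf("  QRAM load              %s MCX blocks (S x L); %s per-qubit bound\n",
              format(x$mcx_load, big.mark = ","),
              format(x$mcx_load_per_qubit, big.mark = ",")))
  invisible(x)
}

#' Quantum/classical crossover analysis
#'
#' Evaluates the gate-complexity comparison between the nested matcher,
#' O(sqrt(n) * L * sqrt(m)), the enumerate-m matcher, O(sqrt(n) * L * m),
#' and the classical linear bound O(n); a theoretical advantage for the
#' nested variant requires `sqrt(n) * L * sqrt(m) < n`.
#'
#' @inheritParams resource_estimate
#' @return A `crossover_report` with both quantum cost expressions, the
#'   classical cost, and the advantage flag.
#' @examples
#' crossover(1e8, 1e4, 20)$advantage  # TRUE: 2e7 < 1e8
#' @export
crossover <- function(n, m, L) {
  if (n <= 0 || m <= 0 || L <= 0) {
    stop("n, m and L must all be positive", call. = FALSE)
  }
  q_nested <- sqrt(n) * L * sqrt(m)
  q_enum <- sqrt(n) * L * m
  structure(list(n = n, m = m, L = L,
                 quantum_cost = q_nested,
                 quantum_cost_enumerate = q_enum,
                 classical_cost = n,
                 advantage = q_nested < n,
                 complexity = list(enumerate_m = "O(sqrt(n) * L * m)",
                                   nested_grover = "O(sqrt(n) * L * sqrt(m))",
                                   classical = "O(n + m)")),
            class = "crossover_report")
}

#' @export
print.crossover_report <- function(x, ...) {
  cat(sprintf("<crossover_report: n = %s, m = %s, L = %g>\n",
              format(x$n, big.mark = ",", scientific = FALSE),
              format(x$m, big.mark = ",", scientific = FALSE), x$L))
  cat(sprintf("  nested quantum cost    sqrt(n)*L*sqrt(m) = %s\n",
              format(x$quantum_cost, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  enumerate quantum cost sqrt(n)*L*m       = %s\n",
              format(x$quantum_cost_enumerate, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  classical cost         n                 = %s\n",
              format(x$classical_cost, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  quantum advantage (nested): %s\n",
              if (x$advantage) "yes" else "no"))
  invisible(x)
}
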