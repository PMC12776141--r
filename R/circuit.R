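#' Quantum registers and circuits
#'
#' A `quantum_circuit` is an ordered list of gate operations over a fixed set
#' of named registers.  Qubits are numbered globally from 0; each register
#' occupies a contiguous block and its qubit list is reported
#' most-significant-bit first, so the integer value of a register matches the
#' bit order used by [encode_kmer()].  The supported gate set is H, X, CNOT,
#' MCX and a final measurement, which is all the matcher circuits need.
#'
#' @param name Register name (unique within a circuit).
#' @param width Number of qubits, >= 1.
#' @param role One of `"address"`, `"data"`, `"pattern_id"`, `"pattern_data"`,
#'   `"equality_ancilla"`, `"match"`, `"work_ancilla"`.
#' @return `qregister()` returns a register description used by
#'   [quantum_circuit()].
#' @examples
#' circ <- quantum_circuit(qregister("address", 2, "address"),
#'                         qregister("match", 1, "match"))
#' circ <- append_gate(circ, gate("H", target = 0))
#' gate_census(circ)
#' @export
qregister <- function(name, width, role = "work_ancilla") {
  roles <- c("address", "data", "pattern_id", "pattern_data",
             "equality_ancilla", "match", "work_ancilla")
  stopifnot(is.character(name), nchar(name) > 0L)
  if (!role %in% roles) {
    stop(sprintf("unknown register role '%s'", role), call. = FALSE)
  }
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("register width must be >= 1", call. = FALSE)
  structure(list(name = name, width = width, role = role),
            class = "qregister")
}

#' @param ... For `quantum_circuit()`: registers created by `qregister()`.
#' @return `quantum_circuit()` returns an empty circuit over the given
#'   registers.
#' @rdname qregister
#' @export
quantum_circuit <- function(...) {
  regs <- list(...)
  if (length(regs) == 1L && is.list(regs[[1]]) && !inherits(regs[[1]], "qregister")) {
    regs <- regs[[1]]
  }
  stopifnot(length(regs) >= 1L, all(vapply(regs, inherits, TRUE, "qregister")))
  names(regs) <- vapply(regs, `[[`, "", "name")
  if (anyDuplicated(names(regs))) {
    stop("register names must be unique within a circuit", call. = FALSE)
  }
  offsets <- unname(cumsum(c(0L, vapply(regs, `[[`, 0L, "width"))))
  for (i in seq_along(regs)) regs[[i]]$offset <- offsets[i]
  structure(list(registers = regs,
                 width = offsets[length(offsets)],
                 ops = list()),
            class = "quantum_circuit")
}

#' Qubit indices of a named register
#'
#' Returns the global 0-based qubit indices of a register, most-significant
#' bit first.
#'
#' @param circ A [quantum_circuit()].
#' @param name Register name.
#' @return Integer vector of qubit indices.
#' @export
reg_qubits <- function(circ, name) {
  reg <- circ$registers[[name]]
  if (is.null(reg)) stop(sprintf("no register named '%s'", name), call. = FALSE)
  # global index q carries weight 2^q; the register's first listed qubit is
  # its MSB, so list the block in decreasing global order
  rev(reg$offset + seq_len(reg$width) - 1L)
}

#' Basis-state index from register values
#'
#' Maps named register values (unmentioned registers are 0) to the 0-based
#' index of the corresponding computational basis state.
#'
#' @param circ A [quantum_circuit()].
#' @param values Named list of integer register values.
#' @return 0-based basis index.
#' @export
basis_index <- function(circ, values) {
  idx <- 0
  for (nm in names(values)) {
    qs <- reg_qubits(circ, nm)
    bits <- value_bits(values[[nm]], length(qs))
    idx <- idx + sum(bits * 2^qs)
  }
  idx
}

#' Gate operations
#'
#' Constructs a single gate operation.  `H` and `X` take no controls, `CNOT`
#' exactly one, `MCX` at least one; `measure` records the qubits read out at
#' the end of the circuit.  Control and target sets must be disjoint.
#'
#' @param kind One of `"H"`, `"X"`, `"CNOT"`, `"MCX"`, `"measure"`.
#' @param target Target qubit index (0-based); for `measure`, the vector of
#'   measured qubits.
#' @param controls Integer vector of control qubit indices.
#' @return A gate operation usable with [append_gate()].
#' @export
gate <- function(kind, target, controls = integer()) {
  kinds <- c("H", "X", "CNOT", "MCX", "measure")
  if (!kind %in% kinds) stop(sprintf("unknown gate kind '%s'", kind), call. = FALSE)
  target <- as.integer(target)
  controls <- as.integer(controls)
  if (kind == "measure") {
    if (length(target) < 1L) stop("measure needs at least one qubit", call. = FALSE)
  } else {
    stopifnot(length(target) == 1L)
  }
  nctl <- length(controls)
  if (kind %in% c("H", "X", "measure") && nctl != 0L) {
    stop(sprintf("%s takes no controls", kind), call. = FALSE)
  }
  if (kind == "CNOT" && nctl != 1L) stop("CNOT takes exactly one control", call. = FALSE)
  if (kind == "MCX" && nctl < 1L) stop("MCX needs at least one control", call. = FALSE)
  if (anyDuplicated(controls) || any(controls %in% target)) {
    stop("control and target qubits must be distinct", call. = FALSE)
  }
  structure(list(kind = kind, controls = controls, target = target),
            class = "quantum_gate")
}

#' Append a gate to a circuit
#'
#' Validates qubit indices against the circuit width and enforces that
#' measurements come last.
#'
#' @param circ A [quantum_circuit()].
#' @param op A gate from [gate()].
#' @return The circuit with the gate appended.
#' @export
append_gate <- function(circ, op) {
  stopifnot(inherits(circ, "quantum_circuit"), inherits(op, "quantum_gate"))
  qs <- c(op$controls, op$target)
  if (any(qs < 0L) || any(qs >= circ$width)) {
    stop(sprintf("qubit index out of range (circuit width %d)", circ$width),
         call. = FALSE)
  }
  n <- length(circ$ops)
  if (n > 0L && circ$ops[[n]]$kind == "measure" && op$kind != "measure") {
    stop("cannot append gates after measurement", call. = FALSE)
  }
  circ$ops[[n + 1L]] <- op
  circ
}

#' @param ops A list of gates (a circuit fragment).
#' @rdname append_gate
#' @export
append_fragment <- function(circ, ops) {
  for (op in ops) circ <- append_gate(circ, op)
  circ
}

#' Gate census of a circuit or fragment
#'
#' Counts gates by kind; MCX gates are additionally bucketed by their number
#' of controls.
#'
#' @param x A [quantum_circuit()] or a plain list of gates.
#' @param include_measure Count `measure` operations as well?
#' @return A list with `kinds` (named counts) and `mcx_by_controls`
#'   (named counts, names are control counts).
#' @export
gate_census <- function(x, include_measure = FALSE) {
  ops <- if (inherits(x, "quantum_circuit")) x$ops else x
  kinds <- vapply(ops, `[[`, "", "kind")
  if (!include_measure) {
    keep <- kinds != "measure"
    ops <- ops[keep]
    kinds <- kinds[keep]
  }
  mcx_ctl <- vapply(ops[kinds == "MCX"], function(op) length(op$controls), 0L)
  list(kinds = if (length(kinds)) table(kinds) else table(character()),
       mcx_by_controls = if (length(mcx_ctl)) table(mcx_ctl) else table(integer()))
}

#' Exact statevector simulation
#'
#' Applies every gate of the circuit (measurements excluded) to an initial
#' state by exact unitary evolution.  Basis index i has qubit q in state 1
#' iff bit q of i is set.
#'
#' @param circ A [quantum_circuit()] or list of gates together with `width`.
#' @param initial Either `NULL` (all-zeros state), a single 0-based basis
#'   index, or a full complex amplitude vector of length `2^width`.
#' @param width Total qubit count; taken from the circuit when omitted.
#' @param cap Refuse simulations above this many qubits
#'   (default `getOption("qkmer.qubit_cap", 24)`).
#' @return Complex amplitude vector of length `2^width`.
#' @export
simulate_statevector <- function(circ, initial = NULL, width = NULL,
                                 cap = getOption("qkmer.qubit_cap", 24L)) {
  if (inherits(circ, "quantum_circuit")) {
    ops <- circ$ops
    width <- circ$width
  } else {
    ops <- circ
    if (is.null(width)) stop("width is required for a bare fragment", call. = FALSE)
  }
  if (width > cap) {
    stop(sprintf(paste0("simulation refused: %d qubits exceed the simulator cap ",
                        "of %d (raise `cap` or options(qkmer.qubit_cap=))"),
                 width, cap), call. = FALSE)
  }
  n <- 2^width
  if (is.null(initial)) {
    state <- complex(n)
    state[1L] <- 1 + 0i
  } else if (length(initial) == 1L && !is.complex(initial)) {
    stopifnot(initial >= 0, initial < n)
    state <- complex(n)
    state[initial + 1L] <- 1 + 0i
  } else {
    stopifnot(length(initial) == n)
    state <- as.complex(initial)
  }
  cpp_apply_ops(state, lapply(ops, .encode_op))
}

#' @noRd
.encode_op <- function(op) {
  code <- switch(op$kind, H = 0L, X = 1L, CNOT = 1L, MCX = 1L, measure = 2L)
  c(code, op$target[1L], op$controls)
}

#' Sample measurement outcomes of a register
#'
#' Computes the exact marginal distribution of a register from a statevector
#' and draws multinomial shot counts under a fixed seed.
#'
#' @param state Complex amplitude vector of length `2^width`.
#' @param qubits Qubit indices of the measured register, MSB first (see
#'   [reg_qubits()]).
#' @param shots Number of trials, >= 1.
#' @param seed Integer seed; identical state + seed give identical counts.
#' @return A `measurement_histogram`: list with `counts` (named integer
#'   vector over all register values), `shots`, and `probabilities` (the
#'   exact marginal).
#' @export
sample_counts <- function(state, qubits, shots, seed) {
  stopifnot(shots >= 1)
  probs <- register_probabilities(state, qubits)
  counts <- with_seed(seed, as.integer(rmultinom(1L, shots, probs)))
  names(counts) <- names(probs)
  structure(list(counts = counts, shots = as.integer(shots),
                 probabilities = probs),
            class = "measurement_histogram")
}

#' Exact marginal distribution of a register
#'
#' @inheritParams sample_counts
#' @return Named numeric vector of probabilities over register values
#'   `0 .. 2^length(qubits) - 1`.
#' @export
register_probabilities <- function(state, qubits) {
  width <- as.integer(round(log2(length(state))))
  stopifnot(2^width == length(state))
  vals <- cpp_register_values(width, as.integer(qubits))
  p <- Mod(state)^2
  m <- 2^length(qubits)
  agg <- rowsum(p, vals)
  probs <- numeric(m)
  probs[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  names(probs) <- as.character(0:(m - 1L))
  probs
}

#' @export
print.quantum_circuit <- function(x, ...) {
  cat(sprintf("<quantum_circuit: %d qubits, %d ops>\n", x$width, length(x$ops)))
  for (r in x$registers) {
    cat(sprintf("  %-16s %2d qubit(s)  [%s]\n", r$name, r$width, r$role))
  }
  cen <- gate_census(x, include_measure = TRUE)
  cat("  gates:", paste(sprintf("%s=%d", names(cen$kinds), cen$kinds),
                        collapse = " "), "\n")
  invisible(x)
}

#' @export
print.measurement_histogram <- function(x, ...) {
  cat(sprintf("<measurement_histogram: %d shots>\n", x$shots))
  nz <- x$counts[x$counts > 0L]
  print(nz[order(-nz)])
  invisible(x)
}

#' Serialize a measurement histogram to JSON
#'
#' Writes `{"shots": int, "counts": {"<address>": int}}`.
#'
#' @param hist A `measurement_histogram`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
histogram_to_json <- function(hist, path = NULL) {
  obj <- list(shots = hist$shots, counts = as.list(hist$counts))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
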