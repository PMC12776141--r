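# Independent oracles used to cross-check the gate-level implementation.
# None of these touch the circuit builders or the C++ simulator.

# Closed-form Grover recursion on N basis states with a marked set:
# phase flip then inversion about the average, repeated R times.
grover_probs <- function(N, marked, R) {
  x <- rep(1 / sqrt(N), N)
  for (r in seq_len(R)) {
    x[marked + 1L] <- -x[marked + 1L]
    x <- 2 * mean(x) - x
  }
  x^2
}

# Abstract amplitude model of the nested search over the padded
# (address, pattern-id) product space.  Valid because the data, pattern and
# equality registers are exactly uncomputed by construction, so the joint
# state stays supported on those registers' zero words between rounds.
nested_abstract_probs <- function(match, R, r) {
  Na <- nrow(match); Np <- ncol(match)
  A <- matrix(1 / sqrt(Na * Np), Na, Np)
  for (o in seq_len(R)) {
    for (k in seq_len(r)) {
      A[match] <- -A[match]
      A <- t(apply(A, 1L, function(row) 2 * mean(row) - row))
    }
    A <- apply(A, 2L, function(col) 2 * mean(col) - col)
  }
  rowSums(A^2)
}

# Padded match matrix for a nested instance: rows are address basis states
# (padding rows match nothing), columns pattern-id basis states.
nested_match_matrix <- function(text, patterns, addressing = "cyclic") {
  spec <- qram_spec(text, nchar(patterns[1]), addressing)
  Na <- 2^spec$address_width
  Np <- 2^max(1L, ceiling(log2(length(patterns))))
  M <- matrix(FALSE, Na, Np)
  for (i in 0:(spec$S - 1L)) {
    sub <- substring_at(spec, i)
    j <- match(sub, patterns)
    if (!is.na(j)) M[i + 1L, j] <- TRUE
  }
  M
}

# Addresses whose phase is flipped by load -> enumerate oracle -> unload,
# read off the exact statevector before/after on the uniform address
# superposition with the match qubit in |->.
flip_set_enumerate <- function(text, patterns, addressing = "linear") {
  L <- nchar(patterns[1])
  spec <- qram_spec(text, L, addressing)
  pad <- 2^spec$address_width - spec$S
  all_a <- any(vapply(patterns, function(p) all(encode_kmer(p) == 0L), TRUE))
  guard <- pad > 0L && all_a
  regs <- list(qregister("address", spec$address_width, "address"),
               qregister("data", 2L * L, "data"),
               qregister("match", 1L, "match"))
  if (guard) regs <- c(regs, list(qregister("validity", 1L)))
  circ <- quantum_circuit(regs)
  addr <- reg_qubits(circ, "address")
  data <- reg_qubits(circ, "data")
  mq <- reg_qubits(circ, "match")
  val <- if (guard) reg_qubits(circ, "validity") else NULL

  prep <- c(lapply(addr, function(q) gate("H", q)), prepare_match_minus(mq))
  vflag <- if (guard) build_validity_flag(spec$S, addr, val) else list()
  body <- c(build_load(spec, addr, data), vflag,
            build_enumerate_oracle(patterns, data, mq, validity = val),
            rev(vflag), build_unload(spec, addr, data))
  before <- simulate_statevector(append_fragment(circ, prep))
  after <- simulate_statevector(append_fragment(append_fragment(circ, prep), body))
  flipped <- integer(0)
  for (i in 0:(2^spec$address_width - 1L)) {
    idx <- basis_index(circ, list(address = i)) + 1L
    if (Re(after[idx] / before[idx]) < 0) flipped <- c(flipped, i)
  }
  flipped
}

# Sign pattern of the equality oracle over every (data, pattern) basis pair,
# obtained from one simulation on the full product superposition.
# Returns a logical matrix flipped[d + 1, p + 1].
flip_pairs_equality <- function(L) {
  w <- 2L * L
  circ <- quantum_circuit(qregister("data", w, "data"),
                          qregister("pattern_data", w, "pattern_data"),
                          qregister("equality", w, "equality_ancilla"),
                          qregister("match", 1L, "match"))
  data <- reg_qubits(circ, "data")
  pdata <- reg_qubits(circ, "pattern_data")
  anc <- reg_qubits(circ, "equality")
  mq <- reg_qubits(circ, "match")
  prep <- c(lapply(c(data, pdata), function(q) gate("H", q)),
            prepare_match_minus(mq))
  oracle <- build_equality_oracle(L, data, pdata, anc, mq)
  before <- simulate_statevector(append_fragment(circ, prep))
  after <- simulate_statevector(append_fragment(append_fragment(circ, prep), oracle))
  n <- 2^w
  flipped <- matrix(NA, n, n)
  for (d in 0:(n - 1L)) {
    for (p in 0:(n - 1L)) {
      idx <- basis_index(circ, list(data = d, pattern_data = p)) + 1L
      flipped[d + 1L, p + 1L] <- Re(after[idx] / before[idx]) < 0
    }
  }
  flipped
}

# Integer value of an MSB-first bit vector.
bits_value_test <- function(bits) sum(bits * 2^(rev(seq_along(bits)) - 1L))

# All strings of length `len` over an alphabet.
all_strings <- function(len, alphabet) {
  if (len == 0L) return("")
  grids <- do.call(expand.grid, rep(list(alphabet), len))
  apply(grids, 1L, paste, collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
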