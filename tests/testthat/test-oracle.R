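test_that("the match qubit preparation gives (|0> - |1>)/sqrt(2)", {
  circ <- quantum_circuit(qregister("match", 1L, "match"))
  out <- simulate_statevector(append_fragment(circ, prepare_match_minus(0L)))
  expect_equal(out, complex(real = c(1, -1)) / sqrt(2), tolerance = 1e-12)
  # fragment followed by its reversal restores |0>
  frag <- prepare_match_minus(0L)
  back <- simulate_statevector(c(frag, rev(frag)), width = 1L)
  expect_equal(Mod(back[1]), 1, tolerance = 1e-12)
})

enum_sign <- function(pattern_set, data_word) {
  # phase acquired by a data basis word under the enumerate oracle
  L <- nchar(pattern_set[1])
  circ <- quantum_circuit(qregister("data", 2L * L, "data"),
                          qregister("match", 1L, "match"))
  data <- reg_qubits(circ, "data")
  mq <- reg_qubits(circ, "match")
  prep <- prepare_match_minus(mq)
  oracle <- build_enumerate_oracle(pattern_set, data, mq)
  init <- basis_index(circ, list(data = bits_value_test(encode_kmer(data_word))))
  before <- simulate_statevector(append_fragment(circ, prep), initial = init)
  after <- simulate_statevector(append_fragment(append_fragment(circ, prep), oracle),
                                initial = init)
  # the data register must be unchanged; only the sign may differ
  expect_equal(Mod(after), Mod(before), tolerance = 1e-12)
  sign(Re(sum(Conj(before) * after)))
}

test_that("the enumerate oracle flips exactly the encoded patterns", {
  expect_equal(enum_sign("GT", "GT"), -1)
  expect_equal(enum_sign("GT", "AC"), 1)
  expect_equal(enum_sign(c("AC", "CG", "GT"), "CG"), -1)
  expect_equal(enum_sign(c("AC", "CG", "GT"), "TT"), 1)
})

test_that("duplicate patterns are rejected at construction", {
  circ <- quantum_circuit(qregister("data", 4L, "data"),
                          qregister("match", 1L, "match"))
  expect_error(build_enumerate_oracle(c("AC", "AC"), reg_qubits(circ, "data"),
                                      reg_qubits(circ, "match")),
               "duplicate")
})

test_that("equality oracle flips iff the registers hold equal words", {
  flipped <- flip_pairs_equality(1L)  # exhaustive over all 16 (data, pattern) pairs
  for (d in 0:3) for (p in 0:3) {
    expect_identical(flipped[d + 1L, p + 1L], d == p)
  }
  # spot checks at L = 3 on basis states, including the smallest all-equal case
  w <- 6L
  circ <- quantum_circuit(qregister("data", w, "data"),
                          qregister("pattern_data", w, "pattern_data"),
                          qregister("equality", w, "equality_ancilla"),
                          qregister("match", 1L, "match"))
  data <- reg_qubits(circ, "data"); pd <- reg_qubits(circ, "pattern_data")
  anc <- reg_qubits(circ, "equality"); mq <- reg_qubits(circ, "match")
  oracle <- build_equality_oracle(3L, data, pd, anc, mq)
  sign_of <- function(dw, pw) {
    init <- basis_index(circ, list(data = bits_value_test(encode_kmer(dw)),
                                   pattern_data = bits_value_test(encode_kmer(pw))))
    prep <- prepare_match_minus(mq)
    before <- simulate_statevector(append_fragment(circ, prep), initial = init)
    after <- simulate_statevector(append_fragment(append_fragment(circ, prep), oracle),
                                  initial = init)
    # ancillas restored: all support stays on the equality = 0 subspace
    vals <- register_probabilities(after, anc)
    expect_equal(unname(vals[["0"]]), 1, tolerance = 1e-9)
    sign(Re(sum(Conj(before) * after)))
  }
  expect_equal(sign_of("GTA", "GTA"), -1)
  expect_equal(sign_of("GTA", "TAC"), 1)
  expect_error(build_equality_oracle(3L, data, pd, anc[1:4], mq), "2L")
})

test_that("an all-A pattern with padding is guarded against false matches", {
  # n = 5, L = 2: S = 4 on a width-2 register plus... use n = 6 so padding exists
  text <- "CGCGCG"  # no AA substring; pattern AA must match nowhere
  flips <- flip_set_enumerate(text, "AA")
  expect_identical(flips, integer(0))
  # and a genuine all-A match is still marked
  flips2 <- flip_set_enumerate("CAACG", "AA")
  expect_identical(flips2, match_naive("CAACG", "AA")$positions)
})

test_that("load -> oracle -> unload leaves data unentangled and zeroed", {
  spec <- qram_spec("ACGTAC", 2L)
  circ <- quantum_circuit(qregister("address", spec$address_width, "address"),
                          qregister("data", 4L, "data"),
                          qregister("match", 1L, "match"))
  addr <- reg_qubits(circ, "address"); data <- reg_qubits(circ, "data")
  mq <- reg_qubits(circ, "match")
  circ <- append_fragment(circ, c(lapply(addr, function(q) gate("H", q)),
                                  prepare_match_minus(mq)))
  circ <- append_fragment(circ, build_load(spec, addr, data))
  circ <- append_fragment(circ, build_enumerate_oracle(c("CG", "TA"), data, mq))
  circ <- append_fragment(circ, build_unload(spec, addr, data))
  state <- simulate_statevector(circ)
  data_marginal <- register_probabilities(state, data)
  expect_equal(unname(data_marginal[["0"]]), 1, tolerance = 1e-9)
})
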