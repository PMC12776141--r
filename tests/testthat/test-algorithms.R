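test_that("the 4-base toy instance has S = 3 positions and a one-round schedule", {
  inst <- search_instance("ACGT", c("AC", "CG", "GT"), "enumerate_m")
  expect_identical(inst$qram$S, 3L)
  expect_identical(inst$qram$address_width, 2L)
  expect_identical(inst$schedule$outer_R, 1L)
})

test_that("enumerate-m reproduces the closed-form Grover distribution exactly", {
  # With 3 of 4 basis addresses marked (the padding state is unmarked) one
  # round drives all probability onto the unmarked padded address: the
  # majority-marked regime of amplitude amplification.
  rep1 <- run_search(search_instance("ACGT", c("AC", "CG", "GT"), "enumerate_m"))
  expect_equal(unname(rep1$address_probs),
               grover_probs(4, marked = c(0L, 1L, 2L), R = 1L), tolerance = 1e-9)
  expect_equal(unname(rep1$address_probs[["3"]]), 1, tolerance = 1e-9)
  # A single sparse pattern is amplified onto its true position exactly.
  rep2 <- run_search(search_instance("ACGT", "AC", "enumerate_m"))
  expect_identical(rep2$predicted, 0L)
  expect_equal(unname(rep2$address_probs[["0"]]), 1, tolerance = 1e-9)
  expect_equal(unname(rep2$address_probs),
               grover_probs(4, marked = 0L, R = 1L), tolerance = 1e-9)
})

test_that("with no occurring pattern the final distribution is exactly uniform", {
  rep <- run_search(search_instance("AAAA", "GT", "enumerate_m"))
  expect_false(rep$amplified)
  expect_equal(unname(rep$address_probs), rep(0.25, 4), tolerance = 1e-9)
})

test_that("enumerate-m matches the closed-form recursion on random sparse instances", {
  set.seed(99)
  tried <- 0L
  while (tried < 12L) {
    n <- sample(4:8, 1L)
    L <- sample(1:3, 1L)
    if (L > n) next
    m <- sample(1:3, 1L)
    pats <- unique(vapply(1:m, function(i) random_dna(L), ""))
    text <- random_dna(n)
    inst <- search_instance(text, pats, "enumerate_m")
    N <- 2^inst$qram$address_width
    marked <- match_naive(text, pats)$positions
    if (length(marked) >= N / 3) next  # sparse regime only (see vignette)
    tried <- tried + 1L
    rep <- run_search(inst)
    expect_equal(unname(rep$address_probs),
                 grover_probs(N, marked, inst$schedule$outer_R), tolerance = 1e-9)
    # soundness: every amplified address is a true classical match
    over <- as.integer(names(rep$address_probs))[rep$address_probs > 1.5 / N]
    expect_true(all(over %in% marked))
  }
})

test_that("nested search agrees with the abstract amplitude model", {
  set.seed(17)
  cases <- list(
    list(text = "ACGTAC", pats = c("G", "T"), R = 1L, r = 1L),
    list(text = "ACGTAC", pats = c("G", "T"), R = 2L, r = 2L),
    list(text = "ACGT", pats = c("A", "C", "G"), R = 1L, r = 2L),
    list(text = "CCGTACG", pats = c("TA", "CG"), R = 1L, r = 1L))
  for (cs in cases) {
    inst <- search_instance(cs$text, cs$pats, "nested_grover",
                            outer_iters = cs$R, inner_iters = cs$r)
    rep <- run_search(inst)
    M <- nested_match_matrix(cs$text, cs$pats)
    expect_equal(unname(rep$address_probs),
                 nested_abstract_probs(M, cs$R, cs$r), tolerance = 1e-9)
  }
})

test_that("the nested toy run pinpoints the cyclic motif positions exactly", {
  inst <- search_instance("ACGTACGT", c("GTA", "TAC"), "nested_grover",
                          outer_iters = 1L, inner_iters = 1L)
  rep <- run_search(inst)
  expect_identical(sort(rep$predicted), c(2L, 3L, 6L, 7L))
  expect_equal(unname(rep$address_probs[c("2", "3", "6", "7")]),
               rep(0.25, 4), tolerance = 1e-9)
  expect_equal(sum(rep$address_probs[c("0", "1", "4", "5")]), 0,
               tolerance = 1e-9)
  expect_true(all(rep$agreement))
})

test_that("default printed-formula schedules leave the dense toy uniform", {
  # Documented degeneracy: with the default schedule (r = 2 for m = 2) the
  # inner loop collapses to a clean phase oracle, and 4 marked of 8 is the
  # degenerate half-marked Grover case, so no address is amplified.  The
  # abstract model shows it without a 23-qubit simulation.
  M <- nested_match_matrix("ACGTACGT", c("GTA", "TAC"))
  inst <- search_instance("ACGTACGT", c("GTA", "TAC"), "nested_grover")
  probs <- nested_abstract_probs(M, inst$schedule$outer_R, inst$schedule$inner_r)
  expect_equal(probs, rep(1 / 8, 8), tolerance = 1e-9)
})

test_that("reports are deterministic for a fixed instance and seed", {
  inst <- search_instance("ACGTACGT", c("GTA", "TAC"), "enumerate_m", seed = 5L)
  r1 <- run_search(inst)
  r2 <- run_search(inst)
  expect_identical(r1$histogram$counts, r2$histogram$counts)
  expect_identical(r1$predicted, r2$predicted)
})

test_that("register inventories follow the design tables", {
  enum <- build_circuit(search_instance("ACGT", c("AC", "CG", "GT"), "enumerate_m"))
  widths <- vapply(enum$registers, `[[`, 0L, "width")
  expect_identical(widths, c(address = 2L, data = 4L, match = 1L))
  nest <- build_circuit(search_instance("ACGTACGT", c("GTA", "TAC"), "nested_grover",
                                        outer_iters = 1L, inner_iters = 1L))
  widths2 <- vapply(nest$registers, `[[`, 0L, "width")
  expect_identical(widths2, c(address = 3L, pattern_id = 1L, data = 6L,
                              pattern_data = 6L, equality = 6L, match = 1L))
  expect_identical(nest$width, 23L)
})

test_that("instances over the simulator cap are refused with a resource message", {
  inst <- search_instance(strrep("ACGT", 20), c("ACGTACGTAC"), "nested_grover")
  expect_error(run_search(inst), "cap")
})
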