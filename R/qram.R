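#' QRAM specification for a DNA text
#'
#' Describes superposed access to the length-L windows of a text.  Linear
#' addressing exposes the S = n - L + 1 proper windows; cyclic addressing
#' wraps past the end of the text, so every one of the n positions starts a
#' valid window.  The address register needs `max(1, ceiling(log2(S)))`
#' qubits; basis states at or beyond S ("padding") load an all-zero data
#' word.
#'
#' @param text DNA string over `{A,C,G,T}` (case-insensitive).
#' @param L Window (k-mer) length, `1 <= L <= nchar(text)`.
#' @param addressing `"linear"` or `"cyclic"`.
#' @return A `qram_spec` with fields `text`, `n`, `L`, `addressing`, `S`,
#'   `address_width`.
#' @examples
#' spec <- qram_spec("ACGT", 2)
#' spec$S              # 3
#' substring_at(spec, 1)  # "CG"
#' @export
qram_spec <- function(text, L, addressing = c("linear", "cyclic")) {
  addressing <- match.arg(addressing)
  stopifnot(is.character(text), length(text) == 1L)
  text <- toupper(text)
  encode_kmer(text)  # validates the alphabet with a position diagnostic
  n <- nchar(text)
  L <- as.integer(L)
  if (L < 1L || L > n) stop("window length L must satisfy 1 <= L <= nchar(text)",
                            call. = FALSE)
  S <- if (addressing == "linear") n - L + 1L else n
  structure(list(text = text, n = n, L = L, addressing = addressing,
                 S = S, address_width = max(1L, as.integer(ceiling(log2(S))))),
            class = "qram_spec")
}

#' Window of the text at an address
#'
#' @param spec A [qram_spec()].
#' @param i 0-based address, `0 <= i < S`.
#' @return The length-L substring starting at `i` (with wraparound under
#'   cyclic addressing).
#' @export
substring_at <- function(spec, i) {
  stopifnot(inherits(spec, "qram_spec"))
  if (i < 0 || i >= spec$S) {
    stop(sprintf("address %d out of range [0, %d)", i, spec$S), call. = FALSE)
  }
  if (spec$addressing == "linear") {
    substr(spec$text, i + 1L, i + spec$L)
  } else {
    idx <- ((i + seq_len(spec$L) - 1L) %% spec$n) + 1L
    paste(strsplit(spec$text, "", fixed = TRUE)[[1]][idx], collapse = "")
  }
}

# One address-conditioned load block: X-conjugate the address qubits that are
# 0 in `value`, then MCX from the whole address register onto every target
# qubit whose bit is 1.
#' @noRd
.multiplex_block <- function(value, width, address, data, bits) {
  abits <- value_bits(value, width)
  conj <- lapply(address[abits == 0L], function(q) gate("X", q))
  loads <- lapply(data[bits == 1L], function(q) gate("MCX", q, controls = address))
  c(conj, loads, rev(conj))
}

#' Build the ideal-QRAM load circuit
#'
#' Emits an explicit address-multiplexed load: one address-conditioned block
#' per valid address writes the 2-bit encoding of its window into the data
#' register, implementing the ideal-QRAM map
#' `sum_i a_i |i>|0...0> -> sum_i a_i |i>|d_i>`.  Padding addresses (>= S)
#' leave the data register at all zeros.
#'
#' @param spec A [qram_spec()].
#' @param address Qubit indices of the address register (MSB first).
#' @param data Qubit indices of the data register, width `2 * L`.
#' @return A circuit fragment (list of gates) with attributes `load_blocks`
#'   (the per-(position, base) block count, `S * L`) and `mcx_count` (the
#'   exact number of emitted MCX gates, which depends on the text content).
#' @export
build_load <- function(spec, address, data) {
  stopifnot(inherits(spec, "qram_spec"),
            length(address) == spec$address_width,
            length(data) == 2L * spec$L)
  ops <- list()
  for (i in 0:(spec$S - 1L)) {
    bits <- encode_kmer(substring_at(spec, i))
    ops <- c(ops, .multiplex_block(i, spec$address_width, address, data, bits))
  }
  mcx <- sum(vapply(ops, function(op) op$kind == "MCX", TRUE))
  structure(ops,
            load_blocks = spec$S * spec$L,
            mcx_count = mcx,
            mcx_per_qubit_bound = 2L * spec$S * spec$L)
}

#' @return `build_unload()` returns the exact gate reversal of
#'   `build_load()`; load followed by unload is the identity.
#' @rdname build_load
#' @export
build_unload <- function(spec, address, data) {
  frag <- build_load(spec, address, data)
  structure(rev(frag),
            load_blocks = attr(frag, "load_blocks"),
            mcx_count = attr(frag, "mcx_count"))
}

#' Build the pattern-dictionary QRAM
#'
#' Loads `|j>|0...0> -> |j>|encode(pattern_j)>` for every pattern index
#' `j < m`; padding indices load all zeros.  The pattern-ID register has
#' `max(1, ceiling(log2(m)))` qubits.
#'
#' @param patterns Character vector of m equal-length k-mers.
#' @param id Qubit indices of the pattern-ID register (MSB first).
#' @param pattern_data Qubit indices of the pattern-data register, width 2L.
#' @return A circuit fragment; reverse it for the unload.
#' @export
build_pattern_qram <- function(patterns, id, pattern_data) {
  m <- length(patterns)
  stopifnot(m >= 1L)
  lens <- nchar(patterns)
  if (length(unique(lens)) != 1L) {
    stop("all patterns must have equal length", call. = FALSE)
  }
  width <- max(1L, ceiling(log2(m)))
  stopifnot(length(id) == width, length(pattern_data) == 2L * lens[1])
  ops <- list()
  for (j in 0:(m - 1L)) {
    bits <- encode_kmer(patterns[j + 1L])
    ops <- c(ops, .multiplex_block(j, width, id, pattern_data, bits))
  }
  ops
}

#' Address-validity flag circuit
#'
#' Flips an ancilla (assumed `|0>`) once for every padding basis state of a
#' register and then inverts it, leaving the ancilla `|1>` exactly on valid
#' basis states (`value < S`).  Reverse the fragment to uncompute.  Used to
#' guard match oracles against the all-zero data word that padding states
#' share with the encoding of an all-A k-mer.
#'
#' @param S Number of valid values.
#' @param register Qubit indices of the guarded register (MSB first).
#' @param ancilla Qubit index of the validity flag.
#' @return A circuit fragment.
#' @export
build_validity_flag <- function(S, register, ancilla) {
  width <- length(register)
  total <- 2^width
  stopifnot(S >= 1L, S <= total)
  ops <- list()
  if (S < total) {
    for (v in S:(total - 1L)) {
      abits <- value_bits(v, width)
      conj <- lapply(register[abits == 0L], function(q) gate("X", q))
      ops <- c(ops, conj, list(gate("MCX", ancilla, controls = register)), rev(conj))
    }
  }
  c(ops, list(gate("X", ancilla)))
}
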