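#' Two-bit nucleotide encoding
#'
#' Each DNA base maps to a fixed pair of bits: A = (0,0), C = (0,1),
#' G = (1,0), T = (1,1), so a k-mer of length L occupies exactly 2L qubits.
#' Within a base the printed pair is stored most-significant-first, and bases
#' are concatenated left to right in sequence order.  Input is
#' case-insensitive; ambiguity codes (N, IUPAC degenerate bases, gaps) are
#' rejected because the 2-bit code has no slot for them.
#'
#' @param base A single character in `A`, `C`, `G`, `T` (either case).
#' @return `encode_base()` returns an integer vector of two bits.
#' @examples
#' encode_base("A")      # 0 0
#' encode_kmer("GT")     # 1 0 1 1
#' decode_bits(c(1L, 1L))  # "T"
#' @export
encode_base <- function(base) {
  stopifnot(is.character(base), length(base) == 1L, nchar(base) == 1L)
  code <- .base_codes[[toupper(base)]]
  if (is.null(code)) {
    stop(sprintf("invalid nucleotide '%s': expected one of A, C, G, T", base),
         call. = FALSE)
  }
  code
}

.base_codes <- list(
  A = c(0L, 0L), C = c(0L, 1L), G = c(1L, 0L), T = c(1L, 1L)
)
.bits_to_base <- c("00" = "A", "01" = "C", "10" = "G", "11" = "T")

#' @param seq A DNA string over `{A,C,G,T}` (case-insensitive), length >= 1.
#' @return `encode_kmer()` returns an integer bit vector of length
#'   `2 * nchar(seq)`.
#' @rdname encode_base
#' @export
encode_kmer <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("cannot encode an empty sequence", call. = FALSE)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(.base_codes))
  if (length(bad) > 0L) {
    stop(sprintf("invalid nucleotide '%s' at position %d (alphabet is A/C/G/T)",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  unlist(lapply(chars, function(ch) .base_codes[[ch]]), use.names = FALSE)
}

#' @param bits An integer bit vector of even length, as produced by
#'   `encode_kmer()`.
#' @return `decode_bits()` returns the decoded DNA string.
#' @rdname encode_base
#' @export
decode_bits <- function(bits) {
  stopifnot(is.numeric(bits), all(bits %in% c(0, 1)))
  if (length(bits) == 0L || length(bits) %% 2L != 0L) {
    stop("bit vector length must be even and positive (2 bits per base)",
         call. = FALSE)
  }
  pairs <- matrix(as.integer(bits), nrow = 2L)
  keys <- paste0(pairs[1L, ], pairs[2L, ])
  paste(.bits_to_base[keys], collapse = "")
}
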