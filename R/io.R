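#' Read a DNA FASTA file
#'
#' Reads one sequence per record via Biostrings, uppercased and validated
#' against the strict A/C/G/T alphabet; ambiguity codes are rejected with
#' the offending record and position named.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercased sequence per record.
#' @export
read_dna_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  seqs <- toupper(as.character(set))
  for (k in seq_along(seqs)) {
    if (nchar(seqs[k]) == 0L) {
      stop(sprintf("empty record '%s' in %s", names(seqs)[k], path), call. = FALSE)
    }
    chars <- strsplit(seqs[k], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% c("A", "C", "G", "T"))
    if (length(bad) > 0L) {
      stop(sprintf("record '%s' in %s: invalid residue '%s' at position %d",
                   names(seqs)[k], path, chars[bad[1]], bad[1]), call. = FALSE)
    }
  }
  seqs
}

#' Read a pattern dictionary
#'
#' Accepts either a plain-text list (one k-mer per line, blank lines
#' ignored) or FASTA.  Patterns must be non-empty, of equal length,
#' distinct, and over A/C/G/T.
#'
#' @param path Path to the pattern file.
#' @return Character vector of uppercased patterns.
#' @export
read_patterns <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop(sprintf("no patterns in %s", path), call. = FALSE)
  pats <- if (startsWith(trimws(nonblank[1]), ">")) {
    unname(read_dna_fasta(path))
  } else {
    toupper(trimws(nonblank))
  }
  for (k in seq_along(pats)) encode_kmer(pats[k])  # alphabet check
  if (length(unique(nchar(pats))) != 1L) {
    stop(sprintf("patterns in %s have mixed lengths (%s); a fixed L is required",
                 path, paste(sort(unique(nchar(pats))), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(pats)) {
    stop(sprintf("duplicate pattern '%s' in %s", pats[anyDuplicated(pats)], path),
         call. = FALSE)
  }
  pats
}

#' Generate a random text with planted motifs
#'
#' Draws `m` distinct random patterns of length `L` and a uniform random
#' text of length `n`, then overwrites `planted` non-overlapping windows
#' with patterns (cycling through the dictionary) at recorded positions.
#' The text may additionally contain chance matches; the fixture records
#' only the planted ones, and every planted position is a true match by
#' construction.
#'
#' @param n Text length.
#' @param m Number of patterns.
#' @param L Pattern length.
#' @param planted Number of planted occurrences; `planted * L <= n`.
#' @param seed Integer seed; the fixture is reproducible.
#' @return A `fixture`: list with `text`, `patterns`, `planted`
#'   (data.frame of position and pattern) and `seed`.
#' @export
generate_fixture <- function(n, m, L, planted, seed) {
  stopifnot(n >= L, L >= 1, m >= 1, planted >= 0)
  if (planted * L > n) {
    stop(sprintf("cannot pack %d non-overlapping length-%d motifs into %d bases",
                 planted, L, n), call. = FALSE)
  }
  if (m > 4^L) stop("fewer than m distinct patterns of length L exist", call. = FALSE)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    pats <- character(0)
    while (length(pats) < m) {
      cand <- paste(sample(bases, L, replace = TRUE), collapse = "")
      if (!cand %in% pats) pats <- c(pats, cand)
    }
    text <- sample(bases, n, replace = TRUE)
    positions <- integer(0)
    used <- rep(FALSE, n)
    if (planted > 0L) {
      for (k in seq_len(planted)) {
        free <- which(!vapply(1:(n - L + 1L), function(s) any(used[s:(s + L - 1L)]), TRUE))
        if (length(free) == 0L) {
          stop("infeasible packing: no free slot left for a planted motif",
               call. = FALSE)
        }
        s <- if (length(free) == 1L) free else sample(free, 1L)
        pat <- pats[(k - 1L) %% m + 1L]
        text[s:(s + L - 1L)] <- strsplit(pat, "", fixed = TRUE)[[1]]
        used[s:(s + L - 1L)] <- TRUE
        positions <- c(positions, s - 1L)  # 0-based
      }
    }
    planted_df <- data.frame(
      position = positions,
      pattern = if (planted > 0L) pats[(seq_len(planted) - 1L) %% m + 1L] else character(0),
      stringsAsFactors = FALSE)
    planted_df <- planted_df[order(planted_df$position), , drop = FALSE]
    rownames(planted_df) <- NULL
    structure(list(text = paste(text, collapse = ""), patterns = pats,
                   planted = planted_df, seed = as.integer(seed)),
              class = "fixture")
  })
}

#' Write a fixture to disk
#'
#' @param fixture A [generate_fixture()] result.
#' @param fasta_path Output FASTA path for the text.
#' @param patterns_path Output path for the one-per-line pattern list.
#' @return The two paths, invisibly.
#' @export
write_fixture <- function(fixture, fasta_path, patterns_path) {
  stopifnot(inherits(fixture, "fixture"))
  writeLines(c(sprintf(">fixture_seed%d", fixture$seed), fixture$text), fasta_path)
  writeLines(fixture$patterns, patterns_path)
  invisible(c(fasta_path, patterns_path))
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf("<fixture: n = %d, m = %d, L = %d, seed = %d>\n",
              nchar(x$text), length(x$patterns), nchar(x$patterns[1]), x$seed))
  cat("  text    :", x$text, "\n")
  cat("  patterns:", paste(x$patterns, collapse = ", "), "\n")
  if (nrow(x$planted)) {
    cat("  planted :", paste(sprintf("%s@%d", x$planted$pattern, x$planted$position),
                             collapse = " "), "\n")
  } else cat("  planted : (none)\n")
  invisible(x)
}
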