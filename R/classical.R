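#' Classical multi-pattern matchers (ground truth)
#'
#' `match_naive()` is the brute-force scanner used as the correctness oracle
#' for every quantum result; `match_ac()` runs an Aho-Corasick automaton
#' built by `ac_automaton()` and is contractually identical to the naive
#' scan.  Positions are 0-based start indices; cyclic addressing scans the
#' text extended by its first L-1 characters and reports positions modulo n.
#'
#' @param text DNA string.
#' @param patterns Character vector of equal-length patterns.
#' @param addressing `"linear"` or `"cyclic"`.
#' @return A `match_set`: list with `positions` (sorted unique 0-based
#'   starts) and `per_pattern` (named list of positions per pattern).
#' @examples
#' match_naive("ACGT", c("AC", "CG", "GT"))$positions   # 0 1 2
#' @export
match_naive <- function(text, patterns, addressing = c("linear", "cyclic")) {
  addressing <- match.arg(addressing)
  text <- toupper(text)
  patterns <- toupper(patterns)
  lens <- nchar(patterns)
  if (length(unique(lens)) != 1L) {
    stop("all patterns must have equal length (quantum registers require fixed L)",
         call. = FALSE)
  }
  L <- lens[1]
  n <- nchar(text)
  S <- if (addressing == "linear") n - L + 1L else n
  scan_text <- if (addressing == "cyclic") paste0(text, substr(text, 1L, L - 1L)) else text
  per <- lapply(patterns, function(p) {
    hits <- integer()
    if (S >= 1L) {
      for (i in 0:(S - 1L)) {
        if (substr(scan_text, i + 1L, i + L) == p) hits <- c(hits, i)
      }
    }
    hits
  })
  names(per) <- patterns
  structure(list(positions = sort(unique(unlist(per, use.names = FALSE))),
                 per_pattern = per),
            class = "match_set")
}

#' @param patterns For `ac_automaton()`: non-empty patterns over A/C/G/T.
#' @return `ac_automaton()` returns the automaton: `goto` (state x base
#'   transition matrix), `fail` (failure links), `output` (list of pattern
#'   indices recognized at each state), `depth`.
#' @rdname match_naive
#' @export
ac_automaton <- function(patterns) {
  patterns <- toupper(patterns)
  stopifnot(length(patterns) >= 1L)
  if (any(nchar(patterns) == 0L)) stop("empty pattern rejected", call. = FALSE)
  alphabet <- c("A", "C", "G", "T")
  # trie: state 1 is the root; goto[state, base] = 0 means undefined
  n_states <- 1L
  goto <- matrix(0L, nrow = 1L + sum(nchar(patterns)), ncol = 4L,
                 dimnames = list(NULL, alphabet))
  output <- vector("list", nrow(goto))
  depth <- integer(nrow(goto))
  for (pi in seq_along(patterns)) {
    chars <- strsplit(patterns[pi], "", fixed = TRUE)[[1]]
    if (!all(chars %in% alphabet)) {
      stop(sprintf("pattern '%s' contains a non-ACGT symbol", patterns[pi]),
           call. = FALSE)
    }
    s <- 1L
    for (ch in chars) {
      nxt <- goto[s, ch]
      if (nxt == 0L) {
        n_states <- n_states + 1L
        goto[s, ch] <- n_states
        depth[n_states] <- depth[s] + 1L
        nxt <- n_states
      }
      s <- nxt
    }
    output[[s]] <- c(output[[s]], pi)
  }
  goto <- goto[seq_len(n_states), , drop = FALSE]
  output <- output[seq_len(n_states)]
  depth <- depth[seq_len(n_states)]
  # BFS failure links; root transitions on undefined symbols loop to root
  fail <- integer(n_states)
  fail[1L] <- 1L
  queue <- integer()
  for (ch in alphabet) {
    s <- goto[1L, ch]
    if (s == 0L) goto[1L, ch] <- 1L else { fail[s] <- 1L; queue <- c(queue, s) }
  }
  while (length(queue) > 0L) {
    s <- queue[1L]; queue <- queue[-1L]
    for (ch in alphabet) {
      t <- goto[s, ch]
      if (t == 0L) {
        goto[s, ch] <- goto[fail[s], ch]
      } else {
        fail[t] <- goto[fail[s], ch]
        # output[t] <- list(...) keeps NULL merges from deleting the element
        output[t] <- list(c(output[[t]], output[[fail[t]]]))
        queue <- c(queue, t)
      }
    }
  }
  structure(list(goto = goto, fail = fail, output = output, depth = depth,
                 patterns = patterns, n_states = n_states),
            class = "ac_automaton")
}

#' @param automaton An automaton from `ac_automaton()`.
#' @rdname match_naive
#' @export
match_ac <- function(automaton, text, addressing = c("linear", "cyclic")) {
  addressing <- match.arg(addressing)
  stopifnot(inherits(automaton, "ac_automaton"))
  text <- toupper(text)
  patterns <- automaton$patterns
  L <- nchar(patterns[1])
  n <- nchar(text)
  scan_text <- if (addressing == "cyclic") paste0(text, substr(text, 1L, L - 1L)) else text
  S <- if (addressing == "linear") n - L + 1L else n
  per <- stats::setNames(rep(list(integer()), length(patterns)), patterns)
  if (n > 0L && S >= 1L) {
    chars <- strsplit(scan_text, "", fixed = TRUE)[[1]]
    s <- 1L
    for (pos in seq_along(chars)) {
      ch <- chars[pos]
      if (!ch %in% colnames(automaton$goto)) {
        stop(sprintf("invalid nucleotide '%s' at position %d", ch, pos),
             call. = FALSE)
      }
      s <- automaton$goto[s, ch]
      for (pi in automaton$output[[s]]) {
        start <- pos - L  # 0-based
        if (start < S) per[[pi]] <- c(per[[pi]], start)
      }
    }
  }
  per <- lapply(per, function(v) sort(unique(v)))
  structure(list(positions = sort(unique(unlist(per, use.names = FALSE))),
                 per_pattern = per),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat("<match_set>\n  positions:",
      if (length(x$positions)) paste(x$positions, collapse = " ") else "(none)",
      "\n")
  for (p in names(x$per_pattern)) {
    cat(sprintf("  %s: %s\n", p,
                if (length(x$per_pattern[[p]])) paste(x$per_pattern[[p]], collapse = " ")
                else "(none)"))
  }
  invisible(x)
}
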