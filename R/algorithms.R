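#' Describe a quantum k-mer search run
#'
#' Bundles a text, a pattern dictionary, the algorithm variant, addressing
#' mode, shot count, seed and iteration schedule into a single instance that
#' [build_circuit()] and [run_search()] consume.
#'
#' Defaults follow the two matcher designs: `enumerate_m` addresses the text
#' linearly (S = n - L + 1 windows), `nested_grover` cyclically (S = n, with
#' wraparound windows).  The default schedule is [outer_iterations()] /
#' [inner_iterations()]; both counts can be overridden.
#'
#' @param text DNA string over `{A,C,G,T}`.
#' @param patterns Character vector of m distinct, equal-length k-mers.
#' @param variant `"enumerate_m"` or `"nested_grover"`.
#' @param addressing `"linear"` or `"cyclic"`; default depends on `variant`.
#' @param shots Number of measurement trials (default 1024).
#' @param seed Integer RNG seed for shot sampling.
#' @param outer_iters,inner_iters Optional overrides of the iteration
#'   schedule.
#' @return A `search_instance`.
#' @examples
#' inst <- search_instance("ACGT", c("AC", "CG", "GT"), "enumerate_m")
#' inst$qram$S              # 3
#' inst$schedule$outer_R    # 1
#' @export
search_instance <- function(text, patterns,
                            variant = c("enumerate_m", "nested_grover"),
                            addressing = NULL, shots = 1024L, seed = 1L,
                            outer_iters = NULL, inner_iters = NULL) {
  variant <- match.arg(variant)
  if (is.null(addressing)) {
    addressing <- if (variant == "nested_grover") "cyclic" else "linear"
  }
  addressing <- match.arg(addressing, c("linear", "cyclic"))
  patterns <- toupper(patterns)
  m <- length(patterns)
  stopifnot(m >= 1L, shots >= 1L)
  if (anyDuplicated(patterns)) stop("patterns must be distinct", call. = FALSE)
  lens <- nchar(patterns)
  if (length(unique(lens)) != 1L) {
    stop("all patterns must have equal length", call. = FALSE)
  }
  L <- lens[1]
  spec <- qram_spec(text, L, addressing)
  outer_R <- if (is.null(outer_iters)) outer_iterations(spec$S) else as.integer(outer_iters)
  inner_r <- if (is.null(inner_iters)) inner_iterations(m) else as.integer(inner_iters)
  stopifnot(outer_R >= 1L, inner_r >= 1L)
  structure(list(text = toupper(text), patterns = patterns, variant = variant,
                 addressing = addressing, qram = spec, m = m, L = L,
                 shots = as.integer(shots), seed = as.integer(seed),
                 schedule = list(outer_R = outer_R, inner_r = inner_r)),
            class = "search_instance")
}

# Guard requirements created by the collision between QRAM padding states
# (which load the all-zero data word) and the all-zero encoding of an all-A
# k-mer.  See the methods vignette.
#' @noRd
.guard_plan <- function(inst) {
  spec <- inst$qram
  pad_addr <- 2^spec$address_width - spec$S
  all_a <- vapply(inst$patterns, function(p) all(encode_kmer(p) == 0L), TRUE)
  if (inst$variant == "enumerate_m") {
    return(list(address = pad_addr > 0L && any(all_a), pattern = FALSE))
  }
  pid_width <- max(1L, ceiling(log2(inst$m)))
  pad_pid <- 2^pid_width - inst$m
  subs_all_a <- any(vapply(0:(spec$S - 1L), function(i) {
    all(encode_kmer(substring_at(spec, i)) == 0L)
  }, TRUE))
  list(address = pad_addr > 0L && (any(all_a) || pad_pid > 0L),
       pattern = pad_pid > 0L && subs_all_a)
}

#' Assemble the full matcher circuit
#'
#' Builds the complete gate-level circuit for a [search_instance()]:
#' uniform superposition over addresses (and pattern IDs for the nested
#' variant), match qubit in `|->`, then the scheduled compute-oracle-
#' uncompute-diffuse rounds, ending in a measurement of the address
#' register.
#'
#' @param inst A [search_instance()].
#' @return A [quantum_circuit()].
#' @export
build_circuit <- function(inst) {
  stopifnot(inherits(inst, "search_instance"))
  if (inst$variant == "enumerate_m") .build_enumerate_m(inst) else .build_nested_grover(inst)
}

#' @noRd
.build_enumerate_m <- function(inst) {
  spec <- inst$qram
  guard <- .guard_plan(inst)
  regs <- list(qregister("address", spec$address_width, "address"),
               qregister("data", 2L * inst$L, "data"),
               qregister("match", 1L, "match"))
  if (guard$address) regs <- c(regs, list(qregister("validity", 1L, "work_ancilla")))
  circ <- quantum_circuit(regs)
  addr <- reg_qubits(circ, "address")
  data <- reg_qubits(circ, "data")
  match <- reg_qubits(circ, "match")
  val <- if (guard$address) reg_qubits(circ, "validity") else NULL

  circ <- append_fragment(circ, lapply(addr, function(q) gate("H", q)))
  circ <- append_fragment(circ, prepare_match_minus(match))
  load <- build_load(spec, addr, data)
  oracle <- build_enumerate_oracle(inst$patterns, data, match, validity = val)
  vflag <- if (guard$address) build_validity_flag(spec$S, addr, val) else list()
  for (r in seq_len(inst$schedule$outer_R)) {
    circ <- append_fragment(circ, load)
    circ <- append_fragment(circ, vflag)
    circ <- append_fragment(circ, oracle)
    circ <- append_fragment(circ, rev(vflag))
    circ <- append_fragment(circ, rev(load))
    circ <- append_fragment(circ, build_diffuser(addr))
  }
  append_gate(circ, gate("measure", addr))
}

#' @noRd
.build_nested_grover <- function(inst) {
  spec <- inst$qram
  guard <- .guard_plan(inst)
  pid_width <- max(1L, ceiling(log2(inst$m)))
  regs <- list(qregister("address", spec$address_width, "address"),
               qregister("pattern_id", pid_width, "pattern_id"),
               qregister("data", 2L * inst$L, "data"),
               qregister("pattern_data", 2L * inst$L, "pattern_data"),
               qregister("equality", 2L * inst$L, "equality_ancilla"),
               qregister("match", 1L, "match"))
  if (guard$address) regs <- c(regs, list(qregister("addr_valid", 1L, "work_ancilla")))
  if (guard$pattern) regs <- c(regs, list(qregister("pid_valid", 1L, "work_ancilla")))
  circ <- quantum_circuit(regs)
  addr <- reg_qubits(circ, "address")
  pid <- reg_qubits(circ, "pattern_id")
  data <- reg_qubits(circ, "data")
  pdata <- reg_qubits(circ, "pattern_data")
  anc <- reg_qubits(circ, "equality")
  match <- reg_qubits(circ, "match")
  va <- if (guard$address) reg_qubits(circ, "addr_valid") else NULL
  vp <- if (guard$pattern) reg_qubits(circ, "pid_valid") else NULL

  circ <- append_fragment(circ, lapply(c(addr, pid), function(q) gate("H", q)))
  circ <- append_fragment(circ, prepare_match_minus(match))

  text_load <- build_load(spec, addr, data)
  pat_load <- build_pattern_qram(inst$patterns, pid, pdata)
  eq_oracle <- build_equality_oracle(inst$L, data, pdata, anc, match,
                                     validity = c(va, vp))
  va_flag <- if (guard$address) build_validity_flag(spec$S, addr, va) else list()
  vp_flag <- if (guard$pattern) build_validity_flag(inst$m, pid, vp) else list()

  for (r in seq_len(inst$schedule$outer_R)) {
    circ <- append_fragment(circ, text_load)
    circ <- append_fragment(circ, va_flag)
    for (k in seq_len(inst$schedule$inner_r)) {
      circ <- append_fragment(circ, pat_load)
      circ <- append_fragment(circ, vp_flag)
      circ <- append_fragment(circ, eq_oracle)
      circ <- append_fragment(circ, rev(vp_flag))
      circ <- append_fragment(circ, rev(pat_load))
      circ <- append_fragment(circ, build_diffuser(pid))
    }
    circ <- append_fragment(circ, rev(va_flag))
    circ <- append_fragment(circ, rev(text_load))
    circ <- append_fragment(circ, build_diffuser(addr))
  }
  append_gate(circ, gate("measure", addr))
}

#' Run a quantum k-mer search
#'
#' Builds the circuit, simulates it exactly, samples the address register,
#' and compares the outcome against the classical ground truth from
#' [match_naive()].
#'
#' An address is *predicted* when its frequency reaches
#' `threshold * shots / 2^address_width` (1.5x the uniform baseline by
#' default); predictions are ranked by frequency.  When no address clears
#' the threshold the report flags that no position was amplified.
#'
#' @param inst A [search_instance()].
#' @param threshold Amplification threshold relative to the uniform
#'   baseline.
#' @param cap Simulator qubit cap, passed to [simulate_statevector()].
#' @return A `match_report` with the histogram, exact address
#'   probabilities, predicted positions, classical positions and
#'   per-position agreement.
#' @examples
#' rep <- run_search(search_instance("ACGT", "AC", "enumerate_m"))
#' rep$predicted   # 0
#' @export
run_search <- function(inst, threshold = 1.5,
                       cap = getOption("qkmer.qubit_cap", 24L)) {
  circ <- build_circuit(inst)
  state <- simulate_statevector(circ, cap = cap)
  addr <- reg_qubits(circ, "address")
  hist <- sample_counts(state, addr, inst$shots, inst$seed)
  n_out <- 2^length(addr)
  cutoff <- threshold * inst$shots / n_out
  predicted <- as.integer(names(hist$counts))[hist$counts >= cutoff]
  predicted <- predicted[order(-hist$counts[as.character(predicted)])]
  classical <- match_naive(inst$text, inst$patterns, inst$addressing)
  agreement <- classical$positions %in% predicted
  names(agreement) <- classical$positions
  structure(list(instance = inst, circuit_width = circ$width,
                 histogram = hist,
                 address_probs = hist$probabilities,
                 predicted = predicted,
                 classical = classical$positions,
                 agreement = agreement,
                 amplified = length(predicted) > 0L,
                 threshold = threshold),
            class = "match_report")
}

#' @export
print.search_instance <- function(x, ...) {
  cat(sprintf("<search_instance: %s>\n", x$variant))
  cat(sprintf("  text    : %s (n = %d)\n", x$text, x$qram$n))
  cat(sprintf("  patterns: %s (m = %d, L = %d)\n",
              paste(x$patterns, collapse = ", "), x$m, x$L))
  cat(sprintf("  addressing %s, S = %d, address width %d\n",
              x$addressing, x$qram$S, x$qram$address_width))
  cat(sprintf("  schedule: outer R = %d, inner r = %d; shots = %d, seed = %d\n",
              x$schedule$outer_R, x$schedule$inner_r, x$shots, x$seed))
  invisible(x)
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report: %s on '%s'>\n", x$instance$variant, x$instance$text))
  cat(sprintf("  circuit width %d qubits; %d shots\n",
              x$circuit_width, x$histogram$shots))
  cat("  classical match positions:",
      if (length(x$classical)) paste(x$classical, collapse = " ") else "(none)", "\n")
  if (x$amplified) {
    cat("  predicted (ranked):", paste(x$predicted, collapse = " "), "\n")
    cat(sprintf("  agreement: %d/%d classical positions recovered\n",
                sum(x$agreement), length(x$agreement)))
  } else {
    cat("  no amplified position (distribution is consistent with uniform)\n")
  }
  invisible(x)
}

#' @export
#' @importFrom graphics barplot legend abline
plot.match_report <- function(x, ...) {
  counts <- x$histogram$counts
  is_match <- as.integer(names(counts)) %in% x$classical
  barplot(counts, col = ifelse(is_match, "firebrick", "grey70"),
          xlab = "start position (address)", ylab = "frequency",
          main = sprintf("%s, %d shots", x$instance$variant, x$histogram$shots),
          ...)
  abline(h = x$threshold * x$histogram$shots / length(counts), lty = 2)
  legend("topright", fill = c("firebrick", "grey70"), bty = "n",
         legend = c("classical match", "non-match"))
  invisible(x)
}

#' Serialize a match report to JSON
#'
#' @param report A `match_report`.
#' @param path Optional output path.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  inst <- report$instance
  obj <- list(
    variant = inst$variant, text = inst$text, patterns = inst$patterns,
    addressing = inst$addressing, n = inst$qram$n, L = inst$L, m = inst$m,
    S = inst$qram$S,
    schedule = inst$schedule,
    shots = report$histogram$shots, seed = inst$seed,
    counts = as.list(report$histogram$counts),
    predicted = report$predicted,
    classical = report$classical,
    agreement = as.list(report$agreement),
    amplified = report$amplified)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
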