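Package: qkmer
Title: Quantum Multi-Pattern k-mer Matching on Simulated Gate-Level Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and exactly simulates gate-level quantum circuits for
    multi-pattern DNA k-mer search based on Grover amplitude amplification
    with an ideal quantum random access memory (QRAM) realised as an explicit
    address-multiplexed load circuit. Two search variants are provided: an
    enumerate-m matcher whose oracle tests the loaded substring against every
    pattern in turn, and a nested search that runs an inner Grover loop over
    the pattern dictionary inside each outer iteration over text positions.
    Includes a 2-bit nucleotide encoding, a statevector simulator with shot
    sampling, closed-form qubit and multi-controlled-X resource accounting
    with a quantum/classical crossover analysis, a classical Aho-Corasick and
    naive reference matcher used as ground truth, FASTA/pattern-list input,
    a reproducible fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    graphics,
    grDevices,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
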