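---
title: "Quantum multi-pattern k-mer search: models, schedules, and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum multi-pattern k-mer search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qkmer)
```

## The problem and the two circuit families

Given a DNA text of $n$ bases and a dictionary of $m$ distinct k-mers of a
common length $L$, we want every start position whose window equals a
dictionary entry. `qkmer` builds two Grover-style matchers as explicit
gate-level circuits over the gate set {H, X, CNOT, MCX} and simulates them
exactly, so that every claim about their behaviour is checkable against
closed-form amplitude algebra and a classical reference matcher
(`match_naive()`, cross-validated by an Aho–Corasick automaton).

Both circuits share the same skeleton:

1. a 2-bit-per-base encoding (A=00, C=01, G=10, T=11; MSB first within a
   base, bases concatenated in sequence order — the printed pairs never fix
   a wire order, so this is a package convention applied consistently);
2. an *address register* of $\max(1,\lceil\log_2 S\rceil)$ qubits in uniform
   superposition over the $S$ valid window positions ($S=n-L+1$ linear,
   $S=n$ cyclic);
3. an ideal-QRAM *load* — one address-conditioned multiplexer block per
   valid position, writing the encoded window into a $2L$-qubit data
   register ($\sum_i \alpha_i\lvert i\rangle\lvert 0\rangle \to
   \sum_i \alpha_i\lvert i\rangle\lvert d_i\rangle$);
4. a phase oracle kicking a $-1$ onto matching branches through a match
   qubit prepared in $\lvert-\rangle$;
5. exact uncomputation of the load (so the oracle is phase-only on the
   address register), then the diffuser $2\lvert s\rangle\langle s\rvert-I$.

**Enumerate-m** hardcodes the dictionary in the oracle: for each pattern,
X-conjugate the data qubits at the pattern's 0-bits, MCX all $2L$ data
qubits into the match qubit, un-conjugate. **Nested Grover** instead loads
patterns from a second QRAM indexed by a pattern-ID register and compares
data and pattern registers with a bitwise XNOR equality oracle ($2L$
dedicated ancillas, exactly uncomputed); an inner diffuser over the
pattern-ID register turns this into an inner amplitude amplification run
inside every outer round.

## Iteration schedules

The marked-position count is unknown at run time, so optimal Grover counts
cannot be used. The package defaults are

* outer: $R = \max(1, \lfloor (\pi/4)\sqrt{S} \rfloor)$ over the valid
  positions ($S{=}3 \to 1$, $S{=}64 \to 6$),
* inner: $r = \lceil \pi\sqrt{m}/4 \rceil$ over the dictionary,

and both can be overridden per instance (`outer_iters`, `inner_iters`) or
from the CLI. We deliberately count over $S$ rather than the padded
$2^{\lceil\log_2 S\rceil}$ space: on the 8-base demonstration below with
linear addressing ($S=6$, two matches among $N=8$ padded states) the
$\sqrt{S}$ rule gives $R=1$ and $\sin^2(3\theta)=1$ — exact concentration
on the two match positions — while counting over the padded space gives
$R=2$ and $\sin^2(5\pi/6)=\tfrac14$, i.e. an exactly uniform output. Both
rules agree on every power-of-two case.

## Why the nested toy run uses one outer and one inner round

The nested structure as specified does *not* uncompute the inner
amplification, and this has a sharp consequence that is easy to derive for
$m=2$. Within an address branch, one inner round acts on the pattern-ID
qubit as $X\cdot F$, where $F$ flips the sign of the matching pattern
index (the width-1 diffuser is $-X$; global phases are irrelevant). Hence
two inner rounds give $(XF)^2 = -I$ on matched branches and $+I$ on
unmatched ones: an even inner count collapses the whole inner loop into a
clean phase oracle on the address register. For the cyclic 8-base instance
`ACGTACGT` with `{GTA, TAC}`, four of the eight addresses match — the
degenerate half-marked case in which amplitude amplification has *no*
effect for any outer count: the output is exactly uniform. The package's
abstract amplitude model (mirrored in the test helpers) confirms this, and
the 23-qubit gate-level simulation agrees to $10^{-9}$.

With **one** inner round the story changes qualitatively: matched branches
end with their pattern qubit in $\lvert-\rangle$ and unmatched in
$\lvert+\rangle$; these orthogonal tags let one outer diffuser move *all*
probability onto the four match addresses — exactly $\tfrac14$ each, zero
elsewhere. That is the behaviour the bundled toy-2 demonstration, the
worked example, and the acceptance test reproduce with the explicit
overrides `outer_iters = 1, inner_iters = 1`. The formula-based defaults
remain the defaults; the demonstration documents its schedule rather than
hiding it.

Related caveat: amplification only *guarantees* that amplified addresses
are true matches in the sparse regime. If $k$ of $N$ padded addresses are
marked, a non-match address can never exceed $1.5\times$ the uniform
baseline when $k < N/3$ (its probability is at most $1/(N-k) < 1.5/N$);
beyond that the guarantee genuinely fails — with 3 of 4 addresses marked,
one round drives all probability onto the only unmarked (padding) state.
The property tests are therefore scoped to $k < N/3$, and the 4-base toy's
exact distribution is asserted as what Grover algebra says it must be.

## Padding and the all-A collision

$\lceil\log_2 S\rceil$ address qubits create $2^{\lceil\log_2 S\rceil}-S$
invalid basis states. These load the all-zero data word — which is also
the valid encoding of the all-A k-mer. Whenever this collision can
produce a false match (an all-A pattern with address padding; in the
nested variant also pattern-ID padding combined with an all-A window), the
builders allocate a validity flag ancilla (`build_validity_flag()`),
computed from the address (or pattern-ID) register, added as an extra MCX
control on exactly the affected marks, and uncomputed before the next
diffuser. Padding states therefore stay measurable but are never falsely
marked. The exhaustive oracle tests over the 2-letter sub-alphabet
exercise this path heavily (every `{A}`/`{AA}`-containing dictionary).

## Numerical and design choices

* **Simulation.** Exact statevector evolution in C++ (one kernel for H,
  one for the X/CNOT/MCX family), no noise model, MCX applied natively as
  a single unitary; decomposition costs appear only in the resource
  accounting. Norm is conserved to $10^{-9}$ and every emitted fragment is
  reversed gate-for-gate for uncomputation (all gates used are
  self-inverse).
* **Qubit cap.** 24 qubits by default (`options(qkmer.qubit_cap = )` or
  the `cap` argument); a refused run reports the instance's width. The
  largest routine simulation in the tests is the 23-qubit nested toy.
* **Measurement.** The address register's exact marginal is computed from
  the statevector and shots are drawn multinomially under a caller-fixed
  seed; reports are bit-reproducible for a fixed (instance, seed).
* **Decision rule.** The histograms carry no intrinsic decision rule, so a
  position is "predicted" when its frequency reaches 1.5× the uniform
  baseline (configurable `threshold`); with no occurring pattern the
  distribution stays exactly uniform and the report flags that nothing was
  amplified.
* **Resource accounting.** `resource_estimate()` follows the printed
  arithmetic conventions: QRAM load cost is counted per (position, base),
  i.e. $S\cdot L$ MCX blocks (the per-qubit bound $2SL$ is reported
  separately), and the enumerate-m overhead is 3 ancillas (phase
  inversion, match, intermediate computation), giving e.g. 10 + 40 + 3 =
  53 qubits for $n=1000, L=20$. Register widths agree with what the
  builders actually allocate (validity guards excepted, as they depend on
  the dictionary content, not only on $(n, m, L)$).
* **Classical reference.** The naive scanner is the defining oracle;
  Aho–Corasick (trie + BFS failure links, cyclic mode scans the text
  extended by its first $L-1$ bases) must agree with it exactly, and is
  itself property-tested on 500 random instances per run.

## The fixture generator

`generate_fixture(n, m, L, planted, seed)` emulates the package's target
inputs: a uniform random ACGT text with `planted` non-overlapping
dictionary occurrences at recorded positions. It makes no attempt to model
GC bias, repeats, or low-complexity regions of real genomes; passing tests
on fixtures show circuit correctness (oracle marks = classical matches,
schedules behave as derived), not robustness to genomic sequence
composition — which does not affect correctness here, since matching is
exact. Chance occurrences beyond the planted ones are legitimate matches
and are deliberately left in.

## Problem sizes and limitations

The simulations in the tests and examples run at toy scale (texts up to 8
bases for full end-to-end circuits, up to ~200 for the classical
matchers), which is where exact statevector verification is meaningful;
the resource estimator covers realistic scales analytically (up to
chromosome-size $n$). Known limitations: the ideal-QRAM assumption is met
by brute-force multiplexing with $O(S\cdot L)$ gate cost per query, so the
asymptotic query advantage lives in the accounting, not in the simulated
gate counts; hardware noise, connectivity and MCX decomposition into
elementary gates are out of scope; dictionaries must have a single k-mer
length; and the nested variant's behaviour away from the analysed
schedules is reported by measurement, not guaranteed by theory.
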