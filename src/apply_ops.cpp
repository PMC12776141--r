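#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gate kernel for the statevector simulator.
//
// `state` is a complex vector of length 2^w; basis index i has qubit q set
// iff (i >> q) & 1.  Each op is an integer vector c(kind, target, controls...)
// with kind 0 = H, 1 = X-family (X / CNOT / MCX), 2 = measure (no-op here).
// All gates are applied in place on a copy of the input vector.

// [[Rcpp::export]]
ComplexVector cpp_apply_ops(ComplexVector state, List ops) {
  const R_xlen_t n = state.size();
  ComplexVector s = clone(state);
  const double inv_sqrt2 = 1.0 / std::sqrt(2.0);

  for (R_xlen_t k = 0; k < ops.size(); ++k) {
    IntegerVector op = ops[k];
    const int kind = op[0];
    if (kind == 2) continue;  // measurement handled by the sampler
    const long long tmask = 1LL << op[1];
    long long cmask = 0;
    for (int j = 2; j < op.size(); ++j) cmask |= (1LL << op[j]);

    if (kind == 0) {  // Hadamard on the target qubit
      for (long long i = 0; i < n; ++i) {
        if (i & tmask) continue;
        const long long j = i | tmask;
        const Rcomplex a = s[i], b = s[j];
        s[i].r = (a.r + b.r) * inv_sqrt2;
        s[i].i = (a.i + b.i) * inv_sqrt2;
        s[j].r = (a.r - b.r) * inv_sqrt2;
        s[j].i = (a.i - b.i) * inv_sqrt2;
      }
    } else {  // X-family: swap the target pair where all controls are set
      for (long long i = 0; i < n; ++i) {
        if (i & tmask) continue;
        if ((i & cmask) != cmask) continue;
        const long long j = i | tmask;
        const Rcomplex t = s[i];
        s[i] = s[j];
        s[j] = t;
      }
    }
  }
  return s;
}

// Register value of every basis index: bits of the (global, little-endian)
// state index gathered MSB-first over the register's qubit list.

// [[Rcpp::export]]
IntegerVector cpp_register_values(int width, IntegerVector qubits) {
  const long long n = 1LL << width;
  const int w = qubits.size();
  IntegerVector out(n);
  for (long long i = 0; i < n; ++i) {
    int v = 0;
    for (int j = 0; j < w; ++j)
      v = (v << 1) | (int)((i >> qubits[j]) & 1LL);
    out[i] = v;
  }
  return out;
}
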