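#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Generators operate on 32-bit words; state travels through R as a double
// (exact for all values < 2^53, so any 32-bit word is representable).

static const int ALG_XORSHIFT32 = 0;
static const int ALG_LCG = 1;

static inline uint32_t xorshift32_step(uint32_t x) {
  x ^= x << 13;
  x ^= x >> 17;
  x ^= x << 5;
  return x;
}

struct Engine {
  int alg;
  uint64_t state;
  uint64_t a, c, m;   // lcg only
  uint64_t range;     // raw values lie in [0, range)

  Engine(int alg_, double state_, double a_, double c_, double m_)
    : alg(alg_), state((uint64_t)state_),
      a((uint64_t)a_), c((uint64_t)c_), m((uint64_t)m_) {
    if (alg == ALG_XORSHIFT32) {
      range = 4294967296ULL;
      if (state == 0) stop("xorshift32 state must be nonzero");
      if (state >= range) stop("xorshift32 state must be a 32-bit word");
    } else if (alg == ALG_LCG) {
      if (m < 2 || m > 4294967296ULL) stop("lcg modulus must be in [2, 2^32]");
      range = m;
      state %= m;
    } else {
      stop("unknown generator algorithm");
    }
  }

  uint64_t next() {
    if (alg == ALG_XORSHIFT32) {
      state = xorshift32_step((uint32_t)state);
    } else {
      state = (a * state + c) % m;
    }
    return state;
  }

  // rejection sampling: accept raw < floor(range/k)*k, return raw % k
  int next_index(int k) {
    uint64_t limit = (range / (uint64_t)k) * (uint64_t)k;
    for (;;) {
      uint64_t v = next();
      if (v < limit) return (int)(v % (uint64_t)k);
    }
  }
};

// [[Rcpp::export]]
List cpp_rng_raw(int alg, double state, double a, double c, double m, int n) {
  if (n < 0) stop("n must be non-negative");
  Engine e(alg, state, a, c, m);
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = (double)e.next();
  return List::create(_["values"] = out, _["state"] = (double)e.state);
}

// [[Rcpp::export]]
List cpp_rng_indices(int alg, double state, double a, double c, double m,
                     int k, int n) {
  if (k < 1) stop("k must be a positive integer");
  if (n < 0) stop("n must be non-negative");
  Engine e(alg, state, a, c, m);
  IntegerVector out(n);
  for (int i = 0; i < n; i++) out[i] = e.next_index(k);
  return List::create(_["indices"] = out, _["state"] = (double)e.state);
}

// Draw one level index per dot cell, row-major over the cell grid, and
// return the cell matrix (1-based level indices, nrow_cells x ncol_cells).
// [[Rcpp::export]]
List cpp_render_cells(int alg, double state, double a, double c, double m,
                      int k, int nrow_cells, int ncol_cells) {
  if (k < 1) stop("palette must be non-empty");
  if (nrow_cells < 1 || ncol_cells < 1) stop("cell grid must be non-empty");
  Engine e(alg, state, a, c, m);
  IntegerMatrix cells(nrow_cells, ncol_cells);
  for (int r = 0; r < nrow_cells; r++)
    for (int cc = 0; cc < ncol_cells; cc++)
      cells(r, cc) = e.next_index(k) + 1;
  return List::create(_["cells"] = cells, _["state"] = (double)e.state);
}
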