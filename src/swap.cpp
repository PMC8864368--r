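#include <Rcpp.h>
using namespace Rcpp;

// Does the binary matrix contain at least one 2x2 checkerboard submatrix?
// [[Rcpp::export]]
bool has_checkerboard_cpp(const IntegerMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  for (int r1 = 0; r1 < nr - 1; ++r1) {
    for (int r2 = r1 + 1; r2 < nr; ++r2) {
      bool ab = false, ba = false; // (1,0) and (0,1) column patterns
      for (int c = 0; c < nc; ++c) {
        const int x = m(r1, c), y = m(r2, c);
        if (x == 1 && y == 0) ab = true;
        else if (x == 0 && y == 1) ba = true;
        if (ab && ba) return true;
      }
    }
  }
  return false;
}

// Independent-swap randomization: perform n_swaps successful 2x2
// checkerboard exchanges at uniformly sampled row/column pairs. Uses R's
// RNG so results are governed by set.seed(). The caller must ensure at
// least one checkerboard exists (a successful swap always leaves one).
// [[Rcpp::export]]
IntegerMatrix independent_swap_cpp(IntegerMatrix m, int n_swaps) {
  IntegerMatrix out = clone(m);
  const int nr = out.nrow(), nc = out.ncol();
  int done = 0;
  while (done < n_swaps) {
    int r1 = (int)(unif_rand() * nr), r2 = (int)(unif_rand() * nr);
    if (r1 == r2) continue;
    int c1 = (int)(unif_rand() * nc), c2 = (int)(unif_rand() * nc);
    if (c1 == c2) continue;
    const int a = out(r1, c1), b = out(r1, c2), c = out(r2, c1), d = out(r2, c2);
    if ((a == 1 && d == 1 && b == 0 && c == 0) ||
        (a == 0 && d == 0 && b == 1 && c == 1)) {
      out(r1, c1) = 1 - a; out(r1, c2) = 1 - b;
      out(r2, c1) = 1 - c; out(r2, c2) = 1 - d;
      ++done;
    }
  }
  return out;
}
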