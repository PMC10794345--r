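#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// reflect index into [0, n-1] (half-sample symmetric: edge pixel repeated,
// scipy "reflect" / MATLAB "symmetric")
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  int j = i % period;
  if (j < 0) j += period;
  return (j < n) ? j : (period - 1 - j);
}

// Separable correlation of a matrix with a symmetric 1-D kernel applied
// along both dimensions, reflect boundary. Kernel is assumed normalised.
// [[Rcpp::export(name = ".conv_sep_reflect")]]
NumericMatrix conv_sep_reflect(const NumericMatrix& x,
                               const NumericVector& kernel) {
  const int nr = x.nrow(), nc = x.ncol();
  const int k = kernel.size();
  const int r = (k - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* kv = kernel.begin();

  // pass 1: along rows (vertical, dim 1); boundary rows use reflection,
  // interior rows take a branch-free fast path
  const int lo1 = std::min(r, nr), hi1 = std::max(nr - r, lo1);
  for (int j = 0; j < nc; ++j) {
    const double* col = &x(0, j);
    double* tcol = &tmp(0, j);
    for (int i = 0; i < lo1; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t)
        acc += kv[t + r] * col[reflect_idx(i + t, nr)];
      tcol[i] = acc;
    }
    for (int i = lo1; i < hi1; ++i) {
      double acc = 0.0;
      const double* p = col + i - r;
      for (int t = 0; t < k; ++t) acc += kv[t] * p[t];
      tcol[i] = acc;
    }
    for (int i = hi1; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t)
        acc += kv[t + r] * col[reflect_idx(i + t, nr)];
      tcol[i] = acc;
    }
  }
  // pass 2: along columns (horizontal, dim 2), accumulating whole
  // columns at a time so memory access stays sequential
  std::fill(out.begin(), out.end(), 0.0);
  for (int j = 0; j < nc; ++j) {
    double* ocol = &out(0, j);
    for (int t = -r; t <= r; ++t) {
      const double w = kv[t + r];
      const double* scol = &tmp(0, reflect_idx(j + t, nc));
      for (int i = 0; i < nr; ++i) ocol[i] += w * scol[i];
    }
  }
  return out;
}

// 8-connected component labelling of a logical matrix.
// Returns an integer matrix: 0 for background, 1..n for components.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      ++next;
      stack.push_back(i0 + j0 * nr);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int i = p % nr, j = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
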