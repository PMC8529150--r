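#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// half-sample symmetric reflection, valid for |i| < 2n
static inline int reflect_idx(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - 1 - i;
  return i;
}

// Convolve a 3-D array (column-major, dims d1 x d2 x d3) with a centred 1-D
// kernel along one axis (1-based), reflecting at the boundaries.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(const NumericVector& arr, const IntegerVector& dims,
                            const NumericVector& kernel, int axis) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int k = kernel.size();
  const int r = (k - 1) / 2;
  if (k % 2 == 0) stop("kernel length must be odd");
  if (axis < 1 || axis > 3) stop("axis must be 1, 2 or 3");
  NumericVector out(no_init(arr.size()));
  const double* a = arr.begin();
  double* o = out.begin();
  const double* kv = kernel.begin();
  const int n = (axis == 1) ? d1 : (axis == 2) ? d2 : d3;
  const long st = (axis == 1) ? 1L : (axis == 2) ? (long)d1 : (long)d1 * d2;

  // iterate over all lines along the chosen axis
  for (int i3 = 0; i3 < d3; ++i3) {
    for (int i2 = 0; i2 < d2; ++i2) {
      for (int i1 = 0; i1 < d1; ++i1) {
        int pos = (axis == 1) ? i1 : (axis == 2) ? i2 : i3;
        if (pos != 0) continue;  // only start of each line
        long base = (long)i1 + (long)i2 * d1 + (long)i3 * d1 * d2;
        for (int p = 0; p < n; ++p) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j) {
            int q = reflect_idx(p + j, n);
            acc += a[base + (long)q * st] * kv[j + r];
          }
          o[base + (long)p * st] = acc;
        }
      }
    }
  }
  return out;
}

// Connected-component labelling of a logical 3-D array.
// connectivity: 4 or 8 -> 2-D, applied independently per slice (axis 1 is the
// slice axis); 6 or 26 -> full 3-D. Labels are 1..K, background 0.
// [[Rcpp::export]]
IntegerVector cpp_label(const LogicalVector& mask, const IntegerVector& dims,
                        int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const long nvox = (long)d1 * d2 * d3;
  IntegerVector lab(nvox, 0);
  const int* m = mask.begin();
  int* L = lab.begin();

  std::vector<int> off_s, off_r, off_c;
  auto add = [&](int ds, int dr, int dc) {
    off_s.push_back(ds); off_r.push_back(dr); off_c.push_back(dc);
  };
  if (connectivity == 4 || connectivity == 6) {
    add(0, 1, 0); add(0, -1, 0); add(0, 0, 1); add(0, 0, -1);
    if (connectivity == 6) { add(1, 0, 0); add(-1, 0, 0); }
  } else if (connectivity == 8 || connectivity == 26) {
    int dsmax = (connectivity == 26) ? 1 : 0;
    for (int ds = -dsmax; ds <= dsmax; ++ds)
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc)
          if (ds || dr || dc) add(ds, dr, dc);
  } else {
    stop("connectivity must be one of 4, 8, 6, 26");
  }
  const int noff = off_s.size();

  int cur = 0;
  std::vector<long> stack;
  stack.reserve(1024);
  for (long v = 0; v < nvox; ++v) {
    if (!m[v] || L[v] != 0) continue;
    ++cur;
    L[v] = cur;
    stack.push_back(v);
    while (!stack.empty()) {
      long u = stack.back(); stack.pop_back();
      int s = (int)(u % d1);
      long rest = u / d1;
      int rr = (int)(rest % d2);
      int cc = (int)(rest / d2);
      for (int t = 0; t < noff; ++t) {
        int s2 = s + off_s[t], r2 = rr + off_r[t], c2 = cc + off_c[t];
        if (s2 < 0 || s2 >= d1 || r2 < 0 || r2 >= d2 || c2 < 0 || c2 >= d3)
          continue;
        long w = (long)s2 + (long)r2 * d1 + (long)c2 * d1 * d2;
        if (m[w] && L[w] == 0) { L[w] = cur; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Eigenvalues of the voxelwise symmetric 3x3 Hessian, for voxels where
// mask is TRUE; returned sorted by increasing absolute value, zero elsewhere.
// [[Rcpp::export]]
List cpp_eigs_sym3(const NumericVector& hss, const NumericVector& hrr,
                   const NumericVector& hcc, const NumericVector& hsr,
                   const NumericVector& hsc, const NumericVector& hrc,
                   const LogicalVector& mask) {
  const long n = mask.size();
  NumericVector e1(n, 0.0), e2(n, 0.0), e3(n, 0.0);
  arma::mat H(3, 3);
  arma::vec ev;
  for (long v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    H(0, 0) = hss[v]; H(1, 1) = hrr[v]; H(2, 2) = hcc[v];
    H(0, 1) = H(1, 0) = hsr[v];
    H(0, 2) = H(2, 0) = hsc[v];
    H(1, 2) = H(2, 1) = hrc[v];
    arma::eig_sym(ev, H);
    double a = ev(0), b = ev(1), c = ev(2);
    // order by |.| ascending
    if (std::abs(a) > std::abs(b)) std::swap(a, b);
    if (std::abs(b) > std::abs(c)) std::swap(b, c);
    if (std::abs(a) > std::abs(b)) std::swap(a, b);
    e1[v] = a; e2[v] = b; e3[v] = c;
  }
  return List::create(_["e1"] = e1, _["e2"] = e2, _["e3"] = e3);
}
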