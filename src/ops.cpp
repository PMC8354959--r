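#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Patch-matrix (im2col) extraction for a rank-2 or rank-3 strided convolution.
// x is a flattened array laid out (spatial..., channels), column-major as in R.
// Row p of the result holds the receptive field of output position p (column-
// major over the output grid); column index is c * k^rank + kk, where kk runs
// column-major over the kernel offsets. Out-of-bounds taps are zero (padding).
// [[Rcpp::export]]
NumericMatrix nd_im2col(NumericVector x, IntegerVector sp, int c_in, int k,
                        int stride, int pad) {
  const int rank = sp.size();
  std::vector<int> od(rank);
  R_xlen_t n_out = 1, n_in = 1;
  for (int d = 0; d < rank; ++d) {
    od[d] = (sp[d] + 2 * pad - k) / stride + 1;
    n_out *= od[d];
    n_in *= sp[d];
  }
  int K = 1;
  for (int d = 0; d < rank; ++d) K *= k;

  NumericMatrix P(n_out, (R_xlen_t)c_in * K);
  std::vector<R_xlen_t> st(rank);
  st[0] = 1;
  for (int d = 1; d < rank; ++d) st[d] = st[d - 1] * sp[d - 1];

  std::vector<int> oc(rank, 0);
  for (R_xlen_t p = 0; p < n_out; ++p) {
    std::vector<int> kc(rank, 0);
    for (int kk = 0; kk < K; ++kk) {
      bool inside = true;
      R_xlen_t base = 0;
      for (int d = 0; d < rank; ++d) {
        const int ic = oc[d] * stride - pad + kc[d];
        if (ic < 0 || ic >= sp[d]) { inside = false; break; }
        base += (R_xlen_t)ic * st[d];
      }
      if (inside) {
        for (int c = 0; c < c_in; ++c)
          P(p, (R_xlen_t)c * K + kk) = x[base + (R_xlen_t)c * n_in];
      }
      for (int d = 0; d < rank; ++d) { if (++kc[d] < k) break; kc[d] = 0; }
    }
    for (int d = 0; d < rank; ++d) { if (++oc[d] < od[d]) break; oc[d] = 0; }
  }
  return P;
}

// Adjoint of nd_im2col: scatter-add a patch-matrix gradient back onto the
// input grid. Same layout conventions as nd_im2col.
// [[Rcpp::export]]
NumericVector nd_col2im(NumericMatrix dP, IntegerVector sp, int c_in, int k,
                        int stride, int pad) {
  const int rank = sp.size();
  std::vector<int> od(rank);
  R_xlen_t n_out = 1, n_in = 1;
  for (int d = 0; d < rank; ++d) {
    od[d] = (sp[d] + 2 * pad - k) / stride + 1;
    n_out *= od[d];
    n_in *= sp[d];
  }
  int K = 1;
  for (int d = 0; d < rank; ++d) K *= k;

  NumericVector dX((R_xlen_t)n_in * c_in);
  std::vector<R_xlen_t> st(rank);
  st[0] = 1;
  for (int d = 1; d < rank; ++d) st[d] = st[d - 1] * sp[d - 1];

  std::vector<int> oc(rank, 0);
  for (R_xlen_t p = 0; p < n_out; ++p) {
    std::vector<int> kc(rank, 0);
    for (int kk = 0; kk < K; ++kk) {
      bool inside = true;
      R_xlen_t base = 0;
      for (int d = 0; d < rank; ++d) {
        const int ic = oc[d] * stride - pad + kc[d];
        if (ic < 0 || ic >= sp[d]) { inside = false; break; }
        base += (R_xlen_t)ic * st[d];
      }
      if (inside) {
        for (int c = 0; c < c_in; ++c)
          dX[base + (R_xlen_t)c * n_in] += dP(p, (R_xlen_t)c * K + kk);
      }
      for (int d = 0; d < rank; ++d) { if (++kc[d] < k) break; kc[d] = 0; }
    }
    for (int d = 0; d < rank; ++d) { if (++oc[d] < od[d]) break; oc[d] = 0; }
  }
  return dX;
}

// Rank-2/3 median filter with window w (odd); values outside the array count
// as zero, matching a zero background outside the brain mask.
// [[Rcpp::export]]
NumericVector nd_median_filter(NumericVector x, IntegerVector sp, int w) {
  const int rank = sp.size();
  const int half = w / 2;
  R_xlen_t n = 1;
  for (int d = 0; d < rank; ++d) n *= sp[d];
  int W = 1;
  for (int d = 0; d < rank; ++d) W *= w;

  NumericVector out(n);
  std::vector<R_xlen_t> st(rank);
  st[0] = 1;
  for (int d = 1; d < rank; ++d) st[d] = st[d - 1] * sp[d - 1];

  std::vector<double> buf(W);
  std::vector<int> vc(rank, 0);
  for (R_xlen_t p = 0; p < n; ++p) {
    int m = 0;
    std::vector<int> kc(rank, 0);
    for (int kk = 0; kk < W; ++kk) {
      bool inside = true;
      R_xlen_t base = 0;
      for (int d = 0; d < rank; ++d) {
        const int ic = vc[d] - half + kc[d];
        if (ic < 0 || ic >= sp[d]) { inside = false; break; }
        base += (R_xlen_t)ic * st[d];
      }
      buf[m++] = inside ? x[base] : 0.0;
      for (int d = 0; d < rank; ++d) { if (++kc[d] < w) break; kc[d] = 0; }
    }
    std::nth_element(buf.begin(), buf.begin() + W / 2, buf.begin() + m);
    out[p] = buf[W / 2];
    for (int d = 0; d < rank; ++d) { if (++vc[d] < sp[d]) break; vc[d] = 0; }
  }
  return out;
}
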