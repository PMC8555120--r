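// In-place numeric kernels for the training loop. Adam touches every
// parameter every step (batch size 1), so the update must not allocate;
// gradient tables are preallocated once and zeroed row-wise after use.
#include <Rcpp.h>
using namespace Rcpp;

// One Adam update, in place: p -= lr * mhat / (sqrt(vhat) + eps).
// bc1 = 1 - beta1^t, bc2 = 1 - beta2^t (bias corrections).
// [[Rcpp::export]]
void cpp_adam_update(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, double lr, double beta1, double beta2,
                     double eps, double bc1, double bc2) {
  R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    double mi = beta1 * m[i] + (1.0 - beta1) * gi;
    double vi = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    m[i] = mi;
    v[i] = vi;
    p[i] -= lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
}

// M[rows, ] += X, in place (rows are 1-based, one per row of X).
// [[Rcpp::export]]
void cpp_add_rows(NumericMatrix M, IntegerVector rows, NumericMatrix X) {
  int nc = M.ncol();
  for (int k = 0; k < rows.size(); ++k) {
    int r = rows[k] - 1;
    for (int c = 0; c < nc; ++c) M(r, c) += X(k, c);
  }
}

// M[rows, ] = 0, in place (1-based rows).
// [[Rcpp::export]]
void cpp_zero_rows(NumericMatrix M, IntegerVector rows) {
  int nc = M.ncol();
  for (int k = 0; k < rows.size(); ++k) {
    int r = rows[k] - 1;
    for (int c = 0; c < nc; ++c) M(r, c) = 0.0;
  }
}

// x[] = 0, in place.
// [[Rcpp::export]]
void cpp_fill_zero(NumericVector x) {
  std::fill(x.begin(), x.end(), 0.0);
}

// M[rows, ] (1-based rows).
// [[Rcpp::export]]
NumericMatrix cpp_gather(NumericMatrix M, IntegerVector rows) {
  int nc = M.ncol(), nr = rows.size();
  NumericMatrix out(nr, nc);
  for (int k = 0; k < nr; ++k) {
    int r = rows[k] - 1;
    for (int c = 0; c < nc; ++c) out(k, c) = M(r, c);
  }
  return out;
}

// A[rowsA, ] + B[rowsB, ] (1-based; rowsA and rowsB the same length).
// [[Rcpp::export]]
NumericMatrix cpp_gather2_sum(NumericMatrix A, IntegerVector rowsA,
                              NumericMatrix B, IntegerVector rowsB) {
  int nc = A.ncol(), nr = rowsA.size();
  NumericMatrix out(nr, nc);
  for (int k = 0; k < nr; ++k) {
    int ra = rowsA[k] - 1, rb = rowsB[k] - 1;
    for (int c = 0; c < nc; ++c) out(k, c) = A(ra, c) + B(rb, c);
  }
  return out;
}

// dH * (ref > 0), elementwise (the ReLU backward mask).
// [[Rcpp::export]]
NumericMatrix cpp_mask_mul(NumericMatrix dH, NumericMatrix ref) {
  R_xlen_t n = dH.size();
  NumericMatrix out(dH.nrow(), dH.ncol());
  for (R_xlen_t i = 0; i < n; ++i) out[i] = ref[i] > 0.0 ? dH[i] : 0.0;
  return out;
}
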