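#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Column gather/scatter kernels for the im2col-style convolutions.
// Activations are stored channels-first as C x (voxels * batch) matrices,
// so gathering a shifted voxel copies one short contiguous column — these
// memory-bound primitives dominate a training step, hence the compiled
// implementation (GEMMs stay in BLAS on the R side).

// [[Rcpp::export]]
NumericMatrix gather_cols(const NumericMatrix& x, const IntegerVector& idx) {
  const int n = idx.size(), c = x.nrow(), nc = x.ncol();
  NumericMatrix out(c, n);
  const double* src = REAL(x);
  double* dst = REAL(out);
  for (int i = 0; i < n; ++i) {
    const int col = idx[i] - 1;
    if (col >= 0 && col < nc) {
      std::memcpy(dst + (size_t)i * c, src + (size_t)col * c, c * sizeof(double));
    } else {
      std::memset(dst + (size_t)i * c, 0, c * sizeof(double));
    }
  }
  return out;
}

// out[, i] = x[, idx[i]] * w[i]
// [[Rcpp::export]]
NumericMatrix gather_cols_scaled(const NumericMatrix& x, const IntegerVector& idx,
                                 const NumericVector& w) {
  const int n = idx.size(), c = x.nrow(), nc = x.ncol();
  NumericMatrix out(c, n);
  const double* src = REAL(x);
  double* dst = REAL(out);
  for (int i = 0; i < n; ++i) {
    const int col = idx[i] - 1;
    double* d = dst + (size_t)i * c;
    if (col >= 0 && col < nc) {
      const double* s = src + (size_t)col * c;
      const double wi = w[i];
      for (int j = 0; j < c; ++j) d[j] = s[j] * wi;
    } else {
      std::memset(d, 0, c * sizeof(double));
    }
  }
  return out;
}

// target[, idx[i]] += vals[, i]; duplicates accumulate. In-place: callers
// pass freshly allocated gradient buffers only.
// [[Rcpp::export]]
void scatter_add_cols(NumericMatrix target, const IntegerVector& idx,
                      const NumericMatrix& vals) {
  const int n = idx.size(), c = target.nrow(), nc = target.ncol();
  if (vals.ncol() != n || vals.nrow() != c) stop("shape mismatch");
  double* dst = REAL(target);
  const double* src = REAL(vals);
  for (int i = 0; i < n; ++i) {
    const int col = idx[i] - 1;
    if (col >= 0 && col < nc) {
      double* d = dst + (size_t)col * c;
      const double* s = src + (size_t)i * c;
      for (int j = 0; j < c; ++j) d[j] += s[j];
    }
  }
}

// target[, idx[i]] += vals[, i] * w[i]
// [[Rcpp::export]]
void scatter_add_cols_scaled(NumericMatrix target, const IntegerVector& idx,
                             const NumericMatrix& vals, const NumericVector& w) {
  const int n = idx.size(), c = target.nrow(), nc = target.ncol();
  if (vals.ncol() != n || vals.nrow() != c) stop("shape mismatch");
  double* dst = REAL(target);
  const double* src = REAL(vals);
  for (int i = 0; i < n; ++i) {
    const int col = idx[i] - 1;
    if (col >= 0 && col < nc) {
      double* d = dst + (size_t)col * c;
      const double* s = src + (size_t)i * c;
      const double wi = w[i];
      for (int j = 0; j < c; ++j) d[j] += s[j] * wi;
    }
  }
}
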