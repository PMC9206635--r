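// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

// Fused convolution and upsampling passes. Activations are channels-first
// C x (voxels * batch) matrices (voxel fastest, column-major grid).
// `idx` holds, per kernel offset, the 1-based padded-grid column of each
// output voxel; batch replication adds multiples of npad. One call per
// layer pass keeps allocations and R-level overhead out of the training
// loop; GEMMs run through Armadillo/BLAS.

static void fill_cols(arma::mat& cols, const double* src, int cin,
                      const IntegerMatrix& idx, int k, int npad, int B) {
  const int no = idx.nrow();
  double* dst = cols.memptr();
  for (int b = 0; b < B; ++b) {
    const size_t boff = (size_t)b * npad;
    double* dcol = dst + (size_t)b * no * cin;
    for (int i = 0; i < no; ++i) {
      const size_t scol = (size_t)(idx(i, k) - 1) + boff;
      std::memcpy(dcol + (size_t)i * cin, src + scol * cin, cin * sizeof(double));
    }
  }
}

// [[Rcpp::export]]
NumericMatrix conv_forward_cpp(const NumericMatrix& P, const IntegerMatrix& idx,
                               int npad, int B, const NumericMatrix& W,
                               const NumericVector& bias) {
  const int no = idx.nrow(), K = idx.ncol();
  const int cin = P.nrow(), cout = W.nrow();
  NumericMatrix out(cout, (size_t)no * B);
  arma::mat outv(REAL(out), cout, (size_t)no * B, false, true);
  const arma::mat Wv(const_cast<double*>(REAL(W)), cout, (size_t)K * cin, false, true);
  const arma::vec bv(const_cast<double*>(REAL(bias)), cout, false, true);
  outv.each_col() = bv;
  arma::mat cols(cin, (size_t)no * B);
  for (int k = 0; k < K; ++k) {
    fill_cols(cols, REAL(P), cin, idx, k, npad, B);
    outv += Wv.cols((size_t)k * cin, (size_t)(k + 1) * cin - 1) * cols;
  }
  return out;
}

// [[Rcpp::export]]
List conv_backward_cpp(const NumericMatrix& P, const IntegerMatrix& idx,
                       int npad, int B, const NumericMatrix& W,
                       const NumericMatrix& dY) {
  const int no = idx.nrow(), K = idx.ncol();
  const int cin = P.nrow(), cout = W.nrow();
  NumericMatrix dW(cout, (size_t)K * cin);
  NumericMatrix dP(cin, P.ncol());
  NumericVector db(cout);
  arma::mat dWv(REAL(dW), cout, (size_t)K * cin, false, true);
  arma::mat dPv(REAL(dP), cin, P.ncol(), false, true);
  const arma::mat Wv(const_cast<double*>(REAL(W)), cout, (size_t)K * cin, false, true);
  const arma::mat dYv(const_cast<double*>(REAL(dY)), cout, (size_t)no * B, false, true);
  arma::vec dbv(REAL(db), cout, false, true);
  dbv = arma::sum(dYv, 1);
  arma::mat cols(cin, (size_t)no * B);
  arma::mat dcols(cin, (size_t)no * B);
  for (int k = 0; k < K; ++k) {
    fill_cols(cols, REAL(P), cin, idx, k, npad, B);
    dWv.cols((size_t)k * cin, (size_t)(k + 1) * cin - 1) = dYv * cols.t();
    dcols = Wv.cols((size_t)k * cin, (size_t)(k + 1) * cin - 1).t() * dYv;
    // scatter-add (no duplicate columns within one offset)
    const double* src = dcols.memptr();
    double* dst = REAL(dP);
    for (int b = 0; b < B; ++b) {
      const size_t boff = (size_t)b * npad;
      const double* scol = src + (size_t)b * no * cin;
      for (int i = 0; i < no; ++i) {
        double* d = dst + ((size_t)(idx(i, k) - 1) + boff) * cin;
        const double* sc = scol + (size_t)i * cin;
        for (int j = 0; j < cin; ++j) d[j] += sc[j];
      }
    }
  }
  return List::create(Named("dW") = dW, Named("db") = db, Named("dP") = dP);
}

// [[Rcpp::export]]
NumericMatrix upsample_forward_cpp(const NumericMatrix& X, const IntegerMatrix& idx,
                                   const NumericMatrix& wts, int B, int nin) {
  const int no = idx.nrow(), NC = idx.ncol();
  const int c = X.nrow();
  NumericMatrix out(c, (size_t)no * B);
  const double* src = REAL(X);
  double* dst = REAL(out);
  for (int ci = 0; ci < NC; ++ci) {
    for (int b = 0; b < B; ++b) {
      const size_t boff = (size_t)b * nin;
      double* dcol = dst + (size_t)b * no * c;
      for (int i = 0; i < no; ++i) {
        const double w = wts(i, ci);
        const double* s = src + ((size_t)(idx(i, ci) - 1) + boff) * c;
        double* d = dcol + (size_t)i * c;
        for (int j = 0; j < c; ++j) d[j] += w * s[j];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix upsample_backward_cpp(const NumericMatrix& dY, const IntegerMatrix& idx,
                                    const NumericMatrix& wts, int B, int nin) {
  const int no = idx.nrow(), NC = idx.ncol();
  const int c = dY.nrow();
  NumericMatrix dX(c, (size_t)nin * B);
  const double* src = REAL(dY);
  double* dst = REAL(dX);
  for (int ci = 0; ci < NC; ++ci) {
    for (int b = 0; b < B; ++b) {
      const size_t boff = (size_t)b * nin;
      const double* scol = src + (size_t)b * no * c;
      for (int i = 0; i < no; ++i) {
        const double w = wts(i, ci);
        double* d = dst + ((size_t)(idx(i, ci) - 1) + boff) * c;
        const double* s = scol + (size_t)i * c;
        for (int j = 0; j < c; ++j) d[j] += w * s[j];
      }
    }
  }
  return dX;
}
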