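#include <Rcpp.h>
using namespace Rcpp;

// Gather kernel patches for im2col. xp: flattened padded image stack,
// (Hp*Wp*C) x N; idx: S x K 1-based linear indices into one image's
// flattened raster. Returns (S*N) x K with the spatial index fastest and
// the batch index next, matching the R-level layout.
// [[Rcpp::export]]
NumericMatrix gather_patches(const NumericMatrix& xp, const IntegerMatrix& idx) {
  const int S = idx.nrow(), K = idx.ncol(), N = xp.ncol();
  NumericMatrix out(S * N, K);
  for (int k = 0; k < K; ++k) {
    const int* ic = &idx(0, k);
    double* oc = &out(0, k);
    for (int n = 0; n < N; ++n) {
      const double* xc = &xp(0, n);
      double* o = oc + (long)n * S;
      for (int s = 0; s < S; ++s) o[s] = xc[ic[s] - 1];
    }
  }
  return out;
}

// Adjoint of gather_patches: scatter-add patch columns back onto the padded
// canvas. cols: (S*N) x K; returns (len) x N.
// [[Rcpp::export]]
NumericMatrix scatter_add_patches(const NumericMatrix& cols,
                                  const IntegerMatrix& idx,
                                  const int len) {
  const int S = idx.nrow(), K = idx.ncol();
  const int N = cols.nrow() / S;
  NumericMatrix out(len, N);
  for (int k = 0; k < K; ++k) {
    const int* ic = &idx(0, k);
    const double* cc = &cols(0, k);
    for (int n = 0; n < N; ++n) {
      double* oc = &out(0, n);
      const double* c = cc + (long)n * S;
      for (int s = 0; s < S; ++s) oc[ic[s] - 1] += c[s];
    }
  }
  return out;
}

// (H,W,C,N) array -> (H*W*N) x C matrix, spatial fastest then batch.
// Both layouts keep each (spatial x 1 channel x 1 image) block contiguous,
// so this is a block copy.
// [[Rcpp::export]]
NumericMatrix tensor_to_mat_cpp(const NumericVector& x, const int H,
                                const int W, const int C, const int N) {
  const long S = (long)H * W;
  NumericMatrix out(S * N, C);
  for (int c = 0; c < C; ++c) {
    double* oc = &out(0, c);
    for (int n = 0; n < N; ++n) {
      const double* src = &x[0] + ((long)n * C + c) * S;
      std::copy(src, src + S, oc + (long)n * S);
    }
  }
  return out;
}

// Inverse of tensor_to_mat_cpp.
// [[Rcpp::export]]
NumericVector mat_to_tensor_cpp(const NumericMatrix& m, const int H,
                                const int W, const int C, const int N) {
  const long S = (long)H * W;
  NumericVector out((long)H * W * C * N);
  for (int c = 0; c < C; ++c) {
    const double* mc = &m(0, c);
    for (int n = 0; n < N; ++n) {
      double* dst = &out[0] + ((long)n * C + c) * S;
      std::copy(mc + (long)n * S, mc + (long)(n + 1) * S, dst);
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}
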