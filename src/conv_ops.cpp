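// Gather/scatter kernels for the 3D convolution engine.
//
// Convolutions are evaluated as im2col + one BLAS matrix product; these
// two routines are the data movement, which dominates runtime when done
// with R-level indexing. `map` is the K x S_out spatial index map built
// by conv_index_map(): entry (j, o) is the 1-based input voxel feeding
// kernel offset j of output voxel o, or 0 for zero padding.

#include <Rcpp.h>
#include <cstring>

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& A, const IntegerMatrix& map,
                         int n_samples, int s_in) {
  const int C = A.nrow();
  const int K = map.nrow();
  const int S_out = map.ncol();
  NumericMatrix out(C * K, S_out * n_samples);
  const double* a = REAL(A);
  double* o = REAL(out);
  const int* m = INTEGER(map);
  for (int n = 0; n < n_samples; ++n) {
    const double* a_n = a + (R_xlen_t)n * s_in * C;
    for (int s = 0; s < S_out; ++s) {
      double* col = o + ((R_xlen_t)n * S_out + s) * (C * K);
      const int* ms = m + (R_xlen_t)s * K;
      for (int j = 0; j < K; ++j) {
        const int src = ms[j];
        if (src > 0)
          std::memcpy(col + (R_xlen_t)j * C,
                      a_n + (R_xlen_t)(src - 1) * C,
                      C * sizeof(double));
        // zero padding: `out` is zero-initialized
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dX, const IntegerMatrix& map,
                         int n_samples, int s_in) {
  const int K = map.nrow();
  const int S_out = map.ncol();
  const int C = dX.nrow() / K;
  NumericMatrix out(C, s_in * n_samples);
  const double* dx = REAL(dX);
  double* o = REAL(out);
  const int* m = INTEGER(map);
  for (int n = 0; n < n_samples; ++n) {
    double* o_n = o + (R_xlen_t)n * s_in * C;
    for (int s = 0; s < S_out; ++s) {
      const double* col = dx + ((R_xlen_t)n * S_out + s) * (C * K);
      const int* ms = m + (R_xlen_t)s * K;
      for (int j = 0; j < K; ++j) {
        const int dst = ms[j];
        if (dst > 0) {
          double* tgt = o_n + (R_xlen_t)(dst - 1) * C;
          const double* src = col + (R_xlen_t)j * C;
          for (int c = 0; c < C; ++c) tgt[c] += src[c];
        }
      }
    }
  }
  return out;
}
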