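// Convolution forward/backward kernels for the autoencoder.  A k x k
// convolution over a channels-first batch (C, H, W, N) is computed as a
// sum over kernel offsets of strided-slice gathers followed by BLAS
// matrix products; the backward pass mirrors it with scatter-adds.
// Inputs arrive already zero-padded; the R side owns padding geometry,
// activation masks and parameter updates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// gather the strided slice for kernel offset (dr, dc) into Xs (C x M)
static void gather_slice(const double* xp, double* xs,
                         int C, int Hp, int Wp, int N,
                         int Hout, int Wout, int sh, int sw,
                         int dr, int dc) {
  const long chw = (long)C * Hp * Wp;
  long m = 0;
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < Wout; ++j) {
      const long base_w = (long)(dc + j * sw) * C * Hp + n * chw;
      for (int i = 0; i < Hout; ++i) {
        const double* src = xp + base_w + (long)(dr + i * sh) * C;
        std::copy(src, src + C, xs + m * C);
        ++m;
      }
    }
  }
}

// scatter-add dXs (C x M) back into the padded gradient array
static void scatter_slice(double* dxp, const double* dxs,
                          int C, int Hp, int Wp, int N,
                          int Hout, int Wout, int sh, int sw,
                          int dr, int dc) {
  const long chw = (long)C * Hp * Wp;
  long m = 0;
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < Wout; ++j) {
      const long base_w = (long)(dc + j * sw) * C * Hp + n * chw;
      for (int i = 0; i < Hout; ++i) {
        double* dst = dxp + base_w + (long)(dr + i * sh) * C;
        const double* src = dxs + m * C;
        for (int c = 0; c < C; ++c) dst[c] += src[c];
        ++m;
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
NumericMatrix conv_fwd_cpp(NumericVector Xp, IntegerVector dims,
                           NumericMatrix W, NumericVector b,
                           int k, int sh, int sw, int Hout, int Wout) {
  const int C = dims[0], Hp = dims[1], Wp = dims[2], N = dims[3];
  const int Cout = W.nrow();
  const long M = (long)Hout * Wout * N;

  arma::mat Y(Cout, M);
  for (long m = 0; m < M; ++m)
    for (int c = 0; c < Cout; ++c) Y(c, m) = b[c];

  arma::mat Xs(C, M);
  const arma::mat Wm(W.begin(), Cout, W.ncol(), false, true);
  for (int dc = 0; dc < k; ++dc) {
    for (int dr = 0; dr < k; ++dr) {
      gather_slice(Xp.begin(), Xs.memptr(), C, Hp, Wp, N,
                   Hout, Wout, sh, sw, dr, dc);
      Y += Wm.cols((dc * k + dr) * C, (dc * k + dr) * C + C - 1) * Xs;
    }
  }
  NumericMatrix out(Cout, M);
  std::copy(Y.memptr(), Y.memptr() + Y.n_elem, out.begin());
  return out;
}

// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(NumericVector Xp, IntegerVector dims,
                  NumericMatrix W, NumericMatrix dYm,
                  int k, int sh, int sw, int Hout, int Wout) {
  const int C = dims[0], Hp = dims[1], Wp = dims[2], N = dims[3];
  const int Cout = W.nrow();
  const long M = (long)Hout * Wout * N;

  const arma::mat Wm(W.begin(), Cout, W.ncol(), false, true);
  const arma::mat dY(dYm.begin(), Cout, M, false, true);

  arma::mat dW(Cout, W.ncol(), arma::fill::zeros);
  NumericVector dXp((long)C * Hp * Wp * N);
  arma::mat Xs(C, M);

  for (int dc = 0; dc < k; ++dc) {
    for (int dr = 0; dr < k; ++dr) {
      gather_slice(Xp.begin(), Xs.memptr(), C, Hp, Wp, N,
                   Hout, Wout, sh, sw, dr, dc);
      const int b0 = (dc * k + dr) * C;
      dW.cols(b0, b0 + C - 1) = dY * Xs.t();
      arma::mat dXs = Wm.cols(b0, b0 + C - 1).t() * dY;
      scatter_slice(dXp.begin(), dXs.memptr(), C, Hp, Wp, N,
                    Hout, Wout, sh, sw, dr, dc);
    }
  }
  NumericMatrix dWout(Cout, W.ncol());
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, dWout.begin());
  return List::create(Named("dW") = dWout, Named("dXp") = dXp);
}
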