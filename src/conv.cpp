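// Compiled inner loops of the convolution layers: im2col gather + GEMM
// forward, and the backward pass (weight/bias gradients and col2im
// scatter-add for the input gradient). Column-major layouts match the R
// arrays: x is (H, W, C, N); the weight matrix is (k*k*C, F) with patch rows
// ordered row-offset fastest, then column-offset, then channel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col_sample(const double* xs, int H, int W, int C,
                                 int k, int stride, int pad,
                                 int oh, int ow, arma::mat& X) {
  const int P = oh * ow;
  for (int dc = 0; dc < C; ++dc) {
    const double* xc = xs + (std::size_t)dc * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = di + k * dj + k * k * dc;
        for (int oj = 0; oj < ow; ++oj) {
          const int wp = oj * stride + dj - pad;
          const bool wok = wp >= 0 && wp < W;
          for (int oi = 0; oi < oh; ++oi) {
            const int hp = oi * stride + di - pad;
            const int p = oi + oh * oj;
            X.at(row, p) = (wok && hp >= 0 && hp < H)
                             ? xc[hp + (std::size_t)wp * H] : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xdim,
                           const arma::mat& Wm, const arma::vec& b,
                           int k, int stride, int pad, bool relu) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  const int F = Wm.n_cols, P = oh * ow;
  NumericVector out((R_xlen_t)P * F * N);
  out.attr("dim") = IntegerVector::create(oh, ow, F, N);
  arma::mat X(k * k * C, P);
  for (int n = 0; n < N; ++n) {
    im2col_sample(x.begin() + (std::size_t)n * H * W * C, H, W, C, k, stride,
                  pad, oh, ow, X);
    arma::mat O = Wm.t() * X;          // (F, P)
    O.each_col() += b;
    if (relu) O.transform([](double v) { return v > 0 ? v : 0.0; });
    double* op = out.begin() + (std::size_t)n * P * F;
    for (int f = 0; f < F; ++f)
      for (int p = 0; p < P; ++p)
        op[p + (std::size_t)f * P] = O.at(f, p);
  }
  return out;
}

// dout must already be masked by the rectifier derivative.
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, IntegerVector xdim, const arma::mat& Wm,
                  NumericVector dout, int k, int stride, int pad,
                  bool need_dx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  const int F = Wm.n_cols, P = oh * ow, k2C = k * k * C;
  arma::mat dW(k2C, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((R_xlen_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  arma::mat X(k2C, P), dy(F, P);
  for (int n = 0; n < N; ++n) {
    const double* dp = dout.begin() + (std::size_t)n * P * F;
    for (int f = 0; f < F; ++f)
      for (int p = 0; p < P; ++p)
        dy.at(f, p) = dp[p + (std::size_t)f * P];
    im2col_sample(x.begin() + (std::size_t)n * H * W * C, H, W, C, k, stride,
                  pad, oh, ow, X);
    dW += X * dy.t();
    db += arma::sum(dy, 1);
    if (need_dx) {
      arma::mat dcols = Wm * dy;       // (k2C, P)
      double* dxn = dx.begin() + (std::size_t)n * H * W * C;
      for (int dc = 0; dc < C; ++dc) {
        double* dxc = dxn + (std::size_t)dc * H * W;
        for (int dj = 0; dj < k; ++dj) {
          for (int di = 0; di < k; ++di) {
            const int row = di + k * dj + k * k * dc;
            for (int oj = 0; oj < ow; ++oj) {
              const int wp = oj * stride + dj - pad;
              if (wp < 0 || wp >= W) continue;
              for (int oi = 0; oi < oh; ++oi) {
                const int hp = oi * stride + di - pad;
                if (hp < 0 || hp >= H) continue;
                dxc[hp + (std::size_t)wp * H] += dcols.at(row, oi + oh * oj);
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db,
                      _["dx"] = need_dx ? (SEXP)dx : R_NilValue);
}
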