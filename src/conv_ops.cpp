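// Correlation-style 2-D convolution kernels used by the autodiff tape.
// Weight matrix layout: nrow = kh*kw*Cin, ncol = Cout, row index
// r = (ki*kw + kj)*Cin + c with (ki, kj) the kernel offset into the padded
// input (no kernel flip). Output size is H + 2*pad - kh + 1 per dimension,
// so pad = (k-1)/2 gives "same" and pad = 0 gives "valid".
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int kh, int kw, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(Ho * Wo, kh * kw * C, fill::zeros);
  for (int ki = 0; ki < kh; ++ki) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int c = 0; c < C; ++c) {
        const int r = (ki * kw + kj) * C + c;
        const mat& xs = x.slice(c);
        for (int j = 0; j < Wo; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int si = i + ki - pad;
            if (si < 0 || si >= H) continue;
            cols(i + j * Ho, r) = xs(si, sj);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int kh, int kw, int pad) {
  const int Ho = x.n_rows + 2 * pad - kh + 1;
  const int Wo = x.n_cols + 2 * pad - kw + 1;
  const int Cout = w.n_cols;
  if (Ho < 1 || Wo < 1) Rcpp::stop("kernel larger than padded input");
  if ((int)w.n_rows != kh * kw * (int)x.n_slices)
    Rcpp::stop("weight rows do not match kh*kw*Cin");
  mat y = im2col(x, kh, kw, pad, Ho, Wo) * w;
  y.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = reshape(y.col(co), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gy, int kh, int kw, int pad,
                          bool need_gx, bool need_gw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  mat gy_mat(Ho * Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    gy_mat.col(co) = vectorise(gy.slice(co));
  Rcpp::List res;
  if (need_gw) {
    mat cols = im2col(x, kh, kw, pad, Ho, Wo);
    res["gw"] = mat(cols.t() * gy_mat);
    res["gb"] = vec(sum(gy_mat, 0).t());
  }
  if (need_gx) {
    mat gcols = gy_mat * w.t();
    cube gx(H, W, C, fill::zeros);
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        for (int c = 0; c < C; ++c) {
          const int r = (ki * kw + kj) * C + c;
          mat& gxs = gx.slice(c);
          for (int j = 0; j < Wo; ++j) {
            const int sj = j + kj - pad;
            if (sj < 0 || sj >= W) continue;
            for (int i = 0; i < Ho; ++i) {
              const int si = i + ki - pad;
              if (si < 0 || si >= H) continue;
              gxs(si, sj) += gcols(i + j * Ho, r);
            }
          }
        }
      }
    }
    res["gx"] = gx;
  }
  return res;
}
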