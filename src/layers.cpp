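// Minimal conv-net primitives: k x k "same" convolution forward/backward via
// im2col + GEMM. Feature maps are arma::cube (rows, cols, channels), matching
// R arrays dim = c(H, W, C). Weight matrix layout: (k*k*Cin) x Cout, with the
// row index running fastest over the kernel row offset, then kernel column
// offset, then input channel (see im2col below); R-side init must follow it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = k / 2;
  mat cols(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pad;
            if (si < 0 || si >= H) continue;
            cols(i + j * H, col) = x(si, sj, c);
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add of column-space gradients back to image space
static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k) {
  const int pad = k / 2;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pad;
            if (si < 0 || si >= H) continue;
            gx(si, sj, c) += cols(i + j * H, col);
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  if ((int)w.n_rows != k * k * (int)x.n_slices)
    Rcpp::stop("weight shape does not match kernel size / input channels");
  mat y = im2col(x, k) * w;
  y.each_row() += b.t();
  cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.col(c), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& gy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  mat gym(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    gym.col(c) = vectorise(gy.slice(c));
  mat cols = im2col(x, k);
  mat gw = cols.t() * gym;
  vec gb = sum(gym, 0).t();
  cube gx = col2im(gym * w.t(), H, W, Cin, k);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
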