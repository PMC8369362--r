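// Minimal CNN primitives for the grid detector: same-padded k x k
// convolution (im2col + BLAS matmul) and non-overlapping average pooling,
// each with its backward pass. Layout: activations are H x W x C cubes,
// conv weights are (k*k*Cin) x Cout matrices with column index
// q = c*k*k + (dj+p)*k + (di+p), i.e. channel-major, then column offset,
// then row offset.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2, kk = k * k;
  mat cols(H * W, (size_t)kk * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& sl = x.slice(c);
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const int q = c * kk + (dj + p) * k + (di + p);
        double* dst = cols.colptr(q);
        const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        if (i1 < i0) continue;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          std::memcpy(dst + (size_t)j * H + i0,
                      sl.colptr(jj) + i0 + di,
                      sizeof(double) * (i1 - i0 + 1));
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k) {
  const int p = (k - 1) / 2, kk = k * k;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& sl = gx.slice(c);
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const int q = c * kk + (dj + p) * k + (di + p);
        const double* src = cols.colptr(q);
        const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        if (i1 < i0) continue;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          double* dcol = sl.colptr(jj) + di;
          const double* scol = src + (size_t)j * H;
          for (int i = i0; i <= i1; ++i) dcol[i] += scol[i];
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, const int k,
                        const bool relu = false) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_cols;
  mat out = im2col(x, k) * W;
  out.each_row() += b.t();
  if (relu) out.transform([](double v) { return v > 0.0 ? v : 0.0; });
  cube y(H, Wd, Cout);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return y;
}

// concatenate two activation cubes along the channel axis
// [[Rcpp::export]]
arma::cube cpp_concat(const arma::cube& a, const arma::cube& b) {
  return arma::join_slices(a, b);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::cube& x, const arma::mat& W,
                        const arma::cube& gy, const int k) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  mat gym((double*)gy.memptr(), (size_t)H * Wd, Cout, false, true);
  mat cols = im2col(x, k);
  mat gW = cols.t() * gym;
  vec gb = sum(gym, 0).t();
  cube gx = col2im(gym * W.t(), H, Wd, Cin, k);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
arma::cube cpp_avgpool_fwd(const arma::cube& x, const int f) {
  const int H = x.n_rows / f, W = x.n_cols / f, C = x.n_slices;
  cube y(H, W, C, fill::zeros);
  const double inv = 1.0 / (f * f);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double s = 0.0;
        for (int b = 0; b < f; ++b)
          for (int a = 0; a < f; ++a) s += x(i * f + a, j * f + b, c);
        y(i, j, c) = s * inv;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool_bwd(const arma::cube& gy, const int f, const int H,
                           const int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  const double inv = 1.0 / (f * f);
  for (int c = 0; c < C; ++c)
    for (size_t j = 0; j < gy.n_cols; ++j)
      for (size_t i = 0; i < gy.n_rows; ++i) {
        const double g = gy(i, j, c) * inv;
        for (int b = 0; b < f; ++b)
          for (int a = 0; a < f; ++a) gx(i * f + a, j * f + b, c) += g;
      }
  return gx;
}
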