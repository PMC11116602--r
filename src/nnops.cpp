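// Convolutional kernels for the compact detector. Tensors are R arrays
// [H, W, C] (row = y, col = x); weights are [k*k*Cin, Cout] matrices so a
// convolution is one GEMM over an im2col buffer.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// column-major patch layout: index runs over (dy, dx, c)
static mat im2col(const cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  mat cols(k * k * C, (uword)Ho * Wo, fill::zeros);
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const uword col = (uword)ow * Ho + oh;
      const int y0 = oh * stride - pad, x0 = ow * stride - pad;
      double* dst = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int dx = 0; dx < k; ++dx) {
          const int xx = x0 + dx;
          for (int dy = 0; dy < k; ++dy) {
            const int yy = y0 + dy;
            if (yy >= 0 && yy < H && xx >= 0 && xx < W)
              dst[(c * k + dx) * k + dy] = x(yy, xx, c);
          }
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& cols, int H, int W, int C, int k, int stride,
                   int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  cube x(H, W, C, fill::zeros);
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const uword col = (uword)ow * Ho + oh;
      const int y0 = oh * stride - pad, x0 = ow * stride - pad;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int dx = 0; dx < k; ++dx) {
          const int xx = x0 + dx;
          for (int dy = 0; dy < k; ++dy) {
            const int yy = y0 + dy;
            if (yy >= 0 && yy < H && xx >= 0 && xx < W)
              x(yy, xx, c) += src[(c * k + dx) * k + dy];
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = w.n_cols;
  mat cols = im2col(x, k, stride, pad);
  mat y = w.t() * cols;            // [Cout, Ho*Wo]
  y.each_col() += b;
  cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c) {
    mat slice_c(y.row(c).t());
    slice_c.reshape(Ho, Wo);
    out.slice(c) = slice_c;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& dy, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  mat dy_mat(Cout, (uword)Ho * Wo);
  for (int c = 0; c < Cout; ++c) {
    mat s = dy.slice(c);
    s.reshape((uword)Ho * Wo, 1);
    dy_mat.row(c) = s.t();
  }
  mat cols = im2col(x, k, stride, pad);
  mat dw = cols * dy_mat.t();      // [k*k*Cin, Cout]
  vec db = sum(dy_mat, 1);
  mat dcols = w * dy_mat;          // [k*k*Cin, Ho*Wo]
  cube dx = col2im(dcols, H, W, C, k, stride, pad);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}
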