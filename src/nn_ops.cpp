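// Low-level tensor ops for the CNN engine. Tensors are arma::cube with
// dimensions (H, W, C), matching R arrays of dim c(H, W, C). Convolution
// weights are (kh*kw*Cin) x Cout matrices whose row order is
// ki + kh*(kj + kw*c) — i.e. the natural column-major order of an R array
// of dim c(kh, kw, Cin). Stride is always 1 except where noted.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw,
                        int pt, int pl, int ho, int wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(kh * kw * C, (size_t)ho * wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int j = 0; j < wo; ++j) {
          const int xj = j - pl + kj;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < ho; ++i) {
            const int xi = i - pt + ki;
            if (xi < 0 || xi >= H) continue;
            cols(r, (size_t)i + (size_t)ho * j) = x(xi, xj, c);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add(arma::cube& gx, const arma::mat& cols, int kh, int kw,
                       int pt, int pl, int ho, int wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int j = 0; j < wo; ++j) {
          const int xj = j - pl + kj;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < ho; ++i) {
            const int xi = i - pt + ki;
            if (xi < 0 || xi >= H) continue;
            gx(xi, xj, c) += cols(r, (size_t)i + (size_t)ho * j);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cq_conv_fwd(const arma::cube& x, const arma::mat& W,
                       const arma::vec& b, int kh, int kw,
                       int pt, int pl, int pb, int pr) {
  const int ho = x.n_rows + pt + pb - kh + 1;
  const int wo = x.n_cols + pl + pr - kw + 1;
  arma::mat cols = im2col(x, kh, kw, pt, pl, ho, wo);
  arma::mat out = cols.t() * W;              // (ho*wo) x Cout
  out.each_row() += b.t();
  arma::cube y(ho, wo, W.n_cols);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return y;
}

// [[Rcpp::export]]
List cq_conv_bwd(const arma::cube& x, const arma::mat& W,
                 const arma::cube& gy, int kh, int kw,
                 int pt, int pl, int pb, int pr) {
  const int ho = gy.n_rows, wo = gy.n_cols, Cout = gy.n_slices;
  arma::mat gmat((double*)gy.memptr(), (size_t)ho * wo, Cout);
  arma::mat cols = im2col(x, kh, kw, pt, pl, ho, wo);
  arma::mat gW = cols * gmat;
  arma::vec gb = arma::sum(gmat, 0).t();
  arma::mat gcols = W * gmat.t();            // K x (ho*wo)
  arma::cube gx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  col2im_add(gx, gcols, kh, kw, pt, pl, ho, wo);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled cube and 1-based argmax
// linear indices into the input cube (for the backward pass).
// [[Rcpp::export]]
List cq_pool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ho = H / 2, wo = W / 2;
  arma::cube y(ho, wo, C);
  IntegerVector idx((size_t)ho * wo * C);
  size_t q = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < ho; ++i) {
        double best = -1e300; int bi = 0, bj = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        y(i, j, c) = best;
        idx[q++] = 1 + bi + H * (bj + (size_t)W * c);
      }
  // arma fills column-major in same (i, j, c) order as the loop
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cq_pool_bwd(const arma::cube& gy, const IntegerVector& idx,
                       int H, int W) {
  arma::cube gx(H, W, gy.n_slices, arma::fill::zeros);
  const double* g = gy.memptr();
  for (size_t q = 0; q < (size_t)idx.size(); ++q)
    gx.memptr()[idx[q] - 1] += g[q];
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
arma::cube cq_up_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cq_up_bwd(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  arma::cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}

// 2x2 transposed convolution, stride 2: output is exactly (2H, 2W).
// Weight layout: (2*2*Cin) x Cout with row order ki + 2*(kj + 2*c).
// [[Rcpp::export]]
arma::cube cq_tconv_fwd(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  arma::cube y(2 * H, 2 * Wd, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co).fill(b(co));
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < 2; ++kj)
        for (int ki = 0; ki < 2; ++ki) {
          const double w = W(ki + 2 * (kj + 2 * c), co);
          if (w == 0.0) continue;
          for (int j = 0; j < Wd; ++j)
            for (int i = 0; i < H; ++i)
              y(2 * i + ki, 2 * j + kj, co) += w * x(i, j, c);
        }
  return y;
}

// [[Rcpp::export]]
List cq_tconv_bwd(const arma::cube& x, const arma::mat& W,
                  const arma::cube& gy) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  arma::cube gx(H, Wd, Cin, arma::fill::zeros);
  arma::mat gW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) gb(co) = arma::accu(gy.slice(co));
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < 2; ++kj)
        for (int ki = 0; ki < 2; ++ki) {
          const int r = ki + 2 * (kj + 2 * c);
          const double w = W(r, co);
          double acc = 0.0;
          for (int j = 0; j < Wd; ++j)
            for (int i = 0; i < H; ++i) {
              const double g = gy(2 * i + ki, 2 * j + kj, co);
              acc += g * x(i, j, c);
              gx(i, j, c) += w * g;
            }
          gW(r, co) += acc;
        }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
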