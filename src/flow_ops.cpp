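// Flow-field construction from instance masks and flow-following
// post-processing that clusters pixels into instances.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Diffusion-from-median-centre flows. For every labelled object a heat
// source is placed at its medoid pixel and diffused (Jacobi iterations)
// inside the object; the per-pixel flow is the normalised spatial gradient
// of log(1 + T). prob is 1 inside objects, 0 outside.
// [[Rcpp::export]]
List cq_masks_to_flows(const IntegerMatrix& labels) {
  const int H = labels.nrow(), W = labels.ncol();
  NumericMatrix dy(H, W), dx(H, W), prob(H, W);
  int K = 0;
  for (int q = 0; q < H * W; ++q) K = std::max(K, labels[q]);
  if (K == 0)
    return List::create(_["prob"] = prob, _["dy"] = dy, _["dx"] = dx);

  std::vector<std::vector<int> > py(K + 1), px(K + 1);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int l = labels(i, j);
      if (l > 0) { py[l].push_back(i); px[l].push_back(j); prob(i, j) = 1.0; }
    }

  for (int l = 1; l <= K; ++l) {
    const size_t n = py[l].size();
    if (n == 0) continue;
    int y0 = H, y1 = -1, x0 = W, x1 = -1;
    for (size_t q = 0; q < n; ++q) {
      y0 = std::min(y0, py[l][q]); y1 = std::max(y1, py[l][q]);
      x0 = std::min(x0, px[l][q]); x1 = std::max(x1, px[l][q]);
    }
    const int bh = y1 - y0 + 3, bw = x1 - x0 + 3;  // 1-px padding ring
    // medoid: object pixel closest to the coordinate medians
    std::vector<int> ys(py[l]), xs(px[l]);
    std::nth_element(ys.begin(), ys.begin() + n / 2, ys.end());
    std::nth_element(xs.begin(), xs.begin() + n / 2, xs.end());
    const double my = ys[n / 2], mx = xs[n / 2];
    size_t ci = 0; double best = 1e300;
    for (size_t q = 0; q < n; ++q) {
      double d = (py[l][q] - my) * (py[l][q] - my) +
                 (px[l][q] - mx) * (px[l][q] - mx);
      if (d < best) { best = d; ci = q; }
    }
    const int cy = py[l][ci] - y0 + 1, cx = px[l][ci] - x0 + 1;

    arma::mat T(bh, bw, arma::fill::zeros), M(bh, bw, arma::fill::zeros);
    for (size_t q = 0; q < n; ++q)
      M(py[l][q] - y0 + 1, px[l][q] - x0 + 1) = 1.0;
    const int n_iter = 2 * (bh + bw);
    arma::mat Tn(bh, bw, arma::fill::zeros);
    for (int it = 0; it < n_iter; ++it) {
      T(cy, cx) += 1.0;
      for (int j = 1; j < bw - 1; ++j)
        for (int i = 1; i < bh - 1; ++i)
          Tn(i, j) = M(i, j) == 1.0
            ? (T(i, j) + T(i - 1, j) + T(i + 1, j) +
               T(i, j - 1) + T(i, j + 1)) / 5.0
            : 0.0;
      T.swap(Tn);
    }
    T = arma::log1p(T);
    for (size_t q = 0; q < n; ++q) {
      const int i = py[l][q] - y0 + 1, j = px[l][q] - x0 + 1;
      double gy = T(i + 1, j) - T(i - 1, j);
      double gx = T(i, j + 1) - T(i, j - 1);
      const double nrm = std::sqrt(gy * gy + gx * gx);
      if (nrm > 1e-12) { gy /= nrm; gx /= nrm; }
      dy(py[l][q], px[l][q]) = gy;
      dx(py[l][q], px[l][q]) = gx;
    }
  }
  return List::create(_["prob"] = prob, _["dy"] = dy, _["dx"] = dx);
}

static inline double bilin(const NumericMatrix& f, double y, double x) {
  const int H = f.nrow(), W = f.ncol();
  if (y < 0) y = 0; if (y > H - 1) y = H - 1;
  if (x < 0) x = 0; if (x > W - 1) x = W - 1;
  const int i0 = (int)std::floor(y), j0 = (int)std::floor(x);
  const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
  const double fy = y - i0, fx = x - j0;
  return f(i0, j0) * (1 - fy) * (1 - fx) + f(i1, j0) * fy * (1 - fx) +
         f(i0, j1) * (1 - fy) * fx + f(i1, j1) * fy * fx;
}

// Advect thresholded pixels along the flow field, histogram the converged
// positions, find local-maximum seeds, expand seed regions over the
// histogram and assign each pixel the label of the cell its trajectory
// landed in. Contested seeds resolve to the lowest label id.
// [[Rcpp::export]]
IntegerMatrix cq_follow_flows(const NumericMatrix& prob,
                              const NumericMatrix& dy,
                              const NumericMatrix& dx,
                              double prob_threshold, int n_steps,
                              double step_size, int seed_min_count,
                              int expand_iters) {
  const int H = prob.nrow(), W = prob.ncol();
  std::vector<int> fy, fx;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (prob(i, j) >= prob_threshold) { fy.push_back(i); fx.push_back(j); }
  IntegerMatrix out(H, W);
  const size_t n = fy.size();
  if (n == 0) return out;

  std::vector<double> py(n), px(n);
  for (size_t q = 0; q < n; ++q) { py[q] = fy[q]; px[q] = fx[q]; }
  for (int s = 0; s < n_steps; ++s)
    for (size_t q = 0; q < n; ++q) {
      const double vy = bilin(dy, py[q], px[q]);
      const double vx = bilin(dx, py[q], px[q]);
      py[q] += step_size * vy; px[q] += step_size * vx;
      if (py[q] < 0) py[q] = 0; if (py[q] > H - 1) py[q] = H - 1;
      if (px[q] < 0) px[q] = 0; if (px[q] > W - 1) px[q] = W - 1;
    }

  // histogram of landing positions
  IntegerMatrix hist(H, W);
  std::vector<int> ly(n), lx(n);
  for (size_t q = 0; q < n; ++q) {
    ly[q] = (int)std::lround(py[q]); lx[q] = (int)std::lround(px[q]);
    hist(ly[q], lx[q]) += 1;
  }
  // seeds: 3x3 local maxima with enough mass; row-major scan order makes
  // the lowest label id win deterministic ties
  IntegerMatrix cell_lab(H, W);
  int K = 0;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      const int h = hist(i, j);
      if (h < seed_min_count) continue;
      bool is_max = true;
      for (int di = -1; di <= 1 && is_max; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || jj < 0 || ii >= H || jj >= W) continue;
          if (di == 0 && dj == 0) continue;
          if (hist(ii, jj) > h ||
              (hist(ii, jj) == h && (ii < i || (ii == i && jj < j)))) {
            is_max = false; break;
          }
        }
      if (is_max) cell_lab(i, j) = ++K;
    }
  if (K == 0) return out;
  // grow seed regions over histogram cells that attracted pixels
  for (int it = 0; it < expand_iters; ++it) {
    IntegerMatrix nxt = clone(cell_lab);
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j) {
        if (cell_lab(i, j) != 0 || hist(i, j) < 1) continue;
        int lab = 0;
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            const int ii = i + di, jj = j + dj;
            if (ii < 0 || jj < 0 || ii >= H || jj >= W) continue;
            const int l = cell_lab(ii, jj);
            if (l > 0 && (lab == 0 || l < lab)) lab = l;
          }
        if (lab > 0) nxt(i, j) = lab;
      }
    cell_lab = nxt;
  }
  for (size_t q = 0; q < n; ++q)
    out(fy[q], fx[q]) = cell_lab(ly[q], lx[q]);
  return out;
}
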