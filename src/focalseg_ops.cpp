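// Low-level numerical kernels: 2-D convolution (im2col based) with its
// adjoints, max-pooling with argmax bookkeeping, exhaustive Gini split
// search for classification trees, and boundary matching for the BF score.
// Everything operates on R arrays in column-major (H, W, C) layout.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::cube to_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  arma::cube c(x.begin(), d[0], d[1], d[2]);
  return c;
}

static arma::cube pad_cube(const arma::cube& x, int pad) {
  if (pad == 0) return x;
  arma::cube xp(x.n_rows + 2 * pad, x.n_cols + 2 * pad, x.n_slices,
                arma::fill::zeros);
  xp.subcube(pad, pad, 0, pad + x.n_rows - 1, pad + x.n_cols - 1,
             x.n_slices - 1) = x;
  return xp;
}

// loop order chosen so writes to `cols` are fully contiguous (column by
// column); reads hit a small sliding window of the padded input
static arma::mat im2col(const arma::cube& xp, int kh, int kw, int stride,
                        int Ho, int Wo) {
  const int C = xp.n_slices;
  arma::mat cols(kh * kw * C, (size_t)Ho * Wo);
  double* out = cols.memptr();
  const double* in = xp.memptr();
  const size_t Hp = xp.n_rows, plane = (size_t)xp.n_rows * xp.n_cols;
  size_t q = 0;
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i) {
      const int r0 = i * stride, c0 = j * stride;
      for (int c = 0; c < C; ++c) {
        const double* base = in + (size_t)c * plane + (size_t)c0 * Hp + r0;
        for (int dj = 0; dj < kw; ++dj) {
          const double* col = base + (size_t)dj * Hp;
          for (int di = 0; di < kh; ++di) out[q++] = col[di];
        }
      }
    }
  return cols;
}

// adjoint of im2col: scatter-add columns back into the padded image
static arma::cube col2im(const arma::mat& cols, int Hp, int Wp, int C, int kh,
                         int kw, int stride, int Ho, int Wo) {
  arma::cube xp(Hp, Wp, C, arma::fill::zeros);
  double* in = xp.memptr();
  const double* src = cols.memptr();
  const size_t plane = (size_t)Hp * Wp;
  size_t q = 0;
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i) {
      const int r0 = i * stride, c0 = j * stride;
      for (int c = 0; c < C; ++c) {
        double* base = in + (size_t)c * plane + (size_t)c0 * Hp + r0;
        for (int dj = 0; dj < kw; ++dj) {
          double* col = base + (size_t)dj * Hp;
          for (int di = 0; di < kh; ++di) col[di] += src[q++];
        }
      }
    }
  return xp;
}

// weight array w has dim (kh, kw, C_in, F); reshaped to (F x kh*kw*C_in)
static arma::mat weight_mat(const NumericVector& w, int kh, int kw, int C,
                            int F) {
  arma::mat W(F, kh * kw * C);
  const double* p = w.begin();
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di)
          W(f, di + kh * (dj + kw * c)) =
              p[di + kh * ((size_t)dj + kw * ((size_t)c + (size_t)C * f))];
  return W;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  arma::cube xc = to_cube(x);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], C = wd[2], F = wd[3];
  if ((int)xc.n_slices != C) stop("channel mismatch between input and kernel");
  arma::cube xp = pad_cube(xc, pad);
  const int Ho = (int)((xp.n_rows - kh) / stride) + 1;
  const int Wo = (int)((xp.n_cols - kw) / stride) + 1;
  arma::mat cols = im2col(xp, kh, kw, stride, Ho, Wo);
  arma::mat W = weight_mat(w, kh, kw, C, F);
  arma::mat out = W * cols;  // F x (Ho*Wo)
  out.each_col() += arma::vec(b.begin(), F);
  NumericVector y(Ho * (size_t)Wo * F);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F);
  double* py = y.begin();
  const double* po = out.memptr();  // F x (Ho*Wo), column-major
  for (size_t q = 0; q < (size_t)Ho * Wo; ++q)
    for (int f = 0; f < F; ++f)
      py[q + (size_t)Ho * Wo * f] = po[f + (size_t)F * q];
  return y;
}

static arma::mat grad_mat(const arma::cube& gyc, int F) {
  const size_t plane = (size_t)gyc.n_rows * gyc.n_cols;
  arma::mat G(F, plane);
  const double* in = gyc.memptr();
  for (int f = 0; f < F; ++f)
    for (size_t q = 0; q < plane; ++q) G(f, q) = in[q + plane * f];
  return G;
}

// gradient of conv output w.r.t. its input; also the forward map of a
// transposed convolution with the same kernel/stride (crop = pad)
// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_input(NumericVector w, NumericVector gy, int H,
                                   int W, int stride, int pad) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], C = wd[2], F = wd[3];
  arma::cube gyc = to_cube(gy);
  const int Ho = gyc.n_rows, Wo = gyc.n_cols;
  arma::mat Wm = weight_mat(w, kh, kw, C, F);
  arma::mat G = grad_mat(gyc, F);
  arma::mat gcols = Wm.t() * G;  // kh*kw*C x Ho*Wo
  arma::cube gxp =
      col2im(gcols, H + 2 * pad, W + 2 * pad, C, kh, kw, stride, Ho, Wo);
  arma::cube gx = (pad == 0)
                      ? gxp
                      : arma::cube(gxp.subcube(pad, pad, 0, pad + H - 1,
                                               pad + W - 1, C - 1));
  return wrap(gx);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd_filter(NumericVector x, NumericVector gy, int kh, int kw,
                           int stride, int pad) {
  arma::cube xc = to_cube(x);
  const int C = xc.n_slices;
  arma::cube gyc = to_cube(gy);
  const int Ho = gyc.n_rows, Wo = gyc.n_cols, F = gyc.n_slices;
  arma::cube xp = pad_cube(xc, pad);
  arma::mat cols = im2col(xp, kh, kw, stride, Ho, Wo);
  arma::mat G = grad_mat(gyc, F);
  arma::mat gW = G * cols.t();     // F x kh*kw*C
  arma::vec gb = arma::sum(G, 1);  // F

  NumericVector gwv((size_t)kh * kw * C * F);
  gwv.attr("dim") = IntegerVector::create(kh, kw, C, F);
  double* pw = gwv.begin();
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di)
          pw[di + kh * ((size_t)dj + kw * ((size_t)c + (size_t)C * f))] =
              gW(f, di + kh * (dj + kw * c));

  return List::create(_["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int size, int stride) {
  arma::cube xc = to_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = (H - size) / stride + 1, Wo = (W - size) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C);
  IntegerVector amax((size_t)Ho * Wo * C);  // 0-based linear index into (H,W,C)
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  amax.attr("dim") = IntegerVector::create(Ho, Wo, C);
  size_t q = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i, ++q) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0, bj = 0;
        for (int dj = 0; dj < size; ++dj)
          for (int di = 0; di < size; ++di) {
            double v = xc(i * stride + di, j * stride + dj, c);
            if (v > best) { best = v; bi = i * stride + di; bj = j * stride + dj; }
          }
        // column-major order (i fastest) but q runs i fastest within j within c,
        // which is exactly R's array order for (Ho, Wo, C)
        y[q] = best;
        amax[q] = bi + H * (bj + (size_t)W * c);
      }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector amax, int H,
                              int W, int C) {
  NumericVector gx((size_t)H * W * C);
  gx.attr("dim") = IntegerVector::create(H, W, C);
  for (R_xlen_t q = 0; q < gy.size(); ++q) gx[amax[q]] += gy[q];
  return gx;
}

// Exhaustive weighted-Gini split search for a binary target.
// Returns feature index (1-based), threshold (midpoint between adjacent
// distinct values), and impurity decrease; feature 0 when no split helps.
// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, IntegerVector y, NumericVector w) {
  const int n = X.nrow(), p = X.ncol();
  double wtot = 0, w1tot = 0;
  for (int i = 0; i < n; ++i) { wtot += w[i]; if (y[i] == 1) w1tot += w[i]; }
  if (wtot <= 0) return List::create(_["feature"] = 0);
  const double pr1 = w1tot / wtot;
  const double parent = 2.0 * pr1 * (1.0 - pr1);  // Gini for 2 classes
  double best_gain = 0.0, best_thr = 0.0;
  int best_f = 0;
  std::vector<int> ord(n);
  std::vector<double> v(n);
  for (int f = 0; f < p; ++f) {
    NumericMatrix::Column col = X(_, f);
    for (int i = 0; i < n; ++i) { ord[i] = i; v[i] = col[i]; }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return v[a] < v[b]; });
    double wl = 0, wl1 = 0;
    for (int t = 0; t < n - 1; ++t) {
      const int i = ord[t];
      wl += w[i];
      if (y[i] == 1) wl1 += w[i];
      const double va = v[ord[t]], vb = v[ord[t + 1]];
      if (vb <= va) continue;  // not a distinct-value boundary
      const double wr = wtot - wl, wr1 = w1tot - wl1;
      if (wl <= 0 || wr <= 0) continue;
      const double pl = wl1 / wl, prr = wr1 / wr;
      const double g = parent - (wl / wtot) * 2.0 * pl * (1.0 - pl) -
                       (wr / wtot) * 2.0 * prr * (1.0 - prr);
      if (g > best_gain + 1e-12) {
        best_gain = g;
        best_f = f + 1;
        best_thr = va + (vb - va) / 2.0;
      }
    }
  }
  return List::create(_["feature"] = best_f, _["threshold"] = best_thr,
                      _["gain"] = best_gain);
}

// Fraction of points in A (rows: row,col coords) having a point of B within
// Euclidean distance tol.  Used by the boundary-F1 segmentation score.
// [[Rcpp::export]]
double cpp_match_fraction(NumericMatrix A, NumericMatrix B, double tol) {
  const int na = A.nrow(), nb = B.nrow();
  if (na == 0) return NA_REAL;
  if (nb == 0) return 0.0;
  const double t2 = tol * tol;
  int matched = 0;
  for (int i = 0; i < na; ++i) {
    const double ar = A(i, 0), ac = A(i, 1);
    for (int j = 0; j < nb; ++j) {
      const double dr = ar - B(j, 0), dc = ac - B(j, 1);
      if (dr * dr + dc * dc <= t2) { ++matched; break; }
    }
  }
  return (double)matched / na;
}
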