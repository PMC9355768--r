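// Low-level numeric kernels: im2col/col2im convolutions (GEMM-backed),
// 2x2 max pooling, connected-component labelling, coordinate-map warping
// and separable Gaussian blur. All array arguments follow R's column-major
// layout with image tensors shaped (H, W, C, N) and convolution weights
// (k, k, Cin, Cout); transposed-convolution weights are (k, k, Cout, Cin).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// cols layout: row = ki + k*kj + k*k*c ; col = io + Ho*jo
static void im2col_slice(const double* x, int H, int W, int C,
                         int k, int stride, int pad, arma::mat& cols) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jin = jo * stride - pad + kj;
          double* dst = cols.memptr() + (size_t)cols.n_rows * Ho * jo + r;
          if (jin < 0 || jin >= W) {
            for (int io = 0; io < Ho; ++io) dst[(size_t)cols.n_rows * io] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)H * jin;
          for (int io = 0; io < Ho; ++io) {
            const int iin = io * stride - pad + ki;
            dst[(size_t)cols.n_rows * io] =
              (iin >= 0 && iin < H) ? src[iin] : 0.0;
          }
        }
      }
    }
  }
}

// adjoint of im2col_slice: scatter-add cols back into an (H, W, C) slice
static void col2im_slice(const arma::mat& cols, double* x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jin = jo * stride - pad + kj;
          if (jin < 0 || jin >= W) continue;
          double* dstcol = xc + (size_t)H * jin;
          const double* src = cols.memptr() + r;
          for (int io = 0; io < Ho; ++io) {
            const int iin = io * stride - pad + ki;
            if (iin >= 0 && iin < H)
              dstcol[iin] += src[(size_t)cols.n_rows * (io + (size_t)Ho * jo)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  arma::mat cols(k * k * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col_slice(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, cols);
    arma::mat yn(y.begin() + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    yn = cols.t() * Wm;
    yn.each_row() += bv;
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  NumericVector gx((size_t)H * W * C * N);
  NumericVector gw((size_t)k * k * C * Cout);
  NumericVector gb(Cout);
  arma::mat gwm(gw.begin(), k * k * C, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);
  arma::mat cols(k * k * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    arma::mat gyn(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * Cout * n,
                  (size_t)Ho * Wo, Cout, false, true);
    im2col_slice(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, cols);
    gwm += cols * gyn;
    gbv += arma::sum(gyn, 0).t();
    arma::mat gcols = Wm * gyn.t();
    col2im_slice(gcols, gx.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad);
  }
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// transposed convolution, weights (k, k, Cout, Cin); output (H-1)*stride + k
// [[Rcpp::export]]
NumericVector cpp_tconv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                             int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[2];
  const int Ho = (H - 1) * stride + k;
  const int Wo = (W - 1) * stride + k;
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cout, Cin, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  for (int n = 0; n < N; ++n) {
    arma::mat xn(const_cast<double*>(x.begin()) + (size_t)H * W * Cin * n,
                 (size_t)H * W, Cin, false, true);
    arma::mat gcols = Wm * xn.t();  // (k*k*Cout) x (H*W)
    col2im_slice(gcols, y.begin() + (size_t)Ho * Wo * Cout * n,
                 Ho, Wo, Cout, k, stride, 0);
  }
  // bias per output channel
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)Cout * n);
      const double bc = b[c];
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t) yc[t] += bc;
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_tconv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                    int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[2];
  const int Ho = (H - 1) * stride + k;
  const int Wo = (W - 1) * stride + k;
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cout, Cin, false, true);
  NumericVector gx((size_t)H * W * Cin * N), gw((size_t)k * k * Cout * Cin), gb(Cout);
  arma::mat gwm(gw.begin(), k * k * Cout, Cin, false, true);
  arma::mat cols(k * k * Cout, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col_slice(gy.begin() + (size_t)Ho * Wo * Cout * n,
                 Ho, Wo, Cout, k, stride, 0, cols);
    arma::mat xn(const_cast<double*>(x.begin()) + (size_t)H * W * Cin * n,
                 (size_t)H * W, Cin, false, true);
    arma::mat gxn(gx.begin() + (size_t)H * W * Cin * n,
                  (size_t)H * W, Cin, false, true);
    gxn = cols.t() * Wm;
    gwm += cols * xn;
    for (int c = 0; c < Cout; ++c) {
      const double* gyc = gy.begin() + (size_t)Ho * Wo * (c + (size_t)Cout * n);
      double s = 0.0;
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t) s += gyc[t];
      gb[c] += s;
    }
  }
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0-based linear index into x
  size_t t = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io, ++t) {
          double best = -1e300; size_t bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const size_t li = base + (2 * io + di) + (size_t)H * (2 * jo + dj);
              if (x[li] > best) { best = x[li]; bi = li; }
            }
          // column-major order over (io, jo, c, n) matches t's increment only
          // if we write explicitly:
          const size_t yo = (size_t)Ho * Wo * (c + (size_t)C * n) + io + (size_t)Ho * jo;
          y[yo] = best; idx[yo] = (int)bi;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t t = 0; t < gy.size(); ++t) gx[idx[t]] += gy[t];
  gx.attr("dim") = xdim;
  return gx;
}

// BFS labelling; connectivity 4 or 8; labels 1..K, background 0
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int di8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dj8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(i + H * j);
      while (!q.empty()) {
        const int p = q.front(); q.pop();
        const int pi = p % H, pj = p / H;
        for (int d = 0; d < nn; ++d) {
          const int ni = pi + di8[d], nj = pj + dj8[d];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push(ni + H * nj);
          }
        }
      }
    }
  return lab;
}

static inline double reflect_coord(double t, int n) {
  if (n == 1) return 1.0;
  const double period = 2.0 * (n - 1);
  t = t - 1.0;
  t -= period * std::floor(t / period);
  if (t > n - 1) t = period - t;
  return t + 1.0;
}

// sample a single-channel image at (mapr, mapc) source coordinates (1-based);
// border handled by mirror reflection; method 0 = nearest, 1 = bilinear
// [[Rcpp::export]]
NumericMatrix cpp_warp2d(NumericMatrix img, NumericMatrix mapr,
                         NumericMatrix mapc, int method) {
  const int H = img.nrow(), W = img.ncol();
  const int Ho = mapr.nrow(), Wo = mapr.ncol();
  NumericMatrix out(Ho, Wo);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i) {
      double r = reflect_coord(mapr(i, j), H);
      double c = reflect_coord(mapc(i, j), W);
      if (method == 0) {
        int ri = (int)std::lround(r) - 1, ci = (int)std::lround(c) - 1;
        if (ri < 0) ri = 0; if (ri >= H) ri = H - 1;
        if (ci < 0) ci = 0; if (ci >= W) ci = W - 1;
        out(i, j) = img(ri, ci);
      } else {
        const int r0 = std::min(std::max((int)std::floor(r) - 1, 0), H - 1);
        const int c0 = std::min(std::max((int)std::floor(c) - 1, 0), W - 1);
        const int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
        const double fr = r - 1 - r0, fc = c - 1 - c0;
        out(i, j) = (1 - fr) * (1 - fc) * img(r0, c0) + fr * (1 - fc) * img(r1, c0)
                  + (1 - fr) * fc * img(r0, c1) + fr * fc * img(r1, c1);
      }
    }
  return out;
}

// separable Gaussian blur with mirror borders
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + rad];
  }
  for (auto& v : ker) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double a = 0.0;
      for (int t = -rad; t <= rad; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii;
        if (ii >= H) ii = 2 * H - 2 - ii;
        if (ii < 0) ii = 0;  // degenerate H == 1
        a += ker[t + rad] * img(ii, j);
      }
      tmp(i, j) = a;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double a = 0.0;
      for (int t = -rad; t <= rad; ++t) {
        int jj = j + t;
        if (jj < 0) jj = -jj;
        if (jj >= W) jj = 2 * W - 2 - jj;
        if (jj < 0) jj = 0;
        a += ker[t + rad] * tmp(i, jj);
      }
      out(i, j) = a;
    }
  return out;
}
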