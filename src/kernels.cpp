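// Low-level numerical kernels for the CNN engine.
// Tensor layout everywhere: column-major 4D array (H, W, C, N).
// Weight layout: (k, k, Cin, Cout).  All kernels are single-threaded and
// deterministic so seeded runs are bit-reproducible.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

// Unpack one sample into the im2col matrix (k*k*C rows, Ho*Wo cols).
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, arma::mat& col) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * c;
        for (int ow = 0; ow < Wo; ++ow) {
          const int w = ow * stride + kw - pad;
          for (int oh = 0; oh < Ho; ++oh) {
            const int h = oh * stride + kh - pad;
            double v = 0.0;
            if (h >= 0 && h < H && w >= 0 && w < W)
              v = x[h + (size_t)H * (w + (size_t)W * c)];
            col(r, oh + (size_t)Ho * ow) = v;
          }
        }
      }
    }
  }
}

static void col2im_add(double* gx, int H, int W, int C,
                       int k, int stride, int pad, const arma::mat& gcol) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * c;
        for (int ow = 0; ow < Wo; ++ow) {
          const int w = ow * stride + kw - pad;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            const int h = oh * stride + kh - pad;
            if (h < 0 || h >= H) continue;
            gx[h + (size_t)H * (w + (size_t)W * c)] +=
              gcol(r, oh + (size_t)Ho * ow);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");

  arma::mat Wm(Cout, k * k * Cin);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          Wm(co, kh + k * kw + k * k * c) =
            w[kh + (size_t)k * (kw + (size_t)k * (c + (size_t)Cin * co))];

  NumericVector y(
      (R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(k * k * Cin, (size_t)Ho * Wo);
  const size_t xstride = (size_t)H * W * C;
  const size_t ystride = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + n * xstride, H, W, C, k, stride, pad, col);
    arma::mat Y = Wm * col;  // (Cout, Ho*Wo)
    double* yp = &y[0] + n * ystride;
    for (int co = 0; co < Cout; ++co)
      for (size_t j = 0; j < (size_t)Ho * Wo; ++j)
        yp[j + (size_t)Ho * Wo * co] = Y(co, j) + b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);

  arma::mat Wm(Cout, k * k * Cin);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          Wm(co, kh + k * kw + k * k * c) =
            w[kh + (size_t)k * (kw + (size_t)k * (c + (size_t)Cin * co))];

  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat gWm(Cout, k * k * Cin, arma::fill::zeros);
  NumericVector gb(Cout);
  arma::mat col(k * k * Cin, (size_t)Ho * Wo);
  arma::mat gyM(Cout, (size_t)Ho * Wo);
  const size_t xstride = (size_t)H * W * C;
  const size_t ystride = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    const double* gyp = &gy[0] + n * ystride;
    for (int co = 0; co < Cout; ++co)
      for (size_t j = 0; j < (size_t)Ho * Wo; ++j)
        gyM(co, j) = gyp[j + (size_t)Ho * Wo * co];
    im2col(&x[0] + n * xstride, H, W, C, k, stride, pad, col);
    gWm += gyM * col.t();
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(gyM.row(co));
    arma::mat gcol = Wm.t() * gyM;
    col2im_add(&gx[0] + n * xstride, H, W, C, k, stride, pad, gcol);
  }

  NumericVector gw((R_xlen_t)k * k * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          gw[kh + (size_t)k * (kw + (size_t)k * (c + (size_t)Cin * co))] =
            gWm(co, kh + k * kw + k * k * c);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2 (H, W must be even).
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = &x[0] + (size_t)H * W * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double best = -INFINITY; int bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const int h = 2 * oh + dh, w = 2 * ow + dw;
              const double v = xp[h + (size_t)H * w];
              if (v > best) { best = v; bi = h + H * w; }
            }
          // column-major output: (oh, ow) for channel c, sample n
          const size_t yi = (size_t)oh + (size_t)Ho * ow +
                            (size_t)Ho * Wo * (c + (size_t)C * n);
          y[yi] = best; idx[yi] = bi; ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(IntegerVector idx, NumericVector gy,
                              int H, int W) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gxp = &gx[0] + (size_t)H * W * (c + (size_t)C * n);
      const size_t base = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (size_t j = 0; j < (size_t)Ho * Wo; ++j)
        gxp[idx[base + j]] += gy[base + j];
    }
  return gx;
}

// 2x2 average pooling, stride 2.
// [[Rcpp::export]]
NumericVector cpp_avgpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = &x[0] + (size_t)H * W * (c + (size_t)C * n);
      double* yp = &y[0] + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double s = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              s += xp[(2 * oh + dh) + (size_t)H * (2 * ow + dw)];
          yp[oh + (size_t)Ho * ow] = 0.25 * s;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bw(NumericVector gy, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gxp = &gx[0] + (size_t)H * W * (c + (size_t)C * n);
      const double* gyp = &gy[0] + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          const double g = 0.25 * gyp[oh + (size_t)Ho * ow];
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              gxp[(2 * oh + dh) + (size_t)H * (2 * ow + dw)] += g;
        }
    }
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = &x[0] + (size_t)H * W * (c + (size_t)C * n);
      double* yp = &y[0] + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = xp[h + (size_t)H * w];
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              yp[(2 * h + dh) + (size_t)Ho * (2 * w + dw)] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector gy) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gxp = &gx[0] + (size_t)H * W * (c + (size_t)C * n);
      const double* gyp = &gy[0] + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double s = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              s += gyp[(2 * h + dh) + (size_t)Ho * (2 * w + dw)];
          gxp[h + (size_t)H * w] = s;
        }
    }
  return gx;
}

// ---------------------------------------------------------------------------
// Canny edge detection: Gaussian smoothing, Sobel gradients, non-maximum
// suppression quantised to 4 directions, double threshold + hysteresis.
// low/high are thresholds relative to the maximum gradient magnitude of
// the image, so the edge map is invariant under positive affine intensity
// changes.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_canny(NumericMatrix img, double low, double high,
                        double sigma) {
  const int H = img.nrow(), W = img.ncol();
  // separable Gaussian blur with reflected borders
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> g(2 * rad + 1);
  double gs = 0;
  for (int i = -rad; i <= rad; ++i) {
    g[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    gs += g[i + rad];
  }
  for (auto& v : g) v /= gs;
  NumericMatrix tmp(H, W), sm(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double s = 0;
      for (int i = -rad; i <= rad; ++i) {
        int hh = h + i;
        if (hh < 0) hh = -hh - 1;
        if (hh >= H) hh = 2 * H - hh - 1;
        s += g[i + rad] * img(hh, w);
      }
      tmp(h, w) = s;
    }
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double s = 0;
      for (int i = -rad; i <= rad; ++i) {
        int ww = w + i;
        if (ww < 0) ww = -ww - 1;
        if (ww >= W) ww = 2 * W - ww - 1;
        s += g[i + rad] * tmp(h, ww);
      }
      sm(h, w) = s;
    }
  // Sobel
  NumericMatrix mag(H, W);
  std::vector<double> dx((size_t)H * W), dy((size_t)H * W);
  auto at = [&](int h, int w) {
    h = std::min(std::max(h, 0), H - 1);
    w = std::min(std::max(w, 0), W - 1);
    return sm(h, w);
  };
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const double gx = (at(h - 1, w + 1) + 2 * at(h, w + 1) + at(h + 1, w + 1)) -
                        (at(h - 1, w - 1) + 2 * at(h, w - 1) + at(h + 1, w - 1));
      const double gyv = (at(h + 1, w - 1) + 2 * at(h + 1, w) + at(h + 1, w + 1)) -
                         (at(h - 1, w - 1) + 2 * at(h - 1, w) + at(h - 1, w + 1));
      dx[h + (size_t)H * w] = gx;
      dy[h + (size_t)H * w] = gyv;
      mag(h, w) = std::sqrt(gx * gx + gyv * gyv);
    }
  // non-maximum suppression
  NumericMatrix nms(H, W);
  for (int w = 1; w < W - 1; ++w)
    for (int h = 1; h < H - 1; ++h) {
      const double m = mag(h, w);
      if (m == 0) continue;
      const double gx = dx[h + (size_t)H * w], gyv = dy[h + (size_t)H * w];
      double ang = std::atan2(gyv, gx) * 180.0 / M_PI;
      if (ang < 0) ang += 180.0;
      double a, b;
      if (ang < 22.5 || ang >= 157.5) {        // horizontal gradient
        a = mag(h, w - 1); b = mag(h, w + 1);
      } else if (ang < 67.5) {                 // diagonal
        a = mag(h - 1, w - 1); b = mag(h + 1, w + 1);
      } else if (ang < 112.5) {                // vertical gradient
        a = mag(h - 1, w); b = mag(h + 1, w);
      } else {
        a = mag(h - 1, w + 1); b = mag(h + 1, w - 1);
      }
      if (m >= a && m >= b) nms(h, w) = m;
    }
  // thresholds relative to the maximum magnitude
  double maxmag = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      if (mag(h, w) > maxmag) maxmag = mag(h, w);
  if (maxmag == 0) return NumericMatrix(H, W);
  low *= maxmag;
  high *= maxmag;
  // double threshold + hysteresis (BFS from strong pixels)
  NumericMatrix edges(H, W);
  std::queue<std::pair<int, int>> q;
  std::vector<char> weak((size_t)H * W, 0);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (nms(h, w) >= high) { edges(h, w) = 1.0; q.push({h, w}); }
      else if (nms(h, w) >= low) weak[h + (size_t)H * w] = 1;
    }
  while (!q.empty()) {
    auto [h, w] = q.front(); q.pop();
    for (int dw = -1; dw <= 1; ++dw)
      for (int dh = -1; dh <= 1; ++dh) {
        const int hh = h + dh, ww = w + dw;
        if (hh < 0 || hh >= H || ww < 0 || ww >= W) continue;
        if (weak[hh + (size_t)H * ww] && edges(hh, ww) == 0.0) {
          edges(hh, ww) = 1.0;
          q.push({hh, ww});
        }
      }
  }
  return edges;
}
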