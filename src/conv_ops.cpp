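#include <Rcpp.h>
using namespace Rcpp;

// Dense tensors cross the R/C++ boundary as numeric vectors carrying a dim
// attribute (c, sx, sy, sz); 2-D data travels with sz = 1. Kernels are
// (c_out, c_in, kx, ky, kz). Channel is the fastest-varying index, so the
// innermost loops below run over contiguous memory.

static inline IntegerVector tensor_dims(const NumericVector &x, int need) {
  IntegerVector d = x.attr("dim");
  if (d.size() != need) stop("tensor has %d dims, expected %d", (int)d.size(), need);
  return d;
}

// stride-1 "same" zero-padded cross-correlation; odd kernel extents
// [[Rcpp::export]]
NumericVector cpp_conv_same(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = tensor_dims(x, 4), wd = tensor_dims(w, 5);
  const int ci_n = xd[0], sx = xd[1], sy = xd[2], sz = xd[3];
  const int co_n = wd[0], kx = wd[2], ky = wd[3], kz = wd[4];
  if (wd[1] != ci_n) stop("kernel expects %d input channels, got %d", (int)wd[1], ci_n);
  if (kx % 2 == 0 || ky % 2 == 0 || kz % 2 == 0) stop("kernel extents must be odd");
  const int hx = kx / 2, hy = ky / 2, hz = kz / 2;
  const bool has_bias = bias.size() > 0;

  NumericVector y(co_n * sx * sy * sz);
  double *yp = REAL(y);
  const double *xp = REAL(x), *wp = REAL(w);

  if (has_bias)
    for (int v = 0; v < sx * sy * sz; ++v)
      for (int co = 0; co < co_n; ++co) yp[co + co_n * v] = bias[co];

  for (int pz = 0; pz < sz; ++pz)
    for (int py = 0; py < sy; ++py)
      for (int px = 0; px < sx; ++px) {
        double *yv = yp + co_n * (px + sx * (py + sy * pz));
        for (int oz = 0; oz < kz; ++oz) {
          int qz = pz + oz - hz; if (qz < 0 || qz >= sz) continue;
          for (int oy = 0; oy < ky; ++oy) {
            int qy = py + oy - hy; if (qy < 0 || qy >= sy) continue;
            for (int ox = 0; ox < kx; ++ox) {
              int qx = px + ox - hx; if (qx < 0 || qx >= sx) continue;
              const double *xv = xp + ci_n * (qx + sx * (qy + sy * qz));
              const double *wk = wp + co_n * ci_n * (ox + kx * (oy + ky * oz));
              for (int ci = 0; ci < ci_n; ++ci) {
                const double xval = xv[ci];
                const double *wc = wk + co_n * ci;
                for (int co = 0; co < co_n; ++co) yv[co] += wc[co] * xval;
              }
            }
          }
        }
      }
  y.attr("dim") = IntegerVector::create(co_n, sx, sy, sz);
  return y;
}

// adjoint of cpp_conv_same w.r.t. the input
// [[Rcpp::export]]
NumericVector cpp_conv_same_bwd_input(NumericVector dy, NumericVector w) {
  IntegerVector yd = tensor_dims(dy, 4), wd = tensor_dims(w, 5);
  const int co_n = yd[0], sx = yd[1], sy = yd[2], sz = yd[3];
  const int ci_n = wd[1], kx = wd[2], ky = wd[3], kz = wd[4];
  if (wd[0] != co_n) stop("kernel/output channel mismatch");
  const int hx = kx / 2, hy = ky / 2, hz = kz / 2;

  NumericVector dx(ci_n * sx * sy * sz);
  double *dxp = REAL(dx);
  const double *dyp = REAL(dy), *wp = REAL(w);

  for (int pz = 0; pz < sz; ++pz)
    for (int py = 0; py < sy; ++py)
      for (int px = 0; px < sx; ++px) {
        const double *gv = dyp + co_n * (px + sx * (py + sy * pz));
        for (int oz = 0; oz < kz; ++oz) {
          int qz = pz + oz - hz; if (qz < 0 || qz >= sz) continue;
          for (int oy = 0; oy < ky; ++oy) {
            int qy = py + oy - hy; if (qy < 0 || qy >= sy) continue;
            for (int ox = 0; ox < kx; ++ox) {
              int qx = px + ox - hx; if (qx < 0 || qx >= sx) continue;
              double *dxv = dxp + ci_n * (qx + sx * (qy + sy * qz));
              const double *wk = wp + co_n * ci_n * (ox + kx * (oy + ky * oz));
              for (int ci = 0; ci < ci_n; ++ci) {
                const double *wc = wk + co_n * ci;
                double acc = 0.0;
                for (int co = 0; co < co_n; ++co) acc += wc[co] * gv[co];
                dxv[ci] += acc;
              }
            }
          }
        }
      }
  dx.attr("dim") = IntegerVector::create(ci_n, sx, sy, sz);
  return dx;
}

// adjoint of cpp_conv_same w.r.t. the kernel
// [[Rcpp::export]]
NumericVector cpp_conv_same_bwd_weight(NumericVector x, NumericVector dy,
                                       IntegerVector kdims) {
  IntegerVector xd = tensor_dims(x, 4), yd = tensor_dims(dy, 4);
  const int ci_n = xd[0], sx = xd[1], sy = xd[2], sz = xd[3];
  const int co_n = yd[0];
  const int kx = kdims[0], ky = kdims[1], kz = kdims[2];
  const int hx = kx / 2, hy = ky / 2, hz = kz / 2;

  NumericVector dw(co_n * ci_n * kx * ky * kz);
  double *dwp = REAL(dw);
  const double *xp = REAL(x), *dyp = REAL(dy);

  for (int pz = 0; pz < sz; ++pz)
    for (int py = 0; py < sy; ++py)
      for (int px = 0; px < sx; ++px) {
        const double *gv = dyp + co_n * (px + sx * (py + sy * pz));
        for (int oz = 0; oz < kz; ++oz) {
          int qz = pz + oz - hz; if (qz < 0 || qz >= sz) continue;
          for (int oy = 0; oy < ky; ++oy) {
            int qy = py + oy - hy; if (qy < 0 || qy >= sy) continue;
            for (int ox = 0; ox < kx; ++ox) {
              int qx = px + ox - hx; if (qx < 0 || qx >= sx) continue;
              const double *xv = xp + ci_n * (qx + sx * (qy + sy * qz));
              double *dwk = dwp + co_n * ci_n * (ox + kx * (oy + ky * oz));
              for (int ci = 0; ci < ci_n; ++ci) {
                const double xval = xv[ci];
                double *dwc = dwk + co_n * ci;
                for (int co = 0; co < co_n; ++co) dwc[co] += gv[co] * xval;
              }
            }
          }
        }
      }
  dw.attr("dim") = IntegerVector::create(co_n, ci_n, kx, ky, kz);
  return dw;
}

// per-channel sum of a gradient tensor (bias adjoint)
// [[Rcpp::export]]
NumericVector cpp_channel_sums(NumericVector dy) {
  IntegerVector yd = tensor_dims(dy, 4);
  const int c = yd[0]; const R_xlen_t n = dy.size() / c;
  NumericVector s(c);
  const double *p = REAL(dy);
  for (R_xlen_t v = 0; v < n; ++v)
    for (int k = 0; k < c; ++k) s[k] += p[k + c * v];
  return s;
}

// stride-2 transpose convolution, kernel extent 2 per active axis
// (non-overlapping learned upsampling); d = number of doubled axes
// [[Rcpp::export]]
NumericVector cpp_tconv2(NumericVector x, NumericVector w, NumericVector bias,
                         int d) {
  IntegerVector xd = tensor_dims(x, 4), wd = tensor_dims(w, 5);
  const int ci_n = xd[0], sx = xd[1], sy = xd[2], sz = xd[3];
  const int co_n = wd[0], kx = wd[2], ky = wd[3], kz = wd[4];
  if (wd[1] != ci_n) stop("kernel expects %d input channels, got %d", (int)wd[1], ci_n);
  if (kx != 2 || ky != 2 || kz != (d == 3 ? 2 : 1))
    stop("transpose kernel extents must be 2 on each doubled axis");
  const int ox_n = 2 * sx, oy_n = 2 * sy, oz_n = (d == 3) ? 2 * sz : sz;
  const bool has_bias = bias.size() > 0;

  NumericVector y(co_n * ox_n * oy_n * oz_n);
  double *yp = REAL(y);
  const double *xp = REAL(x), *wp = REAL(w);

  if (has_bias)
    for (int v = 0; v < ox_n * oy_n * oz_n; ++v)
      for (int co = 0; co < co_n; ++co) yp[co + co_n * v] = bias[co];

  for (int pz = 0; pz < sz; ++pz)
    for (int py = 0; py < sy; ++py)
      for (int px = 0; px < sx; ++px) {
        const double *xv = xp + ci_n * (px + sx * (py + sy * pz));
        for (int oz = 0; oz < kz; ++oz) {
          int qz = (d == 3) ? 2 * pz + oz : pz;
          for (int oy = 0; oy < ky; ++oy) {
            int qy = 2 * py + oy;
            for (int ox = 0; ox < kx; ++ox) {
              int qx = 2 * px + ox;
              double *yv = yp + co_n * (qx + ox_n * (qy + oy_n * qz));
              const double *wk = wp + co_n * ci_n * (ox + kx * (oy + ky * oz));
              for (int ci = 0; ci < ci_n; ++ci) {
                const double xval = xv[ci];
                const double *wc = wk + co_n * ci;
                for (int co = 0; co < co_n; ++co) yv[co] += wc[co] * xval;
              }
            }
          }
        }
      }
  y.attr("dim") = IntegerVector::create(co_n, ox_n, oy_n, oz_n);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_tconv2_bwd_input(NumericVector dy, NumericVector w, int d) {
  IntegerVector yd = tensor_dims(dy, 4), wd = tensor_dims(w, 5);
  const int co_n = yd[0], ox_n = yd[1], oy_n = yd[2], oz_n = yd[3];
  const int ci_n = wd[1], kx = wd[2], ky = wd[3], kz = wd[4];
  const int sx = ox_n / 2, sy = oy_n / 2, sz = (d == 3) ? oz_n / 2 : oz_n;

  NumericVector dx(ci_n * sx * sy * sz);
  double *dxp = REAL(dx);
  const double *dyp = REAL(dy), *wp = REAL(w);

  for (int pz = 0; pz < sz; ++pz)
    for (int py = 0; py < sy; ++py)
      for (int px = 0; px < sx; ++px) {
        double *dxv = dxp + ci_n * (px + sx * (py + sy * pz));
        for (int oz = 0; oz < kz; ++oz) {
          int qz = (d == 3) ? 2 * pz + oz : pz;
          for (int oy = 0; oy < ky; ++oy) {
            int qy = 2 * py + oy;
            for (int ox = 0; ox < kx; ++ox) {
              int qx = 2 * px + ox;
              const double *gv = dyp + co_n * (qx + ox_n * (qy + oy_n * qz));
              const double *wk = wp + co_n * ci_n * (ox + kx * (oy + ky * oz));
              for (int ci = 0; ci < ci_n; ++ci) {
                const double *wc = wk + co_n * ci;
                double acc = 0.0;
                for (int co = 0; co < co_n; ++co) acc += wc[co] * gv[co];
                dxv[ci] += acc;
              }
            }
          }
        }
      }
  dx.attr("dim") = IntegerVector::create(ci_n, sx, sy, sz);
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_tconv2_bwd_weight(NumericVector x, NumericVector dy, int d) {
  IntegerVector xd = tensor_dims(x, 4), yd = tensor_dims(dy, 4);
  const int ci_n = xd[0], sx = xd[1], sy = xd[2], sz = xd[3];
  const int co_n = yd[0], ox_n = yd[1], oy_n = yd[2], oz_n = yd[3];
  const int kx = 2, ky = 2, kz = (d == 3) ? 2 : 1;

  NumericVector dw(co_n * ci_n * kx * ky * kz);
  double *dwp = REAL(dw);
  const double *xp = REAL(x), *dyp = REAL(dy);

  for (int pz = 0; pz < sz; ++pz)
    for (int py = 0; py < sy; ++py)
      for (int px = 0; px < sx; ++px) {
        const double *xv = xp + ci_n * (px + sx * (py + sy * pz));
        for (int oz = 0; oz < kz; ++oz) {
          int qz = (d == 3) ? 2 * pz + oz : pz;
          for (int oy = 0; oy < ky; ++oy) {
            int qy = 2 * py + oy;
            for (int ox = 0; ox < kx; ++ox) {
              int qx = 2 * px + ox;
              const double *gv = dyp + co_n * (qx + ox_n * (qy + oy_n * qz));
              double *dwk = dwp + co_n * ci_n * (ox + kx * (oy + ky * oz));
              for (int ci = 0; ci < ci_n; ++ci) {
                const double xval = xv[ci];
                double *dwc = dwk + co_n * ci;
                for (int co = 0; co < co_n; ++co) dwc[co] += gv[co] * xval;
              }
            }
          }
        }
      }
  dw.attr("dim") = IntegerVector::create(co_n, ci_n, kx, ky, kz);
  return dw;
}

// average pooling, scale 2, on the first d spatial axes
// [[Rcpp::export]]
NumericVector cpp_avgpool2(NumericVector x, int d) {
  IntegerVector xd = tensor_dims(x, 4);
  const int c = xd[0], sx = xd[1], sy = xd[2], sz = xd[3];
  if (sx % 2 || sy % 2 || (d == 3 && sz % 2))
    stop("average pooling needs even spatial dimensions");
  const int ox_n = sx / 2, oy_n = sy / 2, oz_n = (d == 3) ? sz / 2 : sz;
  const int kz = (d == 3) ? 2 : 1;
  const double inv = 1.0 / (4.0 * kz);

  NumericVector y(c * ox_n * oy_n * oz_n);
  double *yp = REAL(y);
  const double *xp = REAL(x);

  for (int pz = 0; pz < oz_n; ++pz)
    for (int py = 0; py < oy_n; ++py)
      for (int px = 0; px < ox_n; ++px) {
        double *yv = yp + c * (px + ox_n * (py + oy_n * pz));
        for (int oz = 0; oz < kz; ++oz)
          for (int oy = 0; oy < 2; ++oy)
            for (int ox = 0; ox < 2; ++ox) {
              int qz = (d == 3) ? 2 * pz + oz : pz;
              const double *xv =
                  xp + c * ((2 * px + ox) + sx * ((2 * py + oy) + sy * qz));
              for (int k = 0; k < c; ++k) yv[k] += xv[k];
            }
        for (int k = 0; k < c; ++k) yv[k] *= inv;
      }
  y.attr("dim") = IntegerVector::create(c, ox_n, oy_n, oz_n);
  return y;
}

// nearest-neighbour upsampling, scale 2, on the first d spatial axes
// [[Rcpp::export]]
NumericVector cpp_upsample_nearest2(NumericVector x, int d) {
  IntegerVector xd = tensor_dims(x, 4);
  const int c = xd[0], sx = xd[1], sy = xd[2], sz = xd[3];
  const int ox_n = 2 * sx, oy_n = 2 * sy, oz_n = (d == 3) ? 2 * sz : sz;

  NumericVector y(c * ox_n * oy_n * oz_n);
  double *yp = REAL(y);
  const double *xp = REAL(x);

  for (int qz = 0; qz < oz_n; ++qz) {
    int pz = (d == 3) ? qz / 2 : qz;
    for (int qy = 0; qy < oy_n; ++qy)
      for (int qx = 0; qx < ox_n; ++qx) {
        const double *xv = xp + c * ((qx / 2) + sx * ((qy / 2) + sy * pz));
        double *yv = yp + c * (qx + ox_n * (qy + oy_n * qz));
        for (int k = 0; k < c; ++k) yv[k] = xv[k];
      }
  }
  y.attr("dim") = IntegerVector::create(c, ox_n, oy_n, oz_n);
  return y;
}
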