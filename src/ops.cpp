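#include <Rcpp.h>
#include <climits>
#include <cmath>
using namespace Rcpp;

// All raster code uses R's column-major IntegerMatrix with row = y (top to
// bottom), col = x.  Border policy for every window operator is replicate-edge
// padding, realised as coordinate clamping (identical for order statistics and
// used explicitly as weights-on-clamped-pixels for convolution).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Window min/max over an arbitrary binary structuring element.
// [[Rcpp::export]]
IntegerMatrix cpp_window_rank(const IntegerMatrix& img, const IntegerMatrix& se,
                              int anchor_r, int anchor_c, bool take_max) {
  const int h = img.nrow(), w = img.ncol();
  const int sh = se.nrow(), sw = se.ncol();
  std::vector<int> dr, dc;
  dr.reserve(sh * sw);
  dc.reserve(sh * sw);
  for (int j = 0; j < sw; ++j)
    for (int i = 0; i < sh; ++i)
      if (se(i, j) != 0) {
        dr.push_back(i - anchor_r);
        dc.push_back(j - anchor_c);
      }
  const int m = (int)dr.size();
  IntegerMatrix out(h, w);
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      int best = take_max ? INT_MIN : INT_MAX;
      for (int k = 0; k < m; ++k) {
        const int rr = clampi(r + dr[k], 0, h - 1);
        const int cc = clampi(c + dc[k], 0, w - 1);
        const int v = img(rr, cc);
        if (take_max ? (v > best) : (v < best)) best = v;
      }
      out(r, c) = best;
    }
  }
  return out;
}

// Separable min/max for full rectangular SEs (horizontal then vertical pass).
// [[Rcpp::export]]
IntegerMatrix cpp_rect_rank(const IntegerMatrix& img, int kh, int kw,
                            bool take_max) {
  const int h = img.nrow(), w = img.ncol();
  const int rh = kh / 2, rw = kw / 2;
  IntegerMatrix tmp(h, w), out(h, w);
  for (int c = 0; c < w; ++c) {
    const int lo = clampi(c - rw, 0, w - 1), hi = clampi(c + rw, 0, w - 1);
    for (int r = 0; r < h; ++r) {
      int best = img(r, lo);
      for (int cc = lo + 1; cc <= hi; ++cc) {
        const int v = img(r, cc);
        if (take_max ? (v > best) : (v < best)) best = v;
      }
      tmp(r, c) = best;
    }
  }
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      const int lo = clampi(r - rh, 0, h - 1), hi = clampi(r + rh, 0, h - 1);
      int best = tmp(lo, c);
      for (int rr = lo + 1; rr <= hi; ++rr) {
        const int v = tmp(rr, c);
        if (take_max ? (v > best) : (v < best)) best = v;
      }
      out(r, c) = best;
    }
  }
  return out;
}

// Separable convolution (correlation; all kernels used are symmetric) with
// replicate borders.  kx runs across columns, ky down rows.
// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(const NumericMatrix& img, const NumericVector& kx,
                           const NumericVector& ky) {
  const int h = img.nrow(), w = img.ncol();
  const int rx = kx.size() / 2, ry = ky.size() / 2;
  NumericMatrix tmp(h, w), out(h, w);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      double acc = 0.0;
      for (int k = -rx; k <= rx; ++k)
        acc += kx[k + rx] * img(r, clampi(c + k, 0, w - 1));
      tmp(r, c) = acc;
    }
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      double acc = 0.0;
      for (int k = -ry; k <= ry; ++k)
        acc += ky[k + ry] * tmp(clampi(r + k, 0, h - 1), c);
      out(r, c) = acc;
    }
  return out;
}

// Dense small-kernel correlation with replicate borders (used for sharpening).
// [[Rcpp::export]]
NumericMatrix cpp_conv2(const NumericMatrix& img, const NumericMatrix& ker) {
  const int h = img.nrow(), w = img.ncol();
  const int rh = ker.nrow() / 2, rw = ker.ncol() / 2;
  NumericMatrix out(h, w);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      double acc = 0.0;
      for (int j = -rw; j <= rw; ++j)
        for (int i = -rh; i <= rh; ++i)
          acc += ker(i + rh, j + rw) *
                 img(clampi(r + i, 0, h - 1), clampi(c + j, 0, w - 1));
      out(r, c) = acc;
    }
  return out;
}

// Resize.  method: 0 nearest, 1 bilinear, 2 area-average.
// Pixel centres sit at integer + 0.5 in both grids, matching the usual
// image-processing convention; same-size calls are exact identities.
// [[Rcpp::export]]
IntegerMatrix cpp_resize(const IntegerMatrix& img, int out_h, int out_w,
                         int method) {
  const int h = img.nrow(), w = img.ncol();
  const double sy = (double)h / out_h, sx = (double)w / out_w;
  IntegerMatrix out(out_h, out_w);
  if (method == 0) {  // nearest
    for (int c = 0; c < out_w; ++c) {
      const int sc = clampi((int)std::floor((c + 0.5) * sx), 0, w - 1);
      for (int r = 0; r < out_h; ++r) {
        const int sr = clampi((int)std::floor((r + 0.5) * sy), 0, h - 1);
        out(r, c) = img(sr, sc);
      }
    }
  } else if (method == 1) {  // bilinear
    for (int c = 0; c < out_w; ++c) {
      const double fc = (c + 0.5) * sx - 0.5;
      int c0 = (int)std::floor(fc);
      const double tc = fc - c0;
      const int c1 = clampi(c0 + 1, 0, w - 1);
      c0 = clampi(c0, 0, w - 1);
      for (int r = 0; r < out_h; ++r) {
        const double fr = (r + 0.5) * sy - 0.5;
        int r0 = (int)std::floor(fr);
        const double tr = fr - r0;
        const int r1 = clampi(r0 + 1, 0, h - 1);
        r0 = clampi(r0, 0, h - 1);
        const double v = (1 - tr) * ((1 - tc) * img(r0, c0) + tc * img(r0, c1)) +
                         tr * ((1 - tc) * img(r1, c0) + tc * img(r1, c1));
        out(r, c) = clampi((int)std::floor(v + 0.5), 0, 255);
      }
    }
  } else {  // area: integrate source over each destination pixel footprint
    for (int c = 0; c < out_w; ++c) {
      const double x0 = c * sx, x1 = (c + 1) * sx;
      const int cx0 = (int)std::floor(x0), cx1 = (int)std::ceil(x1) - 1;
      for (int r = 0; r < out_h; ++r) {
        const double y0 = r * sy, y1 = (r + 1) * sy;
        const int cy0 = (int)std::floor(y0), cy1 = (int)std::ceil(y1) - 1;
        double acc = 0.0, wsum = 0.0;
        for (int j = cx0; j <= cx1; ++j) {
          const double wx = std::min(x1, (double)j + 1) - std::max(x0, (double)j);
          const int jj = clampi(j, 0, w - 1);
          for (int i = cy0; i <= cy1; ++i) {
            const double wy =
                std::min(y1, (double)i + 1) - std::max(y0, (double)i);
            acc += wx * wy * img(clampi(i, 0, h - 1), jj);
            wsum += wx * wy;
          }
        }
        out(r, c) = clampi((int)std::floor(acc / wsum + 0.5), 0, 255);
      }
    }
  }
  return out;
}

// Connected-component labelling (BFS) of nonzero pixels; connectivity 4 or 8.
// Labels are 1..n in scan order of the first-visited pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const IntegerMatrix& mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);  // zero-initialised
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * h);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pr = p % h, pc = p / h;
        for (int k = 0; k < nn; ++k) {
          const int rr = pr + dr8[k], cc = pc + dc8[k];
          if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * h);
          }
        }
      }
    }
  return lab;
}
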