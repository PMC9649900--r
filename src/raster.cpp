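// Polygon rasterization (even-odd rule, pixel centers at integer
// coordinates, boundary-inclusive), 8-connected component labeling,
// and inverse-map image rotation used for geometric augmentation.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static bool on_segment(double px, double py, double x1, double y1,
                       double x2, double y2, double eps) {
  double cross = (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1);
  double len2 = (x2 - x1) * (x2 - x1) + (y2 - y1) * (y2 - y1);
  if (cross * cross > eps * eps * std::max(1.0, len2)) return false;
  double dot = (px - x1) * (x2 - x1) + (py - y1) * (y2 - y1);
  return dot >= -eps && dot <= len2 + eps;
}

// [[Rcpp::export(name = ".cpp_polygon_raster")]]
LogicalMatrix cpp_polygon_raster(NumericVector xs, NumericVector ys,
                                 int height, int width) {
  int m = xs.size();
  LogicalMatrix mask(height, width);
  const double eps = 1e-9;
  for (int r = 0; r < height; ++r) {
    for (int c = 0; c < width; ++c) {
      double px = c, py = r;
      bool inside = false, boundary = false;
      for (int i = 0, j = m - 1; i < m; j = i++) {
        double xi = xs[i], yi = ys[i], xj = xs[j], yj = ys[j];
        if (on_segment(px, py, xi, yi, xj, yj, eps)) { boundary = true; break; }
        if (((yi > py) != (yj > py)) &&
            (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
          inside = !inside;
      }
      mask(r, c) = boundary || inside;
    }
  }
  return mask;
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r0, c0));
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            if (!dr && !dc) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
      }
    }
  return lab;
}

// Rotate counter-clockwise by angle_deg about the image center
// ((H-1)/2, (W-1)/2); inverse mapping with bilinear (images) or
// nearest-neighbor (masks) sampling; out-of-canvas reads are zero.
// [[Rcpp::export(name = ".cpp_rotate")]]
NumericMatrix cpp_rotate(NumericMatrix x, double angle_deg, bool bilinear) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(H, W);
  double th = angle_deg * M_PI / 180.0;
  double ca = std::cos(th), sa = std::sin(th);
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      // forward map rotates content by +theta (x right, y down, so CW in
      // screen terms is consistent for image and polygon transport);
      // inverse map applies -theta.
      double dx = c - cx, dy = r - cy;
      double sx = ca * dx + sa * dy + cx;
      double sy = -sa * dx + ca * dy + cy;
      if (bilinear) {
        int f_x = (int)std::floor(sx), f_y = (int)std::floor(sy);
        double tx = sx - f_x, ty = sy - f_y;
        double acc = 0.0;
        for (int qy = 0; qy <= 1; ++qy)
          for (int qx = 0; qx <= 1; ++qx) {
            int yy = f_y + qy, xx = f_x + qx;
            if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
            double wgt = (qx ? tx : 1 - tx) * (qy ? ty : 1 - ty);
            acc += wgt * x(yy, xx);
          }
        y(r, c) = acc;
      } else {
        int yy = (int)std::lround(sy), xx = (int)std::lround(sx);
        y(r, c) = (yy < 0 || yy >= H || xx < 0 || xx >= W) ? 0.0 : x(yy, xx);
      }
    }
  return y;
}
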