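#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Canvas big enough to hold the full rotated frame (no pixel lost).
static inline void rotated_dims(int H, int W, double theta, int& Hr, int& Wr) {
  double c = std::fabs(std::cos(theta)), s = std::fabs(std::sin(theta));
  // tolerance keeps axis-aligned angles from inflating the canvas by one
  // pixel (ceil of 480 + 8e-14), which would shift the centre half a pixel
  Wr = (int)std::ceil((double)W * c + (double)H * s - 1e-9);
  Hr = (int)std::ceil((double)W * s + (double)H * c - 1e-9);
  if (Wr < 1) Wr = 1;
  if (Hr < 1) Hr = 1;
}

// Clip [lo, hi] (in x' units) by the constraint lo_v <= a*x' + b <= hi_v.
static inline bool clip_interval(double a, double b, double lo_v, double hi_v,
                                 double& lo, double& hi) {
  if (std::fabs(a) < 1e-12) {
    return b >= lo_v && b <= hi_v;  // constraint independent of x'
  }
  double t0 = (lo_v - b) / a, t1 = (hi_v - b) / a;
  if (t0 > t1) std::swap(t0, t1);
  lo = std::max(lo, t0);
  hi = std::min(hi, t1);
  return lo <= hi;
}

// Row sums of the mask rotated by `theta` (radians) about its centre with
// inverse nearest-neighbour mapping: output pixel p' samples the source at
// R(-theta) * (p' - c') + c.  Rotation is mathematically CCW in (x, y)
// coordinates with y pointing down (same convention as EBImage::rotate).
// `m` is the mask in column-major (H x W); `mt` its transpose (may be NULL).
static void profile_one(const int* m, const int* mt, int H, int W,
                        double theta, std::vector<int>& prof) {
  int Hr, Wr;
  rotated_dims(H, W, theta, Hr, Wr);
  double ct = std::cos(theta), st = std::sin(theta);
  double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  double cxr = (Wr - 1) / 2.0, cyr = (Hr - 1) / 2.0;
  // prefer the layout whose fast-varying source index is contiguous:
  // along an output row, sx steps by ct and sy by -st
  bool use_t = (mt != (const int*)0) && std::fabs(ct) > std::fabs(st);
  prof.assign(Hr, 0);
  for (int yr = 0; yr < Hr; ++yr) {
    double dy = yr - cyr;
    // source coords as functions of x': sx = ct*(x'-cxr) + st*dy + cx,
    // sy = -st*(x'-cxr) + ct*dy + cy.  The interval where both stay in
    // bounds is computed analytically (then widened; exactness comes from
    // the per-pixel bounds check, the clip only limits work).
    double ax = -ct * cxr + st * dy + cx;
    double by = st * cxr + ct * dy + cy;
    double lo = 0, hi = Wr - 1;
    if (!clip_interval(ct, ax, -0.5, W - 0.5, lo, hi)) continue;
    if (!clip_interval(-st, by, -0.5, H - 0.5, lo, hi)) continue;
    int x0 = (int)std::ceil(lo) - 2, x1 = (int)std::floor(hi) + 2;
    if (x0 < 0) x0 = 0;
    if (x1 > Wr - 1) x1 = Wr - 1;
    if (x1 < x0) continue;
    int cnt = 0;
    if (use_t) {
      for (int xr = x0; xr <= x1; ++xr) {
        double dx = xr - cxr;
        int ix = (int)std::lround(ct * dx + st * dy + cx);
        int iy = (int)std::lround(-st * dx + ct * dy + cy);
        if (ix >= 0 && ix < W && iy >= 0 && iy < H)
          cnt += mt[ix + (size_t)iy * W] != 0;
      }
    } else {
      for (int xr = x0; xr <= x1; ++xr) {
        double dx = xr - cxr;
        int ix = (int)std::lround(ct * dx + st * dy + cx);
        int iy = (int)std::lround(-st * dx + ct * dy + cy);
        if (ix >= 0 && ix < W && iy >= 0 && iy < H)
          cnt += m[iy + (size_t)ix * H] != 0;
      }
    }
    prof[yr] = cnt;
  }
}

static std::vector<int> transpose_mask(const int* m, int H, int W) {
  std::vector<int> mt((size_t)H * W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      mt[x + (size_t)y * W] = m[y + (size_t)x * H];
  return mt;
}

// [[Rcpp::export]]
IntegerVector cpp_rotation_profile(LogicalMatrix mask, double angle_deg) {
  std::vector<int> prof;
  profile_one(mask.begin(), (const int*)0, mask.nrow(), mask.ncol(),
              angle_deg * M_PI / 180.0, prof);
  return IntegerVector(prof.begin(), prof.end());
}

// Maximum of the row-sum profile at each angle of the grid.
// [[Rcpp::export]]
NumericVector cpp_rotation_search(LogicalMatrix mask, NumericVector angles_deg) {
  int n = angles_deg.size();
  int H = mask.nrow(), W = mask.ncol();
  std::vector<int> mt = transpose_mask(mask.begin(), H, W);
  NumericVector out(n);
  std::vector<int> prof;
  for (int i = 0; i < n; ++i) {
    profile_one(mask.begin(), mt.data(), H, W,
                angles_deg[i] * M_PI / 180.0, prof);
    int mx = 0;
    for (size_t j = 0; j < prof.size(); ++j)
      if (prof[j] > mx) mx = prof[j];
    out[i] = mx;
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full rotated mask (same mapping as profile_one), for crop alignment checks.
// [[Rcpp::export]]
LogicalMatrix cpp_rotate_mask(LogicalMatrix mask, double angle_deg) {
  double theta = angle_deg * M_PI / 180.0;
  int H = mask.nrow(), W = mask.ncol();
  int Hr, Wr;
  rotated_dims(H, W, theta, Hr, Wr);
  double ct = std::cos(theta), st = std::sin(theta);
  double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  double cxr = (Wr - 1) / 2.0, cyr = (Hr - 1) / 2.0;
  LogicalMatrix out(Hr, Wr);
  for (int yr = 0; yr < Hr; ++yr) {
    double dy = yr - cyr;
    for (int xr = 0; xr < Wr; ++xr) {
      double dx = xr - cxr;
      int ix = (int)std::lround(ct * dx + st * dy + cx);
      int iy = (int)std::lround(-st * dx + ct * dy + cy);
      out(yr, xr) = (ix >= 0 && ix < W && iy >= 0 && iy < H && mask(iy, ix));
    }
  }
  return out;
}

// Connected-component labeling by flood fill; connectivity 4 or 8.
// Labels 1..n in scan order, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  int ndir = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r0 + c0 * H);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r = idx % H, c = idx / H;
        for (int d = 0; d < ndir; ++d) {
          int rr = r + dy8[d], cc = c + dx8[d];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * H);
          }
        }
      }
    }
  }
  return lab;
}
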