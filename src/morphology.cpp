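// Digital-topology primitives for 2D bone-section rasters:
//   - exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher)
//   - local thickness (largest inscribed disc, painted from the EDT)
//   - connected-component labelling with selectable 4/8 connectivity
//   - 3x3 box binary opening
// Matrices are column-major as passed from R; mask entries are 0/1.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e30;

// 1D squared-distance lower envelope transform.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    d[q] = ((double)q - v[k]) * ((double)q - v[k]) + f[v[k]];
  }
}

// Squared EDT of a binary mask: distance from each foreground pixel to the
// nearest background pixel centre. The raster border is not treated as
// background: structures touching the border are taken to continue past it.
// A mask with no background at all gets the raster diagonal as distance.
// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix d(nr, nc);
  std::vector<double> f(std::max(nr, nc)), g(std::max(nr, nc));
  const double cap = (double)nr * nr + (double)nc * nc;
  // columns first
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? INF : 0.0;
    dt1d(f, g, nr);
    for (int i = 0; i < nr; ++i) d(i, j) = std::min(g[i], INF);
  }
  // then rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = d(i, j);
    dt1d(f, g, nc);
    for (int j = 0; j < nc; ++j) d(i, j) = std::min(g[j], cap);
  }
  return d;
}

// Local thickness field in pixels: for each foreground pixel, the diameter
// (2*r - 1, pixel units) of the largest inscribed disc that contains it.
// Disc centres are pruned to the distance ridge first: a centre whose disc
// is contained in a neighbour's disc (r_q >= r_p + dist(p, q)) is redundant
// because the neighbour paints a superset at a larger value. All surviving
// discs are painted with a max update.
// [[Rcpp::export(name = ".local_thickness_px")]]
NumericMatrix local_thickness_px(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix dsq = edt_sq(mask);
  NumericMatrix out(nr, nc);
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const double dist8[8] = {1, 1, 1, 1, M_SQRT2, M_SQRT2, M_SQRT2, M_SQRT2};
  for (int cj = 0; cj < nc; ++cj) {
    for (int ci = 0; ci < nr; ++ci) {
      if (!mask(ci, cj)) continue;
      const double r = std::sqrt(dsq(ci, cj));
      bool dominated = false;
      for (int t = 0; t < 8 && !dominated; ++t) {
        const int qi = ci + di8[t], qj = cj + dj8[t];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        if (!mask(qi, qj)) continue;
        if (std::sqrt(dsq(qi, qj)) >= r + dist8[t] - 1e-9) dominated = true;
      }
      if (dominated) continue;
      const double val = 2.0 * r - 1.0;
      const double reff = r - 0.5;     // disc touches the boundary mid-pixel
      const double r2 = reff * reff;
      const int ri = (int)std::floor(reff);
      for (int dj = -ri; dj <= ri; ++dj) {
        const int j = cj + dj;
        if (j < 0 || j >= nc) continue;
        for (int di = -ri; di <= ri; ++di) {
          const int i = ci + di;
          if (i < 0 || i >= nr) continue;
          if ((double)di * di + (double)dj * dj > r2) continue;
          if (out(i, j) < val) out(i, j) = val;
        }
      }
      if (out(ci, cj) < val) out(ci, cj) = val;  // reff < 0.5 case
    }
  }
  return out;
}

// Connected-component labelling of the nonzero pixels, connectivity 4 or 8.
// Labels are 1..k in scan order; background stays 0.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(j * nr + i);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int t = 0; t < nnb; ++t) {
          const int qi = pi + di8[t], qj = pj + dj8[t];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qj * nr + qi);
          }
        }
      }
    }
  }
  return lab;
}

// 3x3 box binary opening (erosion with off-raster treated as foreground,
// dilation with off-raster background), repeated `iter` times.
// [[Rcpp::export(name = ".binary_open3")]]
IntegerMatrix binary_open3(const IntegerMatrix& mask, int iter) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix a = clone(mask), b(nr, nc);
  for (int it = 0; it < iter; ++it) {
    // erode
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        int keep = a(i, j);
        for (int dj = -1; dj <= 1 && keep; ++dj)
          for (int di = -1; di <= 1 && keep; ++di) {
            const int qi = i + di, qj = j + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (!a(qi, qj)) keep = 0;
          }
        b(i, j) = keep;
      }
    // dilate
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        int hit = 0;
        for (int dj = -1; dj <= 1 && !hit; ++dj)
          for (int di = -1; di <= 1 && !hit; ++di) {
            const int qi = i + di, qj = j + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (b(qi, qj)) hit = 1;
          }
        a(i, j) = hit;
      }
  }
  return a;
}
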