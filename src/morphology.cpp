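// Low-level binary/grayscale morphology used by ROI refinement, seed
// generation and the distance transform. All matrices are column-major
// (R layout); masks are logical matrices, foreground == TRUE.
#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// 8- or 4-connected component labelling (BFS), labels 1..K, background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity = 8) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + H * j);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int d = 0; d < nn; ++d) {
          int qi = pi + di8[d], qj = pj + dj8[d];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + H * qj);
          }
        }
      }
    }
  }
  return lab;
}

// Fill enclosed background holes: background is flood-filled 4-connected
// from the frame border; unreachable background becomes foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix out(H, W);
  std::vector<char> open(static_cast<size_t>(H) * W, 0);
  std::vector<int> stack;
  int di[4] = {-1, 1, 0, 0};
  int dj[4] = {0, 0, -1, 1};
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      bool border = (i == 0 || i == H - 1 || j == 0 || j == W - 1);
      if (border && !mask(i, j) && !open[i + H * j]) {
        open[i + H * j] = 1;
        stack.push_back(i + H * j);
        while (!stack.empty()) {
          int p = stack.back();
          stack.pop_back();
          int pi = p % H, pj = p / H;
          for (int d = 0; d < 4; ++d) {
            int qi = pi + di[d], qj = pj + dj[d];
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            int q = qi + H * qj;
            if (!mask(qi, qj) && !open[q]) {
              open[q] = 1;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = mask(i, j) || !open[i + H * j];
  return out;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance (pixel centres) from each foreground pixel to
// the nearest background pixel. Background pixels map to 0.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  const double INF = 1e18;
  NumericMatrix g(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  // columns first
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = mask(i, j) ? INF : 0.0;
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) g(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = g(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) g(i, j) = d[j];
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) g(i, j) = std::sqrt(g(i, j));
  return g;
}

// Grayscale morphological reconstruction by dilation (8-connected),
// marker <= mask required; iterative raster forward/backward sweeps.
// Used for h-maxima suppression of distance-map peaks.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct(NumericMatrix marker, NumericMatrix mask) {
  int H = marker.nrow(), W = marker.ncol();
  NumericMatrix m = clone(marker);
  bool changed = true;
  int guard = 0;
  while (changed && guard < 10000) {
    changed = false;
    ++guard;
    // forward sweep: neighbours already visited in scan order
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double v = m(i, j);
        if (i > 0) v = std::max(v, m(i - 1, j));
        if (j > 0) {
          v = std::max(v, m(i, j - 1));
          if (i > 0) v = std::max(v, m(i - 1, j - 1));
          if (i < H - 1) v = std::max(v, m(i + 1, j - 1));
        }
        v = std::min(v, mask(i, j));
        if (v > m(i, j)) {
          m(i, j) = v;
          changed = true;
        }
      }
    }
    // backward sweep
    for (int j = W - 1; j >= 0; --j) {
      for (int i = H - 1; i >= 0; --i) {
        double v = m(i, j);
        if (i < H - 1) v = std::max(v, m(i + 1, j));
        if (j < W - 1) {
          v = std::max(v, m(i, j + 1));
          if (i < H - 1) v = std::max(v, m(i + 1, j + 1));
          if (i > 0) v = std::max(v, m(i - 1, j + 1));
        }
        v = std::min(v, mask(i, j));
        if (v > m(i, j)) {
          m(i, j) = v;
          changed = true;
        }
      }
    }
  }
  return m;
}
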