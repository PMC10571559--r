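#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Low-level raster primitives shared by the stitching and segmentation
// stages. Images are base-R numeric matrices (row = y, col = x, 1-based in
// R); all functions here treat them column-major as R stores them.

// ---- connected components ------------------------------------------------

// 8- (default) or 4-connected labeling of a logical mask. Labels are
// assigned in raster-scan discovery order, so output is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int cur = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 4) ? 4 : 8;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++cur;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = cur;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = cur;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  lab.attr("n_labels") = cur;
  return lab;
}

// ---- exact Euclidean distance transform ----------------------------------

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas).
static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z) {
  int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in px) from each TRUE pixel to the nearest
// FALSE pixel; 0 outside the mask. Image border counts as background.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix g(nr, nc);
  // pass 1: columns
  {
    std::vector<double> f(nr), d(nr), z(nr + 1);
    std::vector<int> v(nr);
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
      edt_1d(f, d, v, z);
      for (int r = 0; r < nr; ++r) g(r, c) = d[r];
    }
  }
  // pass 2: rows
  NumericMatrix out(nr, nc);
  {
    std::vector<double> f(nc), d(nc), z(nc + 1);
    std::vector<int> v(nc);
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) f[c] = g(r, c);
      edt_1d(f, d, v, z);
      for (int c = 0; c < nc; ++c) {
        // +1 in each 1-D pass would over-count; add half-pixel so border
        // pixels of a mask have distance ~1 rather than 0 after sqrt? No:
        // keep the exact transform (distance to nearest background pixel).
        out(r, c) = std::sqrt(d[c]);
      }
    }
  }
  return out;
}

// ---- local maxima / marker selection -------------------------------------

// Peak markers for marker-controlled watershed: pixels that are >= every
// neighbor within `min_dist` (Chebyshev window, Euclidean check) and
// inside the mask, greedily suppressed so surviving peaks are >= min_dist
// apart (ties broken by value then raster order). Returns a marker label
// image (0 = no marker).
// [[Rcpp::export]]
IntegerMatrix cpp_peak_markers(NumericMatrix img, LogicalMatrix mask,
                               double min_dist) {
  int nr = img.nrow(), nc = img.ncol();
  int w = (int)std::ceil(min_dist);
  std::vector<int> cand;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      double v = img(r, c);
      if (v <= 0) continue;
      bool ok = true;
      for (int dc = -w; dc <= w && ok; ++dc) {
        int c2 = c + dc; if (c2 < 0 || c2 >= nc) continue;
        for (int dr = -w; dr <= w; ++dr) {
          int r2 = r + dr; if (r2 < 0 || r2 >= nr) continue;
          if (dr == 0 && dc == 0) continue;
          if ((double)dr * dr + (double)dc * dc > min_dist * min_dist) continue;
          double u = img(r2, c2);
          if (u > v || (u == v && (c2 * nr + r2) < (c * nr + r))) { ok = false; break; }
        }
      }
      if (ok) cand.push_back(r + c * nr);
    }
  }
  // greedy suppression by decreasing value
  std::sort(cand.begin(), cand.end(), [&](int a, int b) {
    double va = img[a], vb = img[b];
    if (va != vb) return va > vb;
    return a < b;
  });
  IntegerMatrix markers(nr, nc);
  std::vector<int> kept;
  int lab = 0;
  for (int idx : cand) {
    int r = idx % nr, c = idx / nr;
    bool ok = true;
    for (int j : kept) {
      int rj = j % nr, cj = j / nr;
      double d2 = (double)(r - rj) * (r - rj) + (double)(c - cj) * (c - cj);
      if (d2 < min_dist * min_dist) { ok = false; break; }
    }
    if (ok) { kept.push_back(idx); markers(r, c) = ++lab; }
  }
  markers.attr("n_markers") = lab;
  return markers;
}

// ---- grayscale reconstruction by dilation (Vincent's hybrid) -------------

// Morphological reconstruction of `marker` under `mask_img` (marker <=
// mask_img assumed; clamped otherwise), 8-connected. Used for h-maxima /
// extended-maxima marker detection: peaks whose prominence is below h are
// merged with their neighbors.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct(NumericMatrix marker, NumericMatrix mask_img) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J(nr, nc);
  for (int i = 0; i < nr * nc; ++i)
    J[i] = std::min(marker[i], mask_img[i]);
  const int drp[4] = {-1, 0, -1, -1};  // N, W, NW, NE (raster order)
  const int dcp[4] = {0, -1, -1, 1};
  const int drn[4] = {1, 0, 1, 1};     // S, E, SE, SW (anti-raster)
  const int dcn[4] = {0, 1, 1, -1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  // forward pass
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int r2 = r + drp[k], c2 = c + dcp[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (J(r2, c2) > v) v = J(r2, c2);
      }
      J(r, c) = std::min(v, mask_img(r, c));
    }
  // backward pass, queueing unstable pixels
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int r2 = r + drn[k], c2 = c + dcn[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (J(r2, c2) > v) v = J(r2, c2);
      }
      v = std::min(v, mask_img(r, c));
      J(r, c) = v;
      for (int k = 0; k < 4; ++k) {
        int r2 = r + drn[k], c2 = c + dcn[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (J(r2, c2) < v && J(r2, c2) < mask_img(r2, c2)) {
          fifo.push(r + c * nr);
          break;
        }
      }
    }
  while (!fifo.empty()) {
    int idx = fifo.front(); fifo.pop();
    int r = idx % nr, c = idx / nr;
    double v = J(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr8[k], c2 = c + dc8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (J(r2, c2) < v && J(r2, c2) < mask_img(r2, c2)) {
        double nv = std::min(v, mask_img(r2, c2));
        if (nv > J(r2, c2)) {
          J(r2, c2) = nv;
          fifo.push(r2 + c2 * nr);
        }
      }
    }
  }
  return J;
}

// ---- marker-controlled watershed -----------------------------------------

struct QNode {
  double prio;
  long order;
  int idx;
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // min-heap on priority
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Priority-flood watershed restricted to `mask`, growing from `markers`
// in order of increasing `priority` (use the negated distance transform to
// split convex blobs). Every mask pixel gets exactly one marker label;
// mask components with no marker get fresh labels (flooded from their
// raster-first pixel).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix priority, IntegerMatrix markers,
                            LogicalMatrix mask) {
  int nr = priority.nrow(), nc = priority.ncol();
  IntegerMatrix lab(nr, nc);
  int nmark = 0;
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  long counter = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        if (markers(r, c) > nmark) nmark = markers(r, c);
        pq.push({priority(r, c), counter++, r + c * nr});
      }
    }
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!pq.empty()) {
    QNode nd = pq.top(); pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    int l = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr8[k], c2 = c + dc8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) || lab(r2, c2) != 0) continue;
      lab(r2, c2) = l;
      pq.push({priority(r2, c2), counter++, r2 + c2 * nr});
    }
  }
  // orphan components (no marker): label whole component
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c) && lab(r, c) == 0) {
        ++nmark;
        std::vector<int> stack(1, r + c * nr);
        lab(r, c) = nmark;
        while (!stack.empty()) {
          int idx = stack.back(); stack.pop_back();
          int rr = idx % nr, cc = idx / nr;
          for (int k = 0; k < 8; ++k) {
            int r2 = rr + dr8[k], c2 = cc + dc8[k];
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = nmark;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
  lab.attr("n_labels") = nmark;
  return lab;
}

// ---- boundary metrics: perimeter (chain code) and Feret diameter ---------

// Moore-neighbour contour tracing of the outer boundary of each label.
// Perimeter uses the Vossepoel-Smeulders corrected chain-code length
// (0.980 per axial step, 1.406 per diagonal step), which is accurate to
// ~1% on rasterized disks; isolated pixels get perimeter 4 * 0.980.
// Feret is the maximum caliper diameter: max pairwise distance between
// outer-boundary pixel centres plus 1 px for the pixel extent.
// Returns an (n_labels x 2) matrix [perimeter, feret].
// [[Rcpp::export]]
NumericMatrix cpp_boundary_metrics(IntegerMatrix lab, int n_labels) {
  int nr = lab.nrow(), nc = lab.ncol();
  NumericMatrix out(n_labels, 2);
  // first pixel of each label in raster (column-major) order
  std::vector<int> start(n_labels + 1, -1);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l > 0 && start[l] < 0) start[l] = r + c * nr;
    }
  // Moore neighbourhood in clockwise order starting from W
  const int mr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int mc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  auto at = [&](int r, int c, int l) {
    return r >= 0 && r < nr && c >= 0 && c < nc && lab(r, c) == l;
  };
  std::vector<int> brs, bcs;
  for (int l = 1; l <= n_labels; ++l) {
    if (start[l] < 0) { out(l - 1, 0) = NA_REAL; out(l - 1, 1) = NA_REAL; continue; }
    int r0 = start[l] % nr, c0 = start[l] / nr;
    brs.clear(); bcs.clear();
    brs.push_back(r0); bcs.push_back(c0);
    double na = 0, nd = 0, ncorner = 0;  // axial / diagonal / corner counts
    int prev_dir = -1;
    // trace
    int r = r0, c = c0;
    bool closed = false;
    long guard = 0, maxsteps = 4L * (long)(nr + 2) * (nc + 2);
    // single-pixel check
    bool single = true;
    for (int k = 0; k < 8; ++k)
      if (at(r0 + mr[k], c0 + mc[k], l)) { single = false; break; }
    if (!single) {
      // backtrack = direction to the previous (background) pixel; the
      // raster-first pixel of a label has background to its W
      int b = 0;
      while (!closed && ++guard < maxsteps) {
        int k;
        int found = -1;
        for (k = 0; k < 8; ++k) {
          int kk = (b + 1 + k) % 8;
          int r2 = r + mr[kk], c2 = c + mc[kk];
          if (at(r2, c2, l)) { found = kk; break; }
        }
        if (found < 0) break;  // isolated after all
        int r2 = r + mr[found], c2 = c + mc[found];
        if (mr[found] == 0 || mc[found] == 0) na += 1; else nd += 1;
        if (prev_dir >= 0 && found != prev_dir) ncorner += 1;
        prev_dir = found;
        // next backtrack: direction pointing back to current pixel
        b = (found + 4) % 8;
        // re-orient: Moore tracing uses the neighbour *before* found as
        // next start; using opposite-of-move is the standard radial sweep
        r = r2; c = c2;
        brs.push_back(r); bcs.push_back(c);
        if (r == r0 && c == c0 && brs.size() > 2) closed = true;
      }
    }
    double per;
    if (single) {
      per = 4 * 0.980;  // lone pixel: unit square, corrected
    } else {
      // Vossepoel-Smeulders corrected chain length including the corner
      // term, which removes the over-count at direction changes
      per = 0.980 * na + 1.406 * nd - 0.091 * ncorner;
    }
    // Feret over boundary pixels (brute force; boundaries are short)
    double best = 0;
    int nb = (int)brs.size();
    for (int i = 0; i < nb; ++i)
      for (int j = i + 1; j < nb; ++j) {
        double dr = brs[i] - brs[j], dc = bcs[i] - bcs[j];
        double d2 = dr * dr + dc * dc;
        if (d2 > best) best = d2;
      }
    out(l - 1, 0) = per;
    out(l - 1, 1) = std::sqrt(best) + 1.0;
    }
  return out;
}

// ---- integer-shift normalized cross-correlation --------------------------

// Best integer (dy, dx) in [-max_shift, max_shift]^2 aligning `mov` onto
// `ref` (same size): maximizes the Pearson correlation of the overlapping
// region, requiring at least `min_frac` fractional overlap. Returns
// c(dy, dx, ncc). Zero-variance overlaps score -2 (never win); if every
// candidate is degenerate the returned ncc is -2 and the caller keeps the
// nominal offset.
// [[Rcpp::export]]
NumericVector cpp_best_shift_range(NumericMatrix ref, NumericMatrix mov,
                                   int dy_lo, int dy_hi, int dx_lo,
                                   int dx_hi, double min_frac = 0.3) {
  int nr = ref.nrow(), nc = ref.ncol();
  double best = -2.0;
  int bdy = 0, bdx = 0;
  long minpx = (long)(min_frac * nr * nc);
  if (minpx < 16) minpx = 16;
  for (int dy = dy_lo; dy <= dy_hi; ++dy) {
    for (int dx = dx_lo; dx <= dx_hi; ++dx) {
      // overlap region in ref coords
      int r0 = std::max(0, dy), r1 = std::min(nr, nr + dy);
      int c0 = std::max(0, dx), c1 = std::min(nc, nc + dx);
      long n = (long)(r1 - r0) * (c1 - c0);
      if (n < minpx) continue;
      double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
      for (int c = c0; c < c1; ++c) {
        for (int r = r0; r < r1; ++r) {
          double a = ref(r, c);
          double b = mov(r - dy, c - dx);
          sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
        }
      }
      double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
      if (va <= 1e-12 || vb <= 1e-12) continue;
      double ncc = (sab - sa * sb / n) / std::sqrt(va * vb);
      if (ncc > best + 1e-12 ||
          (std::fabs(ncc - best) <= 1e-12 &&
           (std::abs(dy) + std::abs(dx) < std::abs(bdy) + std::abs(bdx)))) {
        best = ncc; bdy = dy; bdx = dx;
      }
    }
  }
  return NumericVector::create(bdy, bdx, best);
}

// Exhaustive integer-shift search over [-max_shift, max_shift]^2.
// [[Rcpp::export]]
NumericVector cpp_best_shift(NumericMatrix ref, NumericMatrix mov,
                             int max_shift, double min_frac = 0.3) {
  return cpp_best_shift_range(ref, mov, -max_shift, max_shift, -max_shift,
                              max_shift, min_frac);
}

// ---- DBSCAN --------------------------------------------------------------

// Grid-binned DBSCAN with standard core/border/noise semantics.
// Neighbourhoods are closed balls (d <= eps) and include the point itself
// in the core-point count. Cluster ids are assigned in scan order over
// points (deterministic); noise points get 0.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y, double eps,
                         int min_samples) {
  int n = x.size();
  IntegerVector cl(n, 0);
  if (n == 0) return cl;
  double eps2 = eps * eps;
  // grid of cell size eps
  double xmin = x[0], ymin = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (y[i] < ymin) ymin = y[i];
  }
  auto cellx = [&](int i) { return (long)std::floor((x[i] - xmin) / eps); };
  auto celly = [&](int i) { return (long)std::floor((y[i] - ymin) / eps); };
  std::map<std::pair<long, long>, std::vector<int>> grid;
  for (int i = 0; i < n; ++i) grid[{cellx(i), celly(i)}].push_back(i);
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    long cx = cellx(i), cy = celly(i);
    for (long gx = cx - 1; gx <= cx + 1; ++gx)
      for (long gy = cy - 1; gy <= cy + 1; ++gy) {
        auto it = grid.find({gx, gy});
        if (it == grid.end()) continue;
        for (int j : it->second) {
          double dx = x[i] - x[j], dy = y[i] - y[j];
          if (dx * dx + dy * dy <= eps2) nb[i].push_back(j);
        }
      }
  }
  std::vector<char> core(n);
  for (int i = 0; i < n; ++i) core[i] = (int)nb[i].size() >= min_samples;
  int cur = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (cl[i] != 0 || !core[i]) continue;
    ++cur;
    cl[i] = cur;
    stack.assign(1, i);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      for (int q : nb[p]) {
        if (cl[q] == 0) {
          cl[q] = cur;
          if (core[q]) stack.push_back(q);
        }
      }
    }
  }
  return cl;
}
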