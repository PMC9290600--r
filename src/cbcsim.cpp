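#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// ---- connected components ------------------------------------------------
// 4- or 8-connectivity labelling of a logical mask, flood fill with an
// explicit stack. Labels are 1..k in scan order.

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int conn = 4) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int ndir = (conn == 8) ? 8 : 4;
  const int *dr = (conn == 8) ? dr8 : dr4;
  const int *dc = (conn == 8) ? dc8 : dc4;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int d = 0; d < ndir; ++d) {
          int r2 = rr + dr[d], c2 = cc + dc[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---- exact Euclidean distance transform ----------------------------------
// Felzenszwalb & Huttenlocher squared EDT: distance of each foreground pixel
// to the nearest background pixel, in pixel units.

static void edt_1d(std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix D(nr, nc);
  const double BIG = 1e18;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      D(r, c) = mask(r, c) ? BIG : 0.0;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {            // columns
    for (int r = 0; r < nr; ++r) f[r] = D(r, c);
    edt_1d(f, d, nr);
    for (int r = 0; r < nr; ++r) D(r, c) = d[r];
  }
  for (int r = 0; r < nr; ++r) {            // rows
    for (int c = 0; c < nc; ++c) f[c] = D(r, c);
    edt_1d(f, d, nc);
    for (int c = 0; c < nc; ++c) D(r, c) = std::sqrt(d[c]);
  }
  return D;
}

// ---- local maxima with minimum separation --------------------------------
// Candidate peaks are 3x3 local maxima above min_val; peaks are then greedily
// accepted in decreasing value order subject to a minimum mutual distance.
// Returns a 2-column matrix of 1-based (row, col).

// [[Rcpp::export]]
IntegerMatrix cpp_peaks(NumericMatrix img, double min_val, double min_dist) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<std::pair<double, int> > cand;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = img(r, c);
      if (v <= min_val) continue;
      bool ismax = true;
      for (int dc = -1; dc <= 1 && ismax; ++dc)
        for (int dr = -1; dr <= 1 && ismax; ++dr) {
          if (!dr && !dc) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (img(r2, c2) > v) ismax = false;
        }
      if (ismax) cand.push_back(std::make_pair(-v, r + c * nr));
    }
  }
  std::sort(cand.begin(), cand.end());
  std::vector<int> keep;
  double md2 = min_dist * min_dist;
  for (size_t i = 0; i < cand.size(); ++i) {
    int r = cand[i].second % nr, c = cand[i].second / nr;
    bool ok = true;
    for (size_t j = 0; j < keep.size() && ok; ++j) {
      int r2 = keep[j] % nr, c2 = keep[j] / nr;
      double dr = r - r2, dc = c - c2;
      if (dr * dr + dc * dc < md2) ok = false;
    }
    if (ok) keep.push_back(cand[i].second);
  }
  IntegerMatrix out(keep.size(), 2);
  for (size_t i = 0; i < keep.size(); ++i) {
    out(i, 0) = keep[i] % nr + 1;
    out(i, 1) = keep[i] / nr + 1;
  }
  return out;
}

// ---- marker watershed ----------------------------------------------------
// Meyer-style flooding on -elevation restricted to mask: markers grow
// outwards, highest elevation first, each unlabelled pixel joining the
// label of the neighbour that reached it first.

struct WsNode {
  double elev; int ord; int idx;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.elev != b.elev) return a.elev < b.elev;  // max-heap on elevation
    return a.ord > b.ord;                          // FIFO tie-break
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix elev, IntegerMatrix markers, LogicalMatrix mask) {
  int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(clone(markers));
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  const int dr[] = {-1, 1, 0, 0}, dc[] = {0, 0, -1, 1};
  int ord = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0 && mask(r, c)) {
        WsNode n = {elev(r, c), ord++, r + c * nr};
        pq.push(n);
      }
  while (!pq.empty()) {
    WsNode n = pq.top(); pq.pop();
    int r = n.idx % nr, c = n.idx / nr;
    int l = lab(r, c);
    for (int d = 0; d < 4; ++d) {
      int r2 = r + dr[d], c2 = c + dc[d];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) || lab(r2, c2) != 0) continue;
      lab(r2, c2) = l;
      WsNode m = {elev(r2, c2), ord++, r2 + c2 * nr};
      pq.push(m);
    }
  }
  return lab;
}

// ---- hard-core sequential placement --------------------------------------
// Random sequential placement of n discs with hard-core radii rhard inside
// [0,w] x [0,h]: uniform draws, redrawn while colliding with an already
// placed disc, forced into place after max_tries failures. Uses the R RNG,
// so results are reproducible under set.seed(). Returns x, y (same units as
// w/h) and a logical 'forced' flag per cell.

// [[Rcpp::export]]
List cpp_place(double w, double h, NumericVector rhard, int max_tries = 100) {
  int n = rhard.size();
  NumericVector x(n), y(n);
  LogicalVector forced(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, (double)rhard[i]);
  double cell = std::max(2.0 * rmax, 1e-6);
  int gx = std::max(1, (int)std::ceil(w / cell));
  int gy = std::max(1, (int)std::ceil(h / cell));
  std::vector<std::vector<int> > grid(gx * gy);
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    double xi = 0, yi = 0;
    for (int t = 0; t < max_tries && !placed; ++t) {
      xi = unif_rand() * w;
      yi = unif_rand() * h;
      int cx = std::min(gx - 1, (int)(xi / cell));
      int cy = std::min(gy - 1, (int)(yi / cell));
      bool collide = false;
      for (int ax = std::max(0, cx - 1); ax <= std::min(gx - 1, cx + 1) && !collide; ++ax)
        for (int ay = std::max(0, cy - 1); ay <= std::min(gy - 1, cy + 1) && !collide; ++ay) {
          const std::vector<int> &b = grid[ax + ay * gx];
          for (size_t k = 0; k < b.size(); ++k) {
            int j = b[k];
            double dx = xi - x[j], dy = yi - y[j];
            double rr = rhard[i] + rhard[j];
            if (dx * dx + dy * dy < rr * rr) { collide = true; break; }
          }
        }
      if (!collide) placed = true;
    }
    if (!placed) {          // forced placement: one last uniform draw
      xi = unif_rand() * w;
      yi = unif_rand() * h;
      forced[i] = true;
    }
    x[i] = xi; y[i] = yi;
    int cx = std::min(gx - 1, (int)(xi / cell));
    int cy = std::min(gy - 1, (int)(yi / cell));
    grid[cx + cy * gx].push_back(i);
  }
  return List::create(_["x"] = x, _["y"] = y, _["forced"] = forced);
}

// ---- footprint overlap pairs ---------------------------------------------
// Pairs (i, j), 1-based, whose disc footprints intersect: dist < r_i + r_j.

// [[Rcpp::export]]
IntegerMatrix cpp_overlap_pairs(NumericVector x, NumericVector y, NumericVector r) {
  int n = x.size();
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, (double)r[i]);
  std::vector<std::pair<int, int> > pairs;
  if (n > 1 && rmax > 0) {
    double xmin = x[0], ymin = y[0];
    for (int i = 1; i < n; ++i) { xmin = std::min(xmin, (double)x[i]); ymin = std::min(ymin, (double)y[i]); }
    double cell = 2.0 * rmax;
    std::map<std::pair<int, int>, std::vector<int> > grid;
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor((x[i] - xmin) / cell);
      int cy = (int)std::floor((y[i] - ymin) / cell);
      grid[std::make_pair(cx, cy)].push_back(i);
    }
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor((x[i] - xmin) / cell);
      int cy = (int)std::floor((y[i] - ymin) / cell);
      for (int ax = cx - 1; ax <= cx + 1; ++ax)
        for (int ay = cy - 1; ay <= cy + 1; ++ay) {
          std::map<std::pair<int, int>, std::vector<int> >::iterator it =
            grid.find(std::make_pair(ax, ay));
          if (it == grid.end()) continue;
          const std::vector<int> &b = it->second;
          for (size_t k = 0; k < b.size(); ++k) {
            int j = b[k];
            if (j <= i) continue;
            double dx = x[i] - x[j], dy = y[i] - y[j], rr = r[i] + r[j];
            if (dx * dx + dy * dy < rr * rr)
              pairs.push_back(std::make_pair(i + 1, j + 1));
          }
        }
    }
  }
  IntegerMatrix out(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[k].first;
    out(k, 1) = pairs[k].second;
  }
  return out;
}

// ---- primitive painter ----------------------------------------------------
// Adds elliptical primitives into one of three physical rasters:
//   channel 0: hemoglobin optical path density, (g/dl)*um per pixel
//   channel 1: fluorescence signal, UV(365)-excited (nuclear stain)
//   channel 2: fluorescence signal, blue(460)-excited (cytoplasmic stain)
// profile 0: flat (value = amp inside u<=1)
// profile 1: biconcave red-cell profile (value = amp * g(u)),
//            g(u) = sqrt(1-u^2) * (a0 + a1 u^2 + a2 u^4)
// profile 3: spherical dome (value = amp * sqrt(1-u^2))
// u is the normalised elliptical radius; ss subsamples per pixel edge give
// area-weighted anti-aliased edges. Coordinates in um, origin at the
// top-left pixel corner; x = column direction, y = row direction.

static const double BA0 = 0.81, BA1 = 7.83, BA2 = -4.39;

// [[Rcpp::export]]
List cpp_paint(int nrow, int ncol, double px,
               NumericVector x, NumericVector y,
               NumericVector rx, NumericVector ry, NumericVector theta,
               IntegerVector channel, NumericVector amp, IntegerVector profile,
               int ss = 2) {
  NumericMatrix hb(nrow, ncol), f365(nrow, ncol), f460(nrow, ncol);
  int n = x.size();
  double inv_ss2 = 1.0 / (ss * ss);
  for (int i = 0; i < n; ++i) {
    double rmax = std::max(rx[i], ry[i]);
    int c0 = std::max(0, (int)std::floor((x[i] - rmax) / px));
    int c1 = std::min(ncol - 1, (int)std::ceil((x[i] + rmax) / px));
    int r0 = std::max(0, (int)std::floor((y[i] - rmax) / px));
    int r1 = std::min(nrow - 1, (int)std::ceil((y[i] + rmax) / px));
    double ct = std::cos(theta[i]), st = std::sin(theta[i]);
    NumericMatrix &out = (channel[i] == 0) ? hb : (channel[i] == 1 ? f365 : f460);
    for (int c = c0; c <= c1; ++c) {
      for (int r = r0; r <= r1; ++r) {
        double acc = 0.0;
        for (int sx = 0; sx < ss; ++sx) {
          double xs = (c + (sx + 0.5) / ss) * px - x[i];
          for (int sy = 0; sy < ss; ++sy) {
            double ys = (r + (sy + 0.5) / ss) * px - y[i];
            double u1 = (xs * ct + ys * st) / rx[i];
            double u2 = (-xs * st + ys * ct) / ry[i];
            double u2sq = u1 * u1 + u2 * u2;
            if (u2sq >= 1.0) continue;
            if (profile[i] == 0) {
              acc += 1.0;
            } else if (profile[i] == 1) {
              double s = std::sqrt(1.0 - u2sq);
              acc += s * (BA0 + BA1 * u2sq + BA2 * u2sq * u2sq);
            } else {
              acc += std::sqrt(1.0 - u2sq);
            }
          }
        }
        if (acc > 0) out(r, c) += amp[i] * acc * inv_ss2;
      }
    }
  }
  return List::create(_["hb"] = hb, _["f365"] = f365, _["f460"] = f460);
}

// ---- per-label accumulation ----------------------------------------------
// Weighted sums per label over a label raster; returns a matrix with one row
// per label 1..nlab and columns: 0 area, 1 sum(w), 2 sum(w^2), 3 sum(row),
// 4 sum(col), 5 border flag, 6-9 bounding box (rmin, rmax, cmin, cmax,
// 1-based), 10 max(w).

// [[Rcpp::export]]
NumericMatrix cpp_label_stats(IntegerMatrix lab, NumericMatrix w, int nlab) {
  int nr = lab.nrow(), nc = lab.ncol();
  NumericMatrix out(nlab, 11);
  for (int l = 0; l < nlab; ++l) {
    out(l, 6) = nr + 1; out(l, 7) = 0;
    out(l, 8) = nc + 1; out(l, 9) = 0;
    out(l, 10) = -1e300;
  }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l <= 0) continue;
      double v = w(r, c);
      out(l - 1, 0) += 1.0;
      out(l - 1, 1) += v;
      out(l - 1, 2) += v * v;
      out(l - 1, 3) += r + 1;
      out(l - 1, 4) += c + 1;
      if (r == 0 || c == 0 || r == nr - 1 || c == nc - 1) out(l - 1, 5) = 1.0;
      if (r + 1 < out(l - 1, 6)) out(l - 1, 6) = r + 1;
      if (r + 1 > out(l - 1, 7)) out(l - 1, 7) = r + 1;
      if (c + 1 < out(l - 1, 8)) out(l - 1, 8) = c + 1;
      if (c + 1 > out(l - 1, 9)) out(l - 1, 9) = c + 1;
      if (v > out(l - 1, 10)) out(l - 1, 10) = v;
    }
  }
  return out;
}
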