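// Low-level 3D image kernels: connected components, exact Euclidean distance
// transform, seeded watershed, binary morphology, closest-pair search.
// Arrays are R arrays with dim = (nz, ny, nx); the first (z) index varies
// fastest in the linear layout, matching R's column-major order. "Raster
// order" everywhere below means R's linear index order.
#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct Grid {
  int nz, ny, nx;
  R_xlen_t n;
  Grid(IntegerVector dim) {
    nz = dim[0]; ny = dim[1]; nx = dim[2];
    n = (R_xlen_t)nz * ny * nx;
  }
  inline void coords(R_xlen_t i, int &z, int &y, int &x) const {
    z = (int)(i % nz);
    R_xlen_t r = i / nz;
    y = (int)(r % ny);
    x = (int)(r / ny);
  }
  inline R_xlen_t index(int z, int y, int x) const {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  }
  inline bool inside(int z, int y, int x) const {
    return z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
  }
};

// neighbor offsets for 6/18/26 connectivity
std::vector<std::array<int,3> > neighborOffsets(int connectivity) {
  std::vector<std::array<int,3> > off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

} // namespace

// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dim,
                         int connectivity) {
  Grid g(dim);
  std::vector<std::array<int,3> > off = neighborOffsets(connectivity);
  IntegerVector lab(g.n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      int z, y, x;
      g.coords(c, z, y, x);
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (!g.inside(zz, yy, xx)) continue;
        R_xlen_t j = g.index(zz, yy, xx);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("n_labels") = next;
  return lab;
}

namespace {
// 1D squared distance transform (Felzenszwalb & Huttenlocher) with spacing w.
// Unreached sources carry the finite sentinel DT_BIG instead of infinity so
// the parabola-envelope arithmetic stays well defined; any output value that
// large means "no background in the volume".
const double DT_BIG = 1e15;

void dt1d(std::vector<double> &f, std::vector<double> &d, std::vector<int> &v,
          std::vector<double> &zb, int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * (double)q * q) -
           (f[v[k]] + w2 * (double)v[k] * v[k])) /
          (2.0 * w2 * (double)(q - v[k]));
      if (s <= zb[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = w * (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}
} // namespace

// squared Euclidean distance from each foreground voxel to nearest background
// (background voxels get 0); spacing = per-axis voxel size (z,y,x)
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing) {
  Grid g(dim);
  NumericVector out(g.n);
  for (R_xlen_t i = 0; i < g.n; ++i) out[i] = mask[i] ? DT_BIG : 0.0;

  int maxn = std::max(g.nz, std::max(g.ny, g.nx));
  std::vector<double> f(maxn), d(maxn), zb(maxn + 1);
  std::vector<int> v(maxn);

  // pass along z
  for (int x = 0; x < g.nx; ++x)
    for (int y = 0; y < g.ny; ++y) {
      for (int z = 0; z < g.nz; ++z) f[z] = out[g.index(z, y, x)];
      dt1d(f, d, v, zb, g.nz, spacing[0]);
      for (int z = 0; z < g.nz; ++z) out[g.index(z, y, x)] = d[z];
    }
  // pass along y
  for (int x = 0; x < g.nx; ++x)
    for (int z = 0; z < g.nz; ++z) {
      for (int y = 0; y < g.ny; ++y) f[y] = out[g.index(z, y, x)];
      dt1d(f, d, v, zb, g.ny, spacing[1]);
      for (int y = 0; y < g.ny; ++y) out[g.index(z, y, x)] = d[y];
    }
  // pass along x
  for (int y = 0; y < g.ny; ++y)
    for (int z = 0; z < g.nz; ++z) {
      for (int x = 0; x < g.nx; ++x) f[x] = out[g.index(z, y, x)];
      dt1d(f, d, v, zb, g.nx, spacing[2]);
      for (int x = 0; x < g.nx; ++x) out[g.index(z, y, x)] = d[x];
    }
  out.attr("dim") = dim;
  return out;
}

// local maxima of vals over the 26-neighborhood, restricted to mask;
// neighbors outside the mask (or the grid) are ignored
// [[Rcpp::export(name = ".local_maxima3d")]]
LogicalVector local_maxima3d(NumericVector vals, LogicalVector mask,
                             IntegerVector dim) {
  Grid g(dim);
  std::vector<std::array<int,3> > off = neighborOffsets(26);
  LogicalVector out(g.n, FALSE);
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (!mask[i]) continue;
    int z, y, x;
    g.coords(i, z, y, x);
    bool ismax = true;
    for (size_t k = 0; k < off.size() && ismax; ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (!g.inside(zz, yy, xx)) continue;
      R_xlen_t j = g.index(zz, yy, xx);
      if (mask[j] && vals[j] > vals[i]) ismax = false;
    }
    out[i] = ismax;
  }
  out.attr("dim") = dim;
  return out;
}

// regional maxima: connected plateaus (equal value, 26-connected within the
// mask) none of whose voxels has a strictly higher foreground neighbor
// [[Rcpp::export(name = ".regional_maxima3d")]]
LogicalVector regional_maxima3d(NumericVector vals, LogicalVector mask,
                                IntegerVector dim) {
  Grid g(dim);
  std::vector<std::array<int,3> > off = neighborOffsets(26);
  std::vector<int> plateau(g.n, 0);
  LogicalVector out(g.n, FALSE);
  std::vector<R_xlen_t> stack, members;
  int next = 0;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (!mask[i] || plateau[i] != 0) continue;
    ++next;
    bool isMax = true;
    double v = vals[i];
    plateau[i] = next;
    stack.clear();
    members.clear();
    stack.push_back(i);
    members.push_back(i);
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      int z, y, x;
      g.coords(c, z, y, x);
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (!g.inside(zz, yy, xx)) continue;
        R_xlen_t j = g.index(zz, yy, xx);
        if (!mask[j]) continue;
        if (vals[j] > v) { isMax = false; continue; }
        if (vals[j] == v && plateau[j] == 0) {
          plateau[j] = next;
          stack.push_back(j);
          members.push_back(j);
        }
      }
    }
    if (isMax)
      for (size_t k = 0; k < members.size(); ++k) out[members[k]] = TRUE;
  }
  out.attr("dim") = dim;
  return out;
}

// h-maxima prominence filter for watershed seed candidates.  Candidates
// (disjoint plateaus, labeled 1..K in `plateauLab`) are processed in the
// given order; a candidate is suppressed when a flood over voxels with
// value > v_c - h reaches either a strictly higher voxel or an
// already-accepted candidate of equal value — i.e. its prominence is
// below h.  Returns the accepted flags.
// [[Rcpp::export(name = ".hmax_accept")]]
LogicalVector hmax_accept(NumericVector vals, LogicalVector mask,
                          IntegerVector dim, IntegerVector plateauLab,
                          IntegerVector startIdx, NumericVector candVal,
                          IntegerVector order, double h) {
  Grid g(dim);
  std::vector<std::array<int,3> > off = neighborOffsets(26);
  int K = startIdx.size();
  LogicalVector accepted(K, FALSE);
  std::vector<int> stamp(g.n, 0);
  std::vector<R_xlen_t> stack;
  for (int oi = 0; oi < K; ++oi) {
    int c = order[oi] - 1;              // 0-based candidate id
    R_xlen_t s0 = startIdx[c] - 1;      // 0-based voxel index
    double vc = candVal[c];             // true peak height of the plateau
    bool keep = true;
    stack.clear();
    stack.push_back(s0);
    stamp[s0] = c + 1;
    while (!stack.empty() && keep) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z, y, x;
      g.coords(cur, z, y, x);
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (!g.inside(zz, yy, xx)) continue;
        R_xlen_t j = g.index(zz, yy, xx);
        if (!mask[j] || stamp[j] == c + 1) continue;
        if (vals[j] <= vc - h) continue;
        if (vals[j] > vc) { keep = false; break; }
        int pl = plateauLab[j];
        if (pl > 0 && pl != c + 1 && accepted[pl - 1] && vals[j] == vc) {
          keep = false;
          break;
        }
        stamp[j] = c + 1;
        stack.push_back(j);
      }
    }
    accepted[c] = keep;
  }
  return accepted;
}

// Seeded watershed by priority flooding: voxels are claimed in order of
// decreasing priority (here the distance transform), FIFO on ties, so the
// result is deterministic.
// [[Rcpp::export(name = ".watershed3d")]]
IntegerVector watershed3d(NumericVector priority, IntegerVector seeds,
                          LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  Grid g(dim);
  std::vector<std::array<int,3> > off = neighborOffsets(connectivity);
  IntegerVector lab(g.n, 0);
  typedef std::tuple<double, long long, R_xlen_t> Node; // (prio, -order, idx)
  std::priority_queue<Node> pq;
  long long counter = 0;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push(Node(priority[i], -(counter++), i));
    }
  }
  while (!pq.empty()) {
    R_xlen_t c = std::get<2>(pq.top());
    pq.pop();
    int z, y, x;
    g.coords(c, z, y, x);
    int l = lab[c];
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (!g.inside(zz, yy, xx)) continue;
      R_xlen_t j = g.index(zz, yy, xx);
      if (mask[j] && lab[j] == 0) {
        lab[j] = l;
        pq.push(Node(priority[j], -(counter++), j));
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// binary dilation by an explicit offset set (rows: dz, dy, dx)
// [[Rcpp::export(name = ".dilate3d")]]
LogicalVector dilate3d(LogicalVector mask, IntegerVector dim,
                       IntegerMatrix offsets) {
  Grid g(dim);
  LogicalVector out(g.n, FALSE);
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (!mask[i]) continue;
    int z, y, x;
    g.coords(i, z, y, x);
    for (int k = 0; k < offsets.nrow(); ++k) {
      int zz = z + offsets(k, 0), yy = y + offsets(k, 1), xx = x + offsets(k, 2);
      if (g.inside(zz, yy, xx)) out[g.index(zz, yy, xx)] = TRUE;
    }
  }
  out.attr("dim") = dim;
  return out;
}

// binary erosion; out-of-bounds voxels count as foreground so that
// closing = erode(dilate(x)) never clips at the volume boundary
// [[Rcpp::export(name = ".erode3d")]]
LogicalVector erode3d(LogicalVector mask, IntegerVector dim,
                      IntegerMatrix offsets) {
  Grid g(dim);
  LogicalVector out(g.n, FALSE);
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (!mask[i]) continue;
    int z, y, x;
    g.coords(i, z, y, x);
    bool keep = true;
    for (int k = 0; k < offsets.nrow() && keep; ++k) {
      int zz = z + offsets(k, 0), yy = y + offsets(k, 1), xx = x + offsets(k, 2);
      if (g.inside(zz, yy, xx) && !mask[g.index(zz, yy, xx)]) keep = false;
    }
    out[i] = keep;
  }
  out.attr("dim") = dim;
  return out;
}

// closest pair between two voxel coordinate sets (rows: z,y,x), exhaustive;
// rows must be supplied in raster order so the first minimal pair found is
// the raster tie-break. Returns squared distance and 1-based row indices.
// [[Rcpp::export(name = ".min_pair_dist")]]
List min_pair_dist(IntegerMatrix a, IntegerMatrix b) {
  double best = std::numeric_limits<double>::infinity();
  int bi = -1, bj = -1;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      double dz = a(i,0) - b(j,0), dy = a(i,1) - b(j,1), dx = a(i,2) - b(j,2);
      double d2 = dz*dz + dy*dy + dx*dx;
      if (d2 < best) { best = d2; bi = i; bj = j; }
    }
  }
  return List::create(_["dist2"] = best, _["i"] = bi + 1, _["j"] = bj + 1);
}

// per-label voxel counts, centroid sums and inclusive bounding boxes in one
// pass; coordinates are 0-based (z,y,x)
// [[Rcpp::export(name = ".label_stats3d")]]
List label_stats3d(IntegerVector lab, IntegerVector dim, int nlab) {
  Grid g(dim);
  NumericVector cnt(nlab), sz(nlab), sy(nlab), sx(nlab);
  IntegerVector zmin(nlab, INT_MAX), zmax(nlab, -1),
                ymin(nlab, INT_MAX), ymax(nlab, -1),
                xmin(nlab, INT_MAX), xmax(nlab, -1);
  for (R_xlen_t i = 0; i < g.n; ++i) {
    int l = lab[i];
    if (l <= 0) continue;
    int z, y, x;
    g.coords(i, z, y, x);
    int k = l - 1;
    cnt[k] += 1; sz[k] += z; sy[k] += y; sx[k] += x;
    if (z < zmin[k]) zmin[k] = z;
    if (z > zmax[k]) zmax[k] = z;
    if (y < ymin[k]) ymin[k] = y;
    if (y > ymax[k]) ymax[k] = y;
    if (x < xmin[k]) xmin[k] = x;
    if (x > xmax[k]) xmax[k] = x;
  }
  return List::create(_["count"] = cnt, _["sum_z"] = sz, _["sum_y"] = sy,
                      _["sum_x"] = sx, _["zmin"] = zmin, _["zmax"] = zmax,
                      _["ymin"] = ymin, _["ymax"] = ymax, _["xmin"] = xmin,
                      _["xmax"] = xmax);
}
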