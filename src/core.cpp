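// Core 3D lattice operations: connected-component labelling, Euclidean
// distance transform, seeded watershed, separable Gaussian smoothing,
// local maxima, per-slice CLAHE, and isosurface area by marching
// tetrahedra. Arrays arrive as R vectors in column-major (x fastest)
// order with dim = (nx, ny, nz).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <tuple>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
// finite "far" sentinel for the distance transform: infinities would produce
// NaN in the parabola-intersection formula
static const double DT_FAR = 1e20;

// Neighbour offsets for 6/18/26 connectivity.
static void neighbour_offsets(int connectivity,
                              std::vector<int>& dx, std::vector<int>& dy,
                              std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6  && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur - (R_xlen_t)cz * nx * ny);
      int cy = rem / nx, cx = rem % nx;
      for (int k = 0; k < nn; ++k) {
        int x = cx + dx[k], y = cy + dy[k], z = cz + dz[k];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        R_xlen_t j = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Felzenszwalb & Huttenlocher 1D squared distance transform.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from every voxel to the nearest
// site voxel. Voxels with sites[i] == TRUE get 0.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector sites, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = sites[i] ? 0.0 : DT_FAR;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f, out, nx, v, z);
      for (int x = 0; x < nx; ++x) d[base + x] = out[x];
    }
  // pass along y
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (R_xlen_t)y * nx];
      dt1d(f, out, ny, v, z);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)y * nx] = out[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int zz = 0; zz < nz; ++zz) f[zz] = d[base + (R_xlen_t)zz * nx * ny];
      dt1d(f, out, nz, v, z);
      for (int zz = 0; zz < nz; ++zz) d[base + (R_xlen_t)zz * nx * ny] = out[zz];
    }
  return d;
}

// Seeded watershed by priority flooding: regions grow from labelled seeds
// across the mask in order of decreasing priority (ties broken FIFO, so the
// result is deterministic for a fixed seed order).
// [[Rcpp::export]]
IntegerVector cpp_watershed_seeded(NumericVector priority, IntegerVector seeds,
                                   LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();
  typedef std::tuple<double, long long, R_xlen_t> Node; // (-pri, order, idx)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  long long order = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0) {
      lab[i] = seeds[i];
      pq.push(Node(-priority[i], order++, i));
    }
  while (!pq.empty()) {
    R_xlen_t cur = std::get<2>(pq.top());
    pq.pop();
    int cz = (int)(cur / ((R_xlen_t)nx * ny));
    int rem = (int)(cur - (R_xlen_t)cz * nx * ny);
    int cy = rem / nx, cx = rem % nx;
    int l = lab[cur];
    for (int k = 0; k < nn; ++k) {
      int x = cx + dx[k], y = cy + dy[k], z = cz + dz[k];
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      R_xlen_t j = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = l;
      pq.push(Node(-priority[j], order++, j));
    }
  }
  return lab;
}

// Separable Gaussian smoothing with reflective boundaries.
static void conv1d_axis(std::vector<double>& buf, const std::vector<double>& ker,
                        std::vector<double>& tmp) {
  const int n = (int)buf.size();
  const int r = ((int)ker.size() - 1) / 2;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = -r; k <= r; ++k) {
      int j = i + k;
      if (j < 0) j = -j - 1;
      if (j >= n) j = 2 * n - j - 1;
      acc += buf[j] * ker[k + r];
    }
    tmp[i] = acc;
  }
  buf = tmp;
}

// [[Rcpp::export]]
NumericVector cpp_gaussian3d(NumericVector vol, IntegerVector dim,
                             double sx, double sy, double sz) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  double sig[3] = {sx, sy, sz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sig[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.5 * s);
    std::vector<double> ker(2 * r + 1);
    double tot = 0.0;
    for (int k = -r; k <= r; ++k) {
      ker[k + r] = std::exp(-0.5 * k * k / (s * s));
      tot += ker[k + r];
    }
    for (double& v : ker) v /= tot;
    int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
    std::vector<double> buf(len), tmp(len);
    if (axis == 0) {
      for (int zz = 0; zz < nz; ++zz)
        for (int y = 0; y < ny; ++y) {
          R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)y * nx;
          for (int x = 0; x < nx; ++x) buf[x] = out[base + x];
          conv1d_axis(buf, ker, tmp);
          for (int x = 0; x < nx; ++x) out[base + x] = buf[x];
        }
    } else if (axis == 1) {
      for (int zz = 0; zz < nz; ++zz)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t base = (R_xlen_t)zz * nx * ny + x;
          for (int y = 0; y < ny; ++y) buf[y] = out[base + (R_xlen_t)y * nx];
          conv1d_axis(buf, ker, tmp);
          for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = buf[y];
        }
    } else {
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t base = (R_xlen_t)y * nx + x;
          for (int zz = 0; zz < nz; ++zz)
            buf[zz] = out[base + (R_xlen_t)zz * nx * ny];
          conv1d_axis(buf, ker, tmp);
          for (int zz = 0; zz < nz; ++zz)
            out[base + (R_xlen_t)zz * nx * ny] = buf[zz];
        }
    }
  }
  return out;
}

// 1-based linear indices of voxels that are >= all their in-volume
// neighbours and lie inside the mask (plateaus report every member).
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector vol, LogicalVector mask,
                               IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();
  std::vector<R_xlen_t> hits;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int cz = (int)(i / ((R_xlen_t)nx * ny));
    int rem = (int)(i - (R_xlen_t)cz * nx * ny);
    int cy = rem / nx, cx = rem % nx;
    bool ok = true;
    for (int k = 0; k < nn && ok; ++k) {
      int x = cx + dx[k], y = cy + dy[k], z = cz + dz[k];
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      R_xlen_t j = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
      if (vol[j] > vol[i]) ok = false;
    }
    if (ok) hits.push_back(i + 1);
  }
  return wrap(hits);
}

// CLAHE on one slice. Tiles of `tile` x `tile` pixels partition the slice
// (the trailing tile absorbs the remainder); each tile's histogram is
// clipped at clip_fraction * tile_pixels with uniform redistribution of the
// excess, and pixels are mapped through bilinear interpolation of the
// neighbouring tile CDFs. Input values are assumed in [0, 1].
// [[Rcpp::export]]
NumericMatrix cpp_clahe_slice(NumericMatrix img, int tile, double clip_fraction,
                              int nbins) {
  const int nr = img.nrow(), nc = img.ncol();
  const int ntr = std::max(1, nr / tile);
  const int ntc = std::max(1, nc / tile);
  std::vector<int> r0(ntr), r1(ntr), c0(ntc), c1(ntc);
  for (int t = 0; t < ntr; ++t) {
    r0[t] = t * tile;
    r1[t] = (t == ntr - 1) ? nr : (t + 1) * tile;
  }
  for (int t = 0; t < ntc; ++t) {
    c0[t] = t * tile;
    c1[t] = (t == ntc - 1) ? nc : (t + 1) * tile;
  }
  std::vector<double> rc(ntr), cc(ntc); // tile centres
  for (int t = 0; t < ntr; ++t) rc[t] = 0.5 * (r0[t] + r1[t]) - 0.5;
  for (int t = 0; t < ntc; ++t) cc[t] = 0.5 * (c0[t] + c1[t]) - 0.5;

  // per-tile clipped-CDF lookup tables
  std::vector<std::vector<double> > map((size_t)ntr * ntc,
                                        std::vector<double>(nbins));
  std::vector<double> hist(nbins);
  for (int tr = 0; tr < ntr; ++tr)
    for (int tc = 0; tc < ntc; ++tc) {
      std::fill(hist.begin(), hist.end(), 0.0);
      double npx = 0.0;
      for (int c = c0[tc]; c < c1[tc]; ++c)
        for (int r = r0[tr]; r < r1[tr]; ++r) {
          int b = (int)(img(r, c) * (nbins - 1) + 0.5);
          if (b < 0) b = 0;
          if (b >= nbins) b = nbins - 1;
          hist[b] += 1.0;
          npx += 1.0;
        }
      if (clip_fraction > 0 && clip_fraction < 1) {
        double clip = clip_fraction * npx;
        if (clip < 1.0) clip = 1.0;
        double excess = 0.0;
        for (int b = 0; b < nbins; ++b)
          if (hist[b] > clip) { excess += hist[b] - clip; hist[b] = clip; }
        double add = excess / nbins;
        for (int b = 0; b < nbins; ++b) hist[b] += add;
      }
      double cum = 0.0;
      std::vector<double>& m = map[(size_t)tr * ntc + tc];
      for (int b = 0; b < nbins; ++b) {
        cum += hist[b];
        m[b] = cum / npx;
      }
    }

  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    // column tile interpolation weights
    int tc0 = 0;
    while (tc0 < ntc - 1 && cc[tc0 + 1] < c) ++tc0;
    int tc1 = tc0;
    double wc = 0.0;
    if (c > cc[tc0] && tc0 < ntc - 1) {
      tc1 = tc0 + 1;
      wc = (c - cc[tc0]) / (cc[tc1] - cc[tc0]);
    } else if (c < cc[tc0] && tc0 > 0) {
      tc1 = tc0 - 1;
      wc = (cc[tc0] - c) / (cc[tc0] - cc[tc1]);
    }
    for (int r = 0; r < nr; ++r) {
      int tr0 = 0;
      while (tr0 < ntr - 1 && rc[tr0 + 1] < r) ++tr0;
      int tr1 = tr0;
      double wr = 0.0;
      if (r > rc[tr0] && tr0 < ntr - 1) {
        tr1 = tr0 + 1;
        wr = (r - rc[tr0]) / (rc[tr1] - rc[tr0]);
      } else if (r < rc[tr0] && tr0 > 0) {
        tr1 = tr0 - 1;
        wr = (rc[tr0] - r) / (rc[tr0] - rc[tr1]);
      }
      int b = (int)(img(r, c) * (nbins - 1) + 0.5);
      if (b < 0) b = 0;
      if (b >= nbins) b = nbins - 1;
      double v00 = map[(size_t)tr0 * ntc + tc0][b];
      double v10 = map[(size_t)tr1 * ntc + tc0][b];
      double v01 = map[(size_t)tr0 * ntc + tc1][b];
      double v11 = map[(size_t)tr1 * ntc + tc1][b];
      out(r, c) = (1 - wr) * (1 - wc) * v00 + wr * (1 - wc) * v10 +
                  (1 - wr) * wc * v01 + wr * wc * v11;
    }
  }
  return out;
}

// Isosurface area of a scalar field at `level` by marching tetrahedra
// (each lattice cell split into 6 tetrahedra around the main diagonal;
// linear interpolation along edges). Returns area in voxel^2 units.
static inline void interp_pt(const double p1[3], const double p2[3],
                             double v1, double v2, double level, double out[3]) {
  double t = (v2 == v1) ? 0.5 : (level - v1) / (v2 - v1);
  for (int k = 0; k < 3; ++k) out[k] = p1[k] + t * (p2[k] - p1[k]);
}

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                 u[0] * v[1] - u[1] * v[0]};
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector field, IntegerVector dim,
                           double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // cube corner offsets
  static const int CO[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                               {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  // 6 tetrahedra around diagonal v0-v6
  static const int TET[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  double area = 0.0;
  double cv[8];
  double cp[8][3];
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any_in = false, any_out = false;
        for (int k = 0; k < 8; ++k) {
          int xx = x + CO[k][0], yy = y + CO[k][1], zz = z + CO[k][2];
          cv[k] = field[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
          cp[k][0] = xx; cp[k][1] = yy; cp[k][2] = zz;
          if (cv[k] >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int in_idx[4], out_idx[4];
          int ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            int c = TET[t][k];
            if (cv[c] >= level) in_idx[ni++] = c; else out_idx[no++] = c;
          }
          if (ni == 0 || ni == 4) continue;
          double p[4][3];
          if (ni == 1) {
            for (int k = 0; k < 3; ++k)
              interp_pt(cp[in_idx[0]], cp[out_idx[k]], cv[in_idx[0]],
                        cv[out_idx[k]], level, p[k]);
            area += tri_area(p[0], p[1], p[2]);
          } else if (ni == 3) {
            for (int k = 0; k < 3; ++k)
              interp_pt(cp[out_idx[0]], cp[in_idx[k]], cv[out_idx[0]],
                        cv[in_idx[k]], level, p[k]);
            area += tri_area(p[0], p[1], p[2]);
          } else { // ni == 2: quad (A-C, A-D, B-D, B-C)
            interp_pt(cp[in_idx[0]], cp[out_idx[0]], cv[in_idx[0]],
                      cv[out_idx[0]], level, p[0]);
            interp_pt(cp[in_idx[0]], cp[out_idx[1]], cv[in_idx[0]],
                      cv[out_idx[1]], level, p[1]);
            interp_pt(cp[in_idx[1]], cp[out_idx[1]], cv[in_idx[1]],
                      cv[out_idx[1]], level, p[2]);
            interp_pt(cp[in_idx[1]], cp[out_idx[0]], cv[in_idx[1]],
                      cv[out_idx[0]], level, p[3]);
            area += tri_area(p[0], p[1], p[2]);
            area += tri_area(p[0], p[2], p[3]);
          }
        }
      }
  return area;
}

// Greedy minimum-separation suppression of candidate points ordered by
// decreasing score (ties by candidate order, which the caller fixes to
// lexicographic voxel index). Returns 1-based indices into the candidate
// list of the accepted points. Candidates carry a group id; separation is
// only enforced between accepted candidates of the same group.
// [[Rcpp::export]]
IntegerVector cpp_min_separation_filter(NumericMatrix pts, NumericVector score,
                                        IntegerVector group, double min_dist) {
  const int n = pts.nrow();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return score[a] > score[b]; });
  std::vector<int> accepted;
  double d2 = min_dist * min_dist;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    bool ok = true;
    for (int j : accepted) {
      if (group[j] != group[i]) continue;
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      if (dx * dx + dy * dy + dz * dz < d2) { ok = false; break; }
    }
    if (ok) accepted.push_back(i);
  }
  IntegerVector out((int)accepted.size());
  for (size_t k = 0; k < accepted.size(); ++k) out[k] = accepted[k] + 1;
  return out;
}
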