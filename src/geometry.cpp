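// 3D geometry kernels for voxel masks: exact Euclidean distance transform,
// topological thinning, isosurface area, and small search helpers.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Felzenszwalb & Huttenlocher 1D squared distance transform (lower envelope
// of parabolas), applied separably along the three axes.
// "absent" sources carry a large finite cost instead of infinity so the
// parabola intersections stay well defined.
static const double BIG = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (k > 0 && s <= z[k]) { --k; } else break;
    }
    if (s <= z[k]) {  // k == 0: replace the only parabola
      v[0] = q;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared distance of every voxel to the nearest TRUE voxel of `target`.
// Array layout is R column-major with dims (n1, n2, n3).
static std::vector<double> edt_sq(const std::vector<char>& target,
                                  int n1, int n2, int n3) {
  std::vector<double> d((size_t)n1 * n2 * n3);
  for (size_t i = 0; i < d.size(); ++i) d[i] = target[i] ? 0.0 : BIG;

  std::vector<double> f, g;
  // pass along axis 1 (stride 1)
  f.resize(n1); g.resize(n1);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      size_t base = (size_t)k * n1 * n2 + (size_t)j * n1;
      for (int i = 0; i < n1; ++i) f[i] = d[base + i];
      dt1d(f, g, n1);
      for (int i = 0; i < n1; ++i) d[base + i] = g[i];
    }
  // axis 2 (stride n1)
  f.resize(n2); g.resize(n2);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      size_t base = (size_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; ++j) f[j] = d[base + (size_t)j * n1];
      dt1d(f, g, n2);
      for (int j = 0; j < n2; ++j) d[base + (size_t)j * n1] = g[j];
    }
  // axis 3 (stride n1*n2)
  f.resize(n3); g.resize(n3);
  size_t s3 = (size_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      size_t base = (size_t)j * n1 + i;
      for (int k = 0; k < n3; ++k) f[k] = d[base + (size_t)k * s3];
      dt1d(f, g, n3);
      for (int k = 0; k < n3; ++k) d[base + (size_t)k * s3] = g[k];
    }
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_dist_to_mask(LogicalVector target) {
  IntegerVector dim = target.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  std::vector<char> t(target.size());
  bool any = false;
  for (R_xlen_t i = 0; i < target.size(); ++i) {
    t[i] = (target[i] == TRUE);
    if (t[i]) any = true;
  }
  NumericVector out(target.size());
  if (!any) {
    std::fill(out.begin(), out.end(), R_PosInf);
  } else {
    std::vector<double> d = edt_sq(t, n1, n2, n3);
    for (R_xlen_t i = 0; i < out.size(); ++i)
      out[i] = (d[i] >= 1e19) ? R_PosInf : std::sqrt(d[i]);
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving sequential thinning.
//
// A border voxel may be deleted when it is "simple" (deletion preserves both
// foreground 26-topology and background 6-topology) and is not a curve
// endpoint.  Candidates are processed in order of increasing distance to the
// background (then lexicographic index) so the medial curve emerges centred.

struct Nbr { int dz, dy, dx; };

static bool simple_point(const std::vector<char>& m, int n1, int n2, int n3,
                         int i, int j, int k) {
  // collect 3x3x3 neighbourhood (center excluded) into a flat cube
  char cube[27];
  int idx = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++idx) {
        int ii = i + di, jj = j + dj, kk = k + dk;
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
          cube[idx] = 0;
        else
          cube[idx] = m[(size_t)kk * n1 * n2 + (size_t)jj * n1 + ii];
      }
  const int center = 13;

  // C*: number of 26-connected components of foreground in N26
  int labels[27];
  for (int a = 0; a < 27; ++a) labels[a] = -1;
  int ncomp_fg = 0;
  for (int a = 0; a < 27; ++a) {
    if (a == center || !cube[a] || labels[a] >= 0) continue;
    // BFS
    std::vector<int> stack{a};
    labels[a] = ncomp_fg;
    while (!stack.empty()) {
      int b = stack.back(); stack.pop_back();
      int bz = b / 9, by = (b % 9) / 3, bx = b % 3;
      for (int c = 0; c < 27; ++c) {
        if (c == center || !cube[c] || labels[c] >= 0) continue;
        int cz = c / 9, cy = (c % 9) / 3, cx = c % 3;
        if (std::abs(bz - cz) <= 1 && std::abs(by - cy) <= 1 &&
            std::abs(bx - cx) <= 1) {
          labels[c] = ncomp_fg;
          stack.push_back(c);
        }
      }
    }
    ++ncomp_fg;
  }
  if (ncomp_fg != 1) return false;

  // C^bar: 6-connected components of background within N18 that touch a
  // 6-neighbour of the center.
  auto in_n18 = [](int a) {
    int az = a / 9 - 1, ay = (a % 9) / 3 - 1, ax = a % 3 - 1;
    int s = std::abs(az) + std::abs(ay) + std::abs(ax);
    return s >= 1 && s <= 2;
  };
  auto is_face = [](int a) {
    int az = a / 9 - 1, ay = (a % 9) / 3 - 1, ax = a % 3 - 1;
    return std::abs(az) + std::abs(ay) + std::abs(ax) == 1;
  };
  for (int a = 0; a < 27; ++a) labels[a] = -1;
  int ncomp_bg = 0;
  for (int a = 0; a < 27; ++a) {
    if (!in_n18(a) || cube[a] || labels[a] >= 0) continue;
    bool touches_face = false;
    std::vector<int> stack{a};
    labels[a] = ncomp_bg;
    std::vector<int> comp{a};
    while (!stack.empty()) {
      int b = stack.back(); stack.pop_back();
      if (is_face(b)) touches_face = true;
      int bz = b / 9, by = (b % 9) / 3, bx = b % 3;
      for (int c = 0; c < 27; ++c) {
        if (!in_n18(c) || cube[c] || labels[c] >= 0) continue;
        int cz = c / 9, cy = (c % 9) / 3, cx = c % 3;
        if (std::abs(bz - cz) + std::abs(by - cy) + std::abs(bx - cx) == 1) {
          labels[c] = ncomp_bg;
          stack.push_back(c);
        }
      }
    }
    if (touches_face) ++ncomp_bg;
  }
  return ncomp_bg == 1;
}

static int count_fg26(const std::vector<char>& m, int n1, int n2, int n3,
                      int i, int j, int k) {
  int cnt = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int ii = i + di, jj = j + dj, kk = k + dk;
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
          continue;
        if (m[(size_t)kk * n1 * n2 + (size_t)jj * n1 + ii]) ++cnt;
      }
  return cnt;
}

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t nn = (size_t)n1 * n2 * n3;
  std::vector<char> m(nn), bg(nn);
  for (size_t i = 0; i < nn; ++i) { m[i] = (mask[i] == TRUE); bg[i] = !m[i]; }

  std::vector<double> dist = edt_sq(bg, n1, n2, n3);  // squared dist to background

  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool changed = true;
  while (changed) {
    changed = false;
    // candidate border voxels with sort keys
    std::vector<std::pair<double, size_t>> cand;
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          size_t p = (size_t)k * n1 * n2 + (size_t)j * n1 + i;
          if (!m[p]) continue;
          bool border = false;
          for (int a = 0; a < 6 && !border; ++a) {
            int ii = i + d6[a][0], jj = j + d6[a][1], kk = k + d6[a][2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3 ||
                !m[(size_t)kk * n1 * n2 + (size_t)jj * n1 + ii])
              border = true;
          }
          if (border) cand.push_back({dist[p], p});
        }
    std::sort(cand.begin(), cand.end());
    for (auto& c : cand) {
      size_t p = c.second;
      if (!m[p]) continue;
      int i = (int)(p % n1), j = (int)((p / n1) % n2), k = (int)(p / ((size_t)n1 * n2));
      if (count_fg26(m, n1, n2, n3, i, j, k) <= 1) continue;  // endpoint
      if (simple_point(m, n1, n2, n3, i, j, k)) {
        m[p] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(mask.size());
  for (size_t i = 0; i < nn; ++i) out[i] = m[i] ? TRUE : FALSE;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra surface area.  Each unit cube is split into six
// tetrahedra sharing the main diagonal; the level-set crossing within a
// tetrahedron is a triangle (1 or 3 corners inside) or a quad (2 corners).
// Case geometry is derived on the fly, so no lookup tables are required.

static double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double w[3] = {u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0]};
  return 0.5 * std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
}

// [[Rcpp::export]]
double cpp_mesh_area(NumericVector vol, double level) {
  IntegerVector dim = vol.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  // cube corner offsets (i, j, k): order fixes the shared main diagonal 0-6
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {
    {0,1,2,6},{0,1,6,5},{0,5,6,4},{0,2,3,6},{0,3,7,6},{0,4,6,7}};

  auto at = [&](int i, int j, int k) {
    return vol[(size_t)k * n1 * n2 + (size_t)j * n1 + i];
  };

  double area = 0.0;
  for (int k = 0; k + 1 < n3; ++k)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        double v[8]; double lo = INF, hi = -INF;
        for (int c = 0; c < 8; ++c) {
          v[c] = at(i + corner[c][0], j + corner[c][1], k + corner[c][2]);
          lo = std::min(lo, v[c]); hi = std::max(hi, v[c]);
        }
        if (lo >= level || hi < level) continue;
        for (int t = 0; t < 6; ++t) {
          double tv[4]; double tp[4][3];
          int inside[4], ni = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = tets[t][c];
            tv[c] = v[cc];
            tp[c][0] = i + corner[cc][0];
            tp[c][1] = j + corner[cc][1];
            tp[c][2] = k + corner[cc][2];
            inside[c] = tv[c] >= level;
            ni += inside[c];
          }
          if (ni == 0 || ni == 4) continue;
          auto interp = [&](int a, int b, double out[3]) {
            double tt = (level - tv[a]) / (tv[b] - tv[a]);
            for (int d = 0; d < 3; ++d) out[d] = tp[a][d] + tt * (tp[b][d] - tp[a][d]);
          };
          if (ni == 1 || ni == 3) {
            int lone = -1;
            for (int c = 0; c < 4; ++c)
              if ((ni == 1 && inside[c]) || (ni == 3 && !inside[c])) lone = c;
            double p[3][3]; int np = 0;
            for (int c = 0; c < 4; ++c)
              if (c != lone) interp(lone, c, p[np++]);
            area += tri_area(p[0], p[1], p[2]);
          } else {  // ni == 2: quad from crossing edges a-c, a-d, b-d, b-c
            int in[2], out2[2], na = 0, nb = 0;
            for (int c = 0; c < 4; ++c)
              if (inside[c]) in[na++] = c; else out2[nb++] = c;
            double pac[3], pad[3], pbd[3], pbc[3];
            interp(in[0], out2[0], pac);
            interp(in[0], out2[1], pad);
            interp(in[1], out2[1], pbd);
            interp(in[1], out2[0], pbc);
            area += tri_area(pac, pad, pbd);
            area += tri_area(pac, pbd, pbc);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// For each query point, index (1-based) of the nearest reference point.
// Ties resolved toward the reference with the lowest lexicographic
// coordinates (compare dim-3, then dim-2, then dim-1 ascending).

// [[Rcpp::export]]
IntegerVector cpp_nearest_ref(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("empty reference set");
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double best = INF; int bi = -1;
    for (int r = 0; r < nr; ++r) {
      double d = 0;
      for (int c = 0; c < 3; ++c) {
        double u = query(q, c) - ref(r, c);
        d += u * u;
      }
      bool better = d < best;
      if (!better && d == best && bi >= 0) {
        for (int c = 2; c >= 0; --c) {
          if (ref(r, c) < ref(bi, c)) { better = true; break; }
          if (ref(r, c) > ref(bi, c)) break;
        }
      }
      if (better) { best = d; bi = r; }
    }
    out[q] = bi + 1;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_max_pairwise(NumericMatrix pts) {
  int n = pts.nrow();
  double best = 0.0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      double d = 0;
      for (int c = 0; c < 3; ++c) {
        double u = pts(a, c) - pts(b, c);
        d += u * u;
      }
      if (d > best) best = d;
    }
  return std::sqrt(best);
}
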