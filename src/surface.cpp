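#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
#include "cell_list.h"
using namespace Rcpp;

// Sum of truncated Gaussian kernels exp(-d^2 / (2 r'^2)) with
// r' = radius_scale * (radius + radius_offset), evaluated on a regular grid.
// [[Rcpp::export]]
NumericVector cpp_gaussian_grid(NumericMatrix coords, NumericVector radii,
                                NumericVector origin, IntegerVector dims,
                                double spacing, double radius_offset,
                                double radius_scale, double kernel_trunc) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector grid((R_xlen_t)nx * ny * nz);
  const double t2 = kernel_trunc * kernel_trunc;
  for (int a = 0; a < coords.nrow(); ++a) {
    const double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    const double rp = radius_scale * (radii[a] + radius_offset);
    const double inv2r2 = 1.0 / (2.0 * rp * rp);
    int i0 = std::max(0, (int)std::ceil((cx - kernel_trunc - origin[0]) / spacing));
    int i1 = std::min(nx - 1, (int)std::floor((cx + kernel_trunc - origin[0]) / spacing));
    int j0 = std::max(0, (int)std::ceil((cy - kernel_trunc - origin[1]) / spacing));
    int j1 = std::min(ny - 1, (int)std::floor((cy + kernel_trunc - origin[1]) / spacing));
    int k0 = std::max(0, (int)std::ceil((cz - kernel_trunc - origin[2]) / spacing));
    int k1 = std::min(nz - 1, (int)std::floor((cz + kernel_trunc - origin[2]) / spacing));
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * spacing - cz, dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * spacing - cy, dyz2 = dy * dy + dz2;
        if (dyz2 > t2) continue;
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * spacing - cx;
          double d2 = dx * dx + dyz2;
          if (d2 > t2) continue;
          grid[base + i] += std::exp(-d2 * inv2r2);
        }
      }
    }
  }
  return grid;
}

// --- isosurface extraction -------------------------------------------------
// Each grid cell is decomposed into the six Kuhn tetrahedra sharing the main
// diagonal; the iso-level crossing within each tetrahedron is triangulated
// with linear interpolation along the crossed edges. The decomposition is
// translation-consistent, so shared cell faces carry matching diagonals and
// the resulting mesh is watertight. Interpolated vertices are welded by the
// (grid-point, grid-point) edge they sit on.

static const int TET[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

// local corner -> (dx, dy, dz)
static const int CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

// [[Rcpp::export]]
List cpp_isosurface(NumericVector grid, IntegerVector dims,
                    NumericVector origin, double spacing, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<uint64_t, int> edge_vertex;

  auto gid = [&](int i, int j, int k) -> R_xlen_t {
    return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };
  // vertex on grid edge (g0, g1), value v0 at g0, v1 at g1 straddling iso
  auto edge_point = [&](R_xlen_t g0, R_xlen_t g1, double v0, double v1) -> int {
    if (g0 > g1) { std::swap(g0, g1); std::swap(v0, v1); }
    uint64_t key = (uint64_t)g0 * (uint64_t)(nx * (R_xlen_t)ny * nz) + (uint64_t)g1;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - v0) / (v1 - v0);
    int i0 = (int)(g0 % nx), j0 = (int)((g0 / nx) % ny), k0 = (int)(g0 / ((R_xlen_t)nx * ny));
    int i1 = (int)(g1 % nx), j1 = (int)((g1 / nx) % ny), k1 = (int)(g1 / ((R_xlen_t)nx * ny));
    vx.push_back(origin[0] + spacing * (i0 + t * (i1 - i0)));
    vy.push_back(origin[1] + spacing * (j0 + t * (j1 - j0)));
    vz.push_back(origin[2] + spacing * (k0 + t * (k1 - k0)));
    int id = (int)vx.size();  // 1-based
    edge_vertex[key] = id;
    return id;
  };

  R_xlen_t cg[8];
  double cv[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c) {
          cg[c] = gid(i + CORNER[c][0], j + CORNER[c][1], k + CORNER[c][2]);
          cv[c] = grid[cg[c]];
        }
        for (int t = 0; t < 6; ++t) {
          const int* T = TET[t];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            in[c] = cv[T[c]] > iso;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          int a[4], b[4], na = 0, nb = 0;  // a: inside, b: outside
          for (int c = 0; c < 4; ++c) (in[c] ? a[na++] : b[nb++]) = T[c];
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? a[0] : b[0];
            const int* base = (nin == 1) ? b : a;
            int p0 = edge_point(cg[apex], cg[base[0]], cv[apex], cv[base[0]]);
            int p1 = edge_point(cg[apex], cg[base[1]], cv[apex], cv[base[1]]);
            int p2 = edge_point(cg[apex], cg[base[2]], cv[apex], cv[base[2]]);
            tri.push_back(p0); tri.push_back(p1); tri.push_back(p2);
          } else {  // 2 in, 2 out -> quad, split into two triangles
            int p00 = edge_point(cg[a[0]], cg[b[0]], cv[a[0]], cv[b[0]]);
            int p01 = edge_point(cg[a[0]], cg[b[1]], cv[a[0]], cv[b[1]]);
            int p10 = edge_point(cg[a[1]], cg[b[0]], cv[a[1]], cv[b[0]]);
            int p11 = edge_point(cg[a[1]], cg[b[1]], cv[a[1]], cv[b[1]]);
            tri.push_back(p00); tri.push_back(p01); tri.push_back(p11);
            tri.push_back(p00); tri.push_back(p11); tri.push_back(p10);
          }
        }
      }

  int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v]; }
  IntegerMatrix Tm(nt, 3);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 3; ++c) Tm(t, c) = tri[3 * t + c];
  return List::create(_["vertices"] = V, _["triangles"] = Tm);
}

// --- Shrake-Rupley ---------------------------------------------------------
// Deterministic golden-spiral sphere points; a point is buried when inside
// the expanded sphere (r_j + probe) of any other atom.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  int n = coords.nrow();
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  double cut = 2.0 * (rmax + probe);
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  NumericVector nobox(3);
  CellList cl(coords, rows, cut, nobox);

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int p = 0; p < n_points; ++p) {
    double z = 1.0 - 2.0 * (p + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    px[p] = r * std::cos(ga * p);
    py[p] = r * std::sin(ga * p);
    pz[p] = z;
  }

  NumericVector area(n);
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    nbr.clear();
    cl.visit_neighbors(coords, i, [&](int j) {
      if (j == i) return;
      double d2 = cl.dist2(coords, i, j);
      double rr = ri + radii[j] + probe;
      if (d2 < rr * rr) nbr.push_back(j);
    });
    int exposed = 0;
    for (int p = 0; p < n_points; ++p) {
      double x = coords(i, 0) + ri * px[p];
      double y = coords(i, 1) + ri * py[p];
      double z = coords(i, 2) + ri * pz[p];
      bool buried = false;
      for (int j : nbr) {
        double dx = x - coords(j, 0), dy = y - coords(j, 1), dz = z - coords(j, 2);
        double rj = radii[j] + probe;
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri * ri * exposed / n_points;
  }
  return area;
}
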