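#ifndef LIGNOCONTACT_CELL_LIST_H
#define LIGNOCONTACT_CELL_LIST_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// Orthorhombic cell list. If box[k] <= 0 the dimension is treated as
// non-periodic and cells are laid over the coordinate bounding box.
struct CellList {
  std::vector<std::vector<int>> cells;  // atom indices (0-based into `idx`)
  std::vector<int> idx;                 // original atom rows (0-based)
  int n[3];
  double lo[3], len[3], box[3];
  bool periodic[3];
  double cutoff;

  CellList(const Rcpp::NumericMatrix& X, const std::vector<int>& rows,
           double cut, const Rcpp::NumericVector& box_) {
    cutoff = cut;
    idx = rows;
    for (int k = 0; k < 3; ++k) {
      box[k] = (box_.size() == 3) ? box_[k] : 0.0;
      periodic[k] = box[k] > 0.0;
    }
    double hi[3];
    for (int k = 0; k < 3; ++k) {
      if (periodic[k]) { lo[k] = 0.0; hi[k] = box[k]; }
      else {
        lo[k] = R_PosInf; hi[k] = R_NegInf;
        for (size_t a = 0; a < rows.size(); ++a) {
          double v = X(rows[a], k);
          if (v < lo[k]) lo[k] = v;
          if (v > hi[k]) hi[k] = v;
        }
        lo[k] -= 1e-9; hi[k] += 1e-9;
      }
      double span = hi[k] - lo[k];
      n[k] = std::max(1, (int)std::floor(span / cut));
      if (periodic[k] && n[k] < 3) n[k] = 1;  // degenerate: single periodic cell
      len[k] = span / n[k];
    }
    cells.assign((size_t)n[0] * n[1] * n[2], {});
    for (size_t a = 0; a < rows.size(); ++a) {
      int c[3];
      for (int k = 0; k < 3; ++k) {
        double v = X(rows[a], k) - lo[k];
        if (periodic[k]) v -= box[k] * std::floor(v / box[k]);
        int ci = (int)std::floor(v / len[k]);
        if (ci < 0) ci = 0;
        if (ci >= n[k]) ci = n[k] - 1;
        c[k] = ci;
      }
      cells[c[0] + (size_t)n[0] * (c[1] + (size_t)n[1] * c[2])].push_back((int)a);
    }
  }

  inline double dist2(const Rcpp::NumericMatrix& X, int i, int j) const {
    double s = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = X(i, k) - X(j, k);
      if (periodic[k]) d -= box[k] * std::round(d / box[k]);
      s += d * d;
    }
    return s;
  }

  // Visit all atoms of the list within `cutoff` cells of point p (row in X).
  template <typename F>
  void visit_neighbors(const Rcpp::NumericMatrix& X, int p, F fun) const {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double v = X(p, k) - lo[k];
      if (periodic[k]) v -= box[k] * std::floor(v / box[k]);
      int ci = (int)std::floor(v / len[k]);
      if (ci < 0) ci = 0;
      if (ci >= n[k]) ci = n[k] - 1;
      c[k] = ci;
    }
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int cc[3] = {c[0] + dx, c[1] + dy, c[2] + dz};
          bool ok = true;
          for (int k = 0; k < 3; ++k) {
            if (periodic[k]) {
              cc[k] = (cc[k] + n[k]) % n[k];
            } else if (cc[k] < 0 || cc[k] >= n[k]) { ok = false; break; }
          }
          if (!ok) continue;
          // with few periodic cells the same cell can be revisited; dedupe
          if ((n[0] < 3 && periodic[0] && dx != 0 && n[0] == 1) ||
              (n[1] < 3 && periodic[1] && dy != 0 && n[1] == 1) ||
              (n[2] < 3 && periodic[2] && dz != 0 && n[2] == 1)) continue;
          const std::vector<int>& cell =
            cells[cc[0] + (size_t)n[0] * (cc[1] + (size_t)n[1] * cc[2])];
          for (int a : cell) fun(idx[a]);
        }
  }
};

#endif
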