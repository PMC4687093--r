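#include <Rcpp.h>
#include <map>
#include <utility>
#include "cell_list.h"
using namespace Rcpp;

static inline double soft_weight(double d, double steep, double mid) {
  return 1.0 / (1.0 + std::exp(steep * (d - mid)));
}

// Sigmoid-weighted contact numbers between atom groups A and B, excluding
// intra-molecular pairs. idxA/idxB are 1-based atom rows. If `identical_ab`
// the unordered pair totals are counted once; per-atom sums are unaffected.
// [[Rcpp::export]]
List cpp_soft_contacts(NumericMatrix coords, IntegerVector mol,
                       IntegerVector idxA, IntegerVector idxB,
                       double steepness, double midpoint, double truncation,
                       NumericVector box, bool identical_ab) {
  std::vector<int> rowsB(idxB.size());
  for (int i = 0; i < idxB.size(); ++i) rowsB[i] = idxB[i] - 1;
  CellList cl(coords, rowsB, truncation, box);

  NumericVector per_atom(idxA.size());
  double trunc2 = truncation * truncation;
  std::map<std::pair<int, int>, double> pair_tot;

  for (int a = 0; a < idxA.size(); ++a) {
    int i = idxA[a] - 1;
    int mi = mol[i];
    double ci = 0.0;
    cl.visit_neighbors(coords, i, [&](int j) {
      if (j == i) return;
      int mj = mol[j];
      if (mj == mi) return;  // inter-molecular only
      double d2 = cl.dist2(coords, i, j);
      if (d2 > trunc2) return;
      double w = soft_weight(std::sqrt(d2), steepness, midpoint);
      ci += w;
      if (!identical_ab || i < j) {
        std::pair<int, int> key(std::min(mi, mj), std::max(mi, mj));
        pair_tot[key] += w;
      }
    });
    per_atom[a] = ci;
  }

  int np = (int)pair_tot.size();
  IntegerVector pm1(np), pm2(np);
  NumericVector ptot(np);
  int k = 0;
  for (auto& kv : pair_tot) {
    pm1[k] = kv.first.first;
    pm2[k] = kv.first.second;
    ptot[k] = kv.second;
    ++k;
  }
  return List::create(_["per_atom"] = per_atom,
                      _["pair_mol_i"] = pm1, _["pair_mol_j"] = pm2,
                      _["pair_total"] = ptot);
}

// Unique inter-molecular pairs with any heavy-atom distance <= cutoff,
// with the minimum distance found. Groups may be identical.
// [[Rcpp::export]]
DataFrame cpp_hard_contact_pairs(NumericMatrix coords, IntegerVector mol,
                                 IntegerVector idxA, IntegerVector idxB,
                                 double cutoff, NumericVector box) {
  std::vector<int> rowsB(idxB.size());
  for (int i = 0; i < idxB.size(); ++i) rowsB[i] = idxB[i] - 1;
  CellList cl(coords, rowsB, cutoff, box);
  double cut2 = cutoff * cutoff;
  std::map<std::pair<int, int>, double> best;
  for (int a = 0; a < idxA.size(); ++a) {
    int i = idxA[a] - 1;
    int mi = mol[i];
    cl.visit_neighbors(coords, i, [&](int j) {
      if (j == i) return;
      int mj = mol[j];
      if (mj == mi) return;
      double d2 = cl.dist2(coords, i, j);
      if (d2 > cut2) return;
      std::pair<int, int> key(std::min(mi, mj), std::max(mi, mj));
      auto it = best.find(key);
      if (it == best.end() || d2 < it->second) best[key] = d2;
    });
  }
  int np = (int)best.size();
  IntegerVector m1(np), m2(np);
  NumericVector md(np);
  int k = 0;
  for (auto& kv : best) {
    m1[k] = kv.first.first;
    m2[k] = kv.first.second;
    md[k] = std::sqrt(kv.second);
    ++k;
  }
  return DataFrame::create(_["mol_i"] = m1, _["mol_j"] = m2,
                           _["min_dist"] = md);
}

// As cpp_hard_contact_pairs but pairs are keyed by `key` (e.g. a residue
// id unique over the scene) while exclusion still uses the molecule id.
// [[Rcpp::export]]
DataFrame cpp_hard_contact_pairs_keyed(NumericMatrix coords, IntegerVector mol,
                                       IntegerVector key,
                                       IntegerVector idxA, IntegerVector idxB,
                                       double cutoff, NumericVector box) {
  std::vector<int> rowsB(idxB.size());
  for (int i = 0; i < idxB.size(); ++i) rowsB[i] = idxB[i] - 1;
  CellList cl(coords, rowsB, cutoff, box);
  double cut2 = cutoff * cutoff;
  std::map<std::pair<int, int>, double> best;
  for (int a = 0; a < idxA.size(); ++a) {
    int i = idxA[a] - 1;
    int mi = mol[i], ki = key[i];
    cl.visit_neighbors(coords, i, [&](int j) {
      if (j == i) return;
      if (mol[j] == mi) return;
      double d2 = cl.dist2(coords, i, j);
      if (d2 > cut2) return;
      int kj = key[j];
      std::pair<int, int> kk(std::min(ki, kj), std::max(ki, kj));
      auto it = best.find(kk);
      if (it == best.end() || d2 < it->second) best[kk] = d2;
    });
  }
  int np = (int)best.size();
  IntegerVector k1(np), k2(np);
  NumericVector md(np);
  int k = 0;
  for (auto& kv : best) {
    k1[k] = kv.first.first;
    k2[k] = kv.first.second;
    md[k] = std::sqrt(kv.second);
    ++k;
  }
  return DataFrame::create(_["key_i"] = k1, _["key_j"] = k2,
                           _["min_dist"] = md);
}

// For each atom in idxA: minimum distance to any atom of idxB within
// `cutoff` (Inf when none). Intra-molecular pairs are NOT excluded here.
// [[Rcpp::export]]
NumericVector cpp_min_dist_to_set(NumericMatrix coords,
                                  IntegerVector idxA, IntegerVector idxB,
                                  double cutoff, NumericVector box) {
  std::vector<int> rowsB(idxB.size());
  for (int i = 0; i < idxB.size(); ++i) rowsB[i] = idxB[i] - 1;
  CellList cl(coords, rowsB, cutoff, box);
  double cut2 = cutoff * cutoff;
  NumericVector out(idxA.size(), R_PosInf);
  for (int a = 0; a < idxA.size(); ++a) {
    int i = idxA[a] - 1;
    double b2 = R_PosInf;
    cl.visit_neighbors(coords, i, [&](int j) {
      if (j == i) return;
      double d2 = cl.dist2(coords, i, j);
      if (d2 <= cut2 && d2 < b2) b2 = d2;
    });
    if (R_finite(b2)) out[a] = std::sqrt(b2);
  }
  return out;
}
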