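#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Squared distance between rows, minimum-image in an orthorhombic box when pbc.
static inline double dist2(const double* a, const double* b,
                           const double* box, bool pbc) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = a[k] - b[k];
    if (pbc) {
      double L = box[k];
      d -= L * std::round(d / L);
    }
    s += d * d;
  }
  return s;
}

// [[Rcpp::export]]
double cpp_min_distance(NumericMatrix a, NumericMatrix b,
                        NumericVector box, bool pbc) {
  int na = a.nrow(), nb = b.nrow();
  std::vector<double> av(3), bv(3), bx(3);
  for (int k = 0; k < 3; ++k) bx[k] = box.size() == 3 ? box[k] : 0.0;
  double best = R_PosInf;
  for (int i = 0; i < na; ++i) {
    av[0] = a(i, 0); av[1] = a(i, 1); av[2] = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      bv[0] = b(j, 0); bv[1] = b(j, 1); bv[2] = b(j, 2);
      double d2 = dist2(av.data(), bv.data(), bx.data(), pbc);
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Per-group minimum distance from groups of A atoms to the whole B set,
// exhaustive over all pairs. groupA is 0-based, values in [0, nGroups).
// [[Rcpp::export]]
NumericVector cpp_group_min_dist_brute(NumericMatrix a, IntegerVector groupA,
                                       int nGroups, NumericMatrix b,
                                       NumericVector box, bool pbc) {
  int na = a.nrow(), nb = b.nrow();
  std::vector<double> bx(3);
  for (int k = 0; k < 3; ++k) bx[k] = box.size() == 3 ? box[k] : 0.0;
  NumericVector out(nGroups, R_PosInf);
  std::vector<double> av(3), bv(3);
  for (int i = 0; i < na; ++i) {
    int g = groupA[i];
    av[0] = a(i, 0); av[1] = a(i, 1); av[2] = a(i, 2);
    double best = out[g];
    for (int j = 0; j < nb; ++j) {
      bv[0] = b(j, 0); bv[1] = b(j, 1); bv[2] = b(j, 2);
      double d2 = dist2(av.data(), bv.data(), bx.data(), pbc);
      double d = std::sqrt(d2);
      if (d < best) best = d;
    }
    out[g] = best;
  }
  return out;
}

// Cell-grid contact query: for each group of A atoms, is any B atom within
// cutoff?  Exact (cell size >= cutoff); falls back to the brute kernel when
// the box supports fewer than 3 cells per dimension or pbc is off.
// [[Rcpp::export]]
LogicalVector cpp_group_contact_grid(NumericMatrix a, IntegerVector groupA,
                                     int nGroups, NumericMatrix b,
                                     double cutoff, NumericVector box,
                                     bool pbc) {
  int na = a.nrow(), nb = b.nrow();
  std::vector<double> bx(3);
  for (int k = 0; k < 3; ++k) bx[k] = box.size() == 3 ? box[k] : 0.0;

  int nc[3];
  bool gridable = pbc;
  for (int k = 0; k < 3 && gridable; ++k) {
    nc[k] = (int)std::floor(bx[k] / cutoff);
    if (nc[k] > 64) nc[k] = 64;   // cell >= cutoff still holds
    if (nc[k] < 3) gridable = false;
  }
  LogicalVector out(nGroups, false);
  double cut2 = cutoff * cutoff;

  if (!gridable) {
    NumericVector md = cpp_group_min_dist_brute(a, groupA, nGroups, b, box, pbc);
    for (int g = 0; g < nGroups; ++g) out[g] = md[g] <= cutoff;
    return out;
  }

  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int>> cells(ncell);
  std::vector<int> bcell(nb);
  for (int j = 0; j < nb; ++j) {
    int idx[3];
    for (int k = 0; k < 3; ++k) {
      double w = b(j, k) / bx[k];
      w -= std::floor(w);                 // wrap into [0,1)
      int c = (int)std::floor(w * nc[k]);
      if (c >= nc[k]) c = nc[k] - 1;
      idx[k] = c;
    }
    int c = (idx[2] * nc[1] + idx[1]) * nc[0] + idx[0];
    cells[c].push_back(j);
    bcell[j] = c;
  }

  std::vector<double> av(3), bv(3);
  for (int i = 0; i < na; ++i) {
    int g = groupA[i];
    if (out[g]) continue;
    av[0] = a(i, 0); av[1] = a(i, 1); av[2] = a(i, 2);
    int idx[3];
    for (int k = 0; k < 3; ++k) {
      double w = av[k] / bx[k];
      w -= std::floor(w);
      int c = (int)std::floor(w * nc[k]);
      if (c >= nc[k]) c = nc[k] - 1;
      idx[k] = c;
    }
    bool hit = false;
    for (int dz = -1; dz <= 1 && !hit; ++dz)
      for (int dy = -1; dy <= 1 && !hit; ++dy)
        for (int dx = -1; dx <= 1 && !hit; ++dx) {
          int cx = (idx[0] + dx + nc[0]) % nc[0];
          int cy = (idx[1] + dy + nc[1]) % nc[1];
          int cz = (idx[2] + dz + nc[2]) % nc[2];
          const std::vector<int>& cell = cells[(cz * nc[1] + cy) * nc[0] + cx];
          for (size_t m = 0; m < cell.size(); ++m) {
            int j = cell[m];
            bv[0] = b(j, 0); bv[1] = b(j, 1); bv[2] = b(j, 2);
            if (dist2(av.data(), bv.data(), bx.data(), true) <= cut2) {
              hit = true;
              break;
            }
          }
        }
    if (hit) out[g] = true;
  }
  return out;
}

// Shrake-Rupley SASA.  sphere: n_points x 3 unit vectors (already expressed
// in whatever frame the caller chose).  radii: per-atom vdW radii.  All in
// the same length unit; returns per-atom accessible area in that unit^2.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii, double probe,
                       NumericMatrix sphere) {
  int n = xyz.nrow(), m = sphere.nrow();
  NumericVector out(n);
  std::vector<double> R(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    R[i] = radii[i] + probe;
    if (R[i] > rmax) rmax = R[i];
  }
  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    double Ri = R[i];
    nb.clear();
    double reach = Ri + rmax;
    double reach2 = reach * reach;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < reach2) {
        double rij = Ri + R[j];
        if (d2 < rij * rij) nb.push_back(j);
      }
    }
    int acc = 0;
    for (int p = 0; p < m; ++p) {
      double px = xyz(i, 0) + Ri * sphere(p, 0);
      double py = xyz(i, 1) + Ri * sphere(p, 1);
      double pz = xyz(i, 2) + Ri * sphere(p, 2);
      bool buried = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        int j = nb[q];
        double dx = px - xyz(j, 0);
        double dy = py - xyz(j, 1);
        double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    out[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)m;
  }
  return out;
}
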