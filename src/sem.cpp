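// Subcellular-element mechanics kernels: Morse pair forces within and
// between cells (adhesion-scaled attraction between cells), external
// forces (zona pellucida confinement, blastocoel cavity), total potential
// energy, cell centroids and contact fractions.
//
// Element pairs are culled at the cell-pair level: a cell pair is visited
// only if the centroid distance is within the sum of the two cells'
// bounding radii plus the potential cutoff, which leaves the computed
// forces identical to the all-pairs evaluation.
#include <Rcpp.h>
using namespace Rcpp;

static inline double clampd(double x, double lo) { return x < lo ? lo : x; }

// dV/dd for a Morse potential with separately scaled attraction:
// V(d) = de * exp(-2 a (d - re)) - alpha * 2 de * exp(-a (d - re))
static inline double morse_dVdd(double d, double de, double a, double re,
                                double alpha) {
  double e1 = std::exp(-a * (d - re));
  return 2.0 * a * de * (alpha * e1 - e1 * e1);
}

static inline double morse_V(double d, double de, double a, double re,
                             double alpha) {
  double e1 = std::exp(-a * (d - re));
  return de * e1 * e1 - alpha * 2.0 * de * e1;
}

static void centroids_and_radii(const NumericMatrix& pos,
                                const IntegerVector& cell, int ncell,
                                NumericMatrix& cen, NumericVector& rad,
                                IntegerVector& cnt) {
  int ne = pos.nrow();
  for (int e = 0; e < ne; ++e) {
    int c = cell[e];
    cen(c, 0) += pos(e, 0); cen(c, 1) += pos(e, 1); cen(c, 2) += pos(e, 2);
    cnt[c]++;
  }
  for (int c = 0; c < ncell; ++c)
    if (cnt[c] > 0)
      for (int k = 0; k < 3; ++k) cen(c, k) /= cnt[c];
  for (int e = 0; e < ne; ++e) {
    int c = cell[e];
    double dx = pos(e, 0) - cen(c, 0), dy = pos(e, 1) - cen(c, 1),
           dz = pos(e, 2) - cen(c, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > rad[c]) rad[c] = r;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_cell_centroids(NumericMatrix pos, IntegerVector cell,
                                 int ncell) {
  NumericMatrix cen(ncell, 3);
  NumericVector rad(ncell);
  IntegerVector cnt(ncell);
  centroids_and_radii(pos, cell, ncell, cen, rad, cnt);
  return cen;
}

// Pairwise (intra + inter) forces. `cell` is the 0-based owning-cell index
// per element; `type` the 0-based adhesion-type index per cell; `alpha`
// the symmetric adhesion-score matrix indexed by type. Intra pairs use an
// unscaled Morse potential; inter pairs scale only the attractive term by
// alpha(type_i, type_k).
// [[Rcpp::export]]
NumericMatrix cpp_pair_forces(NumericMatrix pos, IntegerVector cell,
                              IntegerVector type, NumericMatrix alpha,
                              double de_intra, double a_intra,
                              double re_intra, double cut_intra,
                              double de_inter, double a_inter,
                              double re_inter, double cut_inter,
                              double min_dist, bool intra, bool inter) {
  int ne = pos.nrow();
  int ncell = type.size();
  NumericMatrix F(ne, 3);
  NumericMatrix cen(ncell, 3);
  NumericVector rad(ncell);
  IntegerVector cnt(ncell);
  centroids_and_radii(pos, cell, ncell, cen, rad, cnt);

  // elements grouped by cell
  std::vector< std::vector<int> > members(ncell);
  for (int e = 0; e < ne; ++e) members[cell[e]].push_back(e);

  if (intra) {
    for (int c = 0; c < ncell; ++c) {
      const std::vector<int>& m = members[c];
      for (size_t a = 0; a + 1 < m.size(); ++a) {
        for (size_t b = a + 1; b < m.size(); ++b) {
          int i = m[a], j = m[b];
          double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
                 dz = pos(i, 2) - pos(j, 2);
          double d = clampd(std::sqrt(dx * dx + dy * dy + dz * dz), min_dist);
          if (d >= cut_intra) continue;
          double f = -morse_dVdd(d, de_intra, a_intra, re_intra, 1.0) / d;
          F(i, 0) += f * dx; F(i, 1) += f * dy; F(i, 2) += f * dz;
          F(j, 0) -= f * dx; F(j, 1) -= f * dy; F(j, 2) -= f * dz;
        }
      }
    }
  }
  if (inter) {
    for (int c1 = 0; c1 + 1 < ncell; ++c1) {
      for (int c2 = c1 + 1; c2 < ncell; ++c2) {
        double dx = cen(c1, 0) - cen(c2, 0), dy = cen(c1, 1) - cen(c2, 1),
               dz = cen(c1, 2) - cen(c2, 2);
        double dcen = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dcen > rad[c1] + rad[c2] + cut_inter) continue;  // cull
        double al = alpha(type[c1], type[c2]);
        for (size_t a = 0; a < members[c1].size(); ++a) {
          int i = members[c1][a];
          for (size_t b = 0; b < members[c2].size(); ++b) {
            int j = members[c2][b];
            double ex = pos(i, 0) - pos(j, 0), ey = pos(i, 1) - pos(j, 1),
                   ez = pos(i, 2) - pos(j, 2);
            double d = clampd(std::sqrt(ex * ex + ey * ey + ez * ez),
                              min_dist);
            if (d >= cut_inter) continue;
            double f = -morse_dVdd(d, de_inter, a_inter, re_inter, al) / d;
            F(i, 0) += f * ex; F(i, 1) += f * ey; F(i, 2) += f * ez;
            F(j, 0) -= f * ex; F(j, 1) -= f * ey; F(j, 2) -= f * ez;
          }
        }
      }
    }
  }
  return F;
}

// External forces: linear inward restoring force outside the zona radius,
// and a linear outward force expelling elements from inside the cavity
// sphere (active only when cavity_radius > 0).
// [[Rcpp::export]]
NumericMatrix cpp_external_forces(NumericMatrix pos, double zona_radius,
                                  double zona_k, double cav_x, double cav_y,
                                  double cav_z, double cav_r, double cav_k) {
  int ne = pos.nrow();
  NumericMatrix F(ne, 3);
  for (int e = 0; e < ne; ++e) {
    double x = pos(e, 0), y = pos(e, 1), z = pos(e, 2);
    double r = std::sqrt(x * x + y * y + z * z);
    if (r > zona_radius && r > 0) {
      double f = -zona_k * (r - zona_radius) / r;
      F(e, 0) += f * x; F(e, 1) += f * y; F(e, 2) += f * z;
    }
    if (cav_r > 0) {
      double ux = x - cav_x, uy = y - cav_y, uz = z - cav_z;
      double d = std::sqrt(ux * ux + uy * uy + uz * uz);
      if (d < cav_r) {
        double f = (d > 1e-12) ? cav_k * (cav_r - d) / d : 0.0;
        if (d <= 1e-12) { ux = 0; uy = 0; uz = 1; f = cav_k * cav_r; }
        F(e, 0) += f * ux; F(e, 1) += f * uy; F(e, 2) += f * uz;
      }
    }
  }
  return F;
}

// Total potential energy (pairwise + external), consistent with the
// forces above: external potentials are 0.5 k (excess)^2 wells.
// [[Rcpp::export]]
double cpp_potential_energy(NumericMatrix pos, IntegerVector cell,
                            IntegerVector type, NumericMatrix alpha,
                            double de_intra, double a_intra, double re_intra,
                            double cut_intra, double de_inter, double a_inter,
                            double re_inter, double cut_inter,
                            double min_dist, double zona_radius,
                            double zona_k, double cav_x, double cav_y,
                            double cav_z, double cav_r, double cav_k) {
  int ne = pos.nrow();
  int ncell = type.size();
  double E = 0.0;
  std::vector< std::vector<int> > members(ncell);
  for (int e = 0; e < ne; ++e) members[cell[e]].push_back(e);
  for (int c = 0; c < ncell; ++c) {
    const std::vector<int>& m = members[c];
    for (size_t a = 0; a + 1 < m.size(); ++a)
      for (size_t b = a + 1; b < m.size(); ++b) {
        int i = m[a], j = m[b];
        double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
               dz = pos(i, 2) - pos(j, 2);
        double d = clampd(std::sqrt(dx * dx + dy * dy + dz * dz), min_dist);
        if (d < cut_intra) E += morse_V(d, de_intra, a_intra, re_intra, 1.0);
      }
  }
  for (int c1 = 0; c1 + 1 < ncell; ++c1)
    for (int c2 = c1 + 1; c2 < ncell; ++c2) {
      double al = alpha(type[c1], type[c2]);
      for (size_t a = 0; a < members[c1].size(); ++a)
        for (size_t b = 0; b < members[c2].size(); ++b) {
          int i = members[c1][a], j = members[c2][b];
          double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
                 dz = pos(i, 2) - pos(j, 2);
          double d = clampd(std::sqrt(dx * dx + dy * dy + dz * dz), min_dist);
          if (d < cut_inter) E += morse_V(d, de_inter, a_inter, re_inter, al);
        }
    }
  for (int e = 0; e < ne; ++e) {
    double x = pos(e, 0), y = pos(e, 1), z = pos(e, 2);
    double r = std::sqrt(x * x + y * y + z * z);
    if (r > zona_radius) E += 0.5 * zona_k * (r - zona_radius) * (r - zona_radius);
    if (cav_r > 0) {
      double ux = x - cav_x, uy = y - cav_y, uz = z - cav_z;
      double d = std::sqrt(ux * ux + uy * uy + uz * uz);
      if (d < cav_r) E += 0.5 * cav_k * (cav_r - d) * (cav_r - d);
    }
  }
  return E;
}

// Contacted share of each cell's surface. An element is "exposed" when no
// other element lies within `rcut` inside a cone pointing away from the
// embryo centroid (half-angle ~72 deg); the contact fraction is the share
// of a cell's elements that are NOT exposed (1 = fully interior).
// [[Rcpp::export]]
NumericVector cpp_contact_fraction(NumericMatrix pos, IntegerVector cell,
                                   int ncell, double rcut) {
  int ne = pos.nrow();
  NumericVector frac(ncell);
  IntegerVector cnt(ncell);
  double r2 = rcut * rcut;
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < ne; ++i) { cx += pos(i, 0); cy += pos(i, 1); cz += pos(i, 2); }
  cx /= ne; cy /= ne; cz /= ne;
  for (int i = 0; i < ne; ++i) {
    cnt[cell[i]]++;
    double ox = pos(i, 0) - cx, oy = pos(i, 1) - cy, oz = pos(i, 2) - cz;
    double on = std::sqrt(ox * ox + oy * oy + oz * oz);
    if (on < 1e-12) { frac[cell[i]] += 1.0; continue; }  // central: covered
    ox /= on; oy /= on; oz /= on;
    bool covered = false;
    for (int j = 0; j < ne && !covered; ++j) {
      if (j == i || cell[j] == cell[i]) continue;
      double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1),
             dz = pos(j, 2) - pos(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= r2 || d2 < 1e-24) continue;
      double proj = dx * ox + dy * oy + dz * oz;
      if (proj > 0.3 * std::sqrt(d2)) covered = true;
    }
    if (covered) frac[cell[i]] += 1.0;
  }
  for (int c = 0; c < ncell; ++c)
    if (cnt[c] > 0) frac[c] /= cnt[c];
  return frac;
}
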