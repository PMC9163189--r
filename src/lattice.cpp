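// Compiled kernels for periodic and finite-cluster pair sums.
//
// Conventions: coordinates in Angstrom, energies kJ/mol, charges in e.
// Lattice matrix A has lattice vectors as rows; cart = frac %*% A.
// Pair parameters arrive as a matrix with one row per atom-type pair and
// columns (alpha, beta, a1, a2, A12, C6, C8, delta1, delta6, delta8, A);
// `pairidx` maps (type_i, type_j) to the 0-based row.
// Form codes: 0 = extended, 1 = exp-6-1, 2 = 12-6-1.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double COULOMB_KJ = 1389.35458;

// Tang-Toennies damping f_n(delta, r).
static inline double ttdamp(int n, double delta, double r) {
  double x = delta * r;
  if (x > 700.0) return 1.0;
  double s = 1.0, term = 1.0;
  for (int m = 1; m <= n; ++m) { term *= x / m; s += term; }
  double f = 1.0 - std::exp(-x) * s;
  if (f < 0.0) f = 0.0;
  if (f > 1.0) f = 1.0;
  return f;
}

// Non-Coulomb part of one atom-atom term.
static inline double pair_noncoul(int form, const double* p, double r) {
  double r2 = r * r;
  double r6 = r2 * r2 * r2;
  if (form == 0) {
    double rep = (1.0 + p[2] * r + p[3] * r2) * std::exp(p[0] - p[1] * r);
    double r12 = r6 * r6, r8 = r6 * r2;
    return rep + p[4] / r12
      - ttdamp(6, p[8], r) * p[5] / r6
      - ttdamp(8, p[9], r) * p[6] / r8;
  } else if (form == 1) {
    return p[10] * std::exp(-p[1] * r) - p[5] / r6;
  } else {
    double r12 = r6 * r6;
    return p[4] / r12 - p[5] / r6;
  }
}

// [[Rcpp::export]]
List cpp_lattice_sums(NumericMatrix xyz, IntegerVector molid,
                      IntegerVector typeidx, NumericVector charges,
                      IntegerMatrix pairidx, NumericMatrix par,
                      int form, NumericMatrix A, NumericMatrix Ainv,
                      double cutoff, IntegerVector nmax,
                      bool do_coulomb, double eta, IntegerVector kmax,
                      double contact_floor) {
  int nat = xyz.nrow();
  double cut2 = cutoff * cutoff;
  double e_noncoul = 0.0, e_real = 0.0, e_damp = 0.0;
  double min_contact = R_PosInf, max_pair = R_NegInf;

  // bounding radius of the atom set around its centroid, for image
  // pruning: a whole image block is skipped when even its closest
  // possible pair exceeds the cutoff
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < nat; ++i) { cx += xyz(i,0); cy += xyz(i,1); cz += xyz(i,2); }
  cx /= nat; cy /= nat; cz /= nat;
  double rmax = 0.0;
  for (int i = 0; i < nat; ++i) {
    double dx = xyz(i,0)-cx, dy = xyz(i,1)-cy, dz = xyz(i,2)-cz;
    double rr = dx*dx + dy*dy + dz*dz;
    if (rr > rmax) rmax = rr;
  }
  rmax = std::sqrt(rmax);
  double skip_dist = cutoff + 2.0 * rmax;

  for (int n1 = -nmax[0]; n1 <= nmax[0]; ++n1)
    for (int n2 = -nmax[1]; n2 <= nmax[1]; ++n2)
      for (int n3 = -nmax[2]; n3 <= nmax[2]; ++n3) {
        double tx = n1 * A(0, 0) + n2 * A(1, 0) + n3 * A(2, 0);
        double ty = n1 * A(0, 1) + n2 * A(1, 1) + n3 * A(2, 1);
        double tz = n1 * A(0, 2) + n2 * A(1, 2) + n3 * A(2, 2);
        bool home = (n1 == 0 && n2 == 0 && n3 == 0);
        if (!home && tx * tx + ty * ty + tz * tz > skip_dist * skip_dist)
          continue;
        for (int i = 0; i < nat; ++i) {
          for (int j = 0; j < nat; ++j) {
            if (home && i == j) continue;
            bool same_mol_image = home && (molid[i] == molid[j]);
            double dx = xyz(j, 0) + tx - xyz(i, 0);
            double dy = xyz(j, 1) + ty - xyz(i, 1);
            double dz = xyz(j, 2) + tz - xyz(i, 2);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (same_mol_image) continue;
            if (r2 < min_contact) min_contact = r2;
            if (r2 > cut2) continue;
            double r = std::sqrt(r2);
            int pi = pairidx(typeidx[i], typeidx[j]);
            double prow[11];
            for (int c = 0; c < 11; ++c) prow[c] = par(pi, c);
            double qq = charges[i] * charges[j];
            double enc = pair_noncoul(form, prow, r);
            double etot_pair = enc + COULOMB_KJ * qq / r;
            if (etot_pair > max_pair) max_pair = etot_pair;
            e_noncoul += 0.5 * enc;
            if (do_coulomb) {
              e_real += 0.5 * COULOMB_KJ * qq * std::erfc(eta * r) / r;
              // short-range damping correction: subtract (1 - f1) qq/r
              double f1 = ttdamp(1, prow[7], r);
              e_damp -= 0.5 * COULOMB_KJ * qq * (1.0 - f1) / r;
            }
          }
        }
      }
  min_contact = std::sqrt(min_contact);

  double e_recip = 0.0, e_self = 0.0, e_excl = 0.0;
  if (do_coulomb) {
    // volume = det(A)
    double V = A(0,0)*(A(1,1)*A(2,2)-A(1,2)*A(2,1))
             - A(0,1)*(A(1,0)*A(2,2)-A(1,2)*A(2,0))
             + A(0,2)*(A(1,0)*A(2,1)-A(1,1)*A(2,0));
    V = std::fabs(V);
    double pref = COULOMB_KJ * 2.0 * M_PI / V;
    for (int h1 = -kmax[0]; h1 <= kmax[0]; ++h1)
      for (int h2 = -kmax[1]; h2 <= kmax[1]; ++h2)
        for (int h3 = -kmax[2]; h3 <= kmax[2]; ++h3) {
          if (h1 == 0 && h2 == 0 && h3 == 0) continue;
          double kx = 2.0 * M_PI * (Ainv(0, 0) * h1 + Ainv(0, 1) * h2 + Ainv(0, 2) * h3);
          double ky = 2.0 * M_PI * (Ainv(1, 0) * h1 + Ainv(1, 1) * h2 + Ainv(1, 2) * h3);
          double kz = 2.0 * M_PI * (Ainv(2, 0) * h1 + Ainv(2, 1) * h2 + Ainv(2, 2) * h3);
          double k2 = kx * kx + ky * ky + kz * kz;
          double damp = std::exp(-k2 / (4.0 * eta * eta)) / k2;
          if (damp < 1e-16) continue;
          double sre = 0.0, sim = 0.0;
          for (int i = 0; i < nat; ++i) {
            double ph = kx * xyz(i, 0) + ky * xyz(i, 1) + kz * xyz(i, 2);
            sre += charges[i] * std::cos(ph);
            sim += charges[i] * std::sin(ph);
          }
          e_recip += pref * damp * (sre * sre + sim * sim);
        }
    double q2 = 0.0;
    for (int i = 0; i < nat; ++i) q2 += charges[i] * charges[i];
    e_self = -COULOMB_KJ * eta / std::sqrt(M_PI) * q2;
    // intramolecular exclusion: remove the reciprocal-space contribution
    // of same-molecule same-image pairs (erf(eta r)/r).
    for (int i = 0; i < nat; ++i)
      for (int j = i + 1; j < nat; ++j) {
        if (molid[i] != molid[j]) continue;
        double dx = xyz(j, 0) - xyz(i, 0);
        double dy = xyz(j, 1) - xyz(i, 1);
        double dz = xyz(j, 2) - xyz(i, 2);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        e_excl -= COULOMB_KJ * charges[i] * charges[j] * std::erf(eta * r) / r;
      }
  }

  double e_coul = e_real + e_recip + e_self + e_excl + e_damp;
  return List::create(
    _["noncoul"] = e_noncoul, _["coul"] = e_coul,
    _["min_contact"] = min_contact, _["max_pair_energy"] = max_pair,
    _["collapsed"] = (min_contact < contact_floor));
}

// Finite-cluster pair sums: total two-body energy of a set of molecules
// (no periodicity, no cutoff) plus a per-molecule-pair energy table for
// pairs whose centre-of-mass distance is below `record_rmax`.
// [[Rcpp::export]]
List cpp_cluster_pairs(NumericMatrix xyz, IntegerVector molid,
                       IntegerVector typeidx, NumericVector charges,
                       NumericMatrix com, IntegerMatrix pairidx,
                       NumericMatrix par, int form, double record_rmax) {
  int nat = xyz.nrow();
  int nmol = com.nrow();
  // index atoms by molecule
  std::vector< std::vector<int> > members(nmol);
  for (int i = 0; i < nat; ++i) members[molid[i]].push_back(i);

  double total = 0.0;
  std::vector<int> rec_i, rec_j;
  std::vector<double> rec_e, rec_r;
  for (int mi = 0; mi < nmol; ++mi) {
    for (int mj = mi + 1; mj < nmol; ++mj) {
      double dx = com(mj, 0) - com(mi, 0);
      double dy = com(mj, 1) - com(mi, 1);
      double dz = com(mj, 2) - com(mi, 2);
      double rcom = std::sqrt(dx * dx + dy * dy + dz * dz);
      double e = 0.0;
      for (size_t a = 0; a < members[mi].size(); ++a) {
        int i = members[mi][a];
        for (size_t b = 0; b < members[mj].size(); ++b) {
          int j = members[mj][b];
          double ddx = xyz(j, 0) - xyz(i, 0);
          double ddy = xyz(j, 1) - xyz(i, 1);
          double ddz = xyz(j, 2) - xyz(i, 2);
          double r = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
          int pi = pairidx(typeidx[i], typeidx[j]);
          double prow[11];
          for (int c = 0; c < 11; ++c) prow[c] = par(pi, c);
          double qq = charges[i] * charges[j];
          double f1 = (form == 0) ? ttdamp(1, prow[7], r) : 1.0;
          e += pair_noncoul(form, prow, r) + f1 * COULOMB_KJ * qq / r;
        }
      }
      total += e;
      if (rcom < record_rmax) {
        rec_i.push_back(mi + 1); rec_j.push_back(mj + 1);
        rec_e.push_back(e); rec_r.push_back(rcom);
      }
    }
  }
  return List::create(
    _["total"] = total,
    _["pairs"] = DataFrame::create(_["i"] = rec_i, _["j"] = rec_j,
                                   _["energy"] = rec_e, _["r_com"] = rec_r));
}

// Shortest intermolecular atom-atom distance over periodic images.
// [[Rcpp::export]]
double cpp_min_contact(NumericMatrix xyz, IntegerVector molid,
                       NumericMatrix A, IntegerVector nmax) {
  int nat = xyz.nrow();
  double best = R_PosInf;
  for (int n1 = -nmax[0]; n1 <= nmax[0]; ++n1)
    for (int n2 = -nmax[1]; n2 <= nmax[1]; ++n2)
      for (int n3 = -nmax[2]; n3 <= nmax[2]; ++n3) {
        bool home = (n1 == 0 && n2 == 0 && n3 == 0);
        double tx = n1 * A(0, 0) + n2 * A(1, 0) + n3 * A(2, 0);
        double ty = n1 * A(0, 1) + n2 * A(1, 1) + n3 * A(2, 1);
        double tz = n1 * A(0, 2) + n2 * A(1, 2) + n3 * A(2, 2);
        for (int i = 0; i < nat; ++i)
          for (int j = 0; j < nat; ++j) {
            if (home && molid[i] == molid[j]) continue;
            double dx = xyz(j, 0) + tx - xyz(i, 0);
            double dy = xyz(j, 1) + ty - xyz(i, 1);
            double dz = xyz(j, 2) + tz - xyz(i, 2);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 < best) best = r2;
          }
      }
  return std::sqrt(best);
}

// Expand asymmetric-unit atoms by symmetry operators.
// X: asu atoms (Cartesian rows); ops supplied as k rotation matrices
// (rows of M stacked: 3k x 3) and k translations (k x 3), acting on
// fractional coordinates.  Returns the stacked Cartesian atoms of the
// whole cell (asu entry blocks in op-major order).
// [[Rcpp::export]]
NumericMatrix cpp_expand_ops(NumericMatrix X, NumericMatrix A,
                             NumericMatrix Ainv, NumericMatrix Ms,
                             NumericMatrix ts) {
  int nat = X.nrow();
  int nop = ts.nrow();
  NumericMatrix out(nat * nop, 3);
  // fractional coordinates of X
  std::vector<double> xf(nat * 3);
  for (int i = 0; i < nat; ++i)
    for (int c = 0; c < 3; ++c)
      xf[i * 3 + c] = X(i, 0) * Ainv(0, c) + X(i, 1) * Ainv(1, c) + X(i, 2) * Ainv(2, c);
  for (int k = 0; k < nop; ++k) {
    for (int i = 0; i < nat; ++i) {
      double f[3];
      for (int r = 0; r < 3; ++r) {
        f[r] = ts(k, r);
        for (int c = 0; c < 3; ++c) f[r] += Ms(3 * k + r, c) * xf[i * 3 + c];
      }
      for (int c = 0; c < 3; ++c)
        out(k * nat + i, c) = f[0] * A(0, c) + f[1] * A(1, c) + f[2] * A(2, c);
    }
  }
  return out;
}
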