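// Core MM/CG engine: force-field evaluation (atomistic MM terms, Go-like CG
// terms, confining walls), SHAKE/RATTLE constraint solvers and the BAOAB
// Langevin integrator. All quantities use the package's internal units:
// length A, time ps, mass amu, energy kJ/mol, charge e.
//
// Unit conversions: 1 amu*A^2/ps^2 = 0.01 kJ/mol, so kinetic energy carries a
// factor 0.01 and accelerations from kJ/mol/A forces carry a factor 100.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

static const double KB = 0.008314462618;   // kJ mol-1 K-1
static const double F2A = 100.0;           // (kJ/mol/A)/amu -> A/ps^2
static const double KE_CONV = 0.01;        // amu A^2 ps-2 -> kJ/mol
static const double KE_COUL = 1389.35458;  // kJ mol-1 A e-2

enum TermIdx { T_BOND = 0, T_ANGLE, T_DIHEDRAL, T_LJ, T_COUL,
               T_GOBOND, T_GOCONTACT, T_GOREP, T_WALL, NTERMS };

struct Walls {
  bool enabled = false;
  double k_wall = 0.0, k_drop = 0.0;
  // planar slab (z confinement for membrane-zone protein particles)
  double zlo = 0.0, zhi = 0.0;
  std::vector<int> slab_idx;
  // hemispheric caps
  double cap1_c[3] = {0, 0, 0}, cap2_c[3] = {0, 0, 0};
  double cap1_r = 0.0, cap2_r = 0.0;
  std::vector<int> cap1_idx, cap2_idx;
  // lateral membrane wall: union of spheres around initial Calpha anchors
  std::vector<double> anchors; // 3*m
  double lat_offset = 0.0;
  std::vector<int> lat_idx;
  // water droplet
  int drop_mode = 0; // 0 fixed centre, 1 ligand centroid
  double drop_c[3] = {0, 0, 0};
  double drop_r = 0.0;
  std::vector<int> drop_idx, lig_idx;
  // lipid-head plane excluding water from the implicit membrane slab
  bool water_plane = false;
  double water_zmin = 0.0;
};

struct Sys {
  int n = 0;
  std::vector<double> mass, charge, sigma, eps;
  std::vector<int> is_bead, is_gonode, is_h;
  std::unordered_set<uint64_t> excl, go_pairs;
  std::vector<int> p14_i, p14_j;
  double scale14_lj = 1.0, scale14_coul = 1.0;
  std::vector<int> b_i, b_j;           std::vector<double> b_k, b_r0;
  std::vector<int> a_i, a_j, a_k;      std::vector<double> a_kth, a_th0;
  std::vector<int> d_i, d_j, d_k, d_l; std::vector<double> d_kd, d_phase;
  std::vector<int> d_n;
  std::vector<int> gb_i, gb_j;         std::vector<double> gb_r0, gb_k;
  std::vector<int> gc_i, gc_j;         std::vector<double> gc_r0, gc_eps;
  double sigma_rep = 4.0, eps_rep = 1.0;
  double r_cut = 16.0;
  bool shift = true;
  Walls walls;
  std::vector<int> c_i, c_j;           std::vector<double> c_d0;
  double c_tol = 1e-4;
  int c_maxit = 500;

  uint64_t key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (uint64_t)i * (uint64_t)n + (uint64_t)j;
  }
};

static std::vector<int> as_idx0(SEXP s) {
  IntegerVector v(s);
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] - 1; // R 1-based -> 0-based
  return out;
}
static std::vector<double> as_dvec(SEXP s) {
  NumericVector v(s);
  return std::vector<double>(v.begin(), v.end());
}

static Sys parse_sys(const List &sl) {
  Sys S;
  S.n = as<int>(sl["n"]);
  S.mass = as_dvec(sl["mass"]);
  S.charge = as_dvec(sl["charge"]);
  S.sigma = as_dvec(sl["sigma"]);
  S.eps = as_dvec(sl["eps"]);
  IntegerVector ib = sl["is_bead"], ig = sl["is_gonode"], ih = sl["is_h"];
  S.is_bead.assign(ib.begin(), ib.end());
  S.is_gonode.assign(ig.begin(), ig.end());
  S.is_h.assign(ih.begin(), ih.end());

  std::vector<int> ei = as_idx0(sl["excl_i"]), ej = as_idx0(sl["excl_j"]);
  for (size_t k = 0; k < ei.size(); ++k) S.excl.insert(S.key(ei[k], ej[k]));
  S.p14_i = as_idx0(sl["p14_i"]); S.p14_j = as_idx0(sl["p14_j"]);
  S.scale14_lj = as<double>(sl["scale14_lj"]);
  S.scale14_coul = as<double>(sl["scale14_coul"]);

  S.b_i = as_idx0(sl["bond_i"]); S.b_j = as_idx0(sl["bond_j"]);
  S.b_k = as_dvec(sl["bond_k"]); S.b_r0 = as_dvec(sl["bond_r0"]);
  S.a_i = as_idx0(sl["ang_i"]); S.a_j = as_idx0(sl["ang_j"]); S.a_k = as_idx0(sl["ang_k"]);
  S.a_kth = as_dvec(sl["ang_kth"]); S.a_th0 = as_dvec(sl["ang_th0"]);
  S.d_i = as_idx0(sl["dih_i"]); S.d_j = as_idx0(sl["dih_j"]);
  S.d_k = as_idx0(sl["dih_k"]); S.d_l = as_idx0(sl["dih_l"]);
  S.d_kd = as_dvec(sl["dih_kd"]); S.d_phase = as_dvec(sl["dih_phase"]);
  IntegerVector dn = sl["dih_n"];
  S.d_n.assign(dn.begin(), dn.end());

  S.gb_i = as_idx0(sl["gob_i"]); S.gb_j = as_idx0(sl["gob_j"]);
  S.gb_r0 = as_dvec(sl["gob_r0"]); S.gb_k = as_dvec(sl["gob_k"]);
  S.gc_i = as_idx0(sl["goc_i"]); S.gc_j = as_idx0(sl["goc_j"]);
  S.gc_r0 = as_dvec(sl["goc_r0"]); S.gc_eps = as_dvec(sl["goc_eps"]);
  for (size_t k = 0; k < S.gb_i.size(); ++k) S.go_pairs.insert(S.key(S.gb_i[k], S.gb_j[k]));
  for (size_t k = 0; k < S.gc_i.size(); ++k) S.go_pairs.insert(S.key(S.gc_i[k], S.gc_j[k]));
  if (sl.containsElementNamed("skip_i")) {
    std::vector<int> si = as_idx0(sl["skip_i"]), sj = as_idx0(sl["skip_j"]);
    for (size_t k = 0; k < si.size(); ++k) S.go_pairs.insert(S.key(si[k], sj[k]));
  }

  S.sigma_rep = as<double>(sl["sigma_rep"]);
  S.eps_rep = as<double>(sl["eps_rep"]);
  S.r_cut = as<double>(sl["r_cut"]);
  S.shift = as<bool>(sl["shift"]);

  List wl = sl["walls"];
  Walls &W = S.walls;
  W.enabled = as<bool>(wl["enabled"]);
  if (W.enabled) {
    W.k_wall = as<double>(wl["k_wall"]);
    W.k_drop = as<double>(wl["k_drop"]);
    W.zlo = as<double>(wl["zlo"]); W.zhi = as<double>(wl["zhi"]);
    W.slab_idx = as_idx0(wl["slab_idx"]);
    NumericVector c1 = wl["cap1_center"], c2 = wl["cap2_center"];
    for (int d = 0; d < 3; ++d) { W.cap1_c[d] = c1[d]; W.cap2_c[d] = c2[d]; }
    W.cap1_r = as<double>(wl["cap1_radius"]); W.cap2_r = as<double>(wl["cap2_radius"]);
    W.cap1_idx = as_idx0(wl["cap1_idx"]); W.cap2_idx = as_idx0(wl["cap2_idx"]);
    NumericMatrix am = wl["anchors"];
    W.anchors.resize(3 * am.nrow());
    for (int i = 0; i < am.nrow(); ++i)
      for (int d = 0; d < 3; ++d) W.anchors[3 * i + d] = am(i, d);
    W.lat_offset = as<double>(wl["lat_offset"]);
    W.lat_idx = as_idx0(wl["lat_idx"]);
    W.drop_mode = as<int>(wl["drop_mode"]);
    NumericVector dc = wl["drop_center"];
    for (int d = 0; d < 3; ++d) W.drop_c[d] = dc[d];
    W.drop_r = as<double>(wl["drop_radius"]);
    W.drop_idx = as_idx0(wl["drop_idx"]);
    W.lig_idx = as_idx0(wl["lig_idx"]);
    W.water_plane = as<bool>(wl["water_plane"]);
    W.water_zmin = as<double>(wl["water_zmin"]);
  }

  S.c_i = as_idx0(sl["con_i"]); S.c_j = as_idx0(sl["con_j"]);
  S.c_d0 = as_dvec(sl["con_d0"]);
  S.c_tol = as<double>(sl["con_tol"]);
  S.c_maxit = as<int>(sl["con_maxit"]);
  return S;
}

// ---------------------------------------------------------------------------
// Neighbor (Verlet) pair list with a displacement-triggered rebuild.

struct NbList {
  std::vector<int> pi, pj;
  std::vector<char> type; // 0 = LJ+Coulomb, 1 = r^-12 repulsion (Go/soft)
  std::vector<double> x_ref;
  double skin = 2.0;

  void build(const Sys &S, const double *x) {
    pi.clear(); pj.clear(); type.clear();
    const double rl2 = (S.r_cut + skin) * (S.r_cut + skin);
    for (int i = 0; i < S.n; ++i) {
      for (int j = i + 1; j < S.n; ++j) {
        double dx = x[3 * i] - x[3 * j];
        double dy = x[3 * i + 1] - x[3 * j + 1];
        double dz = x[3 * i + 2] - x[3 * j + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rl2) continue;
        bool bead = S.is_bead[i] || S.is_bead[j];
        if (!bead) {
          if (S.excl.count(S.key(i, j))) continue;
          double eij = S.eps[i] * S.eps[j];
          double qij = S.charge[i] * S.charge[j];
          if (eij == 0.0 && qij == 0.0) continue;
          pi.push_back(i); pj.push_back(j); type.push_back(0);
        } else {
          // hydrogens carry no excluded volume of their own: the bead
          // repulsion acts against heavy atoms only
          if (S.is_h[i] || S.is_h[j]) continue;
          if (S.go_pairs.count(S.key(i, j))) continue;
          if (S.eps_rep == 0.0) continue;
          pi.push_back(i); pj.push_back(j); type.push_back(1);
        }
      }
    }
    x_ref.assign(x, x + 3 * S.n);
  }

  bool stale(const Sys &S, const double *x) const {
    const double lim2 = 0.25 * skin * skin; // half-skin displacement
    for (int i = 0; i < 3 * S.n; i += 3) {
      double dx = x[i] - x_ref[i];
      double dy = x[i + 1] - x_ref[i + 1];
      double dz = x[i + 2] - x_ref[i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// ---------------------------------------------------------------------------
// Energy/force evaluation

static inline double clamp1(double v) {
  return v > 1.0 ? 1.0 : (v < -1.0 ? -1.0 : v);
}

static void pair_lj_coul(const Sys &S, int i, int j, const double *x,
                         double *f, double *terms, double slj, double scoul,
                         bool apply_cut) {
  double d[3];
  double r2 = 0.0;
  for (int k = 0; k < 3; ++k) { d[k] = x[3 * i + k] - x[3 * j + k]; r2 += d[k] * d[k]; }
  if (r2 < 1e-12) stop("overlapping atoms (%d, %d): r < 1e-6 A", i + 1, j + 1);
  if (apply_cut && r2 >= S.r_cut * S.r_cut) return;
  double r = std::sqrt(r2);
  double dEdr = 0.0, E = 0.0;
  double epsij = std::sqrt(S.eps[i] * S.eps[j]);
  if (epsij > 0.0 && slj != 0.0) {
    double sij = 0.5 * (S.sigma[i] + S.sigma[j]);
    double sr2 = sij * sij / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
    double e = 4.0 * epsij * (sr12 - sr6);
    if (S.shift && apply_cut) {
      double cr2 = sij * sij / (S.r_cut * S.r_cut);
      double cr6 = cr2 * cr2 * cr2;
      e -= 4.0 * epsij * (cr6 * cr6 - cr6);
    }
    terms[T_LJ] += slj * e;
    dEdr += slj * (-24.0 * epsij * (2.0 * sr12 - sr6) / r);
  }
  double qij = S.charge[i] * S.charge[j];
  if (qij != 0.0 && scoul != 0.0) {
    // shifted-force truncation: both the pair energy and the pair force
    // vanish at the cutoff, so cutoff crossings conserve energy
    double e, dE;
    if (S.shift && apply_cut) {
      e = KE_COUL * qij * (1.0 / r - 1.0 / S.r_cut +
                           (r - S.r_cut) / (S.r_cut * S.r_cut));
      dE = KE_COUL * qij * (-1.0 / r2 + 1.0 / (S.r_cut * S.r_cut));
    } else {
      e = KE_COUL * qij / r;
      dE = -KE_COUL * qij / r2;
    }
    terms[T_COUL] += scoul * e;
    dEdr += scoul * dE;
  }
  for (int k = 0; k < 3; ++k) {
    double fk = -dEdr * d[k] / r;
    f[3 * i + k] += fk;
    f[3 * j + k] -= fk;
  }
}

static void eval_forces(const Sys &S, const NbList &nb, const double *x,
                        double *f, double *terms) {
  std::fill(f, f + 3 * S.n, 0.0);
  std::fill(terms, terms + NTERMS, 0.0);

  // harmonic bonds
  for (size_t b = 0; b < S.b_i.size(); ++b) {
    int i = S.b_i[b], j = S.b_j[b];
    double d[3], r2 = 0.0;
    for (int k = 0; k < 3; ++k) { d[k] = x[3 * i + k] - x[3 * j + k]; r2 += d[k] * d[k]; }
    if (r2 < 1e-18) stop("zero-length bond vector between atoms %d and %d", i + 1, j + 1);
    double r = std::sqrt(r2);
    double dr = r - S.b_r0[b];
    terms[T_BOND] += 0.5 * S.b_k[b] * dr * dr;
    double dEdr = S.b_k[b] * dr;
    for (int k = 0; k < 3; ++k) {
      double fk = -dEdr * d[k] / r;
      f[3 * i + k] += fk;
      f[3 * j + k] -= fk;
    }
  }

  // harmonic angles
  for (size_t a = 0; a < S.a_i.size(); ++a) {
    int i = S.a_i[a], j = S.a_j[a], k = S.a_k[a];
    double rij[3], rkj[3];
    double nij = 0.0, nkj = 0.0, dotv = 0.0;
    for (int d = 0; d < 3; ++d) {
      rij[d] = x[3 * i + d] - x[3 * j + d];
      rkj[d] = x[3 * k + d] - x[3 * j + d];
      nij += rij[d] * rij[d];
      nkj += rkj[d] * rkj[d];
      dotv += rij[d] * rkj[d];
    }
    nij = std::sqrt(nij); nkj = std::sqrt(nkj);
    double ct = clamp1(dotv / (nij * nkj));
    double st = std::sqrt(1.0 - ct * ct);
    if (st < 1e-8) st = 1e-8;
    double theta = std::acos(ct);
    double dth = theta - S.a_th0[a];
    terms[T_ANGLE] += 0.5 * S.a_kth[a] * dth * dth;
    double dEdth = S.a_kth[a] * dth;
    for (int d = 0; d < 3; ++d) {
      double eij = rij[d] / nij, ekj = rkj[d] / nkj;
      double fi = -dEdth / (st * nij) * (ct * eij - ekj);
      double fk = -dEdth / (st * nkj) * (ct * ekj - eij);
      f[3 * i + d] += fi;
      f[3 * k + d] += fk;
      f[3 * j + d] -= fi + fk;
    }
  }

  // periodic dihedrals E = k (1 + cos(n phi - delta))
  for (size_t t = 0; t < S.d_i.size(); ++t) {
    int i = S.d_i[t], j = S.d_j[t], k = S.d_k[t], l = S.d_l[t];
    double rij[3], rkj[3], rkl[3], m[3], nvec[3];
    for (int d = 0; d < 3; ++d) {
      rij[d] = x[3 * i + d] - x[3 * j + d];
      rkj[d] = x[3 * k + d] - x[3 * j + d];
      rkl[d] = x[3 * k + d] - x[3 * l + d];
    }
    m[0] = rij[1] * rkj[2] - rij[2] * rkj[1];
    m[1] = rij[2] * rkj[0] - rij[0] * rkj[2];
    m[2] = rij[0] * rkj[1] - rij[1] * rkj[0];
    nvec[0] = rkj[1] * rkl[2] - rkj[2] * rkl[1];
    nvec[1] = rkj[2] * rkl[0] - rkj[0] * rkl[2];
    nvec[2] = rkj[0] * rkl[1] - rkj[1] * rkl[0];
    double nrkj = std::sqrt(rkj[0] * rkj[0] + rkj[1] * rkj[1] + rkj[2] * rkj[2]);
    double ipr = rij[0] * nvec[0] + rij[1] * nvec[1] + rij[2] * nvec[2];
    double mn = m[0] * nvec[0] + m[1] * nvec[1] + m[2] * nvec[2];
    double phi = std::atan2(ipr * nrkj, mn);
    double arg = S.d_n[t] * phi - S.d_phase[t];
    terms[T_DIHEDRAL] += S.d_kd[t] * (1.0 + std::cos(arg));
    double ddphi = -S.d_kd[t] * S.d_n[t] * std::sin(arg);
    double m2 = m[0] * m[0] + m[1] * m[1] + m[2] * m[2];
    double n2 = nvec[0] * nvec[0] + nvec[1] * nvec[1] + nvec[2] * nvec[2];
    if (m2 < 1e-12 || n2 < 1e-12) continue; // collinear: torque-free
    double p = (rij[0] * rkj[0] + rij[1] * rkj[1] + rij[2] * rkj[2]) / (nrkj * nrkj);
    double q = (rkl[0] * rkj[0] + rkl[1] * rkj[1] + rkl[2] * rkj[2]) / (nrkj * nrkj);
    for (int d = 0; d < 3; ++d) {
      double fi = -ddphi * nrkj / m2 * m[d];
      double fl = ddphi * nrkj / n2 * nvec[d];
      double sv = p * fi - q * fl;
      f[3 * i + d] += fi;
      f[3 * l + d] += fl;
      f[3 * j + d] += sv - fi;
      f[3 * k + d] += -sv - fl;
    }
  }

  // nonbonded via pair list
  for (size_t p = 0; p < nb.pi.size(); ++p) {
    int i = nb.pi[p], j = nb.pj[p];
    if (nb.type[p] == 0) {
      pair_lj_coul(S, i, j, x, f, terms, 1.0, 1.0, true);
    } else {
      double d[3], r2 = 0.0;
      for (int k = 0; k < 3; ++k) { d[k] = x[3 * i + k] - x[3 * j + k]; r2 += d[k] * d[k]; }
      if (r2 < 1e-12) stop("coincident beads (%d, %d)", i + 1, j + 1);
      if (r2 >= S.r_cut * S.r_cut) continue;
      double r = std::sqrt(r2);
      double sr = S.sigma_rep / r;
      double sr12 = std::pow(sr, 12);
      double e = S.eps_rep * sr12;
      if (S.shift) e -= S.eps_rep * std::pow(S.sigma_rep / S.r_cut, 12);
      terms[T_GOREP] += e;
      double dEdr = -12.0 * S.eps_rep * sr12 / r;
      for (int k = 0; k < 3; ++k) {
        double fk = -dEdr * d[k] / r;
        f[3 * i + k] += fk;
        f[3 * j + k] -= fk;
      }
    }
  }

  // 1-4 pairs at configurable scale, no cutoff shift (treated as bonded-like)
  for (size_t p = 0; p < S.p14_i.size(); ++p)
    pair_lj_coul(S, S.p14_i[p], S.p14_j[p], x, f, terms,
                 S.scale14_lj, S.scale14_coul, false);

  // Go chain bonds (harmonic about the native distance)
  for (size_t b = 0; b < S.gb_i.size(); ++b) {
    int i = S.gb_i[b], j = S.gb_j[b];
    double d[3], r2 = 0.0;
    for (int k = 0; k < 3; ++k) { d[k] = x[3 * i + k] - x[3 * j + k]; r2 += d[k] * d[k]; }
    if (r2 < 1e-12) stop("coincident beads (%d, %d)", i + 1, j + 1);
    double r = std::sqrt(r2);
    double dr = r - S.gb_r0[b];
    terms[T_GOBOND] += 0.5 * S.gb_k[b] * dr * dr;
    double dEdr = S.gb_k[b] * dr;
    for (int k = 0; k < 3; ++k) {
      double fk = -dEdr * d[k] / r;
      f[3 * i + k] += fk;
      f[3 * j + k] -= fk;
    }
  }

  // Go native contacts: 12-10 well, minimum -eps at r_nat
  for (size_t c = 0; c < S.gc_i.size(); ++c) {
    int i = S.gc_i[c], j = S.gc_j[c];
    double d[3], r2 = 0.0;
    for (int k = 0; k < 3; ++k) { d[k] = x[3 * i + k] - x[3 * j + k]; r2 += d[k] * d[k]; }
    if (r2 < 1e-12) stop("coincident beads (%d, %d)", i + 1, j + 1);
    if (r2 >= S.r_cut * S.r_cut) continue;
    double r = std::sqrt(r2);
    double sr2 = S.gc_r0[c] * S.gc_r0[c] / r2;
    double sr10 = sr2 * sr2 * sr2 * sr2 * sr2;
    double sr12 = sr10 * sr2;
    double e = S.gc_eps[c] * (5.0 * sr12 - 6.0 * sr10);
    if (S.shift) {
      double cr2 = S.gc_r0[c] * S.gc_r0[c] / (S.r_cut * S.r_cut);
      double cr10 = cr2 * cr2 * cr2 * cr2 * cr2;
      e -= S.gc_eps[c] * (5.0 * cr10 * cr2 - 6.0 * cr10);
    }
    terms[T_GOCONTACT] += e;
    double dEdr = -60.0 * S.gc_eps[c] * (sr12 - sr10) / r;
    for (int k = 0; k < 3; ++k) {
      double fk = -dEdr * d[k] / r;
      f[3 * i + k] += fk;
      f[3 * j + k] -= fk;
    }
  }

  // walls: half-harmonic penalties outside each allowed region
  if (S.walls.enabled) {
    const Walls &W = S.walls;
    for (int idx : W.slab_idx) {
      double z = x[3 * idx + 2];
      if (z > W.zhi) {
        double d = z - W.zhi;
        terms[T_WALL] += 0.5 * W.k_wall * d * d;
        f[3 * idx + 2] -= W.k_wall * d;
      } else if (z < W.zlo) {
        double d = W.zlo - z;
        terms[T_WALL] += 0.5 * W.k_wall * d * d;
        f[3 * idx + 2] += W.k_wall * d;
      }
    }
    const double *caps_c[2] = {W.cap1_c, W.cap2_c};
    const double cap_r[2] = {W.cap1_r, W.cap2_r};
    const std::vector<int> *cap_idx[2] = {&W.cap1_idx, &W.cap2_idx};
    for (int s = 0; s < 2; ++s) {
      for (int idx : *cap_idx[s]) {
        double d[3], r2 = 0.0;
        for (int k = 0; k < 3; ++k) { d[k] = x[3 * idx + k] - caps_c[s][k]; r2 += d[k] * d[k]; }
        double r = std::sqrt(r2);
        if (r > cap_r[s] && r > 1e-12) {
          double pen = r - cap_r[s];
          terms[T_WALL] += 0.5 * W.k_wall * pen * pen;
          for (int k = 0; k < 3; ++k)
            f[3 * idx + k] -= W.k_wall * pen * d[k] / r;
        }
      }
    }
    int m = (int)(W.anchors.size() / 3);
    if (m > 0) {
      // soft minimum (log-sum-exp, beta = 10 /A) over the anchor distances:
      // C1 everywhere, identical to the hard minimum for a single anchor,
      // and within ~0.1 A of it when spheres overlap. A hard minimum has a
      // force discontinuity across anchor Voronoi boundaries that breaks
      // energy conservation.
      const double beta = 10.0;
      std::vector<double> da(m);
      for (int idx : W.lat_idx) {
        double dmin = 1e300;
        for (int a = 0; a < m; ++a) {
          double r2 = 0.0;
          for (int k = 0; k < 3; ++k) {
            double d = x[3 * idx + k] - W.anchors[3 * a + k];
            r2 += d * d;
          }
          da[a] = std::sqrt(r2);
          if (da[a] < dmin) dmin = da[a];
        }
        double ssum = 0.0;
        for (int a = 0; a < m; ++a) ssum += std::exp(-beta * (da[a] - dmin));
        double dsoft = dmin - std::log(ssum) / beta;
        if (dsoft > W.lat_offset) {
          double pen = dsoft - W.lat_offset;
          terms[T_WALL] += 0.5 * W.k_wall * pen * pen;
          for (int a = 0; a < m; ++a) {
            if (da[a] < 1e-9) continue;
            double w = std::exp(-beta * (da[a] - dmin)) / ssum;
            if (w < 1e-12) continue;
            for (int k = 0; k < 3; ++k) {
              double u = (x[3 * idx + k] - W.anchors[3 * a + k]) / da[a];
              f[3 * idx + k] -= W.k_wall * pen * w * u;
            }
          }
        }
      }
    }
    if (!W.drop_idx.empty()) {
      double c[3] = {W.drop_c[0], W.drop_c[1], W.drop_c[2]};
      int nlig = (int)W.lig_idx.size();
      if (W.drop_mode == 1 && nlig > 0) {
        c[0] = c[1] = c[2] = 0.0;
        for (int idx : W.lig_idx)
          for (int k = 0; k < 3; ++k) c[k] += x[3 * idx + k];
        for (int k = 0; k < 3; ++k) c[k] /= nlig;
      }
      double dEdc[3] = {0, 0, 0};
      for (int idx : W.drop_idx) {
        double d[3], r2 = 0.0;
        for (int k = 0; k < 3; ++k) { d[k] = x[3 * idx + k] - c[k]; r2 += d[k] * d[k]; }
        double r = std::sqrt(r2);
        if (r > W.drop_r && r > 1e-12) {
          double pen = r - W.drop_r;
          terms[T_WALL] += 0.5 * W.k_drop * pen * pen;
          for (int k = 0; k < 3; ++k) {
            f[3 * idx + k] -= W.k_drop * pen * d[k] / r;
            dEdc[k] -= W.k_drop * pen * d[k] / r; // dE/d(centre)
          }
        }
      }
      // a moving (ligand-centroid) centre transmits the reaction force
      if (W.drop_mode == 1 && nlig > 0) {
        for (int idx : W.lig_idx)
          for (int k = 0; k < 3; ++k)
            f[3 * idx + k] -= dEdc[k] / nlig;
      }
      // upper lipid-head plane: water stays out of the membrane slab
      if (W.water_plane) {
        for (int idx : W.drop_idx) {
          double z = x[3 * idx + 2];
          if (z < W.water_zmin) {
            double d = W.water_zmin - z;
            terms[T_WALL] += 0.5 * W.k_drop * d * d;
            f[3 * idx + 2] += W.k_drop * d;
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Constraints

// SHAKE: project positions onto the constraint manifold using reference
// directions from the pre-step geometry. Convergence: |r - d0|/d0 well under
// the set tolerance (criterion on |d0^2 - r^2| <= 2 * 0.2*tol * d0^2).
static void shake(const Sys &S, const double *xref, double *x) {
  size_t nc = S.c_i.size();
  if (nc == 0) return;
  const double crit = 0.4 * S.c_tol; // on |d0^2 - r^2| / d0^2
  int it = 0;
  for (; it < S.c_maxit; ++it) {
    bool done = true;
    for (size_t c = 0; c < nc; ++c) {
      int i = S.c_i[c], j = S.c_j[c];
      double d[3], r2 = 0.0;
      for (int k = 0; k < 3; ++k) { d[k] = x[3 * i + k] - x[3 * j + k]; r2 += d[k] * d[k]; }
      double d02 = S.c_d0[c] * S.c_d0[c];
      double diff = d02 - r2;
      if (std::fabs(diff) > crit * d02) {
        double rd[3], rr = 0.0;
        for (int k = 0; k < 3; ++k) {
          rd[k] = xref[3 * i + k] - xref[3 * j + k];
          rr += rd[k] * d[k];
        }
        if (std::fabs(rr) < 1e-9 * d02)
          stop("SHAKE failure: constraint %d has degenerate geometry", (int)c + 1);
        double im = 1.0 / S.mass[i], jm = 1.0 / S.mass[j];
        double g = diff / (2.0 * (im + jm) * rr);
        for (int k = 0; k < 3; ++k) {
          x[3 * i + k] += g * im * rd[k];
          x[3 * j + k] -= g * jm * rd[k];
        }
        done = false;
      }
    }
    if (done) break;
  }
  if (it == S.c_maxit) {
    // report the worst-violated constraint
    size_t worst = 0; double wv = 0.0;
    for (size_t c = 0; c < nc; ++c) {
      int i = S.c_i[c], j = S.c_j[c];
      double r2 = 0.0;
      for (int k = 0; k < 3; ++k) { double d = x[3 * i + k] - x[3 * j + k]; r2 += d * d; }
      double v = std::fabs(std::sqrt(r2) - S.c_d0[c]) / S.c_d0[c];
      if (v > wv) { wv = v; worst = c; }
    }
    stop("SHAKE did not converge in %d iterations (worst constraint %d, rel. dev. %g)",
         S.c_maxit, (int)worst + 1, wv);
  }
}

// RATTLE velocity projection: remove relative velocity along each constraint.
static void rattle_v(const Sys &S, const double *x, double *v) {
  size_t nc = S.c_i.size();
  if (nc == 0) return;
  for (int it = 0; it < S.c_maxit; ++it) {
    bool done = true;
    for (size_t c = 0; c < nc; ++c) {
      int i = S.c_i[c], j = S.c_j[c];
      double d[3], r2 = 0.0, rv = 0.0;
      for (int k = 0; k < 3; ++k) {
        d[k] = x[3 * i + k] - x[3 * j + k];
        r2 += d[k] * d[k];
        rv += d[k] * (v[3 * i + k] - v[3 * j + k]);
      }
      if (std::fabs(rv) / std::sqrt(r2) > 1e-10) {
        double im = 1.0 / S.mass[i], jm = 1.0 / S.mass[j];
        double g = rv / (r2 * (im + jm));
        for (int k = 0; k < 3; ++k) {
          v[3 * i + k] -= g * im * d[k];
          v[3 * j + k] += g * jm * d[k];
        }
        done = false;
      }
    }
    if (done) break;
  }
}

static void remove_com_velocity(const Sys &S, double *v) {
  double p[3] = {0, 0, 0}, M = 0.0;
  for (int i = 0; i < S.n; ++i) {
    M += S.mass[i];
    for (int k = 0; k < 3; ++k) p[k] += S.mass[i] * v[3 * i + k];
  }
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) v[3 * i + k] -= p[k] / M;
}

static double kinetic_energy(const Sys &S, const double *v) {
  double ke = 0.0;
  for (int i = 0; i < S.n; ++i) {
    double v2 = 0.0;
    for (int k = 0; k < 3; ++k) v2 += v[3 * i + k] * v[3 * i + k];
    ke += 0.5 * S.mass[i] * v2;
  }
  return ke * KE_CONV;
}

// ---------------------------------------------------------------------------
// Exports

static CharacterVector term_names() {
  return CharacterVector::create("bond", "angle", "dihedral", "lj", "coulomb",
                                 "go_bond", "go_contact", "go_rep", "wall");
}

// [[Rcpp::export]]
List cpp_energy_forces(List system, NumericMatrix coords) {
  Sys S = parse_sys(system);
  if (coords.nrow() != S.n) stop("coordinate/topology size mismatch");
  std::vector<double> x(3 * S.n), f(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  NbList nb;
  nb.build(S, x.data());
  double terms[NTERMS];
  eval_forces(S, nb, x.data(), f.data(), terms);
  NumericVector tv(NTERMS);
  double total = 0.0;
  for (int t = 0; t < NTERMS; ++t) { tv[t] = terms[t]; total += terms[t]; }
  tv.attr("names") = term_names();
  NumericMatrix fm(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) fm(i, k) = f[3 * i + k];
  return List::create(_["terms"] = tv, _["total"] = total, _["forces"] = fm);
}

// [[Rcpp::export]]
List cpp_run(List system, NumericMatrix coords, Nullable<NumericMatrix> velocities,
             List params) {
  Sys S = parse_sys(system);
  if (coords.nrow() != S.n) stop("coordinate/topology size mismatch");
  const double dt = as<double>(params["dt"]);
  const double temperature = as<double>(params["temperature"]);
  const double gamma = as<double>(params["gamma"]);
  const int n_steps = as<int>(params["n_steps"]);
  const int out_stride = as<int>(params["out_stride"]);
  const int log_stride = as<int>(params["log_stride"]);
  const uint64_t seed = (uint64_t)as<double>(params["seed"]);
  const int step_offset = as<int>(params["step_offset"]);
  const bool com_removal = as<bool>(params["com_removal"]);
  const int n_df = as<int>(params["n_df"]);
  const bool save_vel = params.containsElementNamed("save_velocities") ?
    as<bool>(params["save_velocities"]) : false;

  std::vector<double> x(3 * S.n), v(3 * S.n, 0.0), f(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);

  if (velocities.isNotNull()) {
    NumericMatrix vm(velocities);
    for (int i = 0; i < S.n; ++i)
      for (int k = 0; k < 3; ++k) v[3 * i + k] = vm(i, k);
  } else {
    // Maxwell-Boltzmann draw at the target temperature from stream 0
    mmcg::RNG rng(seed, 0);
    for (int i = 0; i < S.n; ++i) {
      double sd = std::sqrt(KB * temperature * F2A / S.mass[i]);
      for (int k = 0; k < 3; ++k) v[3 * i + k] = sd * rng.gaussian();
    }
    rattle_v(S, x.data(), v.data());
    if (com_removal) remove_com_velocity(S, v.data());
  }

  NbList nb;
  nb.build(S, x.data());
  double terms[NTERMS];
  eval_forces(S, nb, x.data(), f.data(), terms);

  const int n_frames = n_steps / out_stride + 1;
  const int n_logs = n_steps / log_stride + 1;
  NumericVector frames(Dimension(S.n, 3, n_frames));
  NumericVector vel_frames(save_vel ? Dimension(S.n, 3, n_frames)
                                    : Dimension(1, 1, 1));
  IntegerVector frame_steps(n_frames);
  NumericMatrix log(n_logs, 6 + NTERMS);
  int fi = 0, li = 0;
  const double h2 = 0.5 * dt;
  const double c1 = (gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
  const double c2 = (gamma > 0.0) ? std::sqrt(1.0 - c1 * c1) : 0.0;

  auto record = [&](int step) {
    if (step % out_stride == 0) {
      for (int i = 0; i < S.n; ++i)
        for (int k = 0; k < 3; ++k) {
          frames[fi * 3 * S.n + k * S.n + i] = x[3 * i + k];
          if (save_vel) vel_frames[fi * 3 * S.n + k * S.n + i] = v[3 * i + k];
        }
      frame_steps[fi++] = step_offset + step;
    }
    if (step % log_stride == 0) {
      double pe = 0.0;
      for (int t = 0; t < NTERMS; ++t) pe += terms[t];
      double ke = kinetic_energy(S, v.data());
      double tinst = (n_df > 0) ? 2.0 * ke / (KB * n_df) : 0.0;
      log(li, 0) = step_offset + step;
      log(li, 1) = (step_offset + step) * dt;
      for (int t = 0; t < NTERMS; ++t) log(li, 2 + t) = terms[t];
      log(li, 2 + NTERMS) = pe;
      log(li, 3 + NTERMS) = ke;
      log(li, 4 + NTERMS) = pe + ke;
      log(li, 5 + NTERMS) = tinst;
      li++;
      if (!std::isfinite(pe) || !std::isfinite(ke))
        stop("non-finite energy at step %d (pe=%g ke=%g)", step_offset + step, pe, ke);
    }
  };
  record(0);

  std::vector<double> xpre(3 * S.n), xunc(3 * S.n);
  const size_t nc = S.c_i.size();

  for (int s = 1; s <= n_steps; ++s) {
    mmcg::RNG rng(seed, (uint64_t)(step_offset + s));
    // B
    for (int i = 0; i < S.n; ++i) {
      double a = F2A / S.mass[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += h2 * a * f[3 * i + k];
    }
    if (nc) rattle_v(S, x.data(), v.data());
    // A (half drift + SHAKE with velocity correction)
    for (int half = 0; half < 2; ++half) {
      if (half == 1) {
        // O between the two half drifts
        if (gamma > 0.0) {
          for (int i = 0; i < S.n; ++i) {
            double sd = std::sqrt(KB * temperature * F2A / S.mass[i]);
            for (int k = 0; k < 3; ++k)
              v[3 * i + k] = c1 * v[3 * i + k] + c2 * sd * rng.gaussian();
          }
          if (nc) rattle_v(S, x.data(), v.data());
        }
      }
      xpre = x;
      for (int i = 0; i < 3 * S.n; ++i) x[i] += h2 * v[i];
      if (nc) {
        xunc = x;
        shake(S, xpre.data(), x.data());
        for (int i = 0; i < 3 * S.n; ++i) v[i] += (x[i] - xunc[i]) / h2;
      }
    }
    // force at the new positions, then final B
    if (nb.stale(S, x.data())) nb.build(S, x.data());
    eval_forces(S, nb, x.data(), f.data(), terms);
    for (int i = 0; i < S.n; ++i) {
      double a = F2A / S.mass[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += h2 * a * f[3 * i + k];
    }
    if (nc) rattle_v(S, x.data(), v.data());
    if (com_removal) remove_com_velocity(S, v.data());
    record(s);
    if (s % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  CharacterVector lognames(6 + NTERMS);
  lognames[0] = "step"; lognames[1] = "time";
  CharacterVector tn = term_names();
  for (int t = 0; t < NTERMS; ++t) lognames[2 + t] = tn[t];
  lognames[2 + NTERMS] = "potential";
  lognames[3 + NTERMS] = "kinetic";
  lognames[4 + NTERMS] = "total";
  lognames[5 + NTERMS] = "temperature";
  colnames(log) = lognames;

  NumericMatrix xf(S.n, 3), vf(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) { xf(i, k) = x[3 * i + k]; vf(i, k) = v[3 * i + k]; }

  return List::create(_["frames"] = frames, _["frame_steps"] = frame_steps,
                      _["log"] = log, _["coords"] = xf, _["velocities"] = vf,
                      _["vel_frames"] = save_vel ? (SEXP)vel_frames : R_NilValue);
}

// Constraint-aware steepest-descent energy minimization with backtracking
// line search; each accepted move is projected back onto the constraint
// manifold, so rigid water keeps its geometry.
// [[Rcpp::export]]
List cpp_minimize(List system, NumericMatrix coords, int max_steps,
                  double force_tol, double max_disp) {
  Sys S = parse_sys(system);
  std::vector<double> x(3 * S.n), f(3 * S.n), xt(3 * S.n), ft(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  NbList nb;
  nb.build(S, x.data());
  double terms[NTERMS], tterms[NTERMS];
  eval_forces(S, nb, x.data(), f.data(), terms);
  double e = 0.0;
  for (int t = 0; t < NTERMS; ++t) e += terms[t];
  double step = 1e-4;
  int it = 0;
  for (; it < max_steps; ++it) {
    double fmax = 0.0;
    for (int i = 0; i < 3 * S.n; ++i) fmax = std::max(fmax, std::fabs(f[i]));
    if (fmax < force_tol) break;
    double scale = step;
    if (scale * fmax > max_disp) scale = max_disp / fmax; // trust radius
    for (int i = 0; i < 3 * S.n; ++i) xt[i] = x[i] + scale * f[i];
    bool ok = true;
    double et = 0.0;
    try {
      if (!S.c_i.empty()) shake(S, x.data(), xt.data());
      NbList nbt;
      nbt.build(S, xt.data());
      eval_forces(S, nbt, xt.data(), ft.data(), tterms);
      for (int t = 0; t < NTERMS; ++t) et += tterms[t];
      if (!std::isfinite(et)) ok = false;
    } catch (std::exception &ex) {
      ok = false;
    }
    if (ok && et < e) {
      x = xt;
      f = ft;
      e = et;
      step *= 1.2;
      if (nb.stale(S, x.data())) nb.build(S, x.data());
    } else {
      step *= 0.5;
      if (step < 1e-12) break;
    }
  }
  NumericMatrix xf(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) xf(i, k) = x[3 * i + k];
  return List::create(_["coords"] = xf, _["energy"] = e,
                      _["iterations"] = it);
}

// Maximum relative deviation of each constrained distance in one frame.
// [[Rcpp::export]]
NumericVector cpp_constraint_deviation(List system, NumericMatrix coords) {
  Sys S = parse_sys(system);
  size_t nc = S.c_i.size();
  NumericVector out(nc);
  for (size_t c = 0; c < nc; ++c) {
    int i = S.c_i[c], j = S.c_j[c];
    double r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = coords(i, k) - coords(j, k);
      r2 += d * d;
    }
    out[c] = std::fabs(std::sqrt(r2) - S.c_d0[c]) / S.c_d0[c];
  }
  return out;
}

// Brute-force all-pairs nonbonded evaluation (no neighbor list); used by the
// pair-list regression tests.
// [[Rcpp::export]]
List cpp_energy_forces_bruteforce(List system, NumericMatrix coords) {
  Sys S = parse_sys(system);
  std::vector<double> x(3 * S.n), f(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  NbList nb;
  nb.skin = 1e6; // effectively all pairs
  nb.build(S, x.data());
  double terms[NTERMS];
  eval_forces(S, nb, x.data(), f.data(), terms);
  NumericVector tv(NTERMS);
  double total = 0.0;
  for (int t = 0; t < NTERMS; ++t) { tv[t] = terms[t]; total += terms[t]; }
  tv.attr("names") = term_names();
  NumericMatrix fm(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) fm(i, k) = f[3 * i + k];
  return List::create(_["terms"] = tv, _["total"] = total, _["forces"] = fm);
}

// Deterministic gaussian draws for a (seed, stream) pair; exposed so R-level
// code (velocity sampling, fixtures) shares the engine's RNG.
// [[Rcpp::export]]
NumericVector cpp_gaussians(double seed, double stream, int n) {
  mmcg::RNG rng((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.gaussian();
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_uniforms(double seed, double stream, int n) {
  mmcg::RNG rng((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.uniform();
  return out;
}
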