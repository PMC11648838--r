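// Core Monte-Carlo engine for the coarse-grained peptide sampler.
//
// Beads are stored chain-major, residue-major, in kind order
// NH(0), CA(1), CO(2), SC(3), so bead index = chain_off[c] + 4*res + kind.
// Coordinates are wrapped into [0, L); all pair distances use the minimum
// image convention. The R layer owns all user-facing contracts; this file
// only implements the hot paths (pair counting, constraint checks, moves,
// and the SAMC / fixed-DOS production loops).

#include <Rcpp.h>
#include <random>
#include <map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const int K_NH = 0, K_CA = 1, K_CO = 2, K_SC = 3;

// ---------------------------------------------------------------------------
// geometry helpers

static inline double wrap1(double x, double L) {
  double w = x - L * std::floor(x / L);
  if (w >= L) w -= L;          // guard against x/L rounding up
  if (w < 0) w += L;
  return w;
}

// component of minimum-image displacement, in [-L/2, L/2)
static inline double mi1(double d, double L) {
  return d - L * std::floor(d / L + 0.5);
}

static inline double dist_pbc(const double* a, const double* b, double L,
                              bool periodic) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = a[k] - b[k];
    if (periodic) d = mi1(d, L);
    s += d * d;
  }
  return std::sqrt(s);
}

// ---------------------------------------------------------------------------
// parameters

struct Params {
  double wbb, wsc;
  double bb_lo, bb_hi;       // NH...CO hydrogen-bond well
  double scsc_lo, scsc_hi;   // SC-SC well
  double scbb_lo, scbb_hi;   // SC-NH and SC-CO well
  double ev[4][4];           // excluded-volume contact distance per kind pair
  int min_sep;               // intra-chain residue separation for counting
  int ev_excl;               // intra-chain |dres| <= ev_excl exempt from EV
};

static Params parse_params(const List& p) {
  Params P;
  P.wbb = as<double>(p["w_bb"]);
  P.wsc = as<double>(p["w_sc"]);
  NumericVector bb = p["bb_well"], ss = p["scsc_well"], sb = p["scbb_well"];
  P.bb_lo = bb[0]; P.bb_hi = bb[1];
  P.scsc_lo = ss[0]; P.scsc_hi = ss[1];
  P.scbb_lo = sb[0]; P.scbb_hi = sb[1];
  NumericMatrix ev = p["ev_contact"];
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) P.ev[i][j] = ev(i, j);
  P.min_sep = as<int>(p["min_sep"]);
  P.ev_excl = as<int>(p["ev_res_exclusion"]);
  return P;
}

// ---------------------------------------------------------------------------
// interaction counting (square wells + one-bond-per-partner greedy matching)

struct PairRec {
  double d;
  int i, j;   // i = donor/first bead, j = acceptor/second bead
};

static bool pair_less(const PairRec& a, const PairRec& b) {
  if (a.d != b.d) return a.d < b.d;
  if (a.i != b.i) return a.i < b.i;
  return a.j < b.j;
}

static inline bool count_eligible(int ci, int cj, int ri, int rj, int min_sep) {
  if (ci != cj) return true;
  return std::abs(ri - rj) >= min_sep;
}

// full recount; optionally returns the matched pair lists
static void count_core(const NumericMatrix& X, const IntegerVector& kind,
                       const IntegerVector& chain, const IntegerVector& resid,
                       const Params& P, double L, bool periodic,
                       int& nbb, int& nsc,
                       std::vector<PairRec>* bb_out = nullptr,
                       std::vector<PairRec>* sc_out = nullptr) {
  const int n = X.nrow();
  std::vector<PairRec> hb, sc;
  std::vector<double> xi(3), xj(3);
  for (int i = 0; i < n - 1; ++i) {
    double a[3] = { X(i, 0), X(i, 1), X(i, 2) };
    for (int j = i + 1; j < n; ++j) {
      int ki = kind[i], kj = kind[j];
      bool is_hb = (ki == K_NH && kj == K_CO) || (ki == K_CO && kj == K_NH);
      bool is_scsc = (ki == K_SC && kj == K_SC);
      bool is_scbb = (ki == K_SC && (kj == K_NH || kj == K_CO)) ||
                     (kj == K_SC && (ki == K_NH || ki == K_CO));
      if (!is_hb && !is_scsc && !is_scbb) continue;
      if (!count_eligible(chain[i], chain[j], resid[i], resid[j], P.min_sep))
        continue;
      double b[3] = { X(j, 0), X(j, 1), X(j, 2) };
      double d = dist_pbc(a, b, L, periodic);
      if (is_hb && d >= P.bb_lo && d <= P.bb_hi) {
        PairRec r;
        r.d = d;
        r.i = (ki == K_NH) ? i : j;   // donor NH first
        r.j = (ki == K_NH) ? j : i;
        hb.push_back(r);
      } else if (is_scsc && d >= P.scsc_lo && d <= P.scsc_hi) {
        PairRec r; r.d = d; r.i = i; r.j = j;
        sc.push_back(r);
      } else if (is_scbb && d >= P.scbb_lo && d <= P.scbb_hi) {
        PairRec r; r.d = d; r.i = i; r.j = j;
        sc.push_back(r);
      }
    }
  }
  // greedy matching by ascending distance, index-order tie break:
  // one hydrogen bond per NH donor and per CO acceptor
  std::sort(hb.begin(), hb.end(), pair_less);
  std::vector<char> used(n, 0);
  nbb = 0;
  for (const PairRec& r : hb) {
    if (used[r.i] || used[r.j]) continue;
    used[r.i] = used[r.j] = 1;
    ++nbb;
    if (bb_out) bb_out->push_back(r);
  }
  // sidechain matching is an independent assignment: each bead takes part in
  // at most one sidechain interaction
  std::sort(sc.begin(), sc.end(), pair_less);
  std::fill(used.begin(), used.end(), 0);
  nsc = 0;
  for (const PairRec& r : sc) {
    if (used[r.i] || used[r.j]) continue;
    used[r.i] = used[r.j] = 1;
    ++nsc;
    if (sc_out) sc_out->push_back(r);
  }
}

// [[Rcpp::export]]
List cpp_count(NumericMatrix coords, IntegerVector kind, IntegerVector chain,
               IntegerVector resid, List params, double L, bool periodic) {
  Params P = parse_params(params);
  int nbb = 0, nsc = 0;
  std::vector<PairRec> bb, sc;
  count_core(coords, kind, chain, resid, P, L, periodic, nbb, nsc, &bb, &sc);
  IntegerMatrix bbm(bb.size(), 2), scm(sc.size(), 2);
  for (size_t k = 0; k < bb.size(); ++k) { bbm(k, 0) = bb[k].i + 1; bbm(k, 1) = bb[k].j + 1; }
  for (size_t k = 0; k < sc.size(); ++k) { scm(k, 0) = sc[k].i + 1; scm(k, 1) = sc[k].j + 1; }
  return List::create(_["n_backbone"] = nbb, _["n_sidechain"] = nsc,
                      _["bb_pairs"] = bbm, _["sc_pairs"] = scm);
}

// ---------------------------------------------------------------------------
// constraint validation

// violations: type 1 = bond, 2 = excluded volume
static void validate_core(const NumericMatrix& X, const IntegerVector& kind,
                          const IntegerVector& chain, const IntegerVector& resid,
                          const IntegerMatrix& bonds, const NumericVector& bond_ref,
                          double bond_tol, const Params& P, double L, bool periodic,
                          std::vector<int>& vi, std::vector<int>& vj,
                          std::vector<int>& vtype, std::vector<double>& vdist,
                          std::vector<double>& vbound, bool stop_first = false) {
  const int n = X.nrow();
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double a[3] = { X(i, 0), X(i, 1), X(i, 2) };
    double c[3] = { X(j, 0), X(j, 1), X(j, 2) };
    double d = dist_pbc(a, c, L, periodic);
    if (std::fabs(d - bond_ref[b]) > bond_tol * bond_ref[b]) {
      vi.push_back(i); vj.push_back(j); vtype.push_back(1);
      vdist.push_back(d); vbound.push_back(bond_ref[b]);
      if (stop_first) return;
    }
  }
  for (int i = 0; i < n - 1; ++i) {
    double a[3] = { X(i, 0), X(i, 1), X(i, 2) };
    for (int j = i + 1; j < n; ++j) {
      if (chain[i] == chain[j] &&
          std::abs(resid[i] - resid[j]) <= P.ev_excl) continue;
      double contact = P.ev[kind[i]][kind[j]];
      if (contact <= 0) continue;
      double c[3] = { X(j, 0), X(j, 1), X(j, 2) };
      double d = dist_pbc(a, c, L, periodic);
      if (d < contact) {
        vi.push_back(i); vj.push_back(j); vtype.push_back(2);
        vdist.push_back(d); vbound.push_back(contact);
        if (stop_first) return;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_validate(NumericMatrix coords, IntegerVector kind, IntegerVector chain,
                  IntegerVector resid, IntegerMatrix bonds, NumericVector bond_ref,
                  double bond_tol, List params, double L, bool periodic) {
  Params P = parse_params(params);
  std::vector<int> vi, vj, vtype;
  std::vector<double> vdist, vbound;
  validate_core(coords, kind, chain, resid, bonds, bond_ref, bond_tol, P, L,
                periodic, vi, vj, vtype, vdist, vbound);
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["type"] = wrap(vtype), _["dist"] = wrap(vdist),
                      _["bound"] = wrap(vbound));
}

// fast validity check restricted to a moved bead set (exact when the moved
// set is internally rigid: internal distances are then unchanged)
static bool moved_valid(const NumericMatrix& X, const IntegerVector& kind,
                        const IntegerVector& chain, const IntegerVector& resid,
                        const IntegerMatrix& bonds, const NumericVector& bond_ref,
                        double bond_tol, const Params& P, double L, bool periodic,
                        const std::vector<int>& moved, bool rigid,
                        std::vector<char>& is_moved) {
  const int n = X.nrow();
  for (int m : moved) is_moved[m] = 1;
  bool ok = true;
  for (int b = 0; b < bonds.nrow() && ok; ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    bool mi_ = is_moved[i], mj_ = is_moved[j];
    if (!mi_ && !mj_) continue;
    if (mi_ && mj_ && rigid) continue;
    double a[3] = { X(i, 0), X(i, 1), X(i, 2) };
    double c[3] = { X(j, 0), X(j, 1), X(j, 2) };
    double d = dist_pbc(a, c, L, periodic);
    if (std::fabs(d - bond_ref[b]) > bond_tol * bond_ref[b]) ok = false;
  }
  for (size_t mm = 0; mm < moved.size() && ok; ++mm) {
    int i = moved[mm];
    double a[3] = { X(i, 0), X(i, 1), X(i, 2) };
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (is_moved[j]) {
        if (rigid) continue;
        if (j < i) continue;  // avoid double-checking moved-moved pairs
      }
      if (chain[i] == chain[j] &&
          std::abs(resid[i] - resid[j]) <= P.ev_excl) continue;
      double contact = P.ev[kind[i]][kind[j]];
      if (contact <= 0) continue;
      double c[3] = { X(j, 0), X(j, 1), X(j, 2) };
      double d = dist_pbc(a, c, L, periodic);
      if (d < contact) { ok = false; break; }
    }
  }
  for (int m : moved) is_moved[m] = 0;
  return ok;
}

// ---------------------------------------------------------------------------
// RNG (self-contained so results do not depend on R's RNG state)

struct RNG {
  std::mt19937_64 g;
  explicit RNG(uint64_t s) : g(s) {}
  double unif() { return (g() >> 11) * (1.0 / 9007199254740992.0); }  // [0,1)
  int ri(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
  void sphere(double* v) {
    double r2;
    do {
      v[0] = 2 * unif() - 1; v[1] = 2 * unif() - 1; v[2] = 2 * unif() - 1;
      r2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
    } while (r2 > 1.0 || r2 < 1e-12);
    double inv = 1.0 / std::sqrt(r2);
    v[0] *= inv; v[1] *= inv; v[2] *= inv;
  }
};

// ---------------------------------------------------------------------------
// moves

// unwrap one chain by walking the bonded topology (each pseudo-bond << L/2)
static void unwrap_chain(const NumericMatrix& X, int off, int nres, double L,
                         bool periodic, std::vector<double>& u) {
  int nb = 4 * nres;
  u.resize(3 * nb);
  for (int r = 0; r < nres; ++r) {
    int nh = 4 * r, ca = 4 * r + 1, co = 4 * r + 2, sc = 4 * r + 3;
    int anchors[4] = { r == 0 ? -1 : 4 * (r - 1) + 2, nh, ca, ca };
    int order[4] = { nh, ca, co, sc };
    for (int q = 0; q < 4; ++q) {
      int lc = order[q], an = anchors[q];
      for (int k = 0; k < 3; ++k) {
        double x = X(off + lc, k);
        if (an < 0) {
          u[3 * lc + k] = x;
        } else {
          double d = x - X(off + an, k);
          if (periodic) d = mi1(d, L);
          u[3 * lc + k] = u[3 * an + k] + d;
        }
      }
    }
  }
}

static void rodrigues(const double* p, const double* c, const double* axis,
                      double ang, double* out) {
  double v[3] = { p[0] - c[0], p[1] - c[1], p[2] - c[2] };
  double ca = std::cos(ang), sa = std::sin(ang);
  double dot = axis[0] * v[0] + axis[1] * v[1] + axis[2] * v[2];
  double cr[3] = { axis[1] * v[2] - axis[2] * v[1],
                   axis[2] * v[0] - axis[0] * v[2],
                   axis[0] * v[1] - axis[1] * v[0] };
  for (int k = 0; k < 3; ++k)
    out[k] = c[k] + v[k] * ca + cr[k] * sa + axis[k] * dot * (1 - ca);
}

struct Proposal {
  int type;                  // 0 disp, 1 pivot, 2 chain_rotation, 3 chain_translation
  int chain, residue, axis_kind;  // pivot: axis_kind 0=phi, 1=psi
  double angle;
  double vec[3];             // translation vector / rotation axis
  std::vector<int> moved;    // bead indices (0-based)
  std::vector<double> newpos;
  bool rigid;
};

// pivot applier shared by the proposal generator and the exported function;
// axis_kind 0: rotate about NH->CA of `res` (moves CO, SC of res + later
// residues); 1: rotate about CA->CO (moves residues after res)
static void pivot_newpos(const NumericMatrix& X, int off, int nres, double L,
                         bool periodic, int res, int axis_kind, double angle,
                         std::vector<int>& moved, std::vector<double>& np) {
  std::vector<double> u;
  unwrap_chain(X, off, nres, L, periodic, u);
  int ca = 4 * res + 1;
  double c[3] = { u[3 * ca], u[3 * ca + 1], u[3 * ca + 2] };
  int other = (axis_kind == 0) ? 4 * res : 4 * res + 2;  // NH or CO
  double ax[3];
  double nrm = 0;
  for (int k = 0; k < 3; ++k) {
    ax[k] = (axis_kind == 0) ? (c[k] - u[3 * other + k])
                             : (u[3 * other + k] - c[k]);
    nrm += ax[k] * ax[k];
  }
  nrm = std::sqrt(nrm);
  for (int k = 0; k < 3; ++k) ax[k] /= nrm;
  moved.clear();
  if (axis_kind == 0) {
    moved.push_back(4 * res + 2);
    moved.push_back(4 * res + 3);
  }
  for (int r = res + 1; r < nres; ++r)
    for (int q = 0; q < 4; ++q) moved.push_back(4 * r + q);
  np.resize(3 * moved.size());
  for (size_t m = 0; m < moved.size(); ++m) {
    double out[3];
    rodrigues(&u[3 * moved[m]], c, ax, angle, out);
    for (int k = 0; k < 3; ++k)
      np[3 * m + k] = periodic ? wrap1(out[k], L) : out[k];
  }
  for (size_t m = 0; m < moved.size(); ++m) moved[m] += off;
}

static void chain_rot_newpos(const NumericMatrix& X, int off, int nres, double L,
                             bool periodic, const double* axis, double angle,
                             std::vector<int>& moved, std::vector<double>& np) {
  std::vector<double> u;
  unwrap_chain(X, off, nres, L, periodic, u);
  int nb = 4 * nres;
  double c[3] = { 0, 0, 0 };
  for (int b = 0; b < nb; ++b)
    for (int k = 0; k < 3; ++k) c[k] += u[3 * b + k];
  for (int k = 0; k < 3; ++k) c[k] /= nb;
  moved.resize(nb);
  np.resize(3 * nb);
  for (int b = 0; b < nb; ++b) {
    moved[b] = off + b;
    double out[3];
    rodrigues(&u[3 * b], c, axis, angle, out);
    for (int k = 0; k < 3; ++k)
      np[3 * b + k] = periodic ? wrap1(out[k], L) : out[k];
  }
}

static void make_proposal(const NumericMatrix& X, const IntegerVector& chain_nres,
                          const IntegerVector& chain_off, double L, bool periodic,
                          const NumericVector& mix, double max_disp,
                          double max_pivot, double max_trans, double max_rot,
                          RNG& rng, int force_type, Proposal& pr) {
  int nch = chain_nres.size();
  int n = 0;
  for (int c = 0; c < nch; ++c) n += 4 * chain_nres[c];
  int type = force_type;
  if (type < 0) {
    double u = rng.unif(), acc = 0;
    type = 3;
    for (int k = 0; k < 4; ++k) {
      acc += mix[k];
      if (u < acc) { type = k; break; }
    }
  }
  pr.type = type;
  pr.chain = -1; pr.residue = -1; pr.axis_kind = -1; pr.angle = 0;
  pr.vec[0] = pr.vec[1] = pr.vec[2] = 0;
  if (type == 0) {                                      // single-bead displacement
    int b = rng.ri(n);
    double dir[3];
    rng.sphere(dir);
    double d = rng.unif() * max_disp;
    pr.moved.assign(1, b);
    pr.newpos.resize(3);
    for (int k = 0; k < 3; ++k) {
      double x = X(b, k) + dir[k] * d;
      pr.newpos[k] = periodic ? wrap1(x, L) : x;
    }
    pr.rigid = true;
  } else if (type == 1) {                               // pivot
    int c = rng.ri(nch);
    int nres = chain_nres[c];
    int ak = rng.ri(2);
    if (nres == 1) ak = 0;                              // psi needs a next residue
    int res = (ak == 1) ? rng.ri(nres - 1) : rng.ri(nres);
    double ang = (2 * rng.unif() - 1) * max_pivot;
    pivot_newpos(X, chain_off[c], nres, L, periodic, res, ak, ang,
                 pr.moved, pr.newpos);
    pr.chain = c; pr.residue = res; pr.axis_kind = ak; pr.angle = ang;
    pr.rigid = true;
  } else if (type == 2) {                               // whole-chain rotation
    int c = rng.ri(nch);
    double ax[3];
    rng.sphere(ax);
    double ang = (2 * rng.unif() - 1) * max_rot;
    chain_rot_newpos(X, chain_off[c], chain_nres[c], L, periodic, ax, ang,
                     pr.moved, pr.newpos);
    pr.chain = c; pr.angle = ang;
    for (int k = 0; k < 3; ++k) pr.vec[k] = ax[k];
    pr.rigid = true;
  } else {                                              // whole-chain translation
    int c = rng.ri(nch);
    double dir[3];
    rng.sphere(dir);
    double d = rng.unif() * max_trans;
    int nb = 4 * chain_nres[c];
    pr.moved.resize(nb);
    pr.newpos.resize(3 * nb);
    for (int b = 0; b < nb; ++b) {
      pr.moved[b] = chain_off[c] + b;
      for (int k = 0; k < 3; ++k) {
        double x = X(chain_off[c] + b, k) + dir[k] * d;
        pr.newpos[3 * b + k] = periodic ? wrap1(x, L) : x;
      }
    }
    pr.chain = c;
    for (int k = 0; k < 3; ++k) pr.vec[k] = dir[k] * d;
    pr.rigid = true;
  }
}

// [[Rcpp::export]]
List cpp_propose(NumericMatrix coords, IntegerVector kind, IntegerVector chain,
                 IntegerVector resid, IntegerVector chain_nres,
                 IntegerVector chain_off, IntegerMatrix bonds,
                 NumericVector bond_ref, double bond_tol, List params,
                 double L, bool periodic, NumericVector move_mix,
                 double max_disp, double max_pivot, double max_trans,
                 double max_rot, int seed, int force_type) {
  Params P = parse_params(params);
  RNG rng((uint64_t)seed);
  Proposal pr;
  make_proposal(coords, chain_nres, chain_off, L, periodic, move_mix, max_disp,
                max_pivot, max_trans, max_rot, rng, force_type, pr);
  int nm = pr.moved.size();
  NumericMatrix oldp(nm, 3), newp(nm, 3);
  for (int m = 0; m < nm; ++m)
    for (int k = 0; k < 3; ++k) {
      oldp(m, k) = coords(pr.moved[m], k);
      newp(m, k) = pr.newpos[3 * m + k];
    }
  // validity on the trial configuration
  NumericMatrix trial = clone(coords);
  for (int m = 0; m < nm; ++m)
    for (int k = 0; k < 3; ++k) trial(pr.moved[m], k) = newp(m, k);
  std::vector<char> is_moved(coords.nrow(), 0);
  bool ok = moved_valid(trial, kind, chain, resid, bonds, bond_ref, bond_tol, P,
                        L, periodic, pr.moved, pr.rigid, is_moved);
  IntegerVector mv(nm);
  for (int m = 0; m < nm; ++m) mv[m] = pr.moved[m] + 1;
  return List::create(
      _["type"] = pr.type + 1, _["moved"] = mv, _["old_pos"] = oldp,
      _["new_pos"] = newp, _["valid"] = ok, _["chain"] = pr.chain + 1,
      _["residue"] = pr.residue + 1, _["axis_kind"] = pr.axis_kind + 1,
      _["angle"] = pr.angle,
      _["vec"] = NumericVector::create(pr.vec[0], pr.vec[1], pr.vec[2]));
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_pivot(NumericMatrix coords, IntegerVector chain_nres,
                              IntegerVector chain_off, double L, bool periodic,
                              int chain1, int residue1, int axis_kind1,
                              double angle) {
  int c = chain1 - 1;
  std::vector<int> moved;
  std::vector<double> np;
  pivot_newpos(coords, chain_off[c], chain_nres[c], L, periodic, residue1 - 1,
               axis_kind1 - 1, angle, moved, np);
  NumericMatrix out = clone(coords);
  for (size_t m = 0; m < moved.size(); ++m)
    for (int k = 0; k < 3; ++k) out(moved[m], k) = np[3 * m + k];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_chain_rotation(NumericMatrix coords,
                                       IntegerVector chain_nres,
                                       IntegerVector chain_off, double L,
                                       bool periodic, int chain1,
                                       NumericVector axis, double angle) {
  int c = chain1 - 1;
  double ax[3] = { axis[0], axis[1], axis[2] };
  double nrm = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
  for (int k = 0; k < 3; ++k) ax[k] /= nrm;
  std::vector<int> moved;
  std::vector<double> np;
  chain_rot_newpos(coords, chain_off[c], chain_nres[c], L, periodic, ax, angle,
                   moved, np);
  NumericMatrix out = clone(coords);
  for (size_t m = 0; m < moved.size(); ++m)
    for (int k = 0; k < 3; ++k) out(moved[m], k) = np[3 * m + k];
  return out;
}

// ---------------------------------------------------------------------------
// level bookkeeping

struct DosState {
  std::map<std::pair<int, int>, int> idx;
  std::vector<int> nbb, nsc;
  std::vector<double> logdos, init;
  std::vector<double> visits;
  double min_logdos() const {
    double m = 0;
    bool first = true;
    for (double v : logdos) {
      if (first || v < m) { m = v; first = false; }
    }
    return m;
  }
  int find(int a, int b) const {
    auto it = idx.find(std::make_pair(a, b));
    return it == idx.end() ? -1 : it->second;
  }
  int add(int a, int b, double g0) {
    idx[std::make_pair(a, b)] = (int)nbb.size();
    nbb.push_back(a); nsc.push_back(b);
    logdos.push_back(g0); init.push_back(g0); visits.push_back(0);
    return (int)nbb.size() - 1;
  }
};

static void dos_from_list(const List& d, DosState& s) {
  if (d.size() == 0) return;
  IntegerVector a = d["n_backbone"], b = d["n_sidechain"];
  NumericVector g = d["log_dos"], v = d["visits"], in = d["init_log_dos"];
  for (int k = 0; k < a.size(); ++k) {
    int i = s.add(a[k], b[k], in[k]);
    s.logdos[i] = g[k];
    s.visits[i] = v[k];
  }
}

static List dos_to_list(const DosState& s) {
  // emit levels sorted by (n_backbone, n_sidechain) for determinism
  int nl = (int)s.nbb.size();
  std::vector<int> ord;
  for (const auto& kv : s.idx) ord.push_back(kv.second);
  IntegerVector a(nl), b(nl);
  NumericVector g(nl), v(nl), in(nl);
  for (int k = 0; k < nl; ++k) {
    int i = ord[k];
    a[k] = s.nbb[i]; b[k] = s.nsc[i];
    g[k] = s.logdos[i]; v[k] = s.visits[i]; in[k] = s.init[i];
  }
  return List::create(_["n_backbone"] = a, _["n_sidechain"] = b,
                      _["log_dos"] = g, _["visits"] = v,
                      _["init_log_dos"] = in);
}

// ---------------------------------------------------------------------------
// the Monte-Carlo driver: SAMC (update_dos) or fixed-DOS production

struct Snapshot {
  double step;
  int nbb, nsc;
  std::vector<double> coords;
};

// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix coords, IntegerVector kind, IntegerVector chain,
                IntegerVector resid, IntegerVector chain_nres,
                IntegerVector chain_off, IntegerMatrix bonds,
                NumericVector bond_ref, double bond_tol, List params, double L,
                bool periodic, NumericVector move_mix, double max_disp,
                double max_pivot, double max_trans, double max_rot,
                bool update_dos, double gamma0, double t0, double gamma_min,
                List dos_in, double t_start, double gamma_sum_start,
                double n_steps, double max_steps, int seed, int stride,
                int quota, bool collect_snapshots) {
  Params P = parse_params(params);
  RNG rng((uint64_t)seed);
  NumericMatrix X = clone(coords);
  const int n = X.nrow();

  DosState dos;
  dos_from_list(dos_in, dos);

  // production keeps its own visit ledger so the input DOS stays read-only
  DosState prod;

  int nbb_cur, nsc_cur;
  count_core(X, kind, chain, resid, P, L, periodic, nbb_cur, nsc_cur);
  int cur = dos.find(nbb_cur, nsc_cur);
  if (cur < 0) {
    double g0 = dos.nbb.empty() ? 0.0 : dos.min_logdos();
    cur = dos.add(nbb_cur, nsc_cur, g0);
  }

  std::vector<Snapshot> snaps_first;                   // first-visit snapshots
  std::map<std::pair<int, int>, std::vector<Snapshot> > reservoir;
  std::map<std::pair<int, int>, double> seen;

  auto take_snapshot = [&](double step) {
    Snapshot s;
    s.step = step; s.nbb = nbb_cur; s.nsc = nsc_cur;
    s.coords.resize(3 * n);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) s.coords[3 * i + k] = X(i, k);
    return s;
  };

  double t = t_start, gamma_sum = gamma_sum_start, gamma = NA_REAL;
  double steps_done = 0, accepted = 0, invalid = 0;
  bool converged = false;
  std::vector<char> is_moved(n, 0);
  Proposal pr;

  if (!update_dos && collect_snapshots) {
    // level of the initial configuration counts as visited
    auto key = std::make_pair(nbb_cur, nsc_cur);
    if (reservoir[key].empty()) {
      reservoir[key].push_back(take_snapshot(t));
      seen[key] += 1;
    }
  }

  while (true) {
    if (update_dos) {
      gamma = std::min(gamma0, t0 / (t + 1));
      if (n_steps <= 0 && gamma < gamma_min) { converged = true; break; }
      if (n_steps > 0 && steps_done >= n_steps) break;
      if (steps_done >= max_steps) break;
    } else {
      if (steps_done >= n_steps) break;
    }
    t += 1;
    steps_done += 1;

    make_proposal(X, chain_nres, chain_off, L, periodic, move_mix, max_disp,
                  max_pivot, max_trans, max_rot, rng, -1, pr);
    const int nm = (int)pr.moved.size();
    std::vector<double> oldpos(3 * nm);
    for (int m = 0; m < nm; ++m)
      for (int k = 0; k < 3; ++k) {
        oldpos[3 * m + k] = X(pr.moved[m], k);
        X(pr.moved[m], k) = pr.newpos[3 * m + k];
      }
    bool ok = moved_valid(X, kind, chain, resid, bonds, bond_ref, bond_tol, P,
                          L, periodic, pr.moved, pr.rigid, is_moved);
    bool accept = false;
    int nbb_new = nbb_cur, nsc_new = nsc_cur, lev_new = -1;
    if (ok) {
      count_core(X, kind, chain, resid, P, L, periodic, nbb_new, nsc_new);
      lev_new = dos.find(nbb_new, nsc_new);
      double g_cur = dos.logdos[cur];
      double g_new = (lev_new >= 0) ? dos.logdos[lev_new] : dos.min_logdos();
      double p = (g_cur >= g_new) ? 1.0 : std::exp(g_cur - g_new);
      accept = (p >= 1.0) || (rng.unif() < p);
    } else {
      invalid += 1;
    }
    if (accept) {
      accepted += 1;
      if (lev_new < 0) lev_new = dos.add(nbb_new, nsc_new, dos.min_logdos());
      cur = lev_new;
      nbb_cur = nbb_new;
      nsc_cur = nsc_new;
    } else {
      for (int m = 0; m < nm; ++m)
        for (int k = 0; k < 3; ++k) X(pr.moved[m], k) = oldpos[3 * m + k];
    }

    if (update_dos) {
      dos.logdos[cur] += gamma;
      dos.visits[cur] += 1;
      gamma_sum += gamma;
    } else {
      int pl = prod.find(nbb_cur, nsc_cur);
      if (pl < 0) pl = prod.add(nbb_cur, nsc_cur, 0.0);
      prod.visits[pl] += 1;
      if (collect_snapshots) {
        auto key = std::make_pair(nbb_cur, nsc_cur);
        bool first = reservoir[key].empty();
        bool on_stride = (((long long)steps_done) % (long long)stride == 0);
        if (first || on_stride) {
          std::vector<Snapshot>& rv = reservoir[key];
          double sn = seen[key];
          if ((int)rv.size() < quota) {
            rv.push_back(take_snapshot(t));
          } else {
            int j = (int)(rng.unif() * (sn + 1));
            if (j < quota) rv[j] = take_snapshot(t);
          }
          seen[key] = sn + 1;
        }
      }
    }
  }

  List snaps;
  if (!update_dos && collect_snapshots) {
    std::vector<const Snapshot*> all;
    for (const auto& kv : reservoir)
      for (const Snapshot& s : kv.second) all.push_back(&s);
    std::sort(all.begin(), all.end(),
              [](const Snapshot* a, const Snapshot* b) { return a->step < b->step; });
    snaps = List(all.size());
    for (size_t k = 0; k < all.size(); ++k) {
      const Snapshot* s = all[k];
      NumericMatrix C(n, 3);
      for (int i = 0; i < n; ++i)
        for (int kk = 0; kk < 3; ++kk) C(i, kk) = s->coords[3 * i + kk];
      snaps[k] = List::create(_["step"] = s->step, _["n_backbone"] = s->nbb,
                              _["n_sidechain"] = s->nsc, _["coords"] = C);
    }
  }

  return List::create(
      _["coords"] = X, _["dos"] = dos_to_list(dos),
      _["prod_levels"] = dos_to_list(prod), _["t"] = t,
      // schedule value of the next pending step, so that at a converged
      // termination gamma < gamma_min holds
      _["gamma"] = update_dos ? std::min(gamma0, t0 / (t + 1)) : NA_REAL,
      _["gamma_sum"] = gamma_sum, _["steps"] = steps_done,
      _["accepted"] = accepted, _["invalid"] = invalid,
      _["converged"] = converged, _["snapshots"] = snaps,
      _["current_level"] = IntegerVector::create(nbb_cur, nsc_cur));
}
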