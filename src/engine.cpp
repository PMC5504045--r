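// Monte Carlo engine for patchy heteropolymer chains.
//
// Units: lengths in bead radii (R_bead = 1), energies in kB*T_Ref.
// Hard core acts between non-bonded bead centers at `contact` (2 R_bead).
// Isotropic pair term is truncated at rmax (where it equals eps/2);
// directional patch-patch term is truncated at rcut (3 sigma).

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Par {
  double rbead, contact, rmax, eps_p, s, sigma, rcut,
         spring_k, spring_rest;
  int nu;      // even exponent of the angular factor
  int model;   // 0 = FRC (bonds between centers), 1 = FJC (bonds between anchors)
};

static Par read_par(const List& p) {
  Par o;
  o.rbead       = as<double>(p["bead_radius"]);
  o.contact     = as<double>(p["hardcore_contact"]);
  o.rmax        = as<double>(p["r_max"]);
  o.eps_p       = as<double>(p["eps_p"]);
  o.s           = as<double>(p["s"]);
  o.sigma       = as<double>(p["sigma"]);
  o.rcut        = as<double>(p["r_cut"]);
  o.spring_k    = as<double>(p["spring_k"]);
  o.spring_rest = as<double>(p["spring_rest"]);
  o.nu          = as<int>(p["nu"]);
  o.model       = as<std::string>(p["chain_model"]) == "FJC" ? 1 : 0;
  return o;
}

struct Vec3 { double x, y, z; };
static inline Vec3 sub(const Vec3& a, const Vec3& b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline double dot(const Vec3& a, const Vec3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Quat { double w, x, y, z; };

static inline Quat qmul(const Quat& a, const Quat& b) {
  return { a.w*b.w - a.x*b.x - a.y*b.y - a.z*b.z,
           a.w*b.x + a.x*b.w + a.y*b.z - a.z*b.y,
           a.w*b.y - a.x*b.z + a.y*b.w + a.z*b.x,
           a.w*b.z + a.x*b.y - a.y*b.x + a.z*b.w };
}

static inline void qnormalize(Quat& q) {
  double n = std::sqrt(q.w*q.w + q.x*q.x + q.y*q.y + q.z*q.z);
  q.w /= n; q.x /= n; q.y /= n; q.z /= n;
}

// rotate body-frame vector v by unit quaternion q (active rotation)
static inline Vec3 qrot(const Quat& q, const Vec3& v) {
  // t = 2 q_vec x v ; v' = v + w t + q_vec x t
  double tx = 2.0 * (q.y*v.z - q.z*v.y);
  double ty = 2.0 * (q.z*v.x - q.x*v.z);
  double tz = 2.0 * (q.x*v.y - q.y*v.x);
  return { v.x + q.w*tx + (q.y*tz - q.z*ty),
           v.y + q.w*ty + (q.z*tx - q.x*tz),
           v.z + q.w*tz + (q.x*ty - q.y*tx) };
}

static inline Quat axis_angle(const Vec3& ax, double ang) {
  double h = 0.5 * ang, s = std::sin(h);
  return { std::cos(h), ax.x*s, ax.y*s, ax.z*s };
}

struct Chain {
  std::vector<Vec3> pos;
  std::vector<Quat> ori;
  std::vector<int>  seq;
  double E;
  int walker;
};

struct Model {
  Par par;
  std::vector<Vec3> patch;   // body-frame patch axes (unit)
  std::vector<Vec3> anchor;  // 0 or 2 body-frame anchor axes (fwd, bwd)
  std::vector<double> eps;   // q x q interaction matrix, row-major
  int q;
  double eps_ab(int a, int b) const { return eps[a * q + b]; }
};

static inline double iso_energy(double r, double eps, const Par& p) {
  if (r > p.rmax) return 0.0;
  return eps * (1.0 - 1.0 / (1.0 + std::exp(2.5 * (p.rmax - r))));
}

// directional term between one patch on bead i and one patch on bead j
static inline double patch_pair(const Vec3& pa, const Vec3& wa,
                                const Vec3& pb, const Vec3& wb,
                                const Par& p) {
  Vec3 d = sub(pb, pa);
  double R = norm(d);
  if (R >= p.rcut) return 0.0;
  if (R < 1e-12) return INF;  // coincident patch points
  double inv = 1.0 / R;
  double c1 = dot(wa, d) * inv;
  double c2 = dot(wb, d) * inv;
  double ang = c1 * c2;
  double angp;
  if (p.nu == 2) angp = ang * ang; else angp = std::pow(ang, p.nu);
  double x = p.sigma * inv;
  double x2 = x * x;
  double x10 = x2 * x2; x10 *= x10; x10 *= x2;  // x^10
  double x12 = x10 * x2;
  return p.s * p.eps_p * angp * (5.0 * x12 - 6.0 * x10);
}

// all non-bonded (iso + hard core) and patch terms between beads i and j
static double bead_pair_energy(const Chain& c, int i, int j, const Model& m) {
  const Par& p = m.par;
  Vec3 d = sub(c.pos[j], c.pos[i]);
  double r = norm(d);
  bool bonded = std::abs(i - j) == 1;
  double e = 0.0;
  if (!bonded) {
    if (r < p.contact) return INF;
    if (r <= p.rmax) e += iso_energy(r, m.eps_ab(c.seq[i], c.seq[j]), p);
  }
  // patches: prune if centers too far for any patch pair to be in range
  size_t np = m.patch.size();
  if (np > 0 && r < p.rcut + 2.0 * p.rbead) {
    for (size_t a = 0; a < np; ++a) {
      Vec3 wa = qrot(c.ori[i], m.patch[a]);
      Vec3 pa = { c.pos[i].x + p.rbead * wa.x,
                  c.pos[i].y + p.rbead * wa.y,
                  c.pos[i].z + p.rbead * wa.z };
      for (size_t b = 0; b < np; ++b) {
        Vec3 wb = qrot(c.ori[j], m.patch[b]);
        Vec3 pb = { c.pos[j].x + p.rbead * wb.x,
                    c.pos[j].y + p.rbead * wb.y,
                    c.pos[j].z + p.rbead * wb.z };
        double ep = patch_pair(pa, wa, pb, wb, p);
        if (ep == INF) return INF;
        e += ep;
      }
    }
  }
  return e;
}

// harmonic bond between beads i and i+1
static double bond_pair_energy(const Chain& c, int i, const Model& m) {
  const Par& p = m.par;
  double d;
  if (m.par.model == 0) {
    d = norm(sub(c.pos[i + 1], c.pos[i]));
  } else {
    Vec3 af = qrot(c.ori[i],     m.anchor[0]);
    Vec3 ab = qrot(c.ori[i + 1], m.anchor[1]);
    Vec3 pf = { c.pos[i].x + p.rbead * af.x, c.pos[i].y + p.rbead * af.y,
                c.pos[i].z + p.rbead * af.z };
    Vec3 pb = { c.pos[i+1].x + p.rbead * ab.x, c.pos[i+1].y + p.rbead * ab.y,
                c.pos[i+1].z + p.rbead * ab.z };
    d = norm(sub(pf, pb));
  }
  double dd = d - p.spring_rest;
  return 0.5 * p.spring_k * dd * dd;
}

static double total_energy_terms(const Chain& c, const Model& m,
                                 double& iso, double& dir, double& bond,
                                 bool& violated, bool chain_bonds = true) {
  const Par& p = m.par;
  int N = (int)c.pos.size();
  iso = dir = bond = 0.0;
  violated = false;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      bool bonded = chain_bonds && (j == i + 1);
      Vec3 d = sub(c.pos[j], c.pos[i]);
      double r = norm(d);
      if (!bonded) {
        if (r < p.contact) { violated = true; continue; }
        if (r <= p.rmax) iso += iso_energy(r, m.eps_ab(c.seq[i], c.seq[j]), p);
      }
      size_t np = m.patch.size();
      if (np > 0 && r < p.rcut + 2.0 * p.rbead) {
        for (size_t a = 0; a < np; ++a) {
          Vec3 wa = qrot(c.ori[i], m.patch[a]);
          Vec3 pa = { c.pos[i].x + p.rbead * wa.x, c.pos[i].y + p.rbead * wa.y,
                      c.pos[i].z + p.rbead * wa.z };
          for (size_t b = 0; b < np; ++b) {
            Vec3 wb = qrot(c.ori[j], m.patch[b]);
            Vec3 pb = { c.pos[j].x + p.rbead * wb.x, c.pos[j].y + p.rbead * wb.y,
                        c.pos[j].z + p.rbead * wb.z };
            dir += patch_pair(pa, wa, pb, wb, p);
          }
        }
      }
    }
  }
  if (chain_bonds)
    for (int i = 0; i + 1 < N; ++i) bond += bond_pair_energy(c, i, m);
  return violated ? INF : iso + dir + bond;
}

// energy of all interactions between segment [a..b] and the rest,
// plus the bonds crossing the segment boundary
static double cross_energy(const Chain& c, int a, int b, const Model& m) {
  int N = (int)c.pos.size();
  double e = 0.0;
  for (int i = a; i <= b; ++i) {
    for (int j = 0; j < N; ++j) {
      if (j >= a && j <= b) continue;
      double ep = bead_pair_energy(c, i, j, m);
      if (ep == INF) return INF;
      e += ep;
    }
  }
  if (a > 0)     e += bond_pair_energy(c, a - 1, m);
  if (b < N - 1) e += bond_pair_energy(c, b, m);
  return e;
}

// isotropic interactions of bead i with everything else (for sequence moves)
static double iso_row(const Chain& c, int i, const Model& m, int skip = -1) {
  const Par& p = m.par;
  int N = (int)c.pos.size();
  double e = 0.0;
  for (int j = 0; j < N; ++j) {
    if (j == i || j == skip || std::abs(i - j) == 1) continue;
    double r = norm(sub(c.pos[j], c.pos[i]));
    if (r <= p.rmax) e += iso_energy(r, m.eps_ab(c.seq[i], c.seq[j]), p);
  }
  return e;
}

static Model build_model(const NumericMatrix& patch_axes,
                         const NumericMatrix& anchor_axes,
                         const NumericMatrix& eps, const List& par_list) {
  Model m;
  m.par = read_par(par_list);
  for (int a = 0; a < patch_axes.nrow(); ++a)
    m.patch.push_back({patch_axes(a,0), patch_axes(a,1), patch_axes(a,2)});
  for (int a = 0; a < anchor_axes.nrow(); ++a)
    m.anchor.push_back({anchor_axes(a,0), anchor_axes(a,1), anchor_axes(a,2)});
  m.q = eps.nrow();
  m.eps.resize((size_t)m.q * m.q);
  for (int i = 0; i < m.q; ++i)
    for (int j = 0; j < m.q; ++j)
      m.eps[(size_t)i * m.q + j] = eps(i, j);
  return m;
}

static Chain chain_from_list(const List& st) {
  NumericMatrix pos = st["positions"];
  NumericMatrix ori = st["orientations"];
  IntegerVector seq = st["sequence"];
  Chain c;
  int N = pos.nrow();
  for (int i = 0; i < N; ++i) {
    c.pos.push_back({pos(i,0), pos(i,1), pos(i,2)});
    Quat q = {ori(i,0), ori(i,1), ori(i,2), ori(i,3)};
    qnormalize(q);
    c.ori.push_back(q);
    c.seq.push_back(seq[i]);
  }
  c.E = 0.0; c.walker = 0;
  return c;
}

static List chain_to_list(const Chain& c) {
  int N = (int)c.pos.size();
  NumericMatrix pos(N, 3), ori(N, 4);
  IntegerVector seq(N);
  for (int i = 0; i < N; ++i) {
    pos(i,0) = c.pos[i].x; pos(i,1) = c.pos[i].y; pos(i,2) = c.pos[i].z;
    ori(i,0) = c.ori[i].w; ori(i,1) = c.ori[i].x;
    ori(i,2) = c.ori[i].y; ori(i,3) = c.ori[i].z;
    seq[i] = c.seq[i];
  }
  return List::create(_["positions"] = pos, _["orientations"] = ori,
                      _["sequence"] = seq);
}

// [[Rcpp::export]]
NumericVector cpp_energy_breakdown(List state, NumericMatrix patch_axes,
                                   NumericMatrix anchor_axes,
                                   NumericMatrix eps, List par_list,
                                   bool chain_bonds = true) {
  Model m = build_model(patch_axes, anchor_axes, eps, par_list);
  Chain c = chain_from_list(state);
  double iso, dir, bond; bool viol;
  double tot = total_energy_terms(c, m, iso, dir, bond, viol, chain_bonds);
  return NumericVector::create(_["isotropic"] = iso, _["directional"] = dir,
                               _["bond"] = bond, _["total"] = tot,
                               _["hardcore_violated"] = viol ? 1.0 : 0.0);
}

// [[Rcpp::export]]
double cpp_drmsd(NumericMatrix a, NumericMatrix b) {
  int N = a.nrow();
  double ss = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dxa = a(i,0)-a(j,0), dya = a(i,1)-a(j,1), dza = a(i,2)-a(j,2);
      double dxb = b(i,0)-b(j,0), dyb = b(i,1)-b(j,1), dzb = b(i,2)-b(j,2);
      double da = std::sqrt(dxa*dxa + dya*dya + dza*dza);
      double db = std::sqrt(dxb*dxb + dyb*dyb + dzb*dzb);
      ss += (da - db) * (da - db);
    }
  }
  return std::sqrt(ss) / N;
}

struct MoveStats { long att[6] = {0,0,0,0,0,0}; long acc[6] = {0,0,0,0,0,0}; };

// Move kinds: 0 displacement, 1 rotation, 2 crankshaft, 3 pivot,
//             4 point mutation, 5 pair swap
// [[Rcpp::export]]
List cpp_run_mc(List chains, NumericMatrix patch_axes, NumericMatrix anchor_axes,
                NumericMatrix eps, List par_list, NumericVector temps,
                NumericVector move_weights, NumericVector amps0,
                int n_sweeps, int burnin, int stride, int seed,
                LogicalVector store_slots, int max_store,
                Nullable<NumericMatrix> target_pos_, bool tune,
                int swap_interval) {
  Model m = build_model(patch_axes, anchor_axes, eps, par_list);
  int n_rep = chains.size();
  std::vector<Chain> rep;
  for (int t = 0; t < n_rep; ++t) {
    Chain c = chain_from_list(chains[t]);
    double iso, dir, bond; bool viol;
    c.E = total_energy_terms(c, m, iso, dir, bond, viol);
    if (!std::isfinite(c.E))
      stop("initial configuration violates the hard core");
    c.walker = t;
    rep.push_back(c);
  }
  int N = (int)rep[0].pos.size();
  int q = m.q;

  bool have_target = target_pos_.isNotNull();
  NumericMatrix target_pos;
  if (have_target) target_pos = NumericMatrix(target_pos_);

  // normalise move weights into a cumulative distribution
  std::vector<double> cw(6);
  double wsum = 0.0;
  for (int k = 0; k < 6; ++k) wsum += move_weights[k];
  if (wsum <= 0) stop("at least one move kind must have positive weight");
  double acc_ = 0.0;
  for (int k = 0; k < 6; ++k) { acc_ += move_weights[k] / wsum; cw[k] = acc_; }

  // per-kind amplitudes (displacement, rotation, crankshaft, pivot angles)
  std::vector<double> amp(4);
  for (int k = 0; k < 4; ++k) amp[k] = amps0[k];

  std::vector<std::mt19937_64> rng;
  for (int t = 0; t <= n_rep; ++t) {
    std::mt19937_64 g(0x9E3779B97F4A7C15ULL * (unsigned long long)(seed + 1)
                      + 0x85EBCA77C2B2AE63ULL * (unsigned long long)(t + 1));
    g.discard(16);
    rng.push_back(g);
  }
  std::uniform_real_distribution<double> U(0.0, 1.0);

  MoveStats stats;
  long tune_att[4] = {0,0,0,0}, tune_acc[4] = {0,0,0,0};

  int total_sweeps = burnin + n_sweeps;
  std::vector<int> samp_step, samp_slot, samp_walker;
  std::vector<double> samp_T, samp_E, samp_iso, samp_dir, samp_bond, samp_drmsd;
  std::vector<List> stored;
  std::vector<int> stored_slot, stored_step;

  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    bool measuring = sweep >= burnin;
    for (int t = 0; t < n_rep; ++t) {
      Chain& c = rep[t];
      double T = temps[t];
      std::mt19937_64& g = rng[t];
      for (int mv = 0; mv < N; ++mv) {
        double u = U(g);
        int kind = 0;
        while (kind < 5 && u > cw[kind]) ++kind;
        // degenerate fallbacks for tiny chains
        if (kind == 2 && N < 3) kind = 0;
        if (kind == 5 && N < 2) kind = 4;

        if (kind <= 3) {
          int a, b;                 // moved segment [a..b]
          Chain trial = c;          // copy-modify; N is small
          if (kind == 0) {
            a = b = (int)(U(g) * N); if (a >= N) a = b = N - 1;
            trial.pos[a].x += amp[0] * (2.0 * U(g) - 1.0);
            trial.pos[a].y += amp[0] * (2.0 * U(g) - 1.0);
            trial.pos[a].z += amp[0] * (2.0 * U(g) - 1.0);
          } else if (kind == 1) {
            a = b = (int)(U(g) * N); if (a >= N) a = b = N - 1;
            double z = 2.0 * U(g) - 1.0, phi = 2.0 * M_PI * U(g);
            double rxy = std::sqrt(std::max(0.0, 1.0 - z * z));
            Vec3 ax = {rxy * std::cos(phi), rxy * std::sin(phi), z};
            Quat dq = axis_angle(ax, amp[1] * (2.0 * U(g) - 1.0));
            trial.ori[a] = qmul(dq, trial.ori[a]);
            qnormalize(trial.ori[a]);
          } else if (kind == 2) {
            // crankshaft: rotate interior of [i..j] about the i--j axis
            int i = (int)(U(g) * (N - 2)); if (i > N - 3) i = N - 3;
            int maxlen = std::min(N - 1 - i, 6);
            int j = i + 2 + (int)(U(g) * (maxlen - 1));
            if (j > N - 1) j = N - 1;
            a = i + 1; b = j - 1;
            Vec3 ax = sub(c.pos[j], c.pos[i]);
            double nx = norm(ax);
            if (nx < 1e-12) continue;
            ax.x /= nx; ax.y /= nx; ax.z /= nx;
            Quat dq = axis_angle(ax, amp[2] * (2.0 * U(g) - 1.0));
            for (int k = a; k <= b; ++k) {
              Vec3 rel = sub(c.pos[k], c.pos[i]);
              Vec3 rot = qrot(dq, rel);
              trial.pos[k] = {c.pos[i].x + rot.x, c.pos[i].y + rot.y,
                              c.pos[i].z + rot.z};
              trial.ori[k] = qmul(dq, c.ori[k]);
              qnormalize(trial.ori[k]);
            }
          } else {
            // pivot: rotate the tail beyond bead k rigidly about bead k
            int k0 = (int)(U(g) * (N - 1)); if (k0 > N - 2) k0 = N - 2;
            a = k0 + 1; b = N - 1;
            double z = 2.0 * U(g) - 1.0, phi = 2.0 * M_PI * U(g);
            double rxy = std::sqrt(std::max(0.0, 1.0 - z * z));
            Vec3 ax = {rxy * std::cos(phi), rxy * std::sin(phi), z};
            Quat dq = axis_angle(ax, amp[3] * (2.0 * U(g) - 1.0));
            for (int k = a; k <= b; ++k) {
              Vec3 rel = sub(c.pos[k], c.pos[k0]);
              Vec3 rot = qrot(dq, rel);
              trial.pos[k] = {c.pos[k0].x + rot.x, c.pos[k0].y + rot.y,
                              c.pos[k0].z + rot.z};
              trial.ori[k] = qmul(dq, c.ori[k]);
              qnormalize(trial.ori[k]);
            }
          }
          stats.att[kind]++;
          if (!measuring) tune_att[kind]++;
          double e_old = cross_energy(c, a, b, m);
          double e_new = cross_energy(trial, a, b, m);
          bool ok = false;
          if (std::isfinite(e_new)) {
            double dE = e_new - e_old;
            ok = dE <= 0.0 || U(g) < std::exp(-dE / T);
            if (ok) { trial.E = c.E + dE; c = trial; }
          }
          if (ok) { stats.acc[kind]++; if (!measuring) tune_acc[kind]++; }
        } else if (kind == 4) {
          if (q < 2) continue;
          int i = (int)(U(g) * N); if (i >= N) i = N - 1;
          int nt = (int)(U(g) * (q - 1)); if (nt >= q - 1) nt = q - 2;
          if (nt >= c.seq[i]) ++nt;
          stats.att[4]++;
          double e_old = iso_row(c, i, m);
          int old = c.seq[i];
          c.seq[i] = nt;
          double e_new = iso_row(c, i, m);
          double dE = e_new - e_old;
          if (dE <= 0.0 || U(g) < std::exp(-dE / T)) {
            c.E += dE; stats.acc[4]++;
          } else {
            c.seq[i] = old;
          }
        } else {
          int i = (int)(U(g) * N); if (i >= N) i = N - 1;
          int j = (int)(U(g) * N); if (j >= N) j = N - 1;
          if (i == j || c.seq[i] == c.seq[j]) continue;
          stats.att[5]++;
          double e_old = iso_row(c, i, m, j) + iso_row(c, j, m);
          std::swap(c.seq[i], c.seq[j]);
          double e_new = iso_row(c, i, m, j) + iso_row(c, j, m);
          double dE = e_new - e_old;
          if (dE <= 0.0 || U(g) < std::exp(-dE / T)) {
            c.E += dE; stats.acc[5]++;
          } else {
            std::swap(c.seq[i], c.seq[j]);
          }
        }
      }
    }

    // amplitude tuning toward ~30% acceptance, burn-in only
    if (tune && !((sweep + 1) % 100) && sweep < burnin) {
      for (int k = 0; k < 4; ++k) {
        if (tune_att[k] < 20) continue;
        double rate = (double)tune_acc[k] / tune_att[k];
        if (rate > 0.35) amp[k] *= 1.15;
        else if (rate < 0.25) amp[k] *= 0.85;
        double hi = (k == 0) ? 2.0 : M_PI;
        if (amp[k] > hi) amp[k] = hi;
        if (amp[k] < 1e-3) amp[k] = 1e-3;
        tune_att[k] = tune_acc[k] = 0;
      }
    }

    // nearest-neighbour replica exchange, alternating parity
    if (n_rep > 1 && !((sweep + 1) % swap_interval)) {
      std::mt19937_64& g = rng[n_rep];
      int par = sweep % 2;
      for (int t = par; t + 1 < n_rep; t += 2) {
        double Ta = temps[t], Tb = temps[t + 1];
        double arg = (1.0 / Ta - 1.0 / Tb) * (rep[t].E - rep[t + 1].E);
        if (arg >= 0.0 || U(g) < std::exp(arg)) {
          std::swap(rep[t], rep[t + 1]);
        }
      }
    }

    // periodic full-energy resync to kill incremental drift
    if (!((sweep + 1) % 500)) {
      for (int t = 0; t < n_rep; ++t) {
        double iso, dir, bond; bool viol;
        rep[t].E = total_energy_terms(rep[t], m, iso, dir, bond, viol);
      }
    }

    if (measuring && !((sweep - burnin + 1) % stride)) {
      for (int t = 0; t < n_rep; ++t) {
        double iso, dir, bond; bool viol;
        double tot = total_energy_terms(rep[t], m, iso, dir, bond, viol);
        rep[t].E = tot;
        samp_step.push_back(sweep + 1);
        samp_slot.push_back(t + 1);
        samp_walker.push_back(rep[t].walker + 1);
        samp_T.push_back(temps[t]);
        samp_E.push_back(tot);
        samp_iso.push_back(iso);
        samp_dir.push_back(dir);
        samp_bond.push_back(bond);
        if (have_target) {
          NumericMatrix pm(N, 3);
          for (int i = 0; i < N; ++i) {
            pm(i,0) = rep[t].pos[i].x; pm(i,1) = rep[t].pos[i].y;
            pm(i,2) = rep[t].pos[i].z;
          }
          samp_drmsd.push_back(cpp_drmsd(pm, target_pos));
        } else {
          samp_drmsd.push_back(NA_REAL);
        }
        if (store_slots[t] && (int)stored.size() < max_store * n_rep) {
          stored.push_back(chain_to_list(rep[t]));
          stored_slot.push_back(t + 1);
          stored_step.push_back(sweep + 1);
        }
      }
    }
    if (!((sweep + 1) % 2000)) Rcpp::checkUserInterrupt();
  }

  List final_chains(n_rep);
  for (int t = 0; t < n_rep; ++t) final_chains[t] = chain_to_list(rep[t]);

  DataFrame samples = DataFrame::create(
    _["step"] = samp_step, _["slot"] = samp_slot, _["walker"] = samp_walker,
    _["temperature"] = samp_T, _["energy"] = samp_E,
    _["isotropic"] = samp_iso, _["directional"] = samp_dir,
    _["bond"] = samp_bond, _["drmsd"] = samp_drmsd);

  NumericVector att(6), accv(6);
  for (int k = 0; k < 6; ++k) { att[k] = (double)stats.att[k]; accv[k] = (double)stats.acc[k]; }

  return List::create(
    _["samples"] = samples,
    _["states"] = stored,
    _["state_slot"] = stored_slot,
    _["state_step"] = stored_step,
    _["final"] = final_chains,
    _["attempts"] = att,
    _["accepts"] = accv,
    _["amplitudes"] = NumericVector(amp.begin(), amp.end()));
}
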