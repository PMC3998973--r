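// Event-driven discrete molecular dynamics core.
//
// Between events every bead flies ballistically; events are boundary
// crossings of stepwise pair potentials (hard walls, square-well steps,
// hydrogen-bond window edges), Andersen-thermostat ghost collisions, frame
// saves and neighbour-list rebuilds. Pair events are resolved with exact
// momentum and energy conservation: a crossing is allowed iff the radial
// kinetic energy 0.5*mu*vr^2 exceeds the energy step, otherwise the pair
// reflects elastically. Hydrogen-bond rules are multi-body: the well between
// C(i) and N(i+4) counts only while all of the rule's gating distance
// windows (span, chirality and per-torsion gates) hold; the rule state is
// purely geometric and can only change at a boundary event of one of its
// member pairs, where the summed energy step of every affected rule is
// applied to the crossing pair -- so E_kin + E_pot is conserved exactly
// between ghosts.
//
// Beads carry individual ("lagged") times; positions are synchronised only
// at saves, rebuilds and segment end. The event queue uses lazy deletion via
// per-bead collision counters. A Verlet neighbour list with skin `skin`
// restricts plain nonbonded pair scheduling; the rebuild interval is
// skin/(2*vmax) and any velocity exceeding vmax forces an immediate rebuild,
// so no pair can cross undetected.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <random>
using namespace Rcpp;

enum { B_WALL_LO = 0, B_WALL_HI = 1, B_STEP = 2, B_HB_LO = 3, B_HB_HI = 4 };

static const double NUDGE = 1e-9;   // relative off-boundary nudge
static const double TIME_FUZZ = 1e-12;

struct Bound { double r, r2, du_in; int type, rstart, rcount; };

struct SPair {
  int i, j;        // bead ids (0-based); j == -1 for tethers
  int b0, nb;      // boundary slice
  int tether;      // anchor row or -1
};

struct Ev {
  double t;
  int sp;          // static pair index, or -1 for a plain nonbonded pair
  int i, j, bidx;  // beads and boundary index
  uint32_t ci, cj;
};
struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const { return a.t > b.t; }
};

// Portable deterministic RNG: mt19937_64 + explicit Box-Muller.
struct EngRNG {
  std::mt19937_64 g;
  bool has_spare = false;
  double spare = 0.0;
  explicit EngRNG(uint64_t s) : g(s) {}
  double unif() { return ((g() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
};

// packed Verlet neighbour entry (pair parameters resolved at rebuild)
struct VN { int j; double sig2, wr2, wdep; };

struct Engine {
  int n;
  std::vector<double> x, v, tb, mass;
  std::vector<uint32_t> cnt;
  // force field (raw column-major n x n arrays)
  const double *Psig, *Pwr, *Pwd;
  const int *Pcls;             // 0 excluded, 1 plain NB, 2 static-handled
  std::vector<SPair> sp;
  std::vector<Bound> bounds;
  std::vector<std::vector<int> > sadj;       // bead -> static pair ids
  std::vector<std::vector<VN> > vadj;        // bead -> packed NB partners
  NumericMatrix anchors;
  // HB rules: flat member lists (static-pair ids + windows), and the rule
  // ids attached to each window edge
  std::vector<int> mstart, mcount, mem_sp, edge_rules;
  std::vector<double> mem_lo, mem_hi, rdepth;
  // run state
  double tnow = 0.0, epot = 0.0, horizon = 0.0, vmax = 0.0, skin = 0.8;
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> heap;
  EngRNG rng;
  long long nevents = 0, nghosts = 0, npred = 0, npush = 0, nrebuild = 0;

  Engine(uint64_t seed, const NumericMatrix& sig_, const NumericMatrix& wr_,
         const NumericMatrix& wd_, const IntegerMatrix& cls_,
         NumericMatrix anchors_)
    : Psig(sig_.begin()), Pwr(wr_.begin()), Pwd(wd_.begin()),
      Pcls(cls_.begin()), anchors(anchors_), rng(seed) {}

  double sig(int i, int j) const { return Psig[i + (R_xlen_t)n * j]; }
  double wrr(int i, int j) const { return Pwr[i + (R_xlen_t)n * j]; }
  double wdd(int i, int j) const { return Pwd[i + (R_xlen_t)n * j]; }
  int clsv(int i, int j) const { return Pcls[i + (R_xlen_t)n * j]; }

  void advance(int i, double t) {
    double dt = t - tb[i];
    x[3 * i] += v[3 * i] * dt;
    x[3 * i + 1] += v[3 * i + 1] * dt;
    x[3 * i + 2] += v[3 * i + 2] * dt;
    tb[i] = t;
  }
  void advance_all(double t) { for (int i = 0; i < n; ++i) advance(i, t); }

  double speed(int i) const {
    return std::sqrt(v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                     v[3 * i + 2] * v[3 * i + 2]);
  }

  // relative separation/velocity of a pair at time t (j == -1: anchor row a)
  void rel(int i, int j, int tether, double t, double dr[3], double dv[3]) const {
    double xi[3], xj[3];
    for (int c = 0; c < 3; ++c)
      xi[c] = x[3 * i + c] + v[3 * i + c] * (t - tb[i]);
    if (j >= 0) {
      for (int c = 0; c < 3; ++c) {
        xj[c] = x[3 * j + c] + v[3 * j + c] * (t - tb[j]);
        dv[c] = v[3 * j + c] - v[3 * i + c];
      }
    } else {
      for (int c = 0; c < 3; ++c) {
        xj[c] = anchors(tether, c);
        dv[c] = -v[3 * i + c];
      }
    }
    for (int c = 0; c < 3; ++c) dr[c] = xj[c] - xi[c];
  }

  // earliest positive crossing among boundaries (radii ascending) -- returns
  // time from `t` and boundary index, or false
  bool cross_time(const double dr[3], const double dv[3],
                  const double* r2s, int nb, double& tev, int& bidx) const {
    double r2 = dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2];
    double v2 = dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2];
    if (v2 <= 0.0) return false;
    double b = dr[0] * dv[0] + dr[1] * dv[1] + dr[2] * dv[2];
    int inner = -1, outer = -1;
    for (int k = 0; k < nb; ++k) {
      if (r2s[k] < r2) inner = k; else { outer = k; break; }
    }
    double t_in = R_PosInf, t_out = R_PosInf;
    if (inner >= 0 && b < 0.0) {
      double disc = b * b - v2 * (r2 - r2s[inner]);
      if (disc > 0.0) t_in = (-b - std::sqrt(disc)) / v2;
    }
    if (outer >= 0)
      t_out = (-b + std::sqrt(b * b + v2 * (r2s[outer] - r2))) / v2;
    if (!R_FINITE(t_in) && !R_FINITE(t_out)) return false;
    if (t_in <= t_out) { tev = t_in; bidx = inner; }
    else { tev = t_out; bidx = outer; }
    if (tev < 0.0) tev = 0.0;
    return true;
  }

  // A pair can end up marginally on the illegal side of a hard wall when a
  // same-instant event on a shared bead nudges it across; schedule an
  // immediate (or closest-approach) recovery event so it is recaptured.
  // Returns true when a recovery event was scheduled.
  bool escape_recovery(int s, const SPair& p, const double dr[3],
                       const double dv[3], double r2, double b, double v2) {
    const Bound& lo = bounds[p.b0];
    const Bound& hi = bounds[p.b0 + p.nb - 1];
    double tev = -1.0;
    int bidx = -1;
    if (lo.type == B_WALL_LO && r2 < lo.r2 && b <= 0.0) {
      tev = 0.0; bidx = 0;                     // below a core, going deeper
    } else if (hi.type == B_WALL_HI && r2 > hi.r2) {
      if (b >= 0.0) { tev = 0.0; bidx = p.nb - 1; }   // receding outside
      else {
        double disc = b * b - v2 * (r2 - hi.r2);
        if (disc <= 0.0 && v2 > 0.0) {         // grazing miss outside
          tev = -b / v2; bidx = p.nb - 1;
        }
      }
    }
    if (bidx < 0) return false;
    Ev e; e.t = tnow + tev; e.sp = s; e.i = p.i; e.j = p.j; e.bidx = bidx;
    e.ci = cnt[p.i]; e.cj = (p.j >= 0) ? cnt[p.j] : 0u;
    heap.push(e);
    ++npush;
    return true;
  }

  void schedule_static(int s) {
    const SPair& p = sp[s];
    double dr[3], dv[3];
    rel(p.i, p.j, p.tether, tnow, dr, dv);
    double r2s[8];
    for (int k = 0; k < p.nb; ++k) r2s[k] = bounds[p.b0 + k].r2;
    double tev; int bidx;
    ++npred;
    {
      double r2 = dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2];
      double v2 = dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2];
      double b = dr[0] * dv[0] + dr[1] * dv[1] + dr[2] * dv[2];
      if (escape_recovery(s, p, dr, dv, r2, b, v2)) return;
    }
    if (!cross_time(dr, dv, r2s, p.nb, tev, bidx)) return;
    double tabs = tnow + tev;
    if (tabs > horizon + TIME_FUZZ) return;
    Ev e; e.t = tabs; e.sp = s; e.i = p.i; e.j = p.j; e.bidx = bidx;
    e.ci = cnt[p.i]; e.cj = (p.j >= 0) ? cnt[p.j] : 0u;
    heap.push(e);
    ++npush;
  }

  void schedule_nb(int i, int j, double sig2, double wr2) {
    double r2s[2]; int nb = 0;
    if (sig2 > 0) { r2s[nb++] = sig2; }
    if (wr2 > 0) { r2s[nb++] = wr2; }
    if (nb == 0) return;
    double dr[3], dv[3];
    rel(i, j, -1, tnow, dr, dv);  // j >= 0 here
    double tev; int bidx;
    ++npred;
    if (sig2 > 0) {
      double r2 = dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2];
      double b = dr[0] * dv[0] + dr[1] * dv[1] + dr[2] * dv[2];
      if (r2 < sig2 && b <= 0.0) {   // nudged inside a core, going deeper
        Ev e; e.t = tnow; e.sp = -1; e.i = i; e.j = j; e.bidx = 0;
        e.ci = cnt[i]; e.cj = cnt[j];
        heap.push(e);
        ++npush;
        return;
      }
    }
    if (!cross_time(dr, dv, r2s, nb, tev, bidx)) return;
    double tabs = tnow + tev;
    if (tabs > horizon + TIME_FUZZ) return;
    Ev e; e.t = tabs; e.sp = -1; e.i = i; e.j = j;
    e.bidx = (sig2 > 0) ? bidx : bidx + 1;  // 0 = core, 1 = well
    e.ci = cnt[i]; e.cj = cnt[j];
    heap.push(e);
    ++npush;
  }

  void reschedule_bead(int a, int skip = -1, int skip_sp = -1) {
    for (size_t k = 0; k < sadj[a].size(); ++k)
      if (sadj[a][k] != skip_sp) schedule_static(sadj[a][k]);
    for (size_t k = 0; k < vadj[a].size(); ++k) {
      const VN& vn = vadj[a][k];
      if (vn.j == skip) continue;
      schedule_nb(std::min(a, vn.j), std::max(a, vn.j), vn.sig2, vn.wr2);
    }
  }

  // true iff all member pairs of `rule` other than `me` sit inside their
  // windows
  bool others_in(int rule, int me, double t) const {
    for (int m = mstart[rule]; m < mstart[rule] + mcount[rule]; ++m) {
      int s = mem_sp[m];
      if (s == me) continue;
      const SPair& p = sp[s];
      double dr[3], dv[3];
      rel(p.i, p.j, p.tether, t, dr, dv);
      double d = std::sqrt(dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2]);
      if (d < mem_lo[m] || d >= mem_hi[m]) return false;
    }
    return true;
  }

  void rebuild(double t, double t_end) {
    advance_all(t);
    tnow = t;
    vmax = 0.0;
    for (int i = 0; i < n; ++i) vmax = std::max(vmax, speed(i));
    double dt = (vmax > 0) ? skin / (2.0 * vmax) : (t_end - t) + 1.0;
    horizon = t + std::max(dt, 1e-6);
    ++nrebuild;
    for (int i = 0; i < n; ++i) vadj[i].clear();
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (clsv(i, j) != 1) continue;
        double s = sig(i, j), w = wrr(i, j);
        double rout = std::max(s, w);
        if (rout <= 0) continue;
        double dx = x[3 * j] - x[3 * i];
        double dy = x[3 * j + 1] - x[3 * i + 1];
        double dz = x[3 * j + 2] - x[3 * i + 2];
        double lim = rout + skin;
        if (dx * dx + dy * dy + dz * dz < lim * lim) {
          VN vn; vn.j = j; vn.sig2 = s * s; vn.wr2 = (w > 0) ? w * w : 0.0;
          vn.wdep = wdd(i, j);
          vadj[i].push_back(vn);
          VN vm = vn; vm.j = i;
          vadj[j].push_back(vm);
        }
      }
    }
    // clear the heap and schedule everything inside the new horizon
    std::priority_queue<Ev, std::vector<Ev>, EvCmp> empty;
    heap.swap(empty);
    for (size_t s = 0; s < sp.size(); ++s) schedule_static((int)s);
    for (int i = 0; i < n; ++i) {
      for (size_t k = 0; k < vadj[i].size(); ++k) {
        int j = vadj[i][k].j;
        if (j > i) schedule_nb(i, j, vadj[i][k].sig2, vadj[i][k].wr2);
      }
    }
  }

  void bump(int a) {
    ++cnt[a];
    double s = speed(a);
    if (s > vmax) horizon = tnow;  // force rebuild before further motion
  }

  double ekin() const {
    double e = 0;
    for (int i = 0; i < n; ++i) {
      e += 0.5 * mass[i] * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                            v[3 * i + 2] * v[3 * i + 2]);
    }
    return e;
  }

  // full from-scratch potential energy; stops with an error on invalid states
  double energy_scratch(const IntegerVector& bnd_i, const IntegerVector& bnd_j,
                        const NumericVector& bnd_lo, const NumericVector& bnd_hi) {
    double e = 0.0;
    for (int k = 0; k < bnd_i.size(); ++k) {
      int i = bnd_i[k], j = bnd_j[k];
      double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
             dz = x[3 * j + 2] - x[3 * i + 2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < bnd_lo[k] - 1e-7 || d > bnd_hi[k] + 1e-7)
        stop("bond window violated for beads %d-%d (d = %g)", i + 1, j + 1, d);
    }
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        int c = clsv(i, j);
        if (c == 0) continue;
        double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
               dz = x[3 * j + 2] - x[3 * i + 2];
        double d2 = dx * dx + dy * dy + dz * dz;
        double s = sig(i, j);
        if (s > 0 && d2 < s * s * (1 - 1e-12))
          stop("hard-core overlap between beads %d and %d", i + 1, j + 1);
        if (c == 1) {
          double w = wrr(i, j);
          if (w > 0 && d2 < w * w) e -= wdd(i, j);
        }
      }
    }
    for (size_t s2 = 0; s2 < sp.size(); ++s2) {
      const SPair& p = sp[s2];
      double dr[3], dv[3];
      rel(p.i, p.j, p.tether, tnow, dr, dv);
      double d2 = dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2];
      for (int k = 0; k < p.nb; ++k) {
        const Bound& bd = bounds[p.b0 + k];
        if (bd.r2 > d2) e += bd.du_in;
      }
    }
    for (size_t r = 0; r < rdepth.size(); ++r) {
      bool act = true;
      for (int m = mstart[r]; m < mstart[r] + mcount[r] && act; ++m) {
        const SPair& p = sp[mem_sp[m]];
        double dr[3], dv[3];
        rel(p.i, p.j, p.tether, tnow, dr, dv);
        double d = std::sqrt(dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2]);
        if (d < mem_lo[m] || d >= mem_hi[m]) act = false;
      }
      if (act) e -= rdepth[r];
    }
    return e;
  }

  void execute(const Ev& e) {
    int i = e.i, j = e.j;
    const SPair* p = (e.sp >= 0) ? &sp[e.sp] : 0;
    int tether = p ? p->tether : -1;
    advance(i, e.t);
    if (j >= 0) advance(j, e.t);
    tnow = e.t;

    double dr[3], dv[3];
    rel(i, j, tether, tnow, dr, dv);
    double r = std::sqrt(dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2]);
    if (r <= 0) stop("coincident beads at event");
    double rhat[3] = { dr[0] / r, dr[1] / r, dr[2] / r };
    double b = dr[0] * dv[0] + dr[1] * dv[1] + dr[2] * dv[2];
    bool inward = b < 0.0;

    int type; double rb, du = 0.0;
    if (p) {
      const Bound& bd = bounds[p->b0 + e.bidx];
      type = bd.type; rb = bd.r;
      if (type == B_STEP) du = inward ? bd.du_in : -bd.du_in;
      else if (type == B_HB_LO || type == B_HB_HI) {
        // the crossing pair leaves (or enters) this window; every attached
        // rule whose other members are satisfied steps by +/- its depth
        bool mem_before = inward ? (type == B_HB_LO) : (type == B_HB_HI);
        double sum = 0.0;
        for (int k = bd.rstart; k < bd.rstart + bd.rcount; ++k) {
          int rule = edge_rules[k];
          if (others_in(rule, e.sp, tnow)) sum += rdepth[rule];
        }
        // conditional rule part plus the pair's unconditional window well
        du = (mem_before ? sum : -sum) + (inward ? bd.du_in : -bd.du_in);
      }
    } else {
      if (e.bidx == 0) { type = B_WALL_LO; rb = sig(i, j); }
      else { type = B_STEP; rb = wrr(i, j); du = -wdd(i, j); du = inward ? du : -du; }
    }

    double mi = mass[i];
    double inv_mj = (j >= 0) ? 1.0 / mass[j] : 0.0;
    double mu = 1.0 / (1.0 / mi + inv_mj);
    double vr = b / r;
    double vr_new;
    bool crossed;
    if (type == B_WALL_LO || type == B_WALL_HI) {
      // crossing towards the legal side (an escape recovery) passes freely;
      // crossing away from it reflects
      bool recovery = (type == B_WALL_LO && !inward) ||
                      (type == B_WALL_HI && inward);
      if (recovery) { vr_new = vr; crossed = true; }
      else { vr_new = -vr; crossed = false; }
    } else if (0.5 * mu * vr * vr > du) {
      double s = (vr >= 0) ? 1.0 : -1.0;
      vr_new = s * std::sqrt(vr * vr - 2.0 * du / mu);
      crossed = true;
      epot += du;
    } else {
      vr_new = -vr; crossed = false;
    }
    double dvr = vr_new - vr;
    for (int c = 0; c < 3; ++c) v[3 * i + c] -= (mu / mi) * dvr * rhat[c];
    if (j >= 0)
      for (int c = 0; c < 3; ++c) v[3 * j + c] += mu * inv_mj * dvr * rhat[c];

    // place the pair just off the boundary on the correct side
    bool below_after = crossed ? inward : !inward;
    double rt = rb * (below_after ? (1.0 - NUDGE) : (1.0 + NUDGE));
    double delta = rt - r;
    for (int c = 0; c < 3; ++c) x[3 * i + c] -= (mu / mi) * delta * rhat[c];
    if (j >= 0)
      for (int c = 0; c < 3; ++c) x[3 * j + c] += mu * inv_mj * delta * rhat[c];

    bump(i);
    if (j >= 0) bump(j);
    reschedule_bead(i);
    if (j >= 0) reschedule_bead(j, i, e.sp);
    ++nevents;
  }
};

// [[Rcpp::export(name = ".dmd_run_cpp")]]
List dmd_run_cpp(NumericMatrix x0, NumericMatrix v0, NumericVector mass,
                 IntegerMatrix cls, NumericMatrix sig, NumericMatrix wr,
                 NumericMatrix wd,
                 IntegerVector sp_i, IntegerVector sp_j,
                 IntegerVector sp_tether,
                 IntegerVector sp_b0, IntegerVector sp_nb,
                 NumericVector b_r, IntegerVector b_type, NumericVector b_du,
                 IntegerVector b_rstart, IntegerVector b_rcount,
                 IntegerVector edge_rules,
                 NumericVector r_depth,
                 IntegerVector r_mstart, IntegerVector r_mcount,
                 IntegerVector mem_sp, NumericVector mem_lo,
                 NumericVector mem_hi,
                 NumericMatrix anchors,
                 IntegerVector bnd_i, IntegerVector bnd_j,
                 NumericVector bnd_lo, NumericVector bnd_hi,
                 double temperature, double hex,
                 double t_start, double duration, double save_every,
                 double seed, bool init_velocities, double skin,
                 double max_events) {
  int n = x0.nrow();
  Engine eng((uint64_t)seed, sig, wr, wd, cls, anchors);
  eng.n = n;
  eng.x.resize(3 * n); eng.v.resize(3 * n);
  eng.tb.assign(n, t_start);
  eng.mass.assign(mass.begin(), mass.end());
  eng.cnt.assign(n, 0u);
  eng.skin = skin;
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      eng.x[3 * i + c] = x0(i, c);
      eng.v[3 * i + c] = v0(i, c);
    }
  if (init_velocities) {
    double sd;
    for (int i = 0; i < n; ++i) {
      sd = std::sqrt(temperature / mass[i]);
      for (int c = 0; c < 3; ++c) eng.v[3 * i + c] = sd * eng.rng.norm();
    }
  }
  // static pairs and boundaries
  int ns = sp_i.size();
  eng.sp.resize(ns);
  for (int s = 0; s < ns; ++s) {
    SPair& p = eng.sp[s];
    p.i = sp_i[s]; p.j = sp_j[s]; p.tether = sp_tether[s];
    p.b0 = sp_b0[s]; p.nb = sp_nb[s];
    if (p.nb > 8) stop("too many boundaries on one pair");
  }
  eng.bounds.resize(b_r.size());
  for (int k = 0; k < b_r.size(); ++k) {
    Bound& bd = eng.bounds[k];
    bd.r = b_r[k]; bd.r2 = b_r[k] * b_r[k];
    bd.type = b_type[k]; bd.du_in = b_du[k];
    bd.rstart = b_rstart[k]; bd.rcount = b_rcount[k];
  }
  eng.rdepth.assign(r_depth.begin(), r_depth.end());
  eng.mstart.assign(r_mstart.begin(), r_mstart.end());
  eng.mcount.assign(r_mcount.begin(), r_mcount.end());
  eng.mem_sp.assign(mem_sp.begin(), mem_sp.end());
  eng.mem_lo.assign(mem_lo.begin(), mem_lo.end());
  eng.mem_hi.assign(mem_hi.begin(), mem_hi.end());
  eng.edge_rules.assign(edge_rules.begin(), edge_rules.end());
  eng.sadj.assign(n, std::vector<int>());
  for (int s = 0; s < ns; ++s) {
    eng.sadj[eng.sp[s].i].push_back(s);
    if (eng.sp[s].j >= 0) eng.sadj[eng.sp[s].j].push_back(s);
  }
  eng.vadj.assign(n, std::vector<VN>());

  eng.tnow = t_start;
  double t_end = t_start + duration;
  eng.epot = eng.energy_scratch(bnd_i, bnd_j, bnd_lo, bnd_hi);
  eng.rebuild(t_start, t_end);

  // frame schedule: global multiples of save_every strictly after t_start
  long long k0 = (long long)std::floor(t_start / save_every + 1e-9) + 1;
  long long kmax = (long long)std::floor(t_end / save_every + 1e-9);
  int nf = (int)std::max(0LL, kmax - k0 + 1);
  NumericVector frames(R_xlen_t(n) * 3 * nf);
  NumericVector frame_t(nf), frame_E(nf), frame_K(nf);
  int fidx = 0;
  double next_save = (nf > 0) ? k0 * save_every : R_PosInf;

  double next_ghost = (hex > 0) ? t_start + eng.rng.expo(hex * n) : R_PosInf;

  while (true) {
    double t_heap = eng.heap.empty() ? R_PosInf : eng.heap.top().t;
    // next action = smallest time; ties resolved towards the later checks
    // (pair events win ties, which is safe: zero time elapses)
    double tm = t_end;
    int act = 0;  // 0 finish, 1 rebuild, 2 save, 3 ghost, 4 pair event
    if (eng.horizon < tm) { tm = eng.horizon; act = 1; }
    if (next_save <= tm) { tm = next_save; act = 2; }
    if (next_ghost <= tm) { tm = next_ghost; act = 3; }
    if (t_heap <= tm) { tm = t_heap; act = 4; }
    if (act == 0) {
      eng.advance_all(t_end);
      eng.tnow = t_end;
      break;
    } else if (act == 1) {
      eng.rebuild(eng.horizon, t_end);
    } else if (act == 2) {
      eng.advance_all(next_save);
      eng.tnow = next_save;
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          frames[R_xlen_t(i) + R_xlen_t(n) * (c + 3 * R_xlen_t(fidx))] =
            eng.x[3 * i + c];
      frame_t[fidx] = next_save;
      frame_E[fidx] = eng.epot;
      frame_K[fidx] = eng.ekin();
      ++fidx;
      next_save = (fidx < nf) ? (k0 + fidx) * save_every : R_PosInf;
    } else if (act == 3) {
      eng.tnow = next_ghost;
      int k = (int)(eng.rng.unif() * n);
      if (k >= n) k = n - 1;
      eng.advance(k, next_ghost);
      double sd = std::sqrt(temperature / eng.mass[k]);
      for (int c = 0; c < 3; ++c) eng.v[3 * k + c] = sd * eng.rng.norm();
      eng.bump(k);
      eng.reschedule_bead(k);
      ++eng.nghosts;
      next_ghost = next_ghost + eng.rng.expo(hex * n);
    } else {
      Ev e = eng.heap.top();
      eng.heap.pop();
      if (e.ci != eng.cnt[e.i]) continue;
      if (e.j >= 0 && e.cj != eng.cnt[e.j]) continue;
      eng.execute(e);
      if (eng.nevents > (long long)max_events)
        stop("event budget exceeded (%g events)", max_events);
      if ((eng.nevents & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      xf(i, c) = eng.x[3 * i + c];
      vf(i, c) = eng.v[3 * i + c];
    }
  frames.attr("dim") = IntegerVector::create(n, 3, nf);
  return List::create(_["frames"] = frames, _["frame_t"] = frame_t,
                      _["frame_E"] = frame_E, _["frame_K"] = frame_K,
                      _["x"] = xf, _["v"] = vf, _["epot"] = eng.epot,
                      _["ekin"] = eng.ekin(),
                      _["n_events"] = (double)eng.nevents,
                      _["n_ghosts"] = (double)eng.nghosts,
                      _["n_pred"] = (double)eng.npred,
                      _["n_push"] = (double)eng.npush,
                      _["n_rebuild"] = (double)eng.nrebuild,
                      _["time"] = eng.tnow);
}
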