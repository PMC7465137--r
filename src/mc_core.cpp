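// Coarse-grained bead-chain Monte Carlo core.
//
// One bead per residue, charged or neutral; harmonic bonds; hard-sphere
// excluded volume; screened Coulomb (extended Debye-Hueckel) electrostatics
// between all charged particles (chain beads + explicit counter-ions) under
// the minimum-image convention; harmonic disulfide restraints.
//
// Energies are in units of kT at the reference temperature (298 K); the
// Metropolis criterion scales dE by beta_rel = 298 / T.
//
// All randomness draws from R's RNG stream (RNGScope), so R-level
// set.seed() gives bitwise reproducibility.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static inline double mi(double d, double L) {
  // minimum-image component
  return d - L * std::round(d / L);
}

static inline double dist_mi(const double* a, const double* b, double L) {
  double dx = mi(a[0] - b[0], L);
  double dy = mi(a[1] - b[1], L);
  double dz = mi(a[2] - b[2], L);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

struct Model {
  double a;        // bead radius (all particles)
  double r0;       // equilibrium bond length
  double kbond;    // bond spring constant, kT/A^2
  double lB;       // Bjerrum length
  double lD;       // Debye screening length (may be +Inf)
  double L;        // cubic box edge
  bool   ev;       // hard-sphere excluded volume on/off
  bool   bonds_on; // harmonic bonds on/off (off = free beads, used in tests)
};

// screened-Coulomb pair energy in kT units; sigma = contact distance 2a
static inline double u_elec(double r, double zi, double zj, const Model& M) {
  if (zi == 0.0 || zj == 0.0) return 0.0;
  double sigma = 2.0 * M.a;
  double screen;
  if (!std::isfinite(M.lD)) {
    screen = 1.0;
  } else if (M.lD <= 0.0) {
    return 0.0;
  } else {
    screen = std::exp(-(r - sigma) / M.lD) / (1.0 + sigma / (2.0 * M.lD));
  }
  return zi * zj * M.lB / r * screen;
}

// State: chain beads first (n), then counter-ions (m). Chain coordinates are
// kept continuous (not wrapped) so internal geometry is trivially correct;
// ions are wrapped. All pair energies use minimum image, so the two
// conventions are energetically equivalent.
struct System {
  int n;                       // chain beads
  int m;                       // counter-ions
  std::vector<double> x;       // 3*(n+m), xyz per particle
  std::vector<double> z;       // charges, n+m
  std::vector<int> ri, rj;     // restraint pairs (0-based, chain)
  std::vector<double> rr0, rk; // restraint target, spring constant
  Model M;
};

static const double INF = std::numeric_limits<double>::infinity();

// Energy of all interactions involving at least one particle in the moved
// set (listed in `moved`, flagged in `mask`); pairs with both ends moved are
// counted once. Cost O(|moved| * N). With every particle masked this is the
// full system energy. On a hard-sphere overlap the excluded-volume term is
// set to +Inf and the scan stops early (the caller rejects regardless).
static void energy_partial(const System& S, const std::vector<int>& moved,
                           const std::vector<char>& mask,
                           double& e_bond, double& e_ev, double& e_el,
                           double& e_rs, bool early_exit = true) {
  e_bond = 0.0; e_ev = 0.0; e_el = 0.0; e_rs = 0.0;
  int N = S.n + S.m;
  double sigma = 2.0 * S.M.a;
  double sigma2 = sigma * sigma;
  for (size_t mi_ = 0; mi_ < moved.size(); ++mi_) {
    int i = moved[mi_];
    const double* xi = &S.x[3 * i];
    // bonds touching i (count (i, i+1) from i; (i-1, i) only if i-1 unmoved)
    if (S.M.bonds_on && i < S.n) {
      if (i + 1 < S.n) {
        double r = dist_mi(xi, &S.x[3 * (i + 1)], S.M.L);
        double d = r - S.M.r0;
        e_bond += 0.5 * S.M.kbond * d * d;
      }
      if (i - 1 >= 0 && !mask[i - 1]) {
        double r = dist_mi(xi, &S.x[3 * (i - 1)], S.M.L);
        double d = r - S.M.r0;
        e_bond += 0.5 * S.M.kbond * d * d;
      }
    }
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      if (mask[j] && j < i) continue;  // moved-moved pair counted from min
      double dx = mi(xi[0] - S.x[3 * j], S.M.L);
      double dy = mi(xi[1] - S.x[3 * j + 1], S.M.L);
      double dz = mi(xi[2] - S.x[3 * j + 2], S.M.L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (S.M.ev && r2 < sigma2) {
        e_ev = INF;
        if (early_exit) return;
      }
      if (S.z[i] != 0.0 && S.z[j] != 0.0) {
        e_el += u_elec(std::sqrt(r2), S.z[i], S.z[j], S.M);
      }
    }
  }
  for (size_t k = 0; k < S.ri.size(); ++k) {
    int i = S.ri[k], j = S.rj[k];
    if (!mask[i] && !mask[j]) continue;
    double r = dist_mi(&S.x[3 * i], &S.x[3 * j], S.M.L);
    double d = r - S.rr0[k];
    e_rs += 0.5 * S.rk[k] * d * d;
  }
}

static double energy_total(const System& S, double* parts = nullptr) {
  int N = S.n + S.m;
  std::vector<char> mask(N, 1);
  std::vector<int> moved(N);
  for (int i = 0; i < N; ++i) moved[i] = i;
  double eb, ee, el, er;
  energy_partial(S, moved, mask, eb, ee, el, er, false);
  if (parts) { parts[0] = eb; parts[1] = ee; parts[2] = el; parts[3] = er; }
  return eb + ee + el + er;
}

static System unpack_system(NumericMatrix coords, NumericVector charges,
                            NumericMatrix ions, NumericVector ion_charges,
                            NumericMatrix restraints, List params) {
  System S;
  S.n = coords.nrow();
  S.m = ions.nrow();
  S.x.resize(3 * (S.n + S.m));
  S.z.resize(S.n + S.m);
  for (int i = 0; i < S.n; ++i) {
    S.x[3 * i] = coords(i, 0); S.x[3 * i + 1] = coords(i, 1);
    S.x[3 * i + 2] = coords(i, 2);
    S.z[i] = charges[i];
  }
  for (int i = 0; i < S.m; ++i) {
    int p = S.n + i;
    S.x[3 * p] = ions(i, 0); S.x[3 * p + 1] = ions(i, 1);
    S.x[3 * p + 2] = ions(i, 2);
    S.z[p] = ion_charges[i];
  }
  for (int k = 0; k < restraints.nrow(); ++k) {
    S.ri.push_back((int)restraints(k, 0) - 1);
    S.rj.push_back((int)restraints(k, 1) - 1);
    S.rr0.push_back(restraints(k, 2));
    S.rk.push_back(restraints(k, 3));
  }
  S.M.a = as<double>(params["bead_radius"]);
  S.M.r0 = as<double>(params["bond_length"]);
  S.M.kbond = as<double>(params["bond_k"]);
  S.M.lB = as<double>(params["bjerrum_length"]);
  S.M.lD = as<double>(params["debye_length"]);
  S.M.L = as<double>(params["box_length"]);
  S.M.ev = as<bool>(params["excluded_volume"]);
  S.M.bonds_on = params.containsElementNamed("bonds_on") ?
    as<bool>(params["bonds_on"]) : true;
  return S;
}

// [[Rcpp::export]]
NumericVector cpp_total_energy(NumericMatrix coords, NumericVector charges,
                               NumericMatrix ions, NumericVector ion_charges,
                               NumericMatrix restraints, List params) {
  System S = unpack_system(coords, charges, ions, ion_charges, restraints,
                           params);
  double parts[4];
  double tot = energy_total(S, parts);
  return NumericVector::create(
    _["bond"] = parts[0], _["excluded_volume"] = parts[1],
    _["electrostatic"] = parts[2], _["restraint"] = parts[3],
    _["total"] = tot);
}

// ---- geometry helpers ------------------------------------------------------

static void rand_unit_vector(double* u) {
  // Marsaglia method
  double s = 2.0, a = 0.0, b = 0.0;
  while (s >= 1.0 || s == 0.0) {
    a = 2.0 * unif_rand() - 1.0;
    b = 2.0 * unif_rand() - 1.0;
    s = a * a + b * b;
  }
  double q = 2.0 * std::sqrt(1.0 - s);
  u[0] = a * q; u[1] = b * q; u[2] = 1.0 - 2.0 * s;
}

static void rotation_matrix(const double* axis, double theta, double R[3][3]) {
  double c = std::cos(theta), s = std::sin(theta), t = 1.0 - c;
  double x = axis[0], y = axis[1], z = axis[2];
  R[0][0] = t * x * x + c;     R[0][1] = t * x * y - s * z; R[0][2] = t * x * z + s * y;
  R[1][0] = t * x * y + s * z; R[1][1] = t * y * y + c;     R[1][2] = t * y * z - s * x;
  R[2][0] = t * x * z - s * y; R[2][1] = t * y * z + s * x; R[2][2] = t * z * z + c;
}

static void rotate_about(double* p, const double* origin, const double R[3][3]) {
  double v[3] = { p[0] - origin[0], p[1] - origin[1], p[2] - origin[2] };
  for (int k = 0; k < 3; ++k) {
    p[k] = origin[k] + R[k][0] * v[0] + R[k][1] * v[1] + R[k][2] * v[2];
  }
}

// ---- self-avoiding walk by pivot moves -------------------------------------

// advance a pivot walk by n_accepts accepted moves (hard-sphere acceptance)
static void pivot_advance(std::vector<double>& x, int n, double d2min,
                          int n_accepts) {
  std::vector<double> trial;
  int accepted = 0;
  while (accepted < n_accepts) {
    int p = 1 + (int)(unif_rand() * (n - 2));  // pivot bead, 1..n-2
    if (p >= n - 1) p = n - 2;
    double axis[3], R[3][3];
    rand_unit_vector(axis);
    double theta = (2.0 * unif_rand() - 1.0) * M_PI;
    rotation_matrix(axis, theta, R);
    trial = x;
    for (int i = p + 1; i < n; ++i) rotate_about(&trial[3 * i], &trial[3 * p], R);
    // overlap check: moved tail vs fixed head (tail-internal distances are
    // rotation-invariant)
    bool ok = true;
    for (int i = p + 1; i < n && ok; ++i) {
      for (int j = 0; j <= p; ++j) {
        if (i - j == 1) continue;  // bonded neighbours touch by construction
        double dx = trial[3 * i] - trial[3 * j];
        double dy = trial[3 * i + 1] - trial[3 * j + 1];
        double dz = trial[3 * i + 2] - trial[3 * j + 2];
        if (dx * dx + dy * dy + dz * dz < d2min) { ok = false; break; }
      }
    }
    if (ok) { x = trial; ++accepted; }
  }
}

static NumericMatrix as_matrix(const std::vector<double>& x, int n) {
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[3 * i]; out(i, 1) = x[3 * i + 1]; out(i, 2) = x[3 * i + 2];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_saw_chain(int n, double b, double radius, int n_accepts) {
  // rod start, random pivot rotations, hard-sphere acceptance; returns the
  // configuration after n_accepts accepted pivots.
  std::vector<double> x(3 * n, 0.0);
  for (int i = 0; i < n; ++i) x[3 * i + 2] = b * i;
  pivot_advance(x, n, 4.0 * radius * radius, n_accepts);
  return as_matrix(x, n);
}

// [[Rcpp::export]]
List cpp_saw_ensemble(int n, double b, double radius, int n_samples,
                      int equil_accepts, int stride_accepts) {
  // one pivot walk, sampled every stride_accepts accepted moves after
  // equilibration (pivot decorrelates global observables in a handful of
  // accepted moves)
  std::vector<double> x(3 * n, 0.0);
  for (int i = 0; i < n; ++i) x[3 * i + 2] = b * i;
  double d2min = 4.0 * radius * radius;
  pivot_advance(x, n, d2min, equil_accepts);
  List out(n_samples);
  for (int s = 0; s < n_samples; ++s) {
    pivot_advance(x, n, d2min, stride_accepts);
    out[s] = as_matrix(x, n);
  }
  return out;
}

// ---- Metropolis engine -----------------------------------------------------

enum MoveType { MV_BEAD = 0, MV_PIVOT, MV_CRANK, MV_TRANS, MV_ROT, MV_ION,
                N_MOVES };

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix coords, NumericVector charges,
                NumericMatrix ions, NumericVector ion_charges,
                NumericMatrix restraints, List params, List config) {
  System S = unpack_system(coords, charges, ions, ion_charges, restraints,
                           params);
  int n = S.n, m = S.m, N = n + m;
  double beta = as<double>(config["beta_rel"]);
  int n_sweeps = as<int>(config["n_sweeps"]);
  int thin = as<int>(config["thin"]);
  bool record = as<bool>(config["record"]);
  bool tune = as<bool>(config["tune"]);
  NumericVector prob = config["move_prob"];   // length 6, sums to 1
  NumericVector step = clone(as<NumericVector>(config["step"])); // 6 scales
  double cump[N_MOVES];
  double acc_target_lo = 0.30, acc_target_hi = 0.50;
  {
    double c = 0.0;
    for (int k = 0; k < N_MOVES; ++k) { c += prob[k]; cump[k] = c; }
  }

  int attempts_per_sweep = config.containsElementNamed("attempts_per_sweep") ?
    as<int>(config["attempts_per_sweep"]) : N;

  std::vector<char> mask(N, 0);
  std::vector<int> moved;
  std::vector<double> xsave;
  long att[N_MOVES] = {0}, acc[N_MOVES] = {0};
  long att_win[N_MOVES] = {0}, acc_win[N_MOVES] = {0};

  double e_now = energy_total(S);
  if (!std::isfinite(e_now)) {
    stop("initial configuration has hard-sphere overlaps");
  }

  List frames, ion_frames;
  std::vector<double> sv_e, sv_rg, sv_ree;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int att_i = 0; att_i < attempts_per_sweep; ++att_i) {
      // pick move
      double u = unif_rand();
      int mv = 0;
      while (mv < N_MOVES - 1 && u > cump[mv]) ++mv;
      if (mv == MV_ION && m == 0) mv = MV_BEAD;
      if ((mv == MV_PIVOT || mv == MV_CRANK) && n < 3) mv = MV_BEAD;
      std::fill(mask.begin(), mask.end(), 0);
      moved.clear();
      int lo = 0, hi = -1;       // moved chain range for rigid moves
      int p_piv = -1, c_i = -1, c_j = -1;  // pivot / crankshaft anchors
      double d_axis[3], R[3][3];
      switch (mv) {
      case MV_BEAD: {
        int i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
        mask[i] = 1; lo = hi = i;
        break; }
      case MV_PIVOT: {
        p_piv = 1 + (int)(unif_rand() * (n - 2)); if (p_piv > n - 2) p_piv = n - 2;
        bool tail = unif_rand() < 0.5;
        if (tail) { lo = p_piv + 1; hi = n - 1; } else { lo = 0; hi = p_piv - 1; }
        for (int i = lo; i <= hi; ++i) mask[i] = 1;
        rand_unit_vector(d_axis);
        rotation_matrix(d_axis, (2.0 * unif_rand() - 1.0) * step[MV_PIVOT], R);
        break; }
      case MV_CRANK: {
        c_i = (int)(unif_rand() * (n - 2)); if (c_i > n - 3) c_i = n - 3;
        c_j = c_i + 2 + (int)(unif_rand() * (n - c_i - 2));
        if (c_j > n - 1) c_j = n - 1;
        lo = c_i + 1; hi = c_j - 1;
        for (int k = lo; k <= hi; ++k) mask[k] = 1;
        break; }
      case MV_TRANS: case MV_ROT: {
        lo = 0; hi = n - 1;
        for (int i = 0; i < n; ++i) mask[i] = 1;
        break; }
      case MV_ION: {
        int i = n + (int)(unif_rand() * m); if (i >= N) i = N - 1;
        mask[i] = 1; lo = hi = i;
        break; }
      }
      for (int i = 0; i < N; ++i) if (mask[i]) moved.push_back(i);
      double eb0, ee0, el0, er0, eb1, ee1, el1, er1;
      energy_partial(S, moved, mask, eb0, ee0, el0, er0, false);
      double e_before = eb0 + ee0 + el0 + er0;
      // apply trial move on a saved copy
      xsave = S.x;
      switch (mv) {
      case MV_BEAD: case MV_ION: {
        int i = lo;
        for (int k = 0; k < 3; ++k) {
          S.x[3 * i + k] += (2.0 * unif_rand() - 1.0) *
            step[mv == MV_BEAD ? MV_BEAD : MV_ION];
        }
        if (mv == MV_ION) {  // keep ions wrapped
          for (int k = 0; k < 3; ++k) {
            S.x[3 * i + k] -= S.M.L * std::floor(S.x[3 * i + k] / S.M.L);
          }
        }
        break; }
      case MV_PIVOT: {
        int p = p_piv;
        double origin[3] = { S.x[3 * p], S.x[3 * p + 1], S.x[3 * p + 2] };
        for (int i = lo; i <= hi; ++i) rotate_about(&S.x[3 * i], origin, R);
        break; }
      case MV_CRANK: {
        int i = c_i, j = c_j;
        double ax[3] = { S.x[3 * j] - S.x[3 * i], S.x[3 * j + 1] - S.x[3 * i + 1],
                         S.x[3 * j + 2] - S.x[3 * i + 2] };
        double nrm = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
        if (nrm < 1e-12) break;  // degenerate axis: null move
        for (int k = 0; k < 3; ++k) ax[k] /= nrm;
        double Rl[3][3];
        rotation_matrix(ax, (2.0 * unif_rand() - 1.0) * step[MV_CRANK], Rl);
        double origin[3] = { S.x[3 * i], S.x[3 * i + 1], S.x[3 * i + 2] };
        for (int k = lo; k <= hi; ++k) rotate_about(&S.x[3 * k], origin, Rl);
        break; }
      case MV_TRANS: {
        double d[3];
        for (int k = 0; k < 3; ++k) d[k] = (2.0 * unif_rand() - 1.0) * step[MV_TRANS];
        for (int i = 0; i < n; ++i) {
          for (int k = 0; k < 3; ++k) S.x[3 * i + k] += d[k];
        }
        break; }
      case MV_ROT: {
        rand_unit_vector(d_axis);
        double Rl[3][3];
        rotation_matrix(d_axis, (2.0 * unif_rand() - 1.0) * step[MV_ROT], Rl);
        double c[3] = {0, 0, 0};
        for (int i = 0; i < n; ++i) {
          for (int k = 0; k < 3; ++k) c[k] += S.x[3 * i + k];
        }
        for (int k = 0; k < 3; ++k) c[k] /= n;
        for (int i = 0; i < n; ++i) rotate_about(&S.x[3 * i], c, Rl);
        break; }
      }
      energy_partial(S, moved, mask, eb1, ee1, el1, er1);
      double e_after = eb1 + ee1 + el1 + er1;
      ++att[mv]; ++att_win[mv];
      double dE = e_after - e_before;
      bool accept;
      if (!std::isfinite(e_after)) {
        accept = false;
      } else {
        accept = (dE <= 0.0) || (unif_rand() < std::exp(-beta * dE));
      }
      if (accept) {
        e_now += dE;
        ++acc[mv]; ++acc_win[mv];
      } else {
        S.x = xsave;
      }
    }
    // step-size tuning during equilibration
    if (tune && sweep % 10 == 0) {
      for (int k = 0; k < N_MOVES; ++k) {
        if (att_win[k] < 20) continue;
        double r = (double)acc_win[k] / att_win[k];
        if (r > acc_target_hi) step[k] *= 1.15;
        if (r < acc_target_lo) step[k] *= 0.85;
        // angles capped at pi, translations at a quarter box
        double cap = (k == MV_PIVOT || k == MV_CRANK || k == MV_ROT) ?
          M_PI : S.M.L / 4.0;
        if (step[k] > cap) step[k] = cap;
        if (step[k] < 1e-4) step[k] = 1e-4;
        att_win[k] = 0; acc_win[k] = 0;
      }
    }
    if (record && sweep % thin == 0) {
      NumericMatrix fr(n, 3);
      double c[3] = {0, 0, 0};
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < 3; ++k) c[k] += S.x[3 * i + k];
      }
      for (int k = 0; k < 3; ++k) c[k] /= n;
      double rg2 = 0.0;
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < 3; ++k) {
          double d = S.x[3 * i + k] - c[k];
          rg2 += d * d;
        }
        fr(i, 0) = S.x[3 * i]; fr(i, 1) = S.x[3 * i + 1];
        fr(i, 2) = S.x[3 * i + 2];
      }
      rg2 /= n;
      double dx = S.x[3 * (n - 1)] - S.x[0];
      double dy = S.x[3 * (n - 1) + 1] - S.x[1];
      double dz = S.x[3 * (n - 1) + 2] - S.x[2];
      frames.push_back(fr);
      if (m > 0) {
        NumericMatrix fi(m, 3);
        for (int i = 0; i < m; ++i) {
          fi(i, 0) = S.x[3 * (n + i)]; fi(i, 1) = S.x[3 * (n + i) + 1];
          fi(i, 2) = S.x[3 * (n + i) + 2];
        }
        ion_frames.push_back(fi);
      }
      sv_e.push_back(e_now);
      sv_rg.push_back(std::sqrt(rg2));
      sv_ree.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
    }
  }

  double parts[4];
  double e_recomputed = energy_total(S, parts);
  NumericMatrix out_coords(n, 3), out_ions(m, 3);
  for (int i = 0; i < n; ++i) {
    out_coords(i, 0) = S.x[3 * i]; out_coords(i, 1) = S.x[3 * i + 1];
    out_coords(i, 2) = S.x[3 * i + 2];
  }
  for (int i = 0; i < m; ++i) {
    out_ions(i, 0) = S.x[3 * (n + i)]; out_ions(i, 1) = S.x[3 * (n + i) + 1];
    out_ions(i, 2) = S.x[3 * (n + i) + 2];
  }
  NumericVector attempts(N_MOVES), accepts(N_MOVES);
  for (int k = 0; k < N_MOVES; ++k) {
    attempts[k] = (double)att[k]; accepts[k] = (double)acc[k];
  }
  return List::create(
    _["frames"] = frames, _["ion_frames"] = ion_frames,
    _["energy"] = wrap(sv_e), _["rg"] = wrap(sv_rg), _["ree"] = wrap(sv_ree),
    _["coords"] = out_coords, _["ions"] = out_ions,
    _["attempts"] = attempts, _["accepts"] = accepts,
    _["step"] = step,
    _["energy_incremental"] = e_now,
    _["energy_recomputed"] = e_recomputed);
}

// ---- Debye scattering ------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_debye_intensity(NumericMatrix coords, NumericVector q,
                                  NumericVector f) {
  // I(q) = sum_i sum_j f_i f_j sin(q r_ij) / (q r_ij), sin(0)/0 -> 1
  int n = coords.nrow(), nq = q.size();
  NumericVector I(nq);
  double fsum2 = 0.0;
  for (int i = 0; i < n; ++i) fsum2 += f[i] * f[i];
  for (int k = 0; k < nq; ++k) I[k] = fsum2;  // i == j terms
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double ff = 2.0 * f[i] * f[j];
      for (int k = 0; k < nq; ++k) {
        double x = q[k] * r;
        I[k] += ff * (x < 1e-12 ? 1.0 : std::sin(x) / x);
      }
    }
  }
  return I;
}

// [[Rcpp::export]]
NumericMatrix cpp_contact_indicator(NumericMatrix coords, double cutoff,
                                    int exclusion) {
  // 0/1 contact matrix for one configuration, |i-j| > exclusion
  int n = coords.nrow();
  NumericMatrix C(n, n);
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (j - i <= exclusion) continue;
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) { C(i, j) = 1.0; C(j, i) = 1.0; }
    }
  }
  return C;
}
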