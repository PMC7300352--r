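// Bead-spring Langevin dynamics core: screened-Coulomb (Debye-Hueckel) blob
// repulsion, WCA wall confinement in a cylindrical cell, harmonic bonds,
// optional flat-bottom tethers, BAOAB velocity-Verlet Langevin integration.
// All quantities in reduced units (bead mass = 1, d_b = 1, k_B*T = eps = 1
// by default); unit conversion happens at the R layer.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// PCG32 + Box-Muller: own RNG so trajectories are bit-reproducible from an
// integer seed pair, independent of R's RNG state.
// ---------------------------------------------------------------------------
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double runif() {  // in (0, 1)
    return (next() + 1.0) * (1.0 / 4294967297.0);
  }
};

struct Gauss {
  Pcg32 &rng;
  bool has_spare;
  double spare;
  Gauss(Pcg32 &r) : rng(r), has_spare(false), spare(0.0) {}
  double operator()() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1 = rng.runif(), u2 = rng.runif();
    double mag = std::sqrt(-2.0 * std::log(u1));
    spare = mag * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return mag * std::cos(2.0 * M_PI * u2);
  }
};

// ---------------------------------------------------------------------------
// Forces and potential energies
// ---------------------------------------------------------------------------
struct SystemParams {
  double eps;      // interaction strength, k_B*T units
  double k_bond;   // harmonic spring constant
  double r0_bond;  // bond rest length (= d_b)
  double db;       // full blob diameter (length unit)
  double pair_cutoff;  // Debye-Hueckel cutoff (in d_b units)
};

// Debye-Hueckel pair force/energy with effective diameter de = R_i + R_j.
// U(r) = eps*(de/r)*exp(-r/de); radial force magnitude -dU/dr = U*(1/r + 1/de).
static inline void dh_pair(double r, double de, double eps, double &u, double &f) {
  u = eps * (de / r) * std::exp(-r / de);
  f = u * (1.0 / r + 1.0 / de);
}

// WCA wall term as a function of distance d (> 0) from bead centre to the
// wall surface, with length scale sig (= bead radius). Returns force
// magnitude pushing away from the wall, and adds energy.
static const double WCA_CUT2 = std::pow(2.0, 1.0 / 3.0);  // (2^(1/6))^2

static inline void wca_wall(double d, double sig, double eps, double &u, double &f) {
  if (d * d >= WCA_CUT2 * sig * sig) {
    u = 0.0;
    f = 0.0;
    return;
  }
  double s2 = (sig / d) * (sig / d);
  double s6 = s2 * s2 * s2;
  u = 4.0 * eps * (s6 * s6 - s6 + 0.25);
  f = 4.0 * eps * (12.0 * s6 * s6 - 6.0 * s6) / d;
}

// Full force evaluation. pos: n x 3 (flat, row-major as x[i], y[i], z[i]
// separate arrays for cache friendliness). Throws on wall violation.
struct Forces {
  std::vector<double> fx, fy, fz;
  double e_pair, e_bond, e_wall, e_tether;
};

static void compute_forces(const std::vector<double> &x, const std::vector<double> &y,
                           const std::vector<double> &z, const std::vector<double> &rad,
                           const std::vector<int> &b1, const std::vector<int> &b2,
                           double cell_r, double cell_l, const SystemParams &p,
                           const std::vector<int> &tidx, const double *tpoint,
                           double tether_k, double tether_flat, Forces &F,
                           const std::vector<int> *nl_i = 0,
                           const std::vector<int> *nl_j = 0) {
  int n = (int)x.size();
  F.fx.assign(n, 0.0);
  F.fy.assign(n, 0.0);
  F.fz.assign(n, 0.0);
  F.e_pair = F.e_bond = F.e_wall = F.e_tether = 0.0;

  double rc = p.pair_cutoff * p.db;
  double rc2 = rc * rc;

  // pair repulsion: over a Verlet neighbour list when supplied, otherwise
  // over all pairs
  if (nl_i) {
    size_t m = nl_i->size();
    for (size_t e = 0; e < m; ++e) {
      int i = (*nl_i)[e], j = (*nl_j)[e];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2 || r2 <= 0.0) continue;
      double r = std::sqrt(r2);
      double de = rad[i] + rad[j];
      double u, fmag;
      dh_pair(r, de, p.eps, u, fmag);
      F.e_pair += u;
      double s = fmag / r;
      F.fx[i] += s * dx; F.fy[i] += s * dy; F.fz[i] += s * dz;
      F.fx[j] -= s * dx; F.fy[j] -= s * dy; F.fz[j] -= s * dz;
    }
  } else {
    for (int i = 0; i < n - 1; ++i) {
      double xi = x[i], yi = y[i], zi = z[i], ri = rad[i];
      for (int j = i + 1; j < n; ++j) {
        double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rc2 || r2 <= 0.0) continue;
        double r = std::sqrt(r2);
        double de = ri + rad[j];
        double u, fmag;
        dh_pair(r, de, p.eps, u, fmag);
        F.e_pair += u;
        double s = fmag / r;
        F.fx[i] += s * dx; F.fy[i] += s * dy; F.fz[i] += s * dz;
        F.fx[j] -= s * dx; F.fy[j] -= s * dy; F.fz[j] -= s * dz;
      }
    }
  }

  // bonds
  int nb = (int)b1.size();
  for (int e = 0; e < nb; ++e) {
    int i = b1[e], j = b2[e];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ext = r - p.r0_bond;
    F.e_bond += 0.5 * p.k_bond * ext * ext;
    if (r > 0) {
      double s = -p.k_bond * ext / r;  // restoring toward r0
      F.fx[i] += s * dx; F.fy[i] += s * dy; F.fz[i] += s * dz;
      F.fx[j] -= s * dx; F.fy[j] -= s * dy; F.fz[j] -= s * dz;
    }
  }

  // cylindrical wall: lateral surface at radial distance cell_r from the x
  // axis, flat end caps at x = +/- cell_l/2. Beads must be strictly inside.
  double half_l = 0.5 * cell_l;
  for (int i = 0; i < n; ++i) {
    double rho = std::sqrt(y[i] * y[i] + z[i] * z[i]);
    double d_lat = cell_r - rho;
    double d_cap = half_l - std::fabs(x[i]);
    if (d_lat <= 0.0 || d_cap <= 0.0)
      stop("confinement violation: bead %d outside the cell wall", i + 1);
    double sig = rad[i], u, fmag;
    wca_wall(d_lat, sig, p.eps, u, fmag);
    if (fmag != 0.0 && rho > 1e-12) {
      F.e_wall += u;
      // push toward the axis
      F.fy[i] -= fmag * (y[i] / rho);
      F.fz[i] -= fmag * (z[i] / rho);
    } else {
      F.e_wall += u;
    }
    wca_wall(d_cap, sig, p.eps, u, fmag);
    F.e_wall += u;
    if (fmag != 0.0) F.fx[i] -= fmag * (x[i] >= 0 ? 1.0 : -1.0);
  }

  // flat-bottom harmonic tethers (replication factory): zero force within
  // tether_flat of the anchor, harmonic beyond.
  for (size_t t = 0; t < tidx.size(); ++t) {
    int i = tidx[t];
    double dx = x[i] - tpoint[0], dy = y[i] - tpoint[1], dz = z[i] - tpoint[2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d > tether_flat) {
      double ext = d - tether_flat;
      F.e_tether += 0.5 * tether_k * ext * ext;
      double s = -tether_k * ext / d;
      F.fx[i] += s * dx; F.fy[i] += s * dy; F.fz[i] += s * dz;
    }
  }
}

// [[Rcpp::export]]
List cpp_total_forces(NumericMatrix pos, NumericVector radii, IntegerMatrix bonds,
                      double cell_r, double cell_l, double eps, double k_bond,
                      double r0_bond, double db, double pair_cutoff,
                      IntegerVector tether_idx, NumericVector tether_point,
                      double tether_k, double tether_flat) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), rad(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); rad[i] = radii[i];
  }
  std::vector<int> b1, b2;
  for (int e = 0; e < bonds.nrow(); ++e) {
    b1.push_back(bonds(e, 0) - 1);
    b2.push_back(bonds(e, 1) - 1);
  }
  std::vector<int> tidx;
  for (int t = 0; t < tether_idx.size(); ++t) tidx.push_back(tether_idx[t] - 1);
  double tp[3] = {0, 0, 0};
  if (tether_point.size() == 3) {
    tp[0] = tether_point[0]; tp[1] = tether_point[1]; tp[2] = tether_point[2];
  }
  SystemParams p = {eps, k_bond, r0_bond, db, pair_cutoff};
  Forces F;
  compute_forces(x, y, z, rad, b1, b2, cell_r, cell_l, p, tidx, tp, tether_k,
                 tether_flat, F);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = F.fx[i]; out(i, 1) = F.fy[i]; out(i, 2) = F.fz[i];
  }
  return List::create(_["forces"] = out,
                      _["energy"] = List::create(_["pair"] = F.e_pair,
                                                 _["bond"] = F.e_bond,
                                                 _["wall"] = F.e_wall,
                                                 _["tether"] = F.e_tether));
}

// ---------------------------------------------------------------------------
// BAOAB Langevin velocity-Verlet integration over n_steps, with linear
// per-step interpolation of growing bead radii and cell geometry. Samples
// positions every sample_stride steps (0 = none). Optionally logs per-step
// kinetic/bond/nonbonded/total energies (used for equilibration monitoring).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_integrate(NumericMatrix pos, NumericMatrix vel, NumericVector radii_start,
                   NumericVector radii_end, IntegerMatrix bonds, double cell_r0,
                   double cell_r1, double cell_l0, double cell_l1, double eps,
                   double k_bond, double r0_bond, double db, double pair_cutoff,
                   double dt, double gamma, double kT, double mass, int n_steps,
                   int sample_stride, bool log_energies, IntegerVector tether_idx,
                   NumericVector tether_point, double tether_k, double tether_flat,
                   int seed1, int seed2) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n), rad(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    rad[i] = radii_start[i];
  }
  std::vector<int> b1, b2;
  for (int e = 0; e < bonds.nrow(); ++e) {
    b1.push_back(bonds(e, 0) - 1);
    b2.push_back(bonds(e, 1) - 1);
  }
  std::vector<int> tidx;
  for (int t = 0; t < tether_idx.size(); ++t) tidx.push_back(tether_idx[t] - 1);
  double tp[3] = {0, 0, 0};
  if (tether_point.size() == 3) {
    tp[0] = tether_point[0]; tp[1] = tether_point[1]; tp[2] = tether_point[2];
  }
  SystemParams p = {eps, k_bond, r0_bond, db, pair_cutoff};

  Pcg32 rng((uint64_t)(uint32_t)seed1, (uint64_t)(uint32_t)seed2);
  Gauss gauss(rng);

  // Ornstein-Uhlenbeck coefficients for the O substep (exact solution)
  double c1 = std::exp(-gamma * dt / mass);
  double c2 = std::sqrt(kT / mass * (1.0 - c1 * c1));

  int n_samples = (sample_stride > 0 && n_steps > 0) ? n_steps / sample_stride : 0;
  NumericMatrix samples(n_samples * n, 3);
  IntegerVector sample_steps(n_samples);
  NumericMatrix elog(log_energies ? n_steps : 0, 4);

  // Verlet neighbour list with a 1 d_b skin, rebuilt every 10 steps (bead
  // drift per step is << skin/2 at the overdamped parameters used)
  std::vector<int> nl_i, nl_j;
  const double skin = 1.0 * db;
  double rl2 = (p.pair_cutoff * db + skin) * (p.pair_cutoff * db + skin);
  const int nl_every = 10;
  auto rebuild_nl = [&]() {
    nl_i.clear();
    nl_j.clear();
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        if (dx * dx + dy * dy + dz * dz < rl2) {
          nl_i.push_back(i);
          nl_j.push_back(j);
        }
      }
  };
  rebuild_nl();

  // Elastic reflection fallback: the WCA wall normally keeps beads inside,
  // but a part-grown bead (small sigma) can overshoot the thin repulsive
  // layer within one step. Walls are impenetrable by construction, so such
  // rare crossings are reflected instead of blowing up.
  auto reflect_walls = [&](double cr_, double cl_) {
    double half = 0.5 * cl_;
    for (int i = 0; i < n; ++i) {
      if (std::fabs(x[i]) >= half) {
        double sgn = x[i] >= 0 ? 1.0 : -1.0;
        double xr = 2.0 * sgn * half - x[i];
        if (std::fabs(xr) >= half) xr = sgn * (half - 1e-3);
        x[i] = xr;
        vx[i] = -vx[i];
      }
      double rho2 = y[i] * y[i] + z[i] * z[i];
      if (rho2 >= cr_ * cr_) {
        double rho = std::sqrt(rho2);
        double rr = 2.0 * cr_ - rho;
        if (rr >= cr_ || rr <= 0.0) rr = cr_ - 1e-3;
        double fsc = rr / rho;
        // flip the radial velocity component
        double ny = y[i] / rho, nz = z[i] / rho;
        double vr = vy[i] * ny + vz[i] * nz;
        vy[i] -= 2.0 * vr * ny;
        vz[i] -= 2.0 * vr * nz;
        y[i] *= fsc;
        z[i] *= fsc;
      }
    }
  };

  Forces F;
  double cr = cell_r0, cl = cell_l0;
  reflect_walls(cr, cl);
  compute_forces(x, y, z, rad, b1, b2, cr, cl, p, tidx, tp, tether_k, tether_flat, F,
                 &nl_i, &nl_j);

  double e_init = NA_REAL;
  int isample = 0;
  double half_dt = 0.5 * dt;
  for (int s = 0; s < n_steps; ++s) {
    if (s > 0 && s % nl_every == 0) rebuild_nl();
    double frac = (double)(s + 1) / (double)n_steps;
    cr = cell_r0 + frac * (cell_r1 - cell_r0);
    cl = cell_l0 + frac * (cell_l1 - cell_l0);
    for (int i = 0; i < n; ++i)
      rad[i] = radii_start[i] + frac * (radii_end[i] - radii_start[i]);

    // B: half kick
    for (int i = 0; i < n; ++i) {
      vx[i] += half_dt * F.fx[i] / mass;
      vy[i] += half_dt * F.fy[i] / mass;
      vz[i] += half_dt * F.fz[i] / mass;
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      x[i] += half_dt * vx[i]; y[i] += half_dt * vy[i]; z[i] += half_dt * vz[i];
    }
    // O: exact friction + noise
    if (gamma > 0.0 || kT > 0.0) {
      for (int i = 0; i < n; ++i) {
        vx[i] = c1 * vx[i] + c2 * gauss();
        vy[i] = c1 * vy[i] + c2 * gauss();
        vz[i] = c1 * vz[i] + c2 * gauss();
      }
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      x[i] += half_dt * vx[i]; y[i] += half_dt * vy[i]; z[i] += half_dt * vz[i];
    }
    reflect_walls(cr, cl);
    // recompute forces, B: half kick
    compute_forces(x, y, z, rad, b1, b2, cr, cl, p, tidx, tp, tether_k, tether_flat, F,
                   &nl_i, &nl_j);
    for (int i = 0; i < n; ++i) {
      vx[i] += half_dt * F.fx[i] / mass;
      vy[i] += half_dt * F.fy[i] / mass;
      vz[i] += half_dt * F.fz[i] / mass;
    }

    if (log_energies || (s % 200 == 0)) {
      double ekin = 0.0;
      for (int i = 0; i < n; ++i)
        ekin += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      ekin *= 0.5 * mass;
      double enb = F.e_pair + F.e_wall;
      double ebd = F.e_bond + F.e_tether;
      double etot = ekin + enb + ebd;
      if (!std::isfinite(etot))
        stop("energy divergence at step %d: non-finite total energy", s + 1);
      if (!std::isfinite(e_init) || e_init == 0.0) {
        if (s == 0) e_init = std::fabs(etot) > 1e-12 ? std::fabs(etot) : 1.0;
      }
      if (std::isfinite(e_init) && std::fabs(etot) > 1e3 * e_init && e_init > 1.0)
        stop("energy divergence at step %d: total energy exceeds 1000x initial "
             "(try a smaller time step)", s + 1);
      if (log_energies) {
        elog(s, 0) = ekin; elog(s, 1) = ebd; elog(s, 2) = enb; elog(s, 3) = etot;
      }
    }

    if (sample_stride > 0 && (s + 1) % sample_stride == 0 && isample < n_samples) {
      for (int i = 0; i < n; ++i) {
        samples(isample * n + i, 0) = x[i];
        samples(isample * n + i, 1) = y[i];
        samples(isample * n + i, 2) = z[i];
      }
      sample_steps[isample] = s + 1;
      ++isample;
    }
  }

  NumericMatrix opos(n, 3), ovel(n, 3);
  for (int i = 0; i < n; ++i) {
    opos(i, 0) = x[i]; opos(i, 1) = y[i]; opos(i, 2) = z[i];
    ovel(i, 0) = vx[i]; ovel(i, 1) = vy[i]; ovel(i, 2) = vz[i];
  }
  return List::create(_["pos"] = opos, _["vel"] = ovel, _["radii"] = NumericVector(wrap(rad)),
                      _["samples"] = samples, _["sample_steps"] = sample_steps,
                      _["energy_log"] = elog);
}
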