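// MPCD (stochastic rotation dynamics) solvent engine with stochastic
// reflection (SRR) no-slip walls, collisional coupling to a bead-spring
// chain integrated by velocity-Verlet substeps, a cell-level Maxwellian
// (MBS) thermostat, and a solvent-free chain Monte Carlo sampler.
//
// Conventions: collision cells have unit edge (a0 = 1); x and y are periodic
// with integer box lengths; hard walls sit at z = +-Lz/2. All randomness
// comes from R's RNG so runs are reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- helpers

static inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  return x >= L ? x - L : x;  // guard the floor rounding edge case
}

// linear interpolation on a uniform grid spanning [-Lz/2, Lz/2]
static inline double interp_profile(const double* g, int n, double Lz,
                                    double z) {
  double u = (z + Lz / 2) / Lz * (n - 1);
  if (u <= 0) return g[0];
  if (u >= n - 1) return g[n - 1];
  int i = (int)u;
  double f = u - i;
  return g[i] * (1 - f) + g[i + 1] * f;
}

// random unit vector, uniform on the sphere
static inline void rand_axis(double* n) {
  double z = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  n[0] = r * std::cos(phi);
  n[1] = r * std::sin(phi);
  n[2] = z;
}

// Rodrigues rotation of v by angle (c = cos, s = sin) around unit axis n
static inline void rotate(double* v, const double* n, double c, double s) {
  double nv = n[0] * v[0] + n[1] * v[1] + n[2] * v[2];
  double cx = n[1] * v[2] - n[2] * v[1];
  double cy = n[2] * v[0] - n[0] * v[2];
  double cz = n[0] * v[1] - n[1] * v[0];
  v[0] = v[0] * c + cx * s + n[0] * nv * (1 - c);
  v[1] = v[1] * c + cy * s + n[1] * nv * (1 - c);
  v[2] = v[2] * c + cz * s + n[2] * nv * (1 - c);
}

// SRR wall draw: tangential components Maxwellian at T, normal component
// flux-weighted (Rayleigh) directed into the fluid; sign = +1 at the lower
// wall (outgoing +z), -1 at the upper wall.
static inline void srr_velocity(double kT, double mass, double sign,
                                double* v) {
  double sd = std::sqrt(kT / mass);
  v[0] = sd * norm_rand();
  v[1] = sd * norm_rand();
  double u = unif_rand();
  while (u <= 0.0) u = unif_rand();
  v[2] = sign * sd * std::sqrt(-2.0 * std::log(u));
}

// -------------------------------------------------------------- streaming

// Drift a particle for time dt (velocity already half-kicked); resolve wall
// crossings with the SRR rule. Accumulates wall momentum transfer in dp[3].
static inline void drift_with_walls(double* r, double* v, double dt,
                                    double Lz, double kT, double mass,
                                    double* dp, int* nrefl) {
  double half = Lz / 2;
  double t_rem = dt;
  for (int guard = 0; guard < 64 && t_rem > 0; ++guard) {
    double t_hit = t_rem;
    double sign = 0;
    if (v[2] > 0) {
      double t = (half - r[2]) / v[2];
      if (t < t_hit) { t_hit = t; sign = -1; }
    } else if (v[2] < 0) {
      double t = (-half - r[2]) / v[2];
      if (t < t_hit) { t_hit = t; sign = +1; }
    }
    if (t_hit < 0) t_hit = 0;
    r[0] += v[0] * t_hit;
    r[1] += v[1] * t_hit;
    r[2] += v[2] * t_hit;
    t_rem -= t_hit;
    if (sign == 0) break;
    r[2] = sign > 0 ? -half : half;  // restore to the impact point
    double vnew[3];
    srr_velocity(kT, mass, sign, vnew);
    for (int k = 0; k < 3; ++k) {
      dp[k] += mass * (vnew[k] - v[k]);
      v[k] = vnew[k];
    }
    if (nrefl) ++(*nrefl);
  }
  if (r[2] > half || r[2] < -half)
    stop("internal consistency error: particle beyond wall after streaming");
}

// [[Rcpp::export]]
List cpp_stream(NumericMatrix pos_in, NumericMatrix vel_in, double mass,
                double dt, NumericVector fx_grid, double Lx, double Ly,
                double Lz, double kT) {
  NumericMatrix pos = clone(pos_in), vel = clone(vel_in);
  int n = pos.nrow(), ng = fx_grid.size();
  const double* fg = fx_grid.begin();
  double dp[3] = {0, 0, 0};
  double injected = 0;
  int nrefl = 0;
  for (int i = 0; i < n; ++i) {
    double r[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double v[3] = {vel(i, 0), vel(i, 1), vel(i, 2)};
    double f0 = ng > 1 ? interp_profile(fg, ng, Lz, r[2]) : 0.0;
    v[0] += 0.5 * dt * f0 / mass;    // body force acts along x only
    drift_with_walls(r, v, dt, Lz, kT, mass, dp, &nrefl);
    double f1 = ng > 1 ? interp_profile(fg, ng, Lz, r[2]) : 0.0;
    v[0] += 0.5 * dt * f1 / mass;
    injected += 0.5 * dt * (f0 + f1); // momentum fed in by the body force
    r[0] = wrap(r[0], Lx);
    r[1] = wrap(r[1], Ly);
    for (int k = 0; k < 3; ++k) { pos(i, k) = r[k]; vel(i, k) = v[k]; }
  }
  return List::create(_["pos"] = pos, _["vel"] = vel,
                      _["wall_dp"] = NumericVector::create(dp[0], dp[1], dp[2]),
                      _["injected_px"] = injected,
                      _["n_reflections"] = nrefl);
}

// [[Rcpp::export]]
NumericVector cpp_grid_shift() {
  return NumericVector::create(unif_rand() - 0.5, unif_rand() - 0.5,
                               unif_rand() - 0.5);
}

// Cell ids are 0-based; z cells are truncated at the walls (one extra slot
// on each side absorbs the shifted partial cells).
// [[Rcpp::export]]
IntegerVector cpp_cell_assign(NumericMatrix pos, NumericVector shift,
                              int nx, int ny, int nz, double Lz) {
  int n = pos.nrow();
  IntegerVector cell(n);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(pos(i, 0) - shift[0]);
    int iy = (int)std::floor(pos(i, 1) - shift[1]);
    ix = ((ix % nx) + nx) % nx;
    iy = ((iy % ny) + ny) % ny;
    int iz = (int)std::floor(pos(i, 2) + Lz / 2 - shift[2]);
    if (iz < -1) iz = -1;
    if (iz > nz) iz = nz;
    cell[i] = (iz + 1) + (nz + 2) * (ix + nx * iy);
  }
  return cell;
}

// SRD rotation (angle alpha around a per-cell random axis, relative to the
// mass-weighted cell center-of-mass velocity) followed by the cell-level
// Maxwell-Boltzmann scaling thermostat: the relative kinetic energy of each
// cell is rescaled to a draw from Gamma(3(Nc-1)/2, kT), which preserves the
// center-of-mass velocity exactly and realizes Maxwellian relative-velocity
// statistics.
// [[Rcpp::export]]
NumericMatrix cpp_collide(NumericMatrix vel_in, NumericVector mass,
                          IntegerVector cell, int ncells, double alpha_deg,
                          double kT, bool thermostat, bool rotate_flag) {
  NumericMatrix vel = clone(vel_in);
  int n = vel.nrow();
  std::vector<double> msum(ncells, 0.0), px(ncells, 0.0), py(ncells, 0.0),
      pz(ncells, 0.0);
  std::vector<int> cnt(ncells, 0);
  for (int i = 0; i < n; ++i) {
    int c = cell[i];
    double m = mass[i];
    msum[c] += m;
    px[c] += m * vel(i, 0);
    py[c] += m * vel(i, 1);
    pz[c] += m * vel(i, 2);
    cnt[c]++;
  }
  // per-cell random axis and relative kinetic energy (invariant under the
  // rotation, so it can be measured before rotating)
  std::vector<double> ax(3 * ncells);
  std::vector<double> erel(ncells, 0.0);
  for (int c = 0; c < ncells; ++c)
    if (cnt[c] > 0) rand_axis(&ax[3 * c]);
  for (int i = 0; i < n; ++i) {
    int c = cell[i];
    if (cnt[c] < 2) continue;
    double vx = vel(i, 0) - px[c] / msum[c];
    double vy = vel(i, 1) - py[c] / msum[c];
    double vz = vel(i, 2) - pz[c] / msum[c];
    erel[c] += 0.5 * mass[i] * (vx * vx + vy * vy + vz * vz);
  }
  std::vector<double> scale(ncells, 1.0);
  if (thermostat) {
    for (int c = 0; c < ncells; ++c) {
      if (cnt[c] < 2 || erel[c] <= 0) continue;
      double shape = 1.5 * (cnt[c] - 1);
      double etarget = R::rgamma(shape, kT);
      scale[c] = std::sqrt(etarget / erel[c]);
    }
  }
  double ca = std::cos(alpha_deg * M_PI / 180.0);
  double sa = std::sin(alpha_deg * M_PI / 180.0);
  for (int i = 0; i < n; ++i) {
    int c = cell[i];
    if (cnt[c] < 2) continue;  // a lone particle has zero relative velocity
    double vcm[3] = {px[c] / msum[c], py[c] / msum[c], pz[c] / msum[c]};
    double v[3] = {vel(i, 0) - vcm[0], vel(i, 1) - vcm[1], vel(i, 2) - vcm[2]};
    if (rotate_flag) rotate(v, &ax[3 * c], ca, sa);
    for (int k = 0; k < 3; ++k) vel(i, k) = vcm[k] + scale[c] * v[k];
  }
  return vel;
}

// [[Rcpp::export]]
NumericMatrix cpp_srr_draw(int n, double kT, double mass) {
  NumericMatrix out(n, 3);
  double v[3];
  for (int i = 0; i < n; ++i) {
    srr_velocity(kT, mass, +1.0, v);
    out(i, 0) = v[0]; out(i, 1) = v[1]; out(i, 2) = v[2];
  }
  return out;
}

// ------------------------------------------------------- chain force field

struct ChainParams {
  double sigma, eps, kfene, R0, eps_bend;
};

struct WallParams {
  bool on;           // any wall interaction (SRR plane always applies)
  double Lz;
  double w, kappa, cutoff;
  const double* etab;  // energy table on [0, cutoff], uniform
  int ne;
};

static inline double wall_energy_1(const WallParams& wp, double d) {
  if (!wp.on || wp.w == 0 || d >= wp.cutoff) return 0.0;
  double u = d / wp.cutoff * (wp.ne - 1);
  if (u <= 0) return wp.etab[0];
  int i = (int)u;
  if (i >= wp.ne - 1) return wp.etab[wp.ne - 1];
  double f = u - i;
  return wp.etab[i] * (1 - f) + wp.etab[i + 1] * f;
}

// dU/dd of one wall: exact closed form (zero inside the contact plateau)
static inline double wall_dudd_1(const WallParams& wp, double d,
                                 double sigma) {
  if (!wp.on || wp.w == 0 || d < sigma || d >= wp.cutoff) return 0.0;
  double s6 = std::pow(sigma, 6);
  return 2.0 * M_PI * wp.w * s6 * std::exp(-wp.kappa * d) / std::pow(d, 5);
}

// Total potential energy and forces of the chain. Throws on FENE
// overstretch. F must hold 3*N doubles (zeroed here).
static double chain_forces(const double* x, const double* y, const double* z,
                           int N, const ChainParams& cp, const WallParams& wp,
                           double* F, int step_for_msg) {
  for (int i = 0; i < 3 * N; ++i) F[i] = 0.0;
  double U = 0.0;
  double rc2 = std::pow(2.0, 1.0 / 3.0) * cp.sigma * cp.sigma; // (2^(1/6) s)^2
  // WCA between all pairs
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      if (r2 <= 1e-12)
        stop("monomer overlap at step %d (pair %d,%d)", step_for_msg, i + 1,
             j + 1);
      double s2 = cp.sigma * cp.sigma / r2;
      double s6 = s2 * s2 * s2;
      U += 4 * cp.eps * (s6 * s6 - s6) + cp.eps;
      double fr = 24 * cp.eps * (2 * s6 * s6 - s6) / r2; // F = fr * rvec
      F[3 * i + 0] += fr * dx; F[3 * i + 1] += fr * dy; F[3 * i + 2] += fr * dz;
      F[3 * j + 0] -= fr * dx; F[3 * j + 1] -= fr * dy; F[3 * j + 2] -= fr * dz;
    }
  }
  // FENE bonds
  for (int i = 0; i < N - 1; ++i) {
    double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    double R02 = cp.R0 * cp.R0;
    if (r2 >= R02)
      stop("FENE bond %d overstretched at step %d: r = %.5f >= R0 = %.3f",
           i + 1, step_for_msg, std::sqrt(r2), cp.R0);
    U += -0.5 * cp.kfene * R02 * std::log1p(-r2 / R02);
    double fr = -cp.kfene / (1 - r2 / R02); // F_{i+1} = fr * rvec (restoring)
    F[3 * (i + 1) + 0] += fr * dx;
    F[3 * (i + 1) + 1] += fr * dy;
    F[3 * (i + 1) + 2] += fr * dz;
    F[3 * i + 0] -= fr * dx;
    F[3 * i + 1] -= fr * dy;
    F[3 * i + 2] -= fr * dz;
  }
  // harmonic bending on interior bond angles
  if (cp.eps_bend > 0) {
    for (int i = 1; i < N - 1; ++i) {
      double b1[3] = {x[i] - x[i - 1], y[i] - y[i - 1], z[i] - z[i - 1]};
      double b2[3] = {x[i + 1] - x[i], y[i + 1] - y[i], z[i + 1] - z[i]};
      double l1 = std::sqrt(b1[0] * b1[0] + b1[1] * b1[1] + b1[2] * b1[2]);
      double l2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
      double u[3] = {b1[0] / l1, b1[1] / l1, b1[2] / l1};
      double v[3] = {b2[0] / l2, b2[1] / l2, b2[2] / l2};
      double c = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
      c = std::min(1.0, std::max(-1.0, c));
      double th = std::acos(c);
      U += 0.5 * cp.eps_bend * th * th;
      double s = std::sqrt(std::max(1e-14, 1.0 - c * c));
      double fac = cp.eps_bend * (th > 1e-6 ? th / s : 1.0);
      // F_k = fac * dcos/dr_k  (since dU/dtheta * dtheta/dcos = -fac)
      for (int k = 0; k < 3; ++k) {
        double dprev = -(v[k] - c * u[k]) / l1;
        double dnext = (u[k] - c * v[k]) / l2;
        F[3 * (i - 1) + k] += fac * dprev;
        F[3 * (i + 1) + k] += fac * dnext;
        F[3 * i + k] += -fac * (dprev + dnext);
      }
    }
  }
  // screened vdW attraction of both walls
  if (wp.on && wp.w > 0) {
    double half = wp.Lz / 2;
    for (int i = 0; i < N; ++i) {
      double dlo = half + z[i], dhi = half - z[i];
      U += wall_energy_1(wp, dlo) + wall_energy_1(wp, dhi);
      F[3 * i + 2] += -wall_dudd_1(wp, dlo, cp.sigma) +
                      wall_dudd_1(wp, dhi, cp.sigma);
    }
  }
  return U;
}

static ChainParams chain_params_from(List pp) {
  ChainParams cp;
  cp.sigma = as<double>(pp["sigma"]);
  cp.eps = as<double>(pp["eps"]);
  cp.kfene = as<double>(pp["k"]);
  cp.R0 = as<double>(pp["R0"]);
  cp.eps_bend = as<double>(pp["eps_bend"]);
  return cp;
}

static WallParams wall_params_from(List wp_list, NumericVector& keepalive) {
  WallParams wp;
  wp.on = as<bool>(wp_list["on"]);
  wp.Lz = as<double>(wp_list["Lz"]);
  wp.w = as<double>(wp_list["w"]);
  wp.kappa = as<double>(wp_list["kappa"]);
  wp.cutoff = as<double>(wp_list["cutoff"]);
  keepalive = as<NumericVector>(wp_list["etab"]);
  wp.etab = keepalive.begin();
  wp.ne = keepalive.size();
  return wp;
}

// [[Rcpp::export]]
List cpp_chain_energy_forces(NumericMatrix pos, List pp, List wp_list) {
  int N = pos.nrow();
  std::vector<double> x(N), y(N), z(N), F(3 * N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
  }
  ChainParams cp = chain_params_from(pp);
  NumericVector keep;
  WallParams wp = wall_params_from(wp_list, keep);
  double U = chain_forces(x.data(), y.data(), z.data(), N, cp, wp, F.data(),
                          0);
  NumericMatrix Fm(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) Fm(i, k) = F[3 * i + k];
  return List::create(_["energy"] = U, _["forces"] = Fm);
}

// Velocity-Verlet substeps for the chain between two MPCD collisions. Wall
// crossings are resolved by the same SRR rule as for the solvent (the wall
// excluded volume of the monomers). Positions are NOT wrapped in x,y so the
// chain stays whole; callers wrap only for cell assignment.
static void md_substeps(std::vector<double>& x, std::vector<double>& y,
                        std::vector<double>& z, std::vector<double>& vx,
                        std::vector<double>& vy, std::vector<double>& vz,
                        int N, int n_sub, double dt, double M,
                        const ChainParams& cp, const WallParams& wp,
                        bool walls, double kT, double* wall_dp, int step0) {
  std::vector<double> F(3 * N);
  chain_forces(x.data(), y.data(), z.data(), N, cp, wp, F.data(), step0);
  for (int s = 0; s < n_sub; ++s) {
    for (int i = 0; i < N; ++i) {
      vx[i] += 0.5 * dt * F[3 * i + 0] / M;
      vy[i] += 0.5 * dt * F[3 * i + 1] / M;
      vz[i] += 0.5 * dt * F[3 * i + 2] / M;
      double r[3] = {x[i], y[i], z[i]};
      double v[3] = {vx[i], vy[i], vz[i]};
      if (walls) {
        drift_with_walls(r, v, dt, wp.Lz, kT, M, wall_dp, nullptr);
      } else {
        r[0] += v[0] * dt; r[1] += v[1] * dt; r[2] += v[2] * dt;
      }
      x[i] = r[0]; y[i] = r[1]; z[i] = r[2];
      vx[i] = v[0]; vy[i] = v[1]; vz[i] = v[2];
    }
    chain_forces(x.data(), y.data(), z.data(), N, cp, wp, F.data(),
                 step0 + s);
    for (int i = 0; i < N; ++i) {
      vx[i] += 0.5 * dt * F[3 * i + 0] / M;
      vy[i] += 0.5 * dt * F[3 * i + 1] / M;
      vz[i] += 0.5 * dt * F[3 * i + 2] / M;
    }
  }
}

// [[Rcpp::export]]
List cpp_md_substeps(NumericMatrix pos, NumericMatrix vel, int n_sub,
                     double dt, double M, List pp, List wp_list, bool walls,
                     double kT) {
  int N = pos.nrow();
  std::vector<double> x(N), y(N), z(N), vx(N), vy(N), vz(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  ChainParams cp = chain_params_from(pp);
  NumericVector keep;
  WallParams wp = wall_params_from(wp_list, keep);
  double wall_dp[3] = {0, 0, 0};
  md_substeps(x, y, z, vx, vy, vz, N, n_sub, dt, M, cp, wp, walls, kT,
              wall_dp, 0);
  NumericMatrix p(N, 3), v(N, 3);
  std::vector<double> F(3 * N);
  double U = chain_forces(x.data(), y.data(), z.data(), N, cp, wp, F.data(),
                          n_sub);
  double ke = 0;
  for (int i = 0; i < N; ++i) {
    p(i, 0) = x[i]; p(i, 1) = y[i]; p(i, 2) = z[i];
    v(i, 0) = vx[i]; v(i, 1) = vy[i]; v(i, 2) = vz[i];
    ke += 0.5 * M * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
  }
  return List::create(_["pos"] = p, _["vel"] = v, _["potential"] = U,
                      _["kinetic"] = ke,
                      _["wall_dp"] = NumericVector::create(
                          wall_dp[0], wall_dp[1], wall_dp[2]));
}

// ------------------------------------------------- symmetric 3x3 eigenvalues

// ascending eigenvalues of a symmetric 3x3 matrix (trigonometric method)
static void eig3(const double A[3][3], double lam[3]) {
  double p1 = A[0][1] * A[0][1] + A[0][2] * A[0][2] + A[1][2] * A[1][2];
  double q = (A[0][0] + A[1][1] + A[2][2]) / 3.0;
  if (p1 < 1e-30) {
    lam[0] = A[0][0]; lam[1] = A[1][1]; lam[2] = A[2][2];
  } else {
    double p2 = (A[0][0] - q) * (A[0][0] - q) + (A[1][1] - q) * (A[1][1] - q) +
                (A[2][2] - q) * (A[2][2] - q) + 2 * p1;
    double p = std::sqrt(p2 / 6.0);
    double B[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        B[i][j] = (A[i][j] - (i == j ? q : 0.0)) / p;
    double detB = B[0][0] * (B[1][1] * B[2][2] - B[1][2] * B[2][1]) -
                  B[0][1] * (B[1][0] * B[2][2] - B[1][2] * B[2][0]) +
                  B[0][2] * (B[1][0] * B[2][1] - B[1][1] * B[2][0]);
    double r = detB / 2.0;
    r = std::min(1.0, std::max(-1.0, r));
    double phi = std::acos(r) / 3.0;
    lam[2] = q + 2 * p * std::cos(phi);
    lam[0] = q + 2 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    lam[1] = 3 * q - lam[0] - lam[2];
  }
  if (lam[0] > lam[1]) std::swap(lam[0], lam[1]);
  if (lam[1] > lam[2]) std::swap(lam[1], lam[2]);
  if (lam[0] > lam[1]) std::swap(lam[0], lam[1]);
}

static void gyration_rg_b(const double* x, const double* y, const double* z,
                          int N, double* rg, double* b, double* comz) {
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < N; ++i) { cx += x[i]; cy += y[i]; cz += z[i]; }
  cx /= N; cy /= N; cz /= N;
  double A[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  for (int i = 0; i < N; ++i) {
    double d[3] = {x[i] - cx, y[i] - cy, z[i] - cz};
    for (int a = 0; a < 3; ++a)
      for (int c = a; c < 3; ++c) A[a][c] += d[a] * d[c];
  }
  for (int a = 0; a < 3; ++a)
    for (int c = a; c < 3; ++c) { A[a][c] /= N; A[c][a] = A[a][c]; }
  double lam[3];
  eig3(A, lam);
  double tr = lam[0] + lam[1] + lam[2];
  *rg = std::sqrt(std::max(0.0, tr));
  *b = tr > 0 ? ((lam[2] - lam[1]) * (lam[2] - lam[1]) +
                 (lam[2] - lam[0]) * (lam[2] - lam[0]) +
                 (lam[1] - lam[0]) * (lam[1] - lam[0])) /
                    (2 * tr * tr)
              : NA_REAL;
  *comz = cz;
}

// ------------------------------------------------------------ MPCD run loop

// [[Rcpp::export]]
List cpp_run_mpcd(NumericMatrix spos_in, NumericMatrix svel_in,
                  Nullable<NumericMatrix> mpos_in,
                  Nullable<NumericMatrix> mvel_in, double Lx, double Ly,
                  double Lz, double alpha_deg, double dt_c, double kT,
                  bool thermostat, NumericVector fx_grid, List pp,
                  List wp_list, double M, int n_sub, double dt_md,
                  int nsteps, int sample_stride, int nbins_fluid,
                  int traj_stride, double rho) {
  NumericMatrix spos = clone(spos_in), svel = clone(svel_in);
  int ns = spos.nrow();
  bool has_chain = mpos_in.isNotNull();
  int N = 0;
  std::vector<double> x, y, z, vx, vy, vz;
  if (has_chain) {
    NumericMatrix mp(mpos_in.get()), mv(mvel_in.get());
    N = mp.nrow();
    x.resize(N); y.resize(N); z.resize(N);
    vx.resize(N); vy.resize(N); vz.resize(N);
    for (int i = 0; i < N; ++i) {
      x[i] = mp(i, 0); y[i] = mp(i, 1); z[i] = mp(i, 2);
      vx[i] = mv(i, 0); vy[i] = mv(i, 1); vz[i] = mv(i, 2);
    }
  }
  ChainParams cp = chain_params_from(pp);
  NumericVector keep;
  WallParams wp = wall_params_from(wp_list, keep);
  wp.Lz = Lz;

  int nx = (int)std::lround(Lx), ny = (int)std::lround(Ly),
      nz = (int)std::lround(Lz);
  int ncells = (nz + 2) * nx * ny;
  const double* fg = fx_grid.begin();
  int ng = fx_grid.size();

  // accumulators
  std::vector<double> bin_vx(nbins_fluid, 0.0), bin_v2y(nbins_fluid, 0.0),
      bin_v2z(nbins_fluid, 0.0);
  std::vector<long> bin_cnt(nbins_fluid, 0);
  int nbins_mono = (int)std::lround(Lz / 0.25);
  std::vector<long> mono_hist(nbins_mono, 0);
  double mono_vx_sum = 0.0;
  long mono_vx_n = 0;
  double wall_dp[3] = {0, 0, 0};
  double injected = 0.0;
  int nsamples = 0;
  std::vector<double> com_z, rg_s, b_s;
  int nf_max = traj_stride > 0 ? nsteps / traj_stride + 1 : 0;
  NumericVector fpos(has_chain && nf_max > 0 ? N * 3 * nf_max : 0);
  NumericVector fvel(has_chain && nf_max > 0 ? N * 3 * nf_max : 0);
  int nframes = 0;

  std::vector<double> all_mass(ns + N, 1.0);
  for (int i = 0; i < N; ++i) all_mass[ns + i] = M;
  std::vector<int> cellid(ns + N);
  std::vector<double> msum(ncells), px(ncells), py(ncells), pz(ncells),
      erel(ncells), scale(ncells), axes(3 * ncells), mvirt(ncells);
  std::vector<int> cnt(ncells);

  for (int step = 1; step <= nsteps; ++step) {
    // -- stream solvent with the body force and SRR walls
    for (int i = 0; i < ns; ++i) {
      double r[3] = {spos(i, 0), spos(i, 1), spos(i, 2)};
      double v[3] = {svel(i, 0), svel(i, 1), svel(i, 2)};
      double f0 = ng > 1 ? interp_profile(fg, ng, Lz, r[2]) : 0.0;
      v[0] += 0.5 * dt_c * f0;
      drift_with_walls(r, v, dt_c, Lz, kT, 1.0, wall_dp, nullptr);
      double f1 = ng > 1 ? interp_profile(fg, ng, Lz, r[2]) : 0.0;
      v[0] += 0.5 * dt_c * f1;
      injected += 0.5 * dt_c * (f0 + f1);
      r[0] = wrap(r[0], Lx);
      r[1] = wrap(r[1], Ly);
      for (int k = 0; k < 3; ++k) { spos(i, k) = r[k]; svel(i, k) = v[k]; }
    }
    // -- MD substeps for the chain (no body force on monomers)
    if (has_chain)
      md_substeps(x, y, z, vx, vy, vz, N, n_sub, dt_md, M, cp, wp, true, kT,
                  wall_dp, step);
    // -- collision on the randomly shifted grid, chain included
    double sh[3] = {unif_rand() - 0.5, unif_rand() - 0.5, unif_rand() - 0.5};
    for (int i = 0; i < ns; ++i) {
      int ix = (int)std::floor(spos(i, 0) - sh[0]);
      int iy = (int)std::floor(spos(i, 1) - sh[1]);
      ix = ((ix % nx) + nx) % nx;
      iy = ((iy % ny) + ny) % ny;
      int iz = (int)std::floor(spos(i, 2) + Lz / 2 - sh[2]);
      if (iz < -1) iz = -1;
      if (iz > nz) iz = nz;
      cellid[i] = (iz + 1) + (nz + 2) * (ix + nx * iy);
    }
    for (int i = 0; i < N; ++i) {
      int ix = (int)std::floor(wrap(x[i], Lx) - sh[0]);
      int iy = (int)std::floor(wrap(y[i], Ly) - sh[1]);
      ix = ((ix % nx) + nx) % nx;
      iy = ((iy % ny) + ny) % ny;
      int iz = (int)std::floor(z[i] + Lz / 2 - sh[2]);
      if (iz < -1) iz = -1;
      if (iz > nz) iz = nz;
      cellid[ns + i] = (iz + 1) + (nz + 2) * (ix + nx * iy);
    }
    std::fill(msum.begin(), msum.end(), 0.0);
    std::fill(px.begin(), px.end(), 0.0);
    std::fill(py.begin(), py.end(), 0.0);
    std::fill(pz.begin(), pz.end(), 0.0);
    std::fill(erel.begin(), erel.end(), 0.0);
    std::fill(mvirt.begin(), mvirt.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < ns + N; ++i) {
      int c = cellid[i];
      double m = all_mass[i];
      double vvx = i < ns ? svel(i, 0) : vx[i - ns];
      double vvy = i < ns ? svel(i, 1) : vy[i - ns];
      double vvz = i < ns ? svel(i, 2) : vz[i - ns];
      msum[c] += m; px[c] += m * vvx; py[c] += m * vvy; pz[c] += m * vvz;
      cnt[c]++;
    }
    // Virtual wall particles: a cell cut by a wall plane gets a virtual
    // member of mass rho x (volume outside the fluid) with Maxwellian
    // momentum at the (resting) wall temperature. It enters the cell
    // center-of-mass reference for rotation and thermostat, providing the
    // collisional stress the truncated cell would otherwise fail to pass to
    // the wall (no-slip); momentum exchanged this way is booked to the wall.
    {
      const int izs[4] = {-1, 0, nz - 1, nz};
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix)
          for (int q = 0; q < 4; ++q) {
            int iz = izs[q];
            if ((q == 2 && nz - 1 == 0) || (q == 3 && nz == 1)) continue;
            double ulo = iz + sh[2], uhi = iz + 1 + sh[2];
            double inside = std::min(uhi, Lz) - std::max(ulo, 0.0);
            if (inside < 0) inside = 0;
            double outside = 1.0 - inside;
            if (outside <= 0) continue;
            int c = (iz + 1) + (nz + 2) * (ix + nx * iy);
            double mv = rho * outside;
            double s = std::sqrt(mv * kT);
            mvirt[c] = mv;
            msum[c] += mv;
            px[c] += s * norm_rand();
            py[c] += s * norm_rand();
            pz[c] += s * norm_rand();
          }
    }
    for (int c = 0; c < ncells; ++c)
      if (cnt[c] > 0) rand_axis(&axes[3 * c]);
    for (int i = 0; i < ns + N; ++i) {
      int c = cellid[i];
      if (cnt[c] + (mvirt[c] > 0 ? 1 : 0) < 2) continue;
      double vvx = (i < ns ? svel(i, 0) : vx[i - ns]) - px[c] / msum[c];
      double vvy = (i < ns ? svel(i, 1) : vy[i - ns]) - py[c] / msum[c];
      double vvz = (i < ns ? svel(i, 2) : vz[i - ns]) - pz[c] / msum[c];
      erel[c] += 0.5 * all_mass[i] * (vvx * vvx + vvy * vvy + vvz * vvz);
    }
    for (int c = 0; c < ncells; ++c) {
      scale[c] = 1.0;
      int neff = cnt[c] + (mvirt[c] > 0 ? 1 : 0);
      if (thermostat && cnt[c] >= 1 && neff >= 2 && erel[c] > 0) {
        // dof of the real particles' kinetic energy relative to the cell
        // reference: n - 1 for a pure cell; with a virtual wall member the
        // reference is only partially tied to the real particles, giving
        // n - 1 + m_virt/m_sum effective translational dof
        double dof = cnt[c] - 1.0 + mvirt[c] / msum[c];
        if (dof <= 0) continue;
        double etarget = R::rgamma(1.5 * dof, kT);
        scale[c] = std::sqrt(etarget / erel[c]);
      }
    }
    double ca = std::cos(alpha_deg * M_PI / 180.0);
    double sa = std::sin(alpha_deg * M_PI / 180.0);
    for (int i = 0; i < ns + N; ++i) {
      int c = cellid[i];
      if (cnt[c] + (mvirt[c] > 0 ? 1 : 0) < 2) continue;
      double vcm[3] = {px[c] / msum[c], py[c] / msum[c], pz[c] / msum[c]};
      double v[3], vold[3];
      if (i < ns) {
        vold[0] = svel(i, 0); vold[1] = svel(i, 1); vold[2] = svel(i, 2);
      } else {
        vold[0] = vx[i - ns]; vold[1] = vy[i - ns]; vold[2] = vz[i - ns];
      }
      for (int k = 0; k < 3; ++k) v[k] = vold[k] - vcm[k];
      rotate(v, &axes[3 * c], ca, sa);
      for (int k = 0; k < 3; ++k) v[k] = vcm[k] + scale[c] * v[k];
      if (mvirt[c] > 0)  // momentum exchanged with the wall's virtual member
        for (int k = 0; k < 3; ++k)
          wall_dp[k] += all_mass[i] * (v[k] - vold[k]);
      if (i < ns) {
        svel(i, 0) = v[0]; svel(i, 1) = v[1]; svel(i, 2) = v[2];
      } else {
        vx[i - ns] = v[0]; vy[i - ns] = v[1]; vz[i - ns] = v[2];
      }
    }
    // -- sampling
    if (sample_stride > 0 && step % sample_stride == 0) {
      ++nsamples;
      for (int i = 0; i < ns; ++i) {
        int b = (int)((spos(i, 2) + Lz / 2) / Lz * nbins_fluid);
        if (b < 0) b = 0;
        if (b >= nbins_fluid) b = nbins_fluid - 1;
        bin_vx[b] += svel(i, 0);
        bin_v2y[b] += svel(i, 1) * svel(i, 1);
        bin_v2z[b] += svel(i, 2) * svel(i, 2);
        bin_cnt[b]++;
      }
      if (has_chain) {
        for (int i = 0; i < N; ++i) {
          int b = (int)((z[i] + Lz / 2) / Lz * nbins_mono);
          if (b < 0) b = 0;
          if (b >= nbins_mono) b = nbins_mono - 1;
          mono_hist[b]++;
          mono_vx_sum += vx[i];
          ++mono_vx_n;
        }
        double rg, bb, cz;
        gyration_rg_b(x.data(), y.data(), z.data(), N, &rg, &bb, &cz);
        com_z.push_back(cz);
        rg_s.push_back(rg);
        b_s.push_back(bb);
      }
    }
    if (has_chain && traj_stride > 0 && step % traj_stride == 0 &&
        nframes < nf_max) {
      for (int i = 0; i < N; ++i) {
        fpos[nframes * 3 * N + 0 * N + i] = x[i];
        fpos[nframes * 3 * N + 1 * N + i] = y[i];
        fpos[nframes * 3 * N + 2 * N + i] = z[i];
        fvel[nframes * 3 * N + 0 * N + i] = vx[i];
        fvel[nframes * 3 * N + 1 * N + i] = vy[i];
        fvel[nframes * 3 * N + 2 * N + i] = vz[i];
      }
      ++nframes;
    }
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix mpos_out(N, 3), mvel_out(N, 3);
  for (int i = 0; i < N; ++i) {
    mpos_out(i, 0) = x[i]; mpos_out(i, 1) = y[i]; mpos_out(i, 2) = z[i];
    mvel_out(i, 0) = vx[i]; mvel_out(i, 1) = vy[i]; mvel_out(i, 2) = vz[i];
  }
  return List::create(
      _["spos"] = spos, _["svel"] = svel, _["mpos"] = mpos_out,
      _["mvel"] = mvel_out,
      _["bin_vx"] = NumericVector(bin_vx.begin(), bin_vx.end()),
      _["bin_v2y"] = NumericVector(bin_v2y.begin(), bin_v2y.end()),
      _["bin_v2z"] = NumericVector(bin_v2z.begin(), bin_v2z.end()),
      _["bin_cnt"] = NumericVector(bin_cnt.begin(), bin_cnt.end()),
      _["mono_hist"] = NumericVector(mono_hist.begin(), mono_hist.end()),
      _["mono_vx_sum"] = mono_vx_sum, _["mono_vx_n"] = (double)mono_vx_n,
      _["com_z"] = com_z, _["rg"] = rg_s, _["b"] = b_s,
      _["frames_pos"] = fpos, _["frames_vel"] = fvel,
      _["n_frames"] = nframes, _["n_samples"] = nsamples,
      _["wall_dp"] = NumericVector::create(wall_dp[0], wall_dp[1],
                                           wall_dp[2]),
      _["injected_px"] = injected);
}

// ----------------------------------------------------- chain Monte Carlo

// Energy difference helpers for the Metropolis sampler: total energy is
// cheap at N = 40, but incremental moves keep long runs fast.

static inline double pair_wca(double r2, const ChainParams& cp) {
  double rc2 = std::pow(2.0, 1.0 / 3.0) * cp.sigma * cp.sigma;
  if (r2 >= rc2) return 0.0;
  double s2 = cp.sigma * cp.sigma / r2;
  double s6 = s2 * s2 * s2;
  return 4 * cp.eps * (s6 * s6 - s6) + cp.eps;
}

static inline double bond_fene(double r2, const ChainParams& cp) {
  double R02 = cp.R0 * cp.R0;
  if (r2 >= R02) return 1e12;  // reject overstretching proposals
  return -0.5 * cp.kfene * R02 * std::log1p(-r2 / R02);
}

static inline double angle_at(const std::vector<double>& x,
                              const std::vector<double>& y,
                              const std::vector<double>& z, int i) {
  double b1[3] = {x[i] - x[i - 1], y[i] - y[i - 1], z[i] - z[i - 1]};
  double b2[3] = {x[i + 1] - x[i], y[i + 1] - y[i], z[i + 1] - z[i]};
  double l1 = std::sqrt(b1[0] * b1[0] + b1[1] * b1[1] + b1[2] * b1[2]);
  double l2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  double c = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (l1 * l2);
  c = std::min(1.0, std::max(-1.0, c));
  return std::acos(c);
}

// energy of monomer i with all other monomers + its bonds + wall, used for
// single-bead displacement moves
static double site_energy(const std::vector<double>& x,
                          const std::vector<double>& y,
                          const std::vector<double>& z, int N, int i,
                          const ChainParams& cp, const WallParams& wp,
                          bool walls) {
  double U = 0.0;
  for (int j = 0; j < N; ++j) {
    if (j == i) continue;
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    U += pair_wca(r2, cp);
    if (j == i - 1 || j == i + 1) U += bond_fene(r2, cp);
  }
  if (cp.eps_bend > 0) {
    for (int v = i - 1; v <= i + 1; ++v)
      if (v >= 1 && v <= N - 2) {
        double th = angle_at(x, y, z, v);
        U += 0.5 * cp.eps_bend * th * th;
      }
  }
  if (walls && wp.w > 0) {
    double half = wp.Lz / 2;
    U += wall_energy_1(wp, half + z[i]) + wall_energy_1(wp, half - z[i]);
  }
  return U;
}

// [[Rcpp::export]]
List cpp_chain_mc(NumericMatrix pos0, int n_sweeps, int warmup_sweeps,
                  int sample_stride, List pp, List wp_list, bool walls,
                  double max_disp, double max_pivot, int frame_stride,
                  double kT) {
  int N = pos0.nrow();
  std::vector<double> x(N), y(N), z(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }
  ChainParams cp = chain_params_from(pp);
  NumericVector keep;
  WallParams wp = wall_params_from(wp_list, keep);
  double half = wp.Lz / 2;

  long acc_d = 0, try_d = 0, acc_p = 0, try_p = 0;
  std::vector<double> rg_s, b_s, comz_s, mabs_s;
  double th2_sum = 0.0;
  long th2_n = 0;
  std::vector<NumericMatrix> frames;
  std::vector<double> xn(N), yn(N), zn(N);

  int total = warmup_sweeps + n_sweeps;
  for (int sweep = 1; sweep <= total; ++sweep) {
    // single-bead displacements
    for (int m = 0; m < N; ++m) {
      int i = (int)(unif_rand() * N);
      if (i >= N) i = N - 1;
      double ox = x[i], oy = y[i], oz = z[i];
      double e0 = site_energy(x, y, z, N, i, cp, wp, walls);
      x[i] = ox + max_disp * (2 * unif_rand() - 1);
      y[i] = oy + max_disp * (2 * unif_rand() - 1);
      z[i] = oz + max_disp * (2 * unif_rand() - 1);
      ++try_d;
      bool ok = !(walls && (z[i] >= half || z[i] <= -half));
      if (ok) {
        double e1 = site_energy(x, y, z, N, i, cp, wp, walls);
        double dE = e1 - e0;
        ok = dE <= 0 || unif_rand() < std::exp(-dE / kT);
      }
      if (ok) {
        ++acc_d;
      } else {
        x[i] = ox; y[i] = oy; z[i] = oz;
      }
    }
    // one rigid z-translation of the whole chain: only the wall energy
    // changes, and the chain center equilibrates across the channel far
    // faster than by local moves
    if (walls) {
      double dz = 2.0 * (2 * unif_rand() - 1);
      bool ok = true;
      double e0 = 0, e1 = 0;
      for (int i = 0; i < N && ok; ++i) {
        double znew = z[i] + dz;
        if (znew >= half || znew <= -half) { ok = false; break; }
        if (wp.w > 0) {
          e0 += wall_energy_1(wp, half + z[i]) +
                wall_energy_1(wp, half - z[i]);
          e1 += wall_energy_1(wp, half + znew) +
                wall_energy_1(wp, half - znew);
        }
      }
      if (ok) {
        double dE = e1 - e0;
        ok = dE <= 0 || unif_rand() < std::exp(-dE / kT);
      }
      if (ok)
        for (int i = 0; i < N; ++i) z[i] += dz;
    }
    // two pivot moves: rotate the tail about a random interior vertex
    for (int m = 0; m < 2; ++m) {
      int j = 1 + (int)(unif_rand() * (N - 2));
      if (j > N - 2) j = N - 2;
      double axn[3];
      rand_axis(axn);
      double ang = max_pivot * (2 * unif_rand() - 1);
      double ca = std::cos(ang), sa = std::sin(ang);
      ++try_p;
      // old energy: bending at vertex j + WCA across the pivot + wall(tail)
      double e0 = 0, e1 = 0;
      if (cp.eps_bend > 0) {
        double th = angle_at(x, y, z, j);
        e0 += 0.5 * cp.eps_bend * th * th;
      }
      for (int a = 0; a <= j; ++a)
        for (int b = j + 1; b < N; ++b) {
          if (b - a == 1) continue;  // the pivot bond length is preserved
          double dx = x[a] - x[b], dy = y[a] - y[b], dz = z[a] - z[b];
          e0 += pair_wca(dx * dx + dy * dy + dz * dz, cp);
        }
      if (walls && wp.w > 0)
        for (int b = j + 1; b < N; ++b)
          e0 += wall_energy_1(wp, half + z[b]) +
                wall_energy_1(wp, half - z[b]);
      bool ok = true;
      for (int b = j + 1; b < N; ++b) {
        double v[3] = {x[b] - x[j], y[b] - y[j], z[b] - z[j]};
        rotate(v, axn, ca, sa);
        xn[b] = x[j] + v[0]; yn[b] = y[j] + v[1]; zn[b] = z[j] + v[2];
        if (walls && (zn[b] >= half || zn[b] <= -half)) { ok = false; break; }
      }
      if (ok) {
        if (cp.eps_bend > 0) {
          // angle at vertex j with the rotated next bead
          double b1[3] = {x[j] - x[j - 1], y[j] - y[j - 1], z[j] - z[j - 1]};
          double b2[3] = {xn[j + 1] - x[j], yn[j + 1] - y[j],
                          zn[j + 1] - z[j]};
          double l1 = std::sqrt(b1[0] * b1[0] + b1[1] * b1[1] +
                                b1[2] * b1[2]);
          double l2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] +
                                b2[2] * b2[2]);
          double c = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) /
                     (l1 * l2);
          c = std::min(1.0, std::max(-1.0, c));
          double th = std::acos(c);
          e1 += 0.5 * cp.eps_bend * th * th;
        }
        for (int a = 0; a <= j && ok; ++a)
          for (int b = j + 1; b < N; ++b) {
            if (b - a == 1) continue;
            double dx = x[a] - xn[b], dy = y[a] - yn[b], dz = z[a] - zn[b];
            e1 += pair_wca(dx * dx + dy * dy + dz * dz, cp);
            if (e1 - e0 > 200) { ok = false; break; }
          }
        if (ok && walls && wp.w > 0)
          for (int b = j + 1; b < N; ++b)
            e1 += wall_energy_1(wp, half + zn[b]) +
                  wall_energy_1(wp, half - zn[b]);
        if (ok) {
          double dE = e1 - e0;
          ok = dE <= 0 || unif_rand() < std::exp(-dE / kT);
        }
      }
      if (ok) {
        ++acc_p;
        for (int b = j + 1; b < N; ++b) {
          x[b] = xn[b]; y[b] = yn[b]; z[b] = zn[b];
        }
      }
    }
    if (sweep > warmup_sweeps) {
      int s = sweep - warmup_sweeps;
      if (s % sample_stride == 0) {
        double rg, bb, cz;
        gyration_rg_b(x.data(), y.data(), z.data(), N, &rg, &bb, &cz);
        rg_s.push_back(rg);
        b_s.push_back(bb);
        comz_s.push_back(cz);
        double mabs = 0;
        for (int i = 0; i < N; ++i) mabs += std::fabs(z[i]);
        mabs_s.push_back(mabs / N);
        for (int i = 1; i < N - 1; ++i) {
          double th = angle_at(x, y, z, i);
          th2_sum += th * th;
          ++th2_n;
        }
        if (frame_stride > 0 && (s / sample_stride) % frame_stride == 0) {
          NumericMatrix fr(N, 3);
          for (int i = 0; i < N; ++i) {
            fr(i, 0) = x[i]; fr(i, 1) = y[i]; fr(i, 2) = z[i];
          }
          frames.push_back(fr);
        }
      }
    }
    if (sweep % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix posf(N, 3);
  for (int i = 0; i < N; ++i) {
    posf(i, 0) = x[i]; posf(i, 1) = y[i]; posf(i, 2) = z[i];
  }
  return List::create(
      _["rg"] = rg_s, _["b"] = b_s, _["com_z"] = comz_s,
      _["mono_absz"] = mabs_s,
      _["theta2_mean"] = th2_n > 0 ? th2_sum / th2_n : NA_REAL,
      _["acc_disp"] = (double)acc_d / std::max(1L, try_d),
      _["acc_pivot"] = (double)acc_p / std::max(1L, try_p),
      _["frames"] = wrap(frames), _["pos"] = posf);
}
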