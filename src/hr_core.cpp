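#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Hindmarsh-Rose right-hand side:
//   dx/dt = y - a x^3 + b x^2 - z + I
//   dy/dt = c - d x^2 - y
//   dz/dt = r (s (x - x_rest) - z)
struct HRPars {
  double a, b, c, d, s, xr, r, I;
};

static inline HRPars pars_from(const NumericVector& p) {
  HRPars q;
  q.a = p["a"]; q.b = p["b"]; q.c = p["c"]; q.d = p["d"];
  q.s = p["s"]; q.xr = p["x_rest"]; q.r = p["r"]; q.I = p["I"];
  return q;
}

static inline void hr_rhs(double x, double y, double z, const HRPars& p,
                          double& dx, double& dy, double& dz) {
  dx = y - p.a * x * x * x + p.b * x * x - z + p.I;
  dy = p.c - p.d * x * x - y;
  dz = p.r * (p.s * (x - p.xr) - z);
}

// Parameter drift along a straight segment in the (I, r) plane.
// profile: 0 none, 1 linear over [0, T], 2 exponential approach with
// time constant T/3 (fraction f = 1 - exp(-3 t / T)).
struct Drift {
  int profile;
  double T, I0, r0, I1, r1;
};

static inline void apply_drift(HRPars& p, const Drift& d, double t) {
  if (d.profile == 0) return;
  double f;
  if (d.profile == 1) {
    f = t >= d.T ? 1.0 : t / d.T;
  } else {
    f = 1.0 - std::exp(-3.0 * t / d.T);
  }
  p.I = d.I0 + f * (d.I1 - d.I0);
  p.r = d.r0 + f * (d.r1 - d.r0);
}

static inline void rk4_step(double& x, double& y, double& z, double t,
                            double dt, HRPars p, const Drift& drift) {
  double k1x, k1y, k1z, k2x, k2y, k2z, k3x, k3y, k3z, k4x, k4y, k4z;
  HRPars pm = p, pe = p;
  apply_drift(p, drift, t);
  apply_drift(pm, drift, t + 0.5 * dt);
  apply_drift(pe, drift, t + dt);
  hr_rhs(x, y, z, p, k1x, k1y, k1z);
  hr_rhs(x + 0.5 * dt * k1x, y + 0.5 * dt * k1y, z + 0.5 * dt * k1z, pm,
         k2x, k2y, k2z);
  hr_rhs(x + 0.5 * dt * k2x, y + 0.5 * dt * k2y, z + 0.5 * dt * k2z, pm,
         k3x, k3y, k3z);
  hr_rhs(x + dt * k3x, y + dt * k3y, z + dt * k3z, pe, k4x, k4y, k4z);
  x += dt / 6.0 * (k1x + 2 * k2x + 2 * k3x + k4x);
  y += dt / 6.0 * (k1y + 2 * k2y + 2 * k3y + k4y);
  z += dt / 6.0 * (k1z + 2 * k2z + 2 * k3z + k4z);
}

// Euler-Maruyama step; additive white noise of intensity sigma on the
// chosen equation (1 = dy/dt, 0 = dx/dt).
static inline void em_step(double& x, double& y, double& z, double t,
                           double dt, HRPars p, const Drift& drift,
                           double sigma, int noise_on_y) {
  double dx, dy, dz;
  apply_drift(p, drift, t);
  hr_rhs(x, y, z, p, dx, dy, dz);
  double w = sigma * std::sqrt(dt) * norm_rand();
  x += dt * dx + (noise_on_y ? 0.0 : w);
  y += dt * dy + (noise_on_y ? w : 0.0);
  z += dt * dz;
}

static inline bool bad(double x, double y, double z) {
  return !std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z) ||
         std::fabs(x) > 1e6 || std::fabs(y) > 1e8 || std::fabs(z) > 1e8;
}

static Drift drift_from(const NumericVector& dv) {
  Drift d;
  d.profile = (int)dv[0];
  d.T = dv[1]; d.I0 = dv[2]; d.r0 = dv[3]; d.I1 = dv[4]; d.r1 = dv[5];
  return d;
}

// [[Rcpp::export]]
List hr_traj_cpp(NumericVector pars, NumericVector init, double t_end,
                 double dt, double sigma, int noise_on_y,
                 NumericVector drift) {
  HRPars p = pars_from(pars);
  Drift dr = drift_from(drift);
  int n = (int)std::floor(t_end / dt + 0.5) + 1;
  NumericVector tv(n), xv(n), yv(n), zv(n);
  double x = init[0], y = init[1], z = init[2];
  double blow = NA_REAL;
  int i = 0;
  for (; i < n; ++i) {
    double t = i * dt;
    tv[i] = t; xv[i] = x; yv[i] = y; zv[i] = z;
    if (i == n - 1) break;
    if (sigma > 0.0)
      em_step(x, y, z, t, dt, p, dr, sigma, noise_on_y);
    else
      rk4_step(x, y, z, t, dt, p, dr);
    if (bad(x, y, z)) { blow = (i + 1) * dt; i++; break; }
  }
  int kept = std::min(i + 1, n);
  return List::create(_["t"] = tv[Range(0, kept - 1)],
                      _["x"] = xv[Range(0, kept - 1)],
                      _["y"] = yv[Range(0, kept - 1)],
                      _["z"] = zv[Range(0, kept - 1)],
                      _["blowup_time"] = blow);
}

// Local-maximum detection with quadratic (three-point) refinement of the
// peak time, threshold on x and a refractory floor between accepted peaks.
// Shared by the trajectory-based detector and the streaming simulator.
static void push_spike(std::vector<double>& spikes, double tm1, double dt,
                       double xm1, double x0, double xp1, double threshold,
                       double min_sep) {
  if (x0 < threshold) return;
  double denom = xm1 - 2.0 * x0 + xp1;
  double off = 0.0;
  if (denom < 0.0) off = 0.5 * (xm1 - xp1) / denom;
  if (off < -0.5) off = -0.5;
  if (off > 0.5) off = 0.5;
  double tp = tm1 + dt + off * dt;
  if (!spikes.empty() && tp - spikes.back() < min_sep) return;
  spikes.push_back(tp);
}

// [[Rcpp::export]]
NumericVector detect_spikes_cpp(NumericVector t, NumericVector x,
                                double threshold, double min_sep) {
  int n = t.size();
  std::vector<double> spikes;
  for (int i = 1; i + 1 < n; ++i) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) {
      push_spike(spikes, t[i - 1], t[i] - t[i - 1], x[i - 1], x[i],
                 x[i + 1], threshold, min_sep);
    }
  }
  return wrap(spikes);
}

// Integrate and collect spike times without storing the trajectory.
// Stops at t_end or when max_spikes spikes have been collected.
// [[Rcpp::export]]
List hr_spikes_cpp(NumericVector pars, NumericVector init, double t_end,
                   double dt, double sigma, int noise_on_y,
                   double threshold, double min_sep, int max_spikes,
                   NumericVector drift) {
  HRPars p = pars_from(pars);
  Drift dr = drift_from(drift);
  long nstep = (long)std::floor(t_end / dt + 0.5);
  std::vector<double> spikes;
  spikes.reserve(max_spikes > 0 ? max_spikes : 1024);
  double x = init[0], y = init[1], z = init[2];
  double xm1 = x, x0 = x;
  double blow = NA_REAL, t = 0.0;
  for (long i = 0; i < nstep; ++i) {
    t = i * dt;
    if (sigma > 0.0)
      em_step(x, y, z, t, dt, p, dr, sigma, noise_on_y);
    else
      rk4_step(x, y, z, t, dt, p, dr);
    if (bad(x, y, z)) { blow = t + dt; break; }
    // x is now the value at t + dt; test the previous sample for a maximum
    if (i >= 1 && x0 > xm1 && x0 >= x) {
      push_spike(spikes, t - dt, dt, xm1, x0, x, threshold, min_sep);
      if (max_spikes > 0 && (int)spikes.size() >= max_spikes) {
        t += dt; break;
      }
    }
    xm1 = x0; x0 = x;
    t += dt;
  }
  return List::create(_["spike_times"] = wrap(spikes),
                      _["end_state"] = NumericVector::create(x, y, z),
                      _["t_reached"] = t,
                      _["blowup_time"] = blow);
}

// Analytic Jacobian of the HR flow at (x, ., .).
static inline void hr_jac_mul(double x, const HRPars& p, double vx,
                              double vy, double vz, double& ox, double& oy,
                              double& oz) {
  ox = (-3.0 * p.a * x * x + 2.0 * p.b * x) * vx + vy - vz;
  oy = -2.0 * p.d * x * vx - vy;
  oz = p.r * p.s * vx - p.r * vz;
}

// One RK4 step of state + tangent vector (variational equation).
static inline void rk4_tangent_step(double& x, double& y, double& z,
                                    double& vx, double& vy, double& vz,
                                    double dt, const HRPars& p) {
  double k1x, k1y, k1z, k2x, k2y, k2z, k3x, k3y, k3z, k4x, k4y, k4z;
  double l1x, l1y, l1z, l2x, l2y, l2z, l3x, l3y, l3z, l4x, l4y, l4z;
  hr_rhs(x, y, z, p, k1x, k1y, k1z);
  hr_jac_mul(x, p, vx, vy, vz, l1x, l1y, l1z);
  double x2 = x + 0.5 * dt * k1x, y2 = y + 0.5 * dt * k1y,
         z2 = z + 0.5 * dt * k1z;
  hr_rhs(x2, y2, z2, p, k2x, k2y, k2z);
  hr_jac_mul(x2, p, vx + 0.5 * dt * l1x, vy + 0.5 * dt * l1y,
             vz + 0.5 * dt * l1z, l2x, l2y, l2z);
  double x3 = x + 0.5 * dt * k2x, y3 = y + 0.5 * dt * k2y,
         z3 = z + 0.5 * dt * k2z;
  hr_rhs(x3, y3, z3, p, k3x, k3y, k3z);
  hr_jac_mul(x3, p, vx + 0.5 * dt * l2x, vy + 0.5 * dt * l2y,
             vz + 0.5 * dt * l2z, l3x, l3y, l3z);
  double x4 = x + dt * k3x, y4 = y + dt * k3y, z4 = z + dt * k3z;
  hr_rhs(x4, y4, z4, p, k4x, k4y, k4z);
  hr_jac_mul(x4, p, vx + dt * l3x, vy + dt * l3y, vz + dt * l3z,
             l4x, l4y, l4z);
  x += dt / 6.0 * (k1x + 2 * k2x + 2 * k3x + k4x);
  y += dt / 6.0 * (k1y + 2 * k2y + 2 * k3y + k4y);
  z += dt / 6.0 * (k1z + 2 * k2z + 2 * k3z + k4z);
  vx += dt / 6.0 * (l1x + 2 * l2x + 2 * l3x + l4x);
  vy += dt / 6.0 * (l1y + 2 * l2y + 2 * l3y + l4y);
  vz += dt / 6.0 * (l1z + 2 * l2z + 2 * l3z + l4z);
}

// Benettin largest Lyapunov exponent: evolve state + unit tangent vector,
// renormalize every renorm_interval, average the log stretch factors over
// t_average after a transient of t_transient.
// [[Rcpp::export]]
List hr_lle_cpp(NumericVector pars, NumericVector init, double dt,
                double t_transient, double t_average,
                double renorm_interval, NumericVector tangent0) {
  HRPars p = pars_from(pars);
  double x = init[0], y = init[1], z = init[2];
  double vx = tangent0[0], vy = tangent0[1], vz = tangent0[2];
  double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
  vx /= vn; vy /= vn; vz /= vn;
  long n_tr = (long)std::floor(t_transient / dt + 0.5);
  for (long i = 0; i < n_tr; ++i) {
    rk4_step(x, y, z, i * dt, dt, p, Drift{0, 0, 0, 0, 0, 0});
    if (bad(x, y, z))
      return List::create(_["lle"] = NA_REAL,
                          _["end_state"] = NumericVector::create(x, y, z),
                          _["blowup_time"] = (i + 1) * dt);
  }
  long steps_per_renorm = (long)std::floor(renorm_interval / dt + 0.5);
  if (steps_per_renorm < 1) steps_per_renorm = 1;
  long n_renorm = (long)std::floor(t_average / (steps_per_renorm * dt));
  double sum_log = 0.0;
  for (long k = 0; k < n_renorm; ++k) {
    for (long i = 0; i < steps_per_renorm; ++i) {
      rk4_tangent_step(x, y, z, vx, vy, vz, dt, p);
      if (bad(x, y, z))
        return List::create(_["lle"] = NA_REAL,
                            _["end_state"] = NumericVector::create(x, y, z),
                            _["blowup_time"] = t_transient +
                              (k * steps_per_renorm + i + 1) * dt);
    }
    double nrm = std::sqrt(vx * vx + vy * vy + vz * vz);
    sum_log += std::log(nrm);
    vx /= nrm; vy /= nrm; vz /= nrm;
  }
  double lle = sum_log / (n_renorm * steps_per_renorm * dt);
  return List::create(_["lle"] = lle,
                      _["end_state"] = NumericVector::create(x, y, z),
                      _["blowup_time"] = NA_REAL);
}
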