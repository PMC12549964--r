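#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Velocity-Verlet integration of softened pairwise Coulomb repulsion
// (Plummer form: U = k q_i q_j / sqrt(r^2 + eps^2)), starting from rest.
// Internal units: Angstrom, femtosecond, amu; kConst in amu*A^3/fs^2.
// Terminates at maxTime or when the potential energy falls below
// stopPotentialFrac of the (conserved) total energy.

static double accelerations(const std::vector<double> &x,
                            const std::vector<double> &y,
                            const std::vector<double> &z,
                            const std::vector<double> &q,
                            const std::vector<double> &minv,
                            double kConst, double soft2,
                            std::vector<double> &ax,
                            std::vector<double> &ay,
                            std::vector<double> &az) {
  const int n = (int)x.size();
  std::fill(ax.begin(), ax.end(), 0.0);
  std::fill(ay.begin(), ay.end(), 0.0);
  std::fill(az.begin(), az.end(), 0.0);
  double pe = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i], qi = q[i];
    double fxi = 0.0, fyi = 0.0, fzi = 0.0;
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
      const double r2 = dx * dx + dy * dy + dz * dz + soft2;
      const double rinv = 1.0 / std::sqrt(r2);
      const double kqq = kConst * qi * q[j];
      pe += kqq * rinv;
      const double fmag = kqq * rinv * rinv * rinv; // k q q / (r^2+e^2)^{3/2}
      const double fx = fmag * dx, fy = fmag * dy, fz = fmag * dz;
      fxi += fx; fyi += fy; fzi += fz;
      ax[j] -= fx * minv[j];
      ay[j] -= fy * minv[j];
      az[j] -= fz * minv[j];
    }
    ax[i] += fxi * minv[i];
    ay[i] += fyi * minv[i];
    az[i] += fzi * minv[i];
  }
  return pe;
}

// [[Rcpp::export(name = ".explodeVerlet")]]
List explodeVerlet(NumericMatrix pos, NumericVector charge,
                   NumericVector mass, double dt, double maxTime,
                   double softening, double kConst,
                   double stopPotentialFrac) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), q(n), minv(n);
  std::vector<double> vx(n, 0.0), vy(n, 0.0), vz(n, 0.0);
  std::vector<double> ax(n), ay(n), az(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    q[i] = charge[i]; minv[i] = 1.0 / mass[i];
  }
  const double soft2 = softening * softening;
  double pe = accelerations(x, y, z, q, minv, kConst, soft2, ax, ay, az);
  const double e0 = pe; // starts from rest: total energy = initial PE
  // Adaptive stepping: dt is the base step at t = 0; later steps scale as
  // 1/sqrt(max |a|) relative to the initial acceleration (the standard
  // collisional-N-body criterion), capped at dtGrowLimit * dt. The step
  // never drops below dt, and energy drift is monitored throughout.
  const double dtGrowLimit = 64.0;
  double a0max = 0.0;
  for (int i = 0; i < n; ++i) {
    const double a2 = ax[i] * ax[i] + ay[i] * ay[i] + az[i] * az[i];
    if (a2 > a0max) a0max = a2;
  }
  a0max = std::sqrt(a0max);
  const double accConst = dt * std::sqrt(a0max);
  double t = 0.0;
  int step = 0;
  double maxDrift = 0.0;
  while (t < maxTime) {
    double amax = 0.0;
    for (int i = 0; i < n; ++i) {
      const double a2 = ax[i] * ax[i] + ay[i] * ay[i] + az[i] * az[i];
      if (a2 > amax) amax = a2;
    }
    amax = std::sqrt(amax);
    double h = (amax > 0.0) ? accConst / std::sqrt(amax)
                            : dtGrowLimit * dt;
    if (h < dt) h = dt;
    if (h > dtGrowLimit * dt) h = dtGrowLimit * dt;
    if (t + h > maxTime) h = maxTime - t;
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * h * ax[i];
      vy[i] += 0.5 * h * ay[i];
      vz[i] += 0.5 * h * az[i];
      x[i] += h * vx[i];
      y[i] += h * vy[i];
      z[i] += h * vz[i];
    }
    pe = accelerations(x, y, z, q, minv, kConst, soft2, ax, ay, az);
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * h * ax[i];
      vy[i] += 0.5 * h * ay[i];
      vz[i] += 0.5 * h * az[i];
      ke += 0.5 / minv[i] *
            (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    }
    t += h;
    ++step;
    const double drift = std::fabs((ke + pe - e0) / e0);
    if (drift > maxDrift) maxDrift = drift;
    if (pe < stopPotentialFrac * e0) break;
  }
  NumericMatrix vel(n, 3);
  NumericVector mom(3);
  for (int i = 0; i < n; ++i) {
    vel(i, 0) = vx[i]; vel(i, 1) = vy[i]; vel(i, 2) = vz[i];
    mom[0] += vx[i] / minv[i];
    mom[1] += vy[i] / minv[i];
    mom[2] += vz[i] / minv[i];
  }
  double ke = 0.0;
  for (int i = 0; i < n; ++i)
    ke += 0.5 / minv[i] *
          (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
  return List::create(
    _["velocities"] = vel,
    _["kineticEnergy"] = ke,
    _["potentialEnergy"] = pe,
    _["totalEnergy0"] = e0,
    _["maxEnergyDrift"] = maxDrift,
    _["momentum"] = mom,
    _["stepsRun"] = step,
    _["timeRun"] = t);
}
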