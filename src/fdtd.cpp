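// Explicit time-domain solver for the 2D scalar wave equation
//   d2u/dt2 = (c0/n)^2 laplacian(u)
// on a regular grid with sponge (exponential-damping) absorbing boundary
// layers, optional absorbing screens (aperture stops), and a soft
// monochromatic line source. Units: the wavelength is the length unit and
// c0 = 1, so one optical period is 1 time unit.
//
// The update is the standard 5-point leapfrog
//   u_next = 2 u - u_prev + (C/n)^2 * lap(u),  C = c0 dt / dx
// with the damping factor applied to both stored time levels, fused into a
// single pass per step; the three time levels rotate by pointer swap.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List fdtd_run_cpp(NumericMatrix inv_n2,     // 1/n^2 per cell (nz x nx)
                  NumericMatrix damp,       // damping factor per cell (<= 1)
                  double courant,           // c0 * dt / dx
                  int n_steps,
                  int src_row,              // 1-based row of the line source
                  NumericVector src_amp,    // envelope along x (length nx)
                  NumericVector src_phase,  // phase along x (radians)
                  double omega_dt,          // omega * dt
                  int avg_start,            // 1-based step to start <u^2>
                  int snapshot_every,       // 0 = no snapshots
                  int src_stop,             // 0 = source always on
                  int ramp_steps,           // smooth on/off ramp length
                  int energy_trace) {       // record total field energy
  const int nz = inv_n2.nrow(), nx = inv_n2.ncol();
  if (damp.nrow() != nz || damp.ncol() != nx)
    stop("damp must match the grid");
  if (src_row < 2 || src_row > nz - 1) stop("src_row outside the interior");
  if (src_amp.size() != nx || src_phase.size() != nx)
    stop("source vectors must have length nx");
  if (courant <= 0 || courant > 1.0 / std::sqrt(2.0) + 1e-9)
    stop("unstable step: need 0 < courant <= 1/sqrt(2)");
  if (avg_start < 1 || avg_start > n_steps) stop("invalid avg_start");

  const int ncell = nz * nx;
  std::vector<double> bufA(ncell, 0.0), bufB(ncell, 0.0), bufC(ncell, 0.0);
  double *u = bufA.data(), *up = bufB.data(), *un = bufC.data();
  const double *in2 = REAL(inv_n2), *dp = REAL(damp);
  NumericMatrix acc(nz, nx);
  double *ac = REAL(acc);
  const double c2 = courant * courant;
  // total field energy (kinetic + gradient) per step, optional
  NumericVector trace(energy_trace ? n_steps : 0);
  List snaps;

  for (int t = 1; t <= n_steps; ++t) {
    for (int j = 1; j < nx - 1; ++j) {
      const int off = j * nz;
      const double *uc = u + off, *ul = u + off - nz, *ur = u + off + nz;
      const double *i2 = in2 + off, *dd = dp + off;
      double *pv = up + off, *nn = un + off;
      for (int i = 1; i < nz - 1; ++i) {
        const double lap =
          uc[i - 1] + uc[i + 1] + ul[i] + ur[i] - 4.0 * uc[i];
        nn[i] = (2.0 * uc[i] - pv[i] + c2 * i2[i] * lap) * dd[i];
        pv[i] = uc[i] * dd[i];   // damp the level that becomes u_prev
      }
    }
    // soft source along one row, with raised-cosine on/off ramps so that
    // switching injects no broadband transient
    if (src_stop <= 0 || t <= src_stop) {
      double env = 1.0;
      if (ramp_steps > 0 && t < ramp_steps)
        env = 0.5 * (1.0 - std::cos(M_PI * t / ramp_steps));
      if (ramp_steps > 0 && src_stop > 0 && t > src_stop - ramp_steps)
        env *= 0.5 * (1.0 - std::cos(M_PI * (src_stop - t) / ramp_steps));
      const double ph = omega_dt * t;
      double *row = un + (src_row - 1);
      for (int j = 0; j < nx; ++j) {
        if (src_amp[j] != 0.0)
          row[j * nz] += env * src_amp[j] * std::sin(ph - src_phase[j]);
      }
    }
    // rotate time levels: `up` already holds the damped former u (written
    // in place during the pass), `un` holds the new field, and the stale
    // `u` buffer becomes the next scratch buffer
    double *tmp = u; u = un; un = tmp;

    if (energy_trace) {
      // E = sum[(du/dt)^2 + (c0/n)^2 |grad u|^2] in grid units; `up` holds
      // the damped previous level, exact in the interior where damp = 1
      const double inv_dt2 = 1.0 / (courant * courant);
      double ke = 0.0, pe = 0.0;
      for (int j = 1; j < nx - 1; ++j) {
        const int off = j * nz;
        const double *uc = u + off, *pv = up + off;
        const double *ur = u + off + nz, *i2 = in2 + off;
        for (int i = 1; i < nz - 1; ++i) {
          const double du = uc[i] - pv[i];
          ke += du * du;
          const double gz = uc[i + 1] - uc[i], gx = ur[i] - uc[i];
          pe += i2[i] * (gz * gz + gx * gx);
        }
      }
      trace[t - 1] = ke * inv_dt2 + pe;
    }
    if (t >= avg_start) {
      for (int k = 0; k < ncell; ++k) ac[k] += u[k] * u[k];
    }
    if (snapshot_every > 0 && t % snapshot_every == 0) {
      NumericMatrix s(nz, nx);
      std::copy(u, u + ncell, REAL(s));
      snaps.push_back(s);
    }
  }

  const double n_avg = n_steps - avg_start + 1;
  for (int k = 0; k < ncell; ++k) ac[k] /= n_avg;
  NumericMatrix ufinal(nz, nx);
  std::copy(u, u + ncell, REAL(ufinal));

  return List::create(_["intensity"] = acc, _["field"] = ufinal,
                      _["snapshots"] = snaps, _["trace"] = trace);
}
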