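#include <Rcpp.h>
using namespace Rcpp;

// Explicit finite-difference conduction solver on a cubic-voxel sub-grid:
//
//   rho * cp * dT/dt = div(kappa grad T) + qdot
//
// Face conductivities are harmonic means of the adjacent voxel
// conductivities; grid-edge faces are insulated (zero flux). Boundary
// conditions are applied per voxel after each step via a code array:
//   0 = none, 1 = floor clamp (T >= bc_clamp, metabolic regulation at
//   brain-facing edges), 2 = fixed Dirichlet (bc_fixed, faces open to room).
// The step is 0.9x the explicit stability limit dx^2*min(rho*cp)/(6*max(k)),
// sub-stepped so records land exactly on whole seconds. The grid maximum is
// recorded every second.

static inline double hmean(double a, double b) {
  return (a <= 0 || b <= 0) ? 0.0 : 2.0 * a * b / (a + b);
}

// [[Rcpp::export(rng = false)]]
List thermal_run_cpp(NumericVector T0, IntegerVector dims, double dx_m,
                     NumericVector rho, NumericVector cp, NumericVector kappa,
                     NumericVector qdot,       // W/m^3 while light is on
                     NumericMatrix schedule,   // cols: light_on, duration_s
                     IntegerVector bc, double bc_clamp, double bc_fixed,
                     double safety) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  if (T0.size() != nv || rho.size() != nv || cp.size() != nv ||
      kappa.size() != nv || qdot.size() != nv || bc.size() != nv)
    stop("thermal arrays do not match grid dims");

  std::vector<double> T(T0.begin(), T0.end());
  std::vector<double> Tn(nv);

  double min_rc = 1e300, max_k = 0.0;
  for (R_xlen_t i = 0; i < nv; ++i) {
    const double rc = rho[i] * cp[i];
    if (rc < min_rc) min_rc = rc;
    if (kappa[i] > max_k) max_k = kappa[i];
  }
  if (max_k <= 0) stop("all conductivities are zero");
  const double dt_stab = safety * dx_m * dx_m * min_rc / (6.0 * max_k);

  long total_sec = 0;
  for (int r = 0; r < schedule.nrow(); ++r)
    total_sec += (long)std::llround(schedule(r, 1));

  NumericVector max_trace(total_sec), t_out(total_sec), on_out(total_sec);
  const double inv_dx2 = 1.0 / (dx_m * dx_m);
  double t = 0.0;
  long row = 0;

  // enforce boundary conditions on the initial field too
  for (R_xlen_t i = 0; i < nv; ++i) {
    if (bc[i] == 1 && T[i] < bc_clamp) T[i] = bc_clamp;
    else if (bc[i] == 2) T[i] = bc_fixed;
  }

  for (int r = 0; r < schedule.nrow(); ++r) {
    const bool on = schedule(r, 0) != 0;
    const long secs = (long)std::llround(schedule(r, 1));
    for (long sec = 0; sec < secs; ++sec) {
      Rcpp::checkUserInterrupt();
      const int nsub = (int)std::ceil(1.0 / dt_stab);
      const double dt = 1.0 / nsub;
      for (int k = 0; k < nsub; ++k) {
        for (int iz = 0; iz < nz; ++iz) {
          for (int iy = 0; iy < ny; ++iy) {
            for (int ix = 0; ix < nx; ++ix) {
              const R_xlen_t v = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
              const double Tc = T[v], kc = kappa[v];
              double flux = 0.0;
              if (ix > 0) flux += hmean(kc, kappa[v - 1]) * (T[v - 1] - Tc);
              if (ix < nx - 1) flux += hmean(kc, kappa[v + 1]) * (T[v + 1] - Tc);
              if (iy > 0) flux += hmean(kc, kappa[v - nx]) * (T[v - nx] - Tc);
              if (iy < ny - 1) flux += hmean(kc, kappa[v + nx]) * (T[v + nx] - Tc);
              const R_xlen_t sz = (R_xlen_t)nx * ny;
              if (iz > 0) flux += hmean(kc, kappa[v - sz]) * (T[v - sz] - Tc);
              if (iz < nz - 1) flux += hmean(kc, kappa[v + sz]) * (T[v + sz] - Tc);
              const double src = on ? qdot[v] : 0.0;
              Tn[v] = Tc + dt * (flux * inv_dx2 + src) / (rho[v] * cp[v]);
            }
          }
        }
        for (R_xlen_t i = 0; i < nv; ++i) {
          double x = Tn[i];
          if (bc[i] == 1 && x < bc_clamp) x = bc_clamp;
          else if (bc[i] == 2) x = bc_fixed;
          if (!std::isfinite(x)) stop("non-finite temperature (CFL violation?)");
          T[i] = x;
        }
      }
      t += 1.0;
      double mx = -1e300;
      for (R_xlen_t i = 0; i < nv; ++i)
        if (T[i] > mx) mx = T[i];
      max_trace[row] = mx;
      t_out[row] = t;
      on_out[row] = on ? 1.0 : 0.0;
      ++row;
    }
  }

  return List::create(_["T"] = NumericVector(T.begin(), T.end()),
                      _["t"] = t_out, _["max_trace"] = max_trace,
                      _["light_on"] = on_out, _["dt_stability"] = dt_stab);
}
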