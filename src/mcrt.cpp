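#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// Monte Carlo photon-packet transport on a regular voxel grid.
//
// Track-length fluence estimator: every path segment of length l inside a
// voxel adds weight*l to that voxel's tally; dividing by voxel volume and
// packet count gives fluence rate per unit source power. Absorption is
// handled by implicit capture (weight *= albedo at each interaction) with
// Russian-roulette termination; refractive-index mismatches at voxel faces
// get unpolarized Fresnel reflection/refraction (optional). Grid edges are
// absorbing: escaping weight is tallied, never reflected.

static inline int idx3(int ix, int iy, int iz, int nx, int ny) {
  return ix + nx * (iy + ny * iz);
}

// unpolarized Fresnel reflectance; ci = |cos(incidence)|, n1 -> n2
static inline double fresnel_R(double ci, double n1, double n2) {
  const double eta = n1 / n2;
  const double st2 = eta * eta * (1.0 - ci * ci);
  if (st2 >= 1.0) return 1.0;  // total internal reflection
  const double ct = std::sqrt(1.0 - st2);
  const double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  const double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// rotate unit vector (ux,uy,uz) by deflection cosine ct and azimuth phi
static inline void scatter_dir(double& ux, double& uy, double& uz,
                               double ct, double phi) {
  const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  const double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    const double den = std::sqrt(1.0 - uz * uz);
    const double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    const double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    const double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  const double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// [[Rcpp::export(rng = false)]]
List mcrt_transport_cpp(NumericVector mua, NumericVector mus,
                        NumericVector gfac, NumericVector nref,
                        IntegerVector dims, NumericVector spacing,
                        NumericVector src_pos, NumericVector src_dir,
                        int src_type,  // 0 = isotropic point, 1 = pencil
                        double n_packets, double seed,
                        bool fresnel, double roulette_wmin,
                        double roulette_surv) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double Lx = nx * dx, Ly = ny * dy, Lz = nz * dz;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (mua.size() != nvox) stop("optics arrays do not match grid dims");
  NumericVector psi_raw(nvox);  // sum of weight * path length (cm)
  double escaped = 0.0, absorbed = 0.0, killed_rr = 0.0;
  const long np = (long)n_packets;
  const long max_events = 50000000L;  // guard against pathological loops

  for (long ip = 0; ip < np; ++ip) {
    if ((ip & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    Rng rng = Rng::stream((uint64_t)seed, (uint64_t)ip);

    double x = src_pos[0], y = src_pos[1], z = src_pos[2];
    double ux, uy, uz;
    if (src_type == 0) {
      uz = 2.0 * rng.runif() - 1.0;
      const double phi = 2.0 * M_PI * rng.runif();
      const double st = std::sqrt(std::max(0.0, 1.0 - uz * uz));
      ux = st * std::cos(phi);
      uy = st * std::sin(phi);
    } else {
      ux = src_dir[0]; uy = src_dir[1]; uz = src_dir[2];
    }
    double w = 1.0;
    int ix = (int)std::floor(x / dx), iy = (int)std::floor(y / dy),
        iz = (int)std::floor(z / dz);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
      stop("source position outside the grid");

    double tau = -std::log(rng.runif());  // remaining optical depth
    long events = 0;
    bool alive = true;

    while (alive) {
      if (++events > max_events)
        stop("packet exceeded the event budget (check optics)");
      const int v = idx3(ix, iy, iz, nx, ny);
      const double ma = mua[v], ms = mus[v];
      const double mt = ma + ms;

      // distance to the nearest voxel face along the flight direction
      double db = 1e30;
      int axis = -1, step = 0;
      if (ux > 1e-12) {
        const double d = ((ix + 1) * dx - x) / ux;
        if (d < db) { db = d; axis = 0; step = 1; }
      } else if (ux < -1e-12) {
        const double d = (ix * dx - x) / ux;
        if (d < db) { db = d; axis = 0; step = -1; }
      }
      if (uy > 1e-12) {
        const double d = ((iy + 1) * dy - y) / uy;
        if (d < db) { db = d; axis = 1; step = 1; }
      } else if (uy < -1e-12) {
        const double d = (iy * dy - y) / uy;
        if (d < db) { db = d; axis = 1; step = -1; }
      }
      if (uz > 1e-12) {
        const double d = ((iz + 1) * dz - z) / uz;
        if (d < db) { db = d; axis = 2; step = 1; }
      } else if (uz < -1e-12) {
        const double d = (iz * dz - z) / uz;
        if (d < db) { db = d; axis = 2; step = -1; }
      }
      if (db < 0) db = 0;

      const double dint = (mt > 0) ? tau / mt : 1e30;

      if (dint < db) {
        // interaction inside this voxel
        psi_raw[v] += w * dint;
        x += ux * dint; y += uy * dint; z += uz * dint;
        const double albedo = (mt > 0) ? ms / mt : 1.0;
        absorbed += w * (1.0 - albedo);
        w *= albedo;
        if (w <= 0.0) { alive = false; break; }
        const double ct = sample_hg_cos(gfac[v], rng);
        const double phi = 2.0 * M_PI * rng.runif();
        scatter_dir(ux, uy, uz, ct, phi);
        tau = -std::log(rng.runif());
        if (w < roulette_wmin) {
          if (rng.runif() < roulette_surv) {
            w /= roulette_surv;
          } else {
            killed_rr += w;
            alive = false;
          }
        }
      } else {
        // stream to the voxel face
        psi_raw[v] += w * db;
        if (mt > 0) tau -= db * mt;
        if (tau < 0) tau = 0;
        x += ux * db; y += uy * db; z += uz * db;
        int jx = ix, jy = iy, jz = iz;
        if (axis == 0) jx += step;
        else if (axis == 1) jy += step;
        else jz += step;

        // snap onto the face to avoid drift
        if (axis == 0) x = (step > 0 ? (ix + 1) : ix) * dx;
        else if (axis == 1) y = (step > 0 ? (iy + 1) : iy) * dy;
        else z = (step > 0 ? (iz + 1) : iz) * dz;

        const bool outside =
            (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz);
        if (outside) {
          escaped += w;
          alive = false;
          break;
        }
        const int vn = idx3(jx, jy, jz, nx, ny);
        if (fresnel && nref[vn] != nref[v]) {
          const double n1 = nref[v], n2 = nref[vn];
          double ci;
          if (axis == 0) ci = std::fabs(ux);
          else if (axis == 1) ci = std::fabs(uy);
          else ci = std::fabs(uz);
          const double R = fresnel_R(ci, n1, n2);
          if (rng.runif() < R) {
            // specular reflection: stay in current voxel
            if (axis == 0) ux = -ux;
            else if (axis == 1) uy = -uy;
            else uz = -uz;
            continue;
          }
          // refraction: scale tangential components by n1/n2
          const double eta = n1 / n2;
          const double ct2 = std::sqrt(1.0 - eta * eta * (1.0 - ci * ci));
          if (axis == 0) {
            const double s = (ux >= 0 ? 1.0 : -1.0);
            ux = s * ct2; uy *= eta; uz *= eta;
          } else if (axis == 1) {
            const double s = (uy >= 0 ? 1.0 : -1.0);
            uy = s * ct2; ux *= eta; uz *= eta;
          } else {
            const double s = (uz >= 0 ? 1.0 : -1.0);
            uz = s * ct2; ux *= eta; uy *= eta;
          }
          const double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= nrm; uy /= nrm; uz /= nrm;
        }
        ix = jx; iy = jy; iz = jz;
      }
      if (!std::isfinite(w))
        stop("non-finite packet weight at voxel (%d, %d, %d)", ix, iy, iz);
      (void)Lx; (void)Ly; (void)Lz;
    }
  }

  return List::create(_["psi_raw"] = psi_raw, _["escaped"] = escaped,
                      _["absorbed"] = absorbed, _["roulette_killed"] = killed_rr,
                      _["n_packets"] = (double)np);
}

// [[Rcpp::export(rng = false)]]
NumericVector sample_step_cpp(double mu_t, double n, double seed) {
  const long nn = (long)n;
  NumericVector out(nn);
  Rng rng((uint64_t)seed);
  for (long i = 0; i < nn; ++i) out[i] = sample_path(mu_t, rng);
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericVector sample_hg_cpp(double g, double n, double seed) {
  const long nn = (long)n;
  NumericVector out(nn);
  Rng rng((uint64_t)seed);
  for (long i = 0; i < nn; ++i) out[i] = sample_hg_cos(g, rng);
  return out;
}
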