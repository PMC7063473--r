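// Reference isotropic Monte Carlo for a homogeneous box.
//
// Written independently of the voxelized engine as a validation oracle: one
// scalar scattering coefficient, free paths sampled analytically against the
// box walls (no voxel walking, no dimensionless-step bookkeeping), deposition
// binned to a grid only at interaction sites.  Shares nothing with the
// engine beyond the R RNG stream and the standard Henyey-Greenstein and
// launch formulas.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double runi() { return unif_rand(); }

static inline void basis_from(const double w[3], double a[3], double b[3]) {
  double t[3] = {1, 0, 0};
  if (std::fabs(w[0]) > 0.8) { t[0] = 0; t[1] = 1; }
  a[0] = w[1] * t[2] - w[2] * t[1];
  a[1] = w[2] * t[0] - w[0] * t[2];
  a[2] = w[0] * t[1] - w[1] * t[0];
  double n = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
  a[0] /= n; a[1] /= n; a[2] /= n;
  b[0] = w[1] * a[2] - w[2] * a[1];
  b[1] = w[2] * a[0] - w[0] * a[2];
  b[2] = w[0] * a[1] - w[1] * a[0];
}

// [[Rcpp::export(name = ".mc_iso_oracle")]]
List mc_iso_oracle(int nx, int ny, int nz, double dx, double dy, double dz,
                   double mua, double mus, double g,
                   NumericVector src_pos, NumericVector src_axis,
                   double src_radius, double cos_half, int profile,
                   int n_photons, double roulette_threshold,
                   double roulette_survival) {
  const double Lx = nx * dx, Ly = ny * dy, Lz = nz * dz;
  const double mut = mua + mus;
  NumericVector absorbed((R_xlen_t)nx * ny * nz);
  double escaped = 0.0;

  double w0[3] = {src_axis[0], src_axis[1], src_axis[2]};
  double s0[3] = {src_pos[0], src_pos[1], src_pos[2]};
  double ea[3], eb[3];
  basis_from(w0, ea, eb);

  for (int ip = 0; ip < n_photons; ++ip) {
    double p[3], u[3], W = 1.0;
    if (profile == 2) {
      p[0] = s0[0]; p[1] = s0[1]; p[2] = s0[2];
      double c = 2.0 * runi() - 1.0, ph = 2.0 * M_PI * runi();
      double sn = std::sqrt(std::max(0.0, 1.0 - c * c));
      u[0] = sn * std::cos(ph); u[1] = sn * std::sin(ph); u[2] = c;
    } else {
      double r = src_radius * std::sqrt(runi()), ps = 2.0 * M_PI * runi();
      for (int a = 0; a < 3; ++a)
        p[a] = s0[a] + r * std::cos(ps) * ea[a] + r * std::sin(ps) * eb[a];
      if (profile == 1) {
        u[0] = w0[0]; u[1] = w0[1]; u[2] = w0[2];
      } else {
        double c = 1.0 - runi() * (1.0 - cos_half);
        double sn = std::sqrt(std::max(0.0, 1.0 - c * c));
        double ph = 2.0 * M_PI * runi();
        for (int a = 0; a < 3; ++a)
          u[a] = c * w0[a] +
                 sn * (std::cos(ph) * ea[a] + std::sin(ph) * eb[a]);
      }
    }

    for (;;) {
      double s = -std::log(runi()) / mut;
      // analytic distance to the box wall along u
      double texit = R_PosInf;
      for (int a = 0; a < 3; ++a) {
        double L = (a == 0 ? Lx : (a == 1 ? Ly : Lz));
        if (u[a] > 0) texit = std::min(texit, (L - p[a]) / u[a]);
        else if (u[a] < 0) texit = std::min(texit, (0.0 - p[a]) / u[a]);
      }
      if (s >= texit) { escaped += W; break; }
      for (int a = 0; a < 3; ++a) p[a] += s * u[a];
      int ix = (int)std::floor(p[0] / dx);
      int iy = (int)std::floor(p[1] / dy);
      int iz = (int)std::floor(p[2] / dz);
      if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
      if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
      if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
      double dW = W * mua / mut;
      absorbed[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] += dW;
      W -= dW;
      if (W < roulette_threshold) {
        if (runi() <= roulette_survival) W /= roulette_survival;
        else break;
      }
      // Henyey-Greenstein deflection about the current direction
      double cost;
      if (g == 0.0) {
        cost = 2.0 * runi() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * runi());
        cost = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (cost > 1.0) cost = 1.0;
        if (cost < -1.0) cost = -1.0;
      }
      double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
      double phi = 2.0 * M_PI * runi();
      double cp = std::cos(phi), sp = std::sin(phi);
      double nu[3];
      if (std::fabs(u[2]) > 0.99999) {
        nu[0] = sint * cp; nu[1] = sint * sp;
        nu[2] = cost * (u[2] >= 0 ? 1 : -1);
      } else {
        double den = std::sqrt(1.0 - u[2] * u[2]);
        nu[0] = sint * (u[0] * u[2] * cp - u[1] * sp) / den + u[0] * cost;
        nu[1] = sint * (u[1] * u[2] * cp + u[0] * sp) / den + u[1] * cost;
        nu[2] = -den * sint * cp + u[2] * cost;
      }
      double nn = std::sqrt(nu[0] * nu[0] + nu[1] * nu[1] + nu[2] * nu[2]);
      u[0] = nu[0] / nn; u[1] = nu[1] / nn; u[2] = nu[2] / nn;
    }
    if ((ip & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["absorbed"] = absorbed, _["escaped"] = escaped,
                      _["n_photons"] = (double)n_photons);
}
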