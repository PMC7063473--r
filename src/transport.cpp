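// Voxelized Monte Carlo photon transport with direction-resolved scattering.
//
// Hop-drop-spin photon-packet transport in the MCML/mcxyz lineage, extended
// so that each voxel carries one full scattering coefficient per Cartesian
// axis.  At every step (and at every voxel-boundary crossing) the effective
// scattering coefficient is rebuilt from the photon's current direction of
// flight, either as the squared-direction-cosine combination
//   mus_eff = ux^2 mus_x + uy^2 mus_y + uz^2 mus_z
// (default; reduces exactly to the isotropic coefficient when the three axis
// values are equal) or as an |u|-weighted normalized mean.  Dimensionless
// step bookkeeping ("sleft") is kept across boundary crossings so that a
// change of mu_t mid-flight consumes the remaining sampled optical depth
// consistently; the direction, and hence mus_eff, only changes at scatter
// events.
//
// Uses R's RNG stream (single photon loop, fixed order) so that set.seed()
// in R gives bit-identical results.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double EPS_NUDGE = 1e-9;   // mm, push across a voxel face

// uniform in (0,1); R's Mersenne-Twister never returns exactly 0 or 1
static inline double ru() { return unif_rand(); }

// orthonormal basis completing unit vector w
static inline void make_basis(const double w[3], double e1[3], double e2[3]) {
  if (std::fabs(w[2]) < 0.9) {
    // e1 = w x z_hat, normalized
    double nx = w[1], ny = -w[0], nz = 0.0;
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    e1[0] = nx / nn; e1[1] = ny / nn; e1[2] = nz / nn;
  } else {
    double nx = -w[2], ny = 0.0, nz = w[0];
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    e1[0] = nx / nn; e1[1] = ny / nn; e1[2] = nz / nn;
  }
  e2[0] = w[1] * e1[2] - w[2] * e1[1];
  e2[1] = w[2] * e1[0] - w[0] * e1[2];
  e2[2] = w[0] * e1[1] - w[1] * e1[0];
}

// Henyey-Greenstein deflection cosine, inverse-CDF sampling
static inline double hg_cos(double g) {
  if (g == 0.0) return 2.0 * ru() - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * ru());
  double c = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// rotate direction u by polar cosine `cost`, uniform azimuth (MCML spin)
static inline void spin(double u[3], double cost) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * ru();
  double cosp = std::cos(phi), sinp = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  double nx, ny, nz;
  if (std::fabs(uz) > 0.99999) {
    nx = sint * cosp;
    ny = sint * sinp;
    nz = cost * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    nx = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    ny = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    nz = -den * sint * cosp + uz * cost;
  }
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  u[0] = nx / nn; u[1] = ny / nn; u[2] = nz / nn;
}

static inline double combine_mus(const double u[3], double mx, double my,
                                 double mz, int mode) {
  if (mode == 0) {
    // quadratic (squared direction cosines), written so that equal axis
    // coefficients return exactly that coefficient for any unit vector
    return mx + u[1] * u[1] * (my - mx) + u[2] * u[2] * (mz - mx);
  }
  double ax = std::fabs(u[0]), ay = std::fabs(u[1]), az = std::fabs(u[2]);
  return mx + (ay * (my - mx) + az * (mz - mx)) / (ax + ay + az);
}

// distance along u to the nearest voxel face from pos within voxel (ix,iy,iz)
static inline double boundary_dist(const double pos[3], const double u[3],
                                   int ix, int iy, int iz,
                                   double dx, double dy, double dz) {
  double t = R_PosInf;
  if (u[0] > 0)      t = std::min(t, ((ix + 1) * dx - pos[0]) / u[0]);
  else if (u[0] < 0) t = std::min(t, (ix * dx - pos[0]) / u[0]);
  if (u[1] > 0)      t = std::min(t, ((iy + 1) * dy - pos[1]) / u[1]);
  else if (u[1] < 0) t = std::min(t, (iy * dy - pos[1]) / u[1]);
  if (u[2] > 0)      t = std::min(t, ((iz + 1) * dz - pos[2]) / u[2]);
  else if (u[2] < 0) t = std::min(t, (iz * dz - pos[2]) / u[2]);
  return std::max(t, 0.0);
}

// which grid face (0..5: x-,x+,y-,y+,z-,z+) a photon left through
static inline int exit_face(const double pos[3], const double u[3],
                            double Lx, double Ly, double Lz) {
  if (pos[0] <= 0) return 0;
  if (pos[0] >= Lx) return 1;
  if (pos[1] <= 0) return 2;
  if (pos[1] >= Ly) return 3;
  if (pos[2] <= 0) return 4;
  if (pos[2] >= Lz) return 5;
  // should not happen; attribute by dominant direction component
  int a = 0;
  if (std::fabs(u[1]) > std::fabs(u[a])) a = 1;
  if (std::fabs(u[2]) > std::fabs(u[a])) a = 2;
  return 2 * a + (u[a] > 0 ? 1 : 0);
}

// Launch one photon: position on the fiber face disc, direction within the
// acceptance cone (uniform in solid angle).  profile: 0 = flat_disc cone,
// 1 = collimated disc, 2 = isotropic point.
static inline void launch(const double spos[3], const double e1[3],
                          const double e2[3], const double axis[3],
                          double radius, double cos_half, int profile,
                          double pos[3], double u[3]) {
  if (profile == 2) {
    pos[0] = spos[0]; pos[1] = spos[1]; pos[2] = spos[2];
    double c = 2.0 * ru() - 1.0;
    double s = std::sqrt(std::max(0.0, 1.0 - c * c));
    double phi = 2.0 * M_PI * ru();
    u[0] = s * std::cos(phi); u[1] = s * std::sin(phi); u[2] = c;
    return;
  }
  double r = radius * std::sqrt(ru());
  double psi = 2.0 * M_PI * ru();
  double c1 = r * std::cos(psi), c2 = r * std::sin(psi);
  for (int a = 0; a < 3; ++a) pos[a] = spos[a] + c1 * e1[a] + c2 * e2[a];
  if (profile == 1) {
    u[0] = axis[0]; u[1] = axis[1]; u[2] = axis[2];
    return;
  }
  double cost = 1.0 - ru() * (1.0 - cos_half);
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * ru();
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int a = 0; a < 3; ++a)
    u[a] = cost * axis[a] + sint * (cp * e1[a] + sp * e2[a]);
  double nn = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= nn; u[1] /= nn; u[2] /= nn;
}

// [[Rcpp::export(name = ".mc_engine")]]
List mc_engine(IntegerVector labels, int nx, int ny, int nz,
               double dx, double dy, double dz,
               NumericMatrix props,      // row l: mua, mus_x, mus_y, mus_z, g for label l
               NumericVector src_pos, NumericVector src_axis,
               double src_radius, double cos_half, int profile,
               int n_photons, double roulette_threshold,
               double roulette_survival, int combination_mode,
               double max_path, double det_cos_min) {
  const double Lx = nx * dx, Ly = ny * dy, Lz = nz * dz;
  NumericVector absorbed((R_xlen_t)nx * ny * nz);
  double esc_face[6] = {0, 0, 0, 0, 0, 0};
  double esc_label0 = 0.0, lost = 0.0, det_weight = 0.0;

  double axis[3] = {src_axis[0], src_axis[1], src_axis[2]};
  double spos[3] = {src_pos[0], src_pos[1], src_pos[2]};
  double e1[3], e2[3];
  make_basis(axis, e1, e2);

  const int nlab = props.nrow();

  for (int ip = 0; ip < n_photons; ++ip) {
    double pos[3], u[3];
    launch(spos, e1, e2, axis, src_radius, cos_half, profile, pos, u);
    double W = 1.0, path = 0.0;
    bool entered = false;

    for (;;) {
      int ix = (int)std::floor(pos[0] / dx);
      int iy = (int)std::floor(pos[1] / dy);
      int iz = (int)std::floor(pos[2] / dz);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        int f = exit_face(pos, u, Lx, Ly, Lz);
        esc_face[f] += W;
        if (f == 3 && u[1] >= det_cos_min) det_weight += W;
        break;
      }
      R_xlen_t idx = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      int lab = labels[idx];
      if (lab == 0) {
        if (entered) { esc_label0 += W; break; }
        // ballistic transit through the surrounding medium before first
        // tissue entry (fiber face may sit over a curved surface)
        double db = boundary_dist(pos, u, ix, iy, iz, dx, dy, dz);
        for (int a = 0; a < 3; ++a) pos[a] += (db + EPS_NUDGE) * u[a];
        path += db;
        if (path > max_path) { lost += W; break; }
        continue;
      }
      if (lab > nlab) stop("voxel label has no optical-property entry");
      entered = true;
      double mua = props(lab - 1, 0);
      double mx = props(lab - 1, 1), my = props(lab - 1, 2),
             mz = props(lab - 1, 3);
      double g = props(lab - 1, 4);
      double mus_eff = combine_mus(u, mx, my, mz, combination_mode);
      double mut = mua + mus_eff;

      // HOP: consume one dimensionless step across voxel boundaries
      double sleft = -std::log(ru());
      bool gone = false;
      while (sleft > 0.0) {
        double s = sleft / mut;
        double db = boundary_dist(pos, u, ix, iy, iz, dx, dy, dz);
        if (db < s) {
          for (int a = 0; a < 3; ++a) pos[a] += (db + EPS_NUDGE) * u[a];
          path += db;
          sleft -= db * mut;
          ix = (int)std::floor(pos[0] / dx);
          iy = (int)std::floor(pos[1] / dy);
          iz = (int)std::floor(pos[2] / dz);
          if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 ||
              iz >= nz) {
            int f = exit_face(pos, u, Lx, Ly, Lz);
            esc_face[f] += W;
            if (f == 3 && u[1] >= det_cos_min) det_weight += W;
            gone = true; break;
          }
          idx = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
          lab = labels[idx];
          if (lab == 0) { esc_label0 += W; gone = true; break; }
          if (lab > nlab) stop("voxel label has no optical-property entry");
          mua = props(lab - 1, 0);
          mx = props(lab - 1, 1); my = props(lab - 1, 2);
          mz = props(lab - 1, 3);
          g = props(lab - 1, 4);
          mus_eff = combine_mus(u, mx, my, mz, combination_mode);
          mut = mua + mus_eff;
        } else {
          for (int a = 0; a < 3; ++a) pos[a] += s * u[a];
          path += s;
          sleft = 0.0;
        }
        if (path > max_path) { lost += W; gone = true; break; }
      }
      if (gone) break;

      // DROP: deposit the absorbed fraction of the packet weight
      double dW = W * mua / mut;
      absorbed[idx] += dW;
      W -= dW;

      // roulette (expectation-preserving)
      if (W < roulette_threshold) {
        if (ru() <= roulette_survival) W /= roulette_survival;
        else break;  // packet terminated; weight already in expectation
      }

      // SPIN
      spin(u, hg_cos(g));
    }
    if ((ip & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["absorbed"] = absorbed,
      _["escaped_faces"] = NumericVector::create(
          esc_face[0], esc_face[1], esc_face[2], esc_face[3], esc_face[4],
          esc_face[5]),
      _["escaped_label0"] = esc_label0,
      _["lost"] = lost,
      _["detector_weight"] = det_weight,
      _["n_photons"] = (double)n_photons);
}
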