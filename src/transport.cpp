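// Compiled core: divergent fan-beam projection through the voxel grid and
// Monte Carlo photon transport (Woodcock/delta tracking, photoelectric
// absorption + Klein-Nishina incoherent scatter, kerma approximation).
//
// Conventions shared with the R side:
//  - voxel arrays are R arrays with dim (nz, ny, nx): flat index
//    iz + nz*(iy + ny*ix); world coordinates are voxel centres in mm,
//    already shifted by any phantom off-centring, so this file never sees
//    offsets explicitly;
//  - gantry frame: rotation axis along z through the origin; a gantry
//    angle theta places the source at (sid*sin(theta), -sid*cos(theta))
//    in (x, y), so theta = 0 is the PA position (tube below the patient);
//  - energies in keV on an integer grid e0..e0+ne-1 (10..150 by default);
//    mass coefficients in cm^2/g, linear attenuation derived per mm.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const double ME_KEV = 510.99895;
static const double KEV_TO_MGY_PER_G = 1.602176634e-10; // keV/g -> mGy

struct Grid {
  int nz, ny, nx;
  double dz, dy, dx;     // spacing mm
  double oz, oy, ox;     // world coord of voxel (0,0,0) centre
  double z0, z1, y0, y1, x0, x1; // bounding box (outer voxel faces)
  void init(IntegerVector dims, NumericVector spacing, NumericVector origin) {
    nz = dims[0]; ny = dims[1]; nx = dims[2];
    dz = spacing[0]; dy = spacing[1]; dx = spacing[2];
    oz = origin[0]; oy = origin[1]; ox = origin[2];
    z0 = oz - 0.5 * dz; z1 = oz + (nz - 0.5) * dz;
    y0 = oy - 0.5 * dy; y1 = oy + (ny - 0.5) * dy;
    x0 = ox - 0.5 * dx; x1 = ox + (nx - 0.5) * dx;
  }
  inline int index(double pz, double py, double px) const {
    int iz = (int)std::floor((pz - oz) / dz + 0.5);
    int iy = (int)std::floor((py - oy) / dy + 0.5);
    int ix = (int)std::floor((px - ox) / dx + 0.5);
    if (iz < 0 || iz >= nz || iy < 0 || iy >= ny || ix < 0 || ix >= nx)
      return -1;
    return iz + nz * (iy + (std::int64_t)ny * ix);
  }
};

// slab clipping of a ray p + t*d against the grid box; returns false if no
// intersection, else [t0, t1]
static bool clip_box(const Grid& g, const double p[3], const double d[3],
                     double& t0, double& t1) {
  t0 = 0.0; t1 = 1e30;
  const double lo[3] = {g.z0, g.y0, g.x0};
  const double hi[3] = {g.z1, g.y1, g.x1};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p[a] < lo[a] || p[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - p[a]) / d[a];
      double tb = (hi[a] - p[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0;
}

// ---------------------------------------------------------------------------
// Fan-beam projection: per-slice 2D divergent rays from a point source to a
// virtual detector line; returns line integrals of mu (per mm) for every
// (slice, detector pixel).
// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector mu, IntegerVector dims,
                          NumericVector spacing, NumericVector origin,
                          double src_x, double src_y,
                          double det_dist, double det_pitch, int n_det,
                          double step) {
  Grid g; g.init(dims, spacing, origin);
  NumericMatrix out(g.nz, n_det);
  double sn = std::sqrt(src_x * src_x + src_y * src_y);
  double ux = -src_x / sn, uy = -src_y / sn;   // source -> isocentre
  double px_ = -uy, py_ = ux;                   // detector line direction
  double cx = src_x + ux * det_dist, cy = src_y + uy * det_dist;
  const double* muv = mu.begin();
  for (int j = 0; j < n_det; ++j) {
    double off = (j - (n_det - 1) / 2.0) * det_pitch;
    double ex = cx + px_ * off, ey = cy + py_ * off;
    double ddx = ex - src_x, ddy = ey - src_y;
    double L = std::sqrt(ddx * ddx + ddy * ddy);
    ddx /= L; ddy /= L;
    // 2D clip in (y, x)
    double t0 = 0.0, t1 = L;
    {
      const double p2[2] = {src_y, src_x};
      const double d2[2] = {ddy, ddx};
      const double lo[2] = {g.y0, g.x0}, hi[2] = {g.y1, g.x1};
      bool ok = true;
      for (int a = 0; a < 2 && ok; ++a) {
        if (std::fabs(d2[a]) < 1e-12) {
          if (p2[a] < lo[a] || p2[a] > hi[a]) ok = false;
        } else {
          double ta = (lo[a] - p2[a]) / d2[a];
          double tb = (hi[a] - p2[a]) / d2[a];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
        }
      }
      if (!ok || t1 <= t0) continue;
    }
    int nstep = (int)std::ceil((t1 - t0) / step);
    double h = (t1 - t0) / nstep;
    for (int iz = 0; iz < g.nz; ++iz) out(iz, j) = 0.0;
    for (int i = 0; i < nstep; ++i) {
      double t = t0 + (i + 0.5) * h;
      double py = src_y + ddy * t, px = src_x + ddx * t;
      int iy = (int)std::floor((py - g.oy) / g.dy + 0.5);
      int ix = (int)std::floor((px - g.ox) / g.dx + 0.5);
      if (iy < 0 || iy >= g.ny || ix < 0 || ix >= g.nx) continue;
      std::int64_t base = g.nz * (iy + (std::int64_t)g.ny * ix);
      for (int iz = 0; iz < g.nz; ++iz) out(iz, j) += muv[base + iz] * h;
    }
  }
  return out;
}

// Single 3D line integral of mu (per mm) between two world points.
// [[Rcpp::export]]
double cpp_line_integral(NumericVector mu, IntegerVector dims,
                         NumericVector spacing, NumericVector origin,
                         NumericVector p0, NumericVector p1, double step) {
  Grid g; g.init(dims, spacing, origin);
  double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L <= 0) return 0.0;
  for (int a = 0; a < 3; ++a) d[a] /= L;
  double p[3] = {p0[0], p0[1], p0[2]};
  double t0, t1;
  if (!clip_box(g, p, d, t0, t1)) return 0.0;
  if (t0 < 0) t0 = 0;
  if (t1 > L) t1 = L;
  if (t1 <= t0) return 0.0;
  int nstep = (int)std::ceil((t1 - t0) / step);
  double h = (t1 - t0) / nstep, acc = 0.0;
  const double* muv = mu.begin();
  for (int i = 0; i < nstep; ++i) {
    double t = t0 + (i + 0.5) * h;
    int idx = g.index(p0[0] + d[0] * t, p0[1] + d[1] * t, p0[2] + d[2] * t);
    if (idx >= 0) acc += muv[idx] * h;
  }
  return acc;
}

// ---------------------------------------------------------------------------
// RNG: xoshiro-free, use std::mt19937_64 for portability and determinism.
#include <random>

struct Rng {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> uni;
  Rng(std::uint64_t seed) : eng(seed), uni(0.0, 1.0) {}
  inline double operator()() { return uni(eng); }
};

// Klein-Nishina scattered-energy fraction sampling (Geant4-style
// composition + rejection). Returns eps = E'/E; cos(theta) follows from
// eps via the Compton relation.
static double sample_kn_eps(double e_kev, Rng& rng) {
  double k = e_kev / ME_KEV;
  double eps0 = 1.0 / (1.0 + 2.0 * k);
  double a1 = std::log(1.0 / eps0);
  double a2 = 0.5 * (1.0 - eps0 * eps0);
  double eps, greject;
  do {
    if (rng() * (a1 + a2) < a1) {
      eps = std::exp(-a1 * rng());
    } else {
      eps = std::sqrt(eps0 * eps0 + (1.0 - eps0 * eps0) * rng());
    }
    double t = (1.0 - eps) / (k * eps);
    double sint2 = t * (2.0 - t);
    greject = 1.0 - eps * sint2 / (1.0 + eps * eps);
  } while (rng() > greject);
  return eps;
}

// Expose Compton cos(theta) samples for distribution tests.
// [[Rcpp::export]]
NumericVector cpp_sample_compton(double e_kev, int n, int seed) {
  Rng rng((std::uint64_t)seed * 2654435761u + 1u);
  double k = e_kev / ME_KEV;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double eps = sample_kn_eps(e_kev, rng);
    out[i] = 1.0 - (1.0 - eps) / (k * eps);
  }
  return out;
}

// rotate unit vector v by polar angle theta (cos ct) about itself with
// uniform azimuth phi; standard scattering frame rotation
static void rotate_direction(double v[3], double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double sp = std::sin(phi), cp = std::cos(phi);
  double vz = v[0], vy = v[1], vx = v[2]; // (z, y, x) storage
  // build orthonormal basis around v
  double az = std::fabs(vz);
  double b[3], c[3];
  if (az < 0.99) { b[0] = 1; b[1] = 0; b[2] = 0; }
  else { b[0] = 0; b[1] = 1; b[2] = 0; }
  // c = v x b
  c[0] = vy * b[2] - vx * b[1];
  c[1] = vx * b[0] - vz * b[2];
  c[2] = vz * b[1] - vy * b[0];
  double cn = std::sqrt(c[0] * c[0] + c[1] * c[1] + c[2] * c[2]);
  c[0] /= cn; c[1] /= cn; c[2] /= cn;
  // d = v x c
  double dgz = vy * c[2] - vx * c[1];
  double dgy = vx * c[0] - vz * c[2];
  double dgx = vz * c[1] - vy * c[0];
  v[0] = ct * vz + st * (cp * c[0] + sp * dgz);
  v[1] = ct * vy + st * (cp * c[1] + sp * dgy);
  v[2] = ct * vx + st * (cp * c[2] + sp * dgx);
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  v[0] /= n; v[1] /= n; v[2] /= n;
}

static inline int ebin(double e, int e0, int ne) {
  int i = (int)std::floor(e - e0 + 0.5);
  if (i < 0) i = 0;
  if (i >= ne) i = ne - 1;
  return i;
}

// ---------------------------------------------------------------------------
// Helical (or fixed-angle) CT scan Monte Carlo.
//
// material: integer codes 0..nmat-1 per voxel; coef_pe/coef_inc:
// (ne x nmat) mass attenuation cm^2/g on the integer energy grid;
// mat_density: nominal density per material code used for the majorant.
// spec_e / spec_cdf: spectrum sampling table. z_cdf_grid / z_cdf: table
// position sampling (importance sampling proportional to the mA profile).
// Photon weight carries only the bowtie transmission.
//
// Returns list(edep = total keV per voxel, batch = keV per voxel per batch,
//              emitted_kev, deposited_kev)
// [[Rcpp::export]]
List cpp_simulate_scan(NumericVector density, IntegerVector material,
                       IntegerVector dims, NumericVector spacing,
                       NumericVector origin,
                       NumericMatrix coef_pe, NumericMatrix coef_inc,
                       NumericVector mat_density, int e0,
                       IntegerVector spec_e, NumericVector spec_cdf,
                       NumericVector z_cdf_grid, NumericVector z_cdf,
                       double sid, double gamma_max, double collimation,
                       double feed, double z_start, double theta0,
                       double bowtie_tmax, NumericVector bowtie_mu,
                       bool bowtie_on, bool scatter_on, bool fixed_angle,
                       double fixed_theta,
                       int n_photons, int n_batches, int seed) {
  Grid g; g.init(dims, spacing, origin);
  int ne = coef_pe.nrow(), nmat = coef_pe.ncol();
  std::int64_t nvox = (std::int64_t)g.nz * g.ny * g.nx;
  NumericVector edep(nvox);
  NumericMatrix batch(n_batches, 1); // per-batch totals of deposited energy
  std::vector<std::vector<double> > organ_unused; // placeholder
  // per-batch per-voxel would be heavy for large grids; we instead tally
  // per-voxel totals plus per-batch voxel tallies compressed to doubles on
  // demand from R via separate runs. Batches here carry total deposits for
  // convergence checks.
  // majorant linear attenuation per energy bin (per mm)
  std::vector<double> maj(ne, 0.0);
  for (int e = 0; e < ne; ++e) {
    double m = 0.0;
    for (int j = 0; j < nmat; ++j) {
      double v = (coef_pe(e, j) + coef_inc(e, j)) * mat_density[j] / 10.0;
      if (v > m) m = v;
    }
    maj[e] = std::max(m, 1e-12);
  }
  Rng rng((std::uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);
  const double* dens = density.begin();
  const int* matv = material.begin();
  double emitted = 0.0, deposited = 0.0;
  int nz_cdf = z_cdf.size();
  int nspec = spec_cdf.size();

  for (int ip = 0; ip < n_photons; ++ip) {
    int ib = (int)(((std::int64_t)ip * n_batches) / n_photons);
    // --- emission ---
    // energy
    double u = rng();
    int lo = 0, hi = nspec - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (spec_cdf[mid] < u) lo = mid + 1; else hi = mid; }
    double E = (double)spec_e[lo];
    // table position
    double zt;
    if (nz_cdf == 1) {
      zt = z_cdf_grid[0];
    } else {
      double uz = rng();
      int a = 0, b = nz_cdf - 1;
      while (a < b) { int mid = (a + b) / 2; if (z_cdf[mid] < uz) a = mid + 1; else b = mid; }
      if (a == 0) zt = z_cdf_grid[0];
      else {
        double c0 = z_cdf[a - 1], c1 = z_cdf[a];
        double f = (c1 > c0) ? (uz - c0) / (c1 - c0) : 0.5;
        zt = z_cdf_grid[a - 1] + f * (z_cdf_grid[a] - z_cdf_grid[a - 1]);
      }
    }
    double theta = fixed_angle ? fixed_theta
                               : theta0 + 2.0 * M_PI * std::fabs(zt - z_start) / feed;
    double sx = sid * std::sin(theta), sy = -sid * std::cos(theta);
    double ux = -sx / sid, uy = -sy / sid;      // towards isocentre
    double gam = (2.0 * rng() - 1.0) * gamma_max;
    double zeta = (rng() - 0.5) * collimation;  // z offset at isocentre
    double cg = std::cos(gam), sg = std::sin(gam);
    double fx = cg * ux - sg * uy;
    double fy = sg * ux + cg * uy;
    double fz = zeta / sid;
    double norm = std::sqrt(fx * fx + fy * fy + fz * fz);
    double dir[3] = {fz / norm, fy / norm, fx / norm}; // (z, y, x)
    double pos[3] = {zt, sy, sx};
    double w = 1.0;
    if (bowtie_on && bowtie_tmax > 0) {
      double frac = gam / gamma_max;
      double t_mm = bowtie_tmax * frac * frac;
      w = std::exp(-bowtie_mu[ebin(E, e0, ne)] * t_mm);
    }
    emitted += w * E;
    // --- transport ---
    for (int bounce = 0; bounce < 1000; ++bounce) {
      double t0, t1;
      if (!clip_box(g, pos, dir, t0, t1)) break;
      if (t0 < 0) t0 = 0;
      int eb = ebin(E, e0, ne);
      double mu_maj = maj[eb];
      double t = t0;
      bool interacted = false;
      while (true) {
        t += -std::log(1.0 - rng()) / mu_maj;
        if (t > t1) break;
        double pz = pos[0] + dir[0] * t;
        double py = pos[1] + dir[1] * t;
        double px = pos[2] + dir[2] * t;
        int idx = g.index(pz, py, px);
        if (idx < 0) continue; // numeric edge; treat as void
        int m = matv[idx];
        double rho = dens[idx];
        double mu_pe = coef_pe(eb, m) * rho / 10.0;
        double mu_in = coef_inc(eb, m) * rho / 10.0;
        double mu_tot = mu_pe + mu_in;
        if (rng() * mu_maj > mu_tot) continue; // virtual collision
        // real interaction
        pos[0] = pz; pos[1] = py; pos[2] = px;
        if (!scatter_on || rng() * mu_tot < mu_pe) {
          edep[idx] += w * E; deposited += w * E; batch(ib, 0) += w * E;
          E = 0.0;
        } else {
          double eps = sample_kn_eps(E, rng);
          double Enew = E * eps;
          double edep_here = E - Enew;
          double k = E / ME_KEV;
          double ct = 1.0 - (1.0 - eps) / (k * eps);
          if (Enew < 10.0) {
            edep_here = E; // terminate below cut-off, deposit everything
            Enew = 0.0;
          }
          edep[idx] += w * edep_here; deposited += w * edep_here;
          batch(ib, 0) += w * edep_here;
          E = Enew;
          if (E > 0.0) rotate_direction(dir, ct, 2.0 * M_PI * rng());
        }
        interacted = true;
        break;
      }
      if (!interacted || E <= 0.0) break;
    }
  }
  return List::create(_["edep"] = edep,
                      _["batch_total"] = NumericVector(batch.begin(), batch.end()),
                      _["emitted_kev"] = emitted,
                      _["deposited_kev"] = deposited);
}

// ---------------------------------------------------------------------------
// Free-in-air kerma at a point on the central axis, per emitted photon.
// Fan geometry identical to the scan source at a fixed gantry angle; the
// scoring volume is a disc of radius r_mm perpendicular to the central
// axis at distance d_mm from the source.
// Returns list(kerma_mgy, batch (per-batch kerma), n_hits)
// [[Rcpp::export]]
List cpp_air_kerma(IntegerVector spec_e, NumericVector spec_cdf,
                   NumericVector muen_air, int e0,
                   double gamma_max, double collimation, double sid,
                   double d_mm, double r_mm,
                   double bowtie_tmax, NumericVector bowtie_mu,
                   bool bowtie_on, int n_photons, int n_batches, int seed) {
  Rng rng((std::uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);
  int ne = muen_air.size();
  int nspec = spec_cdf.size();
  std::vector<double> acc(n_batches, 0.0);
  long hits = 0;
  // source at origin, central axis along +y; scoring point at (0, d, 0)
  for (int ip = 0; ip < n_photons; ++ip) {
    int ib = (int)(((std::int64_t)ip * n_batches) / n_photons);
    double u = rng();
    int lo = 0, hi = nspec - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (spec_cdf[mid] < u) lo = mid + 1; else hi = mid; }
    double E = (double)spec_e[lo];
    double gam = (2.0 * rng() - 1.0) * gamma_max;
    double zeta = (rng() - 0.5) * collimation; // at isocentre distance sid
    double dy = std::cos(gam), dx = std::sin(gam), dz = zeta / sid;
    double n = std::sqrt(dx * dx + dy * dy + dz * dz);
    dx /= n; dy /= n; dz /= n;
    // distance from scoring point P=(x=0,y=d,z=0) to the ray through origin
    double tproj = dy * d_mm; // dot(dir, P)
    double cx = dx * tproj - 0.0, cy = dy * tproj - d_mm, cz = dz * tproj - 0.0;
    double dist = std::sqrt(cx * cx + cy * cy + cz * cz);
    if (dist > r_mm || tproj <= 0) continue;
    double w = 1.0;
    if (bowtie_on && bowtie_tmax > 0) {
      double frac = gam / gamma_max;
      double t_mm = bowtie_tmax * frac * frac;
      w = std::exp(-bowtie_mu[ebin(E, e0, ne)] * t_mm);
    }
    ++hits;
    acc[ib] += w * E * muen_air[ebin(E, e0, ne)];
  }
  double r_cm = r_mm / 10.0;
  double area_cm2 = M_PI * r_cm * r_cm;
  double total = 0.0;
  NumericVector batch(n_batches);
  for (int b = 0; b < n_batches; ++b) {
    // per-batch kerma per photon (each batch has ~n/n_batches photons)
    double nb = (double)n_photons / n_batches;
    batch[b] = acc[b] / area_cm2 / nb * KEV_TO_MGY_PER_G;
    total += acc[b];
  }
  double kerma = total / area_cm2 / n_photons * KEV_TO_MGY_PER_G;
  return List::create(_["kerma_mgy_per_photon"] = kerma,
                      _["batch"] = batch, _["n_hits"] = hits);
}
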