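// Voxelized weighted-photon (implicit capture) Monte Carlo transport kernel.
// MCML/MCX-style: dimensionless step sampling with exact voxel-boundary
// traversal, weight deposition mua/mut at each interaction, Henyey-Greenstein
// scattering, Fresnel reflection at the top surface for a refractive-index
// mismatch, absorbing side/bottom faces, Russian roulette below a weight
// threshold. Single-threaded with a counter-free xoshiro256++ generator so a
// given seed reproduces runs bit-for-bit.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t x = seed + 0x9E3779B97f4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]; never exactly 0 so -log(u) is finite
  inline double runif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
};

inline double sample_hg_cos(Xoshiro& rng, double g) {
  double u = rng.runif();
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

inline void scatter(Xoshiro& rng, double g,
                    double& ux, double& uy, double& uz) {
  double ct = sample_hg_cos(rng, g);
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 6.283185307179586 * rng.runif();
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double tmp = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / tmp + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / tmp + uy * ct;
    double nz = -st * cp * tmp + uz * ct;
    double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / norm; uy = ny / norm; uz = nz / norm;
  }
}

// unpolarized Fresnel reflectance, internal (n_rel = n_in / n_out) incidence
inline double fresnel_R(double n_rel, double cos_i) {
  if (n_rel == 1.0) return 0.0;
  double sin_i2 = 1.0 - cos_i * cos_i;
  double sin_t2 = n_rel * n_rel * sin_i2;
  if (sin_t2 >= 1.0) return 1.0; // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n_rel * cos_i - cos_t) / (n_rel * cos_i + cos_t);
  double rp = (n_rel * cos_t - cos_i) / (n_rel * cos_t + cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".fd_sample_hg")]]
NumericVector fd_sample_hg(int n, double g, int seed) {
  Xoshiro rng(static_cast<uint64_t>(seed) * 0x9E3779B97f4A7C15ULL + 1u);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_hg_cos(rng, g);
  return out;
}

// source_type: 0 planar (uniform over top face, +z), 1 pencil (top center,
// +z), 2 isotropic point at source_params (x, y, z), 3 isotropic voxel
// source sampled from source_cumw over source_voxels (0-based flat indices).
// All returned tallies are per unit launched weight (each photon launches
// with weight 1).
//' @noRd
// [[Rcpp::export(name = ".fd_mc_transport")]]
List fd_mc_transport(IntegerVector labels, IntegerVector dims, double voxel_mm,
                     NumericVector mua_by_label, NumericVector mus_by_label,
                     NumericVector g_by_label, double n_rel,
                     int source_type, NumericVector source_params,
                     IntegerVector source_voxels, NumericVector source_cumw,
                     double n_photons, double seed,
                     double roulette_threshold, double roulette_survival,
                     bool record_absorption) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double h = voxel_mm;
  const double Lx = nx * h, Ly = ny * h, Lz = nz * h;
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  if (labels.size() != nvox) stop("label grid does not match dims");
  const int* lab = INTEGER(labels);
  const int nlab = mua_by_label.size();
  std::vector<double> mua(nlab), mus(nlab), mut(nlab), inv_mut(nlab),
      albedo_a(nlab), gg(nlab);
  for (int l = 0; l < nlab; ++l) {
    mua[l] = mua_by_label[l];
    mus[l] = mus_by_label[l];
    mut[l] = mua[l] + mus[l];
    inv_mut[l] = 1.0 / mut[l];
    albedo_a[l] = mua[l] / mut[l];
    gg[l] = g_by_label[l];
    if (mua[l] <= 0) stop("mua must be > 0 for every label");
  }
  const double inv_h = 1.0 / h;

  NumericVector absorption(record_absorption ? nvox : 0);
  double* amap = record_absorption ? REAL(absorption) : nullptr;
  NumericMatrix surface(nx, ny);
  double* simg = REAL(surface);

  double deposited = 0, escaped_top = 0, escaped_side = 0, specular = 0;
  double roulette_killed = 0, roulette_gained = 0, guard_killed = 0;

  const double eps = 1e-9 * h;
  const long n_ph = static_cast<long>(n_photons);
  Xoshiro rng(static_cast<uint64_t>(seed) + 0x5DEECE66DULL);

  // specular reflection for external normal incidence (planar/pencil launch)
  double rsp = 0.0;
  if ((source_type == 0 || source_type == 1) && n_rel != 1.0) {
    double r = (n_rel - 1.0) / (n_rel + 1.0);
    rsp = r * r;
  }

  const int n_src = source_voxels.size();

  for (long ph = 0; ph < n_ph; ++ph) {
    double x, y, z, ux, uy, uz, w = 1.0;
    if (source_type == 0) {
      x = rng.runif() * Lx; y = rng.runif() * Ly; z = eps;
      ux = 0; uy = 0; uz = 1;
      specular += rsp; w -= rsp;
    } else if (source_type == 1) {
      x = 0.5 * Lx; y = 0.5 * Ly; z = eps;
      ux = 0; uy = 0; uz = 1;
      specular += rsp; w -= rsp;
    } else if (source_type == 2) {
      x = source_params[0]; y = source_params[1]; z = source_params[2];
      double ct = 2.0 * rng.runif() - 1.0;
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 6.283185307179586 * rng.runif();
      ux = st * std::cos(phi); uy = st * std::sin(phi); uz = ct;
    } else {
      // voxel source: binary search the cumulative weights
      double u = rng.runif();
      int lo = 0, hi = n_src - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (source_cumw[mid] < u) lo = mid + 1; else hi = mid;
      }
      R_xlen_t v = source_voxels[lo];
      int iz = static_cast<int>(v / (static_cast<R_xlen_t>(nx) * ny));
      int rem = static_cast<int>(v - static_cast<R_xlen_t>(iz) * nx * ny);
      int iy = rem / nx, ix = rem % nx;
      x = (ix + rng.runif()) * h;
      y = (iy + rng.runif()) * h;
      z = (iz + rng.runif()) * h;
      double ct = 2.0 * rng.runif() - 1.0;
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 6.283185307179586 * rng.runif();
      ux = st * std::cos(phi); uy = st * std::sin(phi); uz = ct;
    }

    bool alive = true;
    long n_inter = 0;
    // inverse direction components, refreshed after every direction change
    double iux = (ux != 0) ? 1.0 / ux : 1e30;
    double iuy = (uy != 0) ? 1.0 / uy : 1e30;
    double iuz = (uz != 0) ? 1.0 / uz : 1e30;
    while (alive) {
      double s = -std::log(rng.runif()); // dimensionless path length
      while (s > 0 && alive) {
        int ix = static_cast<int>(x * inv_h); if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
        int iy = static_cast<int>(y * inv_h); if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
        int iz = static_cast<int>(z * inv_h); if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
        R_xlen_t idx = ix + static_cast<R_xlen_t>(nx) * (iy + static_cast<R_xlen_t>(ny) * iz);
        int l = lab[idx];
        double mt = mut[l];

        // distance to the nearest voxel face along the direction of flight
        double db = 1e30;
        if (ux > 0)      { double t = ((ix + 1) * h - x) * iux; if (t < db) db = t; }
        else if (ux < 0) { double t = (ix * h - x) * iux;       if (t < db) db = t; }
        if (uy > 0)      { double t = ((iy + 1) * h - y) * iuy; if (t < db) db = t; }
        else if (uy < 0) { double t = (iy * h - y) * iuy;       if (t < db) db = t; }
        if (uz > 0)      { double t = ((iz + 1) * h - z) * iuz; if (t < db) db = t; }
        else if (uz < 0) { double t = (iz * h - z) * iuz;       if (t < db) db = t; }
        if (db < 0) db = 0;

        if (mt * db >= s) {
          // interaction inside this voxel
          double step = s * inv_mut[l];
          x += step * ux; y += step * uy; z += step * uz;
          s = 0;
          double dw = w * albedo_a[l];
          deposited += dw;
          if (record_absorption) amap[idx] += dw;
          w -= dw;
          scatter(rng, gg[l], ux, uy, uz);
          iux = (ux != 0) ? 1.0 / ux : 1e30;
          iuy = (uy != 0) ? 1.0 / uy : 1e30;
          iuz = (uz != 0) ? 1.0 / uz : 1e30;
          ++n_inter;
          if (w < roulette_threshold) {
            if (rng.runif() < roulette_survival) {
              double gain = w / roulette_survival - w;
              roulette_gained += gain;
              w /= roulette_survival;
            } else {
              roulette_killed += w;
              alive = false;
            }
          }
          if (n_inter > 10000000L) { guard_killed += w; alive = false; }
        } else {
          // advance to the voxel boundary and nudge across it
          x += (db + eps) * ux; y += (db + eps) * uy; z += (db + eps) * uz;
          s -= mt * db;
          if (z < 0) {
            double ci = -uz;
            double R = fresnel_R(n_rel, ci);
            if (R > 0 && rng.runif() < R) {
              z = -z; uz = -uz; iuz = -iuz; // internally reflected at the surface
            } else {
              int px = static_cast<int>(x / h);
              if (px < 0) px = 0; if (px >= nx) px = nx - 1;
              int py = static_cast<int>(y / h);
              if (py < 0) py = 0; if (py >= ny) py = ny - 1;
              simg[px + static_cast<R_xlen_t>(nx) * py] += w;
              escaped_top += w;
              alive = false;
            }
          } else if (x < 0 || x >= Lx || y < 0 || y >= Ly || z >= Lz) {
            escaped_side += w;
            alive = false;
          }
        }
      }
    }
  }

  const double inv_n = 1.0 / static_cast<double>(n_ph);
  for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(nx) * ny; ++i) simg[i] *= inv_n;
  if (record_absorption) {
    for (R_xlen_t i = 0; i < nvox; ++i) amap[i] *= inv_n;
  }
  return List::create(
    _["surface"] = surface,
    _["absorption"] = absorption,
    _["deposited"] = deposited * inv_n,
    _["escaped_top"] = escaped_top * inv_n,
    _["escaped_side"] = escaped_side * inv_n,
    _["specular"] = specular * inv_n,
    _["roulette_killed"] = roulette_killed * inv_n,
    _["roulette_gained"] = roulette_gained * inv_n,
    _["guard_killed"] = guard_killed * inv_n,
    _["n_photons"] = static_cast<double>(n_ph));
}
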