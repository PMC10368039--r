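// 3D Monte Carlo photon transport through the cylinder-in-holder construct:
// [ambient | top glass window | sample cylinder + lateral gap | bottom window | ambient]
// z increases downward from the illuminated top surface; lengths in mm.
//
// Weighted-photon scheme (MCML lineage): exponential free paths in mu_t,
// per-interaction deposition of w*mu_a/mu_t, Henyey-Greenstein deflection,
// unpolarized Fresnel reflection/refraction at every index step, Russian
// roulette termination. All randomness comes from a per-photon xoshiro256++
// stream seeded by splitmix64(run seed, photon index), so photon i sees the
// same stream regardless of the optical properties: common random numbers
// across lookup-table nodes and sensitivity arms.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

namespace {

// ---- RNG: splitmix64 -> xoshiro256++ -----------------------------------

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t run_seed, uint64_t stream) {
    uint64_t x = run_seed ^ (0xD1B54A32D192ED03ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on the open interval (0, 1)
  double runif() {
    return (static_cast<double>(next() >> 11) + 0.5) * 0x1.0p-53;
  }
};

// ---- geometry ----------------------------------------------------------

enum Region { AMBIENT_TOP = 0, TOP_WINDOW, SAMPLE, GAP, BOTTOM_WINDOW,
              AMBIENT_BOTTOM, WALL };

struct Geometry {
  double rs, d, wt, wb;          // sample radius, thickness, window thicknesses
  double rh;                     // holder radius
  double cut_k;                  // oblique-cut slope: depth(x) = cut_k*(x+rs)
  double cut_depth;
  bool lambertian_bottom;
  double z_top_win, z_mid_top, z_mid_bot, z_bot;  // plane positions

  void init() {
    z_top_win = 0.0;
    z_mid_top = wt;
    z_mid_bot = wt + d;
    z_bot = wt + d + wb;
    cut_k = (cut_depth > 0.0) ? cut_depth / (2.0 * rs) : 0.0;
  }

  // signed value: < 0 above (sample side of) the bottom-cut plane
  double cut_f(double x, double z) const {
    return z - (z_mid_bot - cut_k * (x + rs));
  }

  int region_of(double x, double y, double z) const {
    if (z < 0.0) return AMBIENT_TOP;
    if (z >= z_bot) return AMBIENT_BOTTOM;
    double r2 = x * x + y * y;
    if (r2 >= rh * rh) return WALL;
    if (wt > 0.0 && z < z_mid_top) return TOP_WINDOW;
    if (z < z_mid_bot) {
      if (r2 < rs * rs && cut_f(x, z) < 0.0) return SAMPLE;
      return GAP;
    }
    if (wb > 0.0) return BOTTOM_WINDOW;
    return AMBIENT_BOTTOM;
  }
};

struct Medium { double mua, mus, g, n; };

const double EPS = 1e-9;      // boundary push, mm
const double TMAX = 1e9;

// distance to plane z = zp along direction uz from z
inline double dist_plane(double z, double uz, double zp) {
  if (std::fabs(uz) < 1e-300) return TMAX;
  double t = (zp - z) / uz;
  return (t > EPS) ? t : TMAX;
}

// distance to cylinder radius r about the z axis
inline double dist_cyl(double x, double y, double ux, double uy, double r) {
  double a = ux * ux + uy * uy;
  if (a < 1e-300) return TMAX;
  double b = x * ux + y * uy;
  double c = x * x + y * y - r * r;
  double disc = b * b - a * c;
  if (disc <= 0.0) return TMAX;
  double sq = std::sqrt(disc);
  double t1 = (-b - sq) / a;
  double t2 = (-b + sq) / a;
  if (t1 > EPS) return t1;
  if (t2 > EPS) return t2;
  return TMAX;
}

struct Photon {
  double x, y, z, ux, uy, uz, w;
  bool scattered;
};

// rotate direction by (cos_theta, phi) about current direction
inline void deflect(Photon& p, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = p.ux, uy = p.uy, uz = p.uz;
  if (std::fabs(uz) > 0.99999) {
    p.ux = st * cp;
    p.uy = st * sp;
    p.uz = ct * (uz >= 0.0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    p.ux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    p.uy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    p.uz = -st * cp * den + uz * ct;
  }
  double nrm = std::sqrt(p.ux * p.ux + p.uy * p.uy + p.uz * p.uz);
  p.ux /= nrm; p.uy /= nrm; p.uz /= nrm;
}

inline double fresnel(double n1, double n2, double ci) {
  if (n1 == n2) return 0.0;
  double s2 = (n1 / n2) * (n1 / n2) * (1.0 - ci * ci);
  if (s2 >= 1.0) return 1.0;
  double ct = std::sqrt(1.0 - s2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// cosine-weighted direction about unit normal (nx, ny, nz)
inline void lambertian_about(Photon& p, double nx, double ny, double nz,
                             Xoshiro& rng) {
  double u1 = rng.runif(), u2 = rng.runif();
  double st = std::sqrt(u1), ct = std::sqrt(1.0 - u1);
  double phi = 2.0 * M_PI * u2;
  // build tangent frame around the normal
  double tx, ty, tz;
  if (std::fabs(nz) < 0.9) { tx = -ny; ty = nx; tz = 0.0; }
  else { tx = 1.0; ty = 0.0; tz = 0.0; }
  double tn = std::sqrt(tx * tx + ty * ty + tz * tz);
  tx /= tn; ty /= tn; tz /= tn;
  double bx = ny * tz - nz * ty;
  double by = nz * tx - nx * tz;
  double bz = nx * ty - ny * tx;
  p.ux = st * std::cos(phi) * tx + st * std::sin(phi) * bx + ct * nx;
  p.uy = st * std::cos(phi) * ty + st * std::sin(phi) * by + ct * ny;
  p.uz = st * std::cos(phi) * tz + st * std::sin(phi) * bz + ct * nz;
}

}  // namespace

// [[Rcpp::export(name = ".mc_simulate_cpp")]]
Rcpp::List mc_simulate_cpp(double mua, double mus, double g, double n_sample,
                           double sample_radius, double sample_thickness,
                           double window_thickness, double window_n,
                           double gap_mua, double gap_mus, double gap_g,
                           double gap_n,
                           double holder_radius, double beam_radius,
                           double cut_depth, bool lambertian_bottom,
                           int n_photons, double seed,
                           double roulette_wmin = 1e-4,
                           double roulette_p = 0.1) {
  if (n_photons < 1) Rcpp::stop("n_photons must be >= 1");
  if (mua < 0 || mus < 0 || std::fabs(g) >= 1 || n_sample < 1)
    Rcpp::stop("nonphysical sample optical properties");
  if (gap_mua < 0 || gap_mus < 0 || gap_n < 1)
    Rcpp::stop("nonphysical gap medium properties");

  Geometry geo;
  geo.rs = sample_radius; geo.d = sample_thickness;
  geo.wt = window_thickness; geo.wb = window_thickness;
  geo.rh = holder_radius;
  geo.cut_depth = cut_depth;
  geo.lambertian_bottom = lambertian_bottom;
  geo.init();

  Medium med[6];
  med[AMBIENT_TOP] = {0, 0, 0, 1.0};
  med[TOP_WINDOW] = {0, 0, 0, window_n};
  med[SAMPLE] = {mua, mus, g, n_sample};
  med[GAP] = {gap_mua, gap_mus, gap_g, gap_n};
  med[BOTTOM_WINDOW] = {0, 0, 0, window_n};
  med[AMBIENT_BOTTOM] = {0, 0, 0, 1.0};

  double R_diffuse = 0, R_specular = 0, T_total = 0, A_sample = 0,
         A_other = 0, side_loss = 0, roulette_net = 0;
  double sum_r = 0, sum_r2 = 0, sum_t = 0, sum_t2 = 0;

  const uint64_t useed = static_cast<uint64_t>(seed);
  const long max_events = 4000000L;

  for (int i = 0; i < n_photons; ++i) {
    Xoshiro rng;
    rng.seed(useed, static_cast<uint64_t>(i));

    Photon p;
    double br = beam_radius * std::sqrt(rng.runif());
    double bphi = 2.0 * M_PI * rng.runif();
    p.x = br * std::cos(bphi); p.y = br * std::sin(bphi);
    p.z = -10.0 * EPS;
    p.ux = 0; p.uy = 0; p.uz = 1;
    p.w = 1.0;
    p.scattered = false;

    double phot_r = 0, phot_t = 0;
    bool alive = true;
    long events = 0;

    while (alive) {
      if (++events > max_events) {  // safety cap; effectively never reached
        A_other += p.w;
        break;
      }
      int reg = geo.region_of(p.x, p.y, p.z);
      if (reg == AMBIENT_TOP && p.uz < 0) {
        if (p.scattered) { R_diffuse += p.w; phot_r += p.w; }
        else R_specular += p.w;
        break;
      }
      if (reg == AMBIENT_BOTTOM && p.uz > 0) {
        T_total += p.w; phot_t += p.w;
        break;
      }
      if (reg == WALL) { side_loss += p.w; break; }

      const Medium& m = med[reg];
      double mut = m.mua + m.mus;
      double s = (mut > 0.0) ? -std::log(rng.runif()) / mut : TMAX;

      // nearest boundary along the flight direction
      double t = TMAX;
      int surf = -1;  // 0: z=0, 1: z=mid_top, 2: z=mid_bot, 3: z=z_bot,
                      // 4: r=rs, 5: r=rh, 6: cut plane
      double cand;
      cand = dist_plane(p.z, p.uz, geo.z_top_win);
      if (cand < t) { t = cand; surf = 0; }
      if (geo.wt > 0.0) {
        cand = dist_plane(p.z, p.uz, geo.z_mid_top);
        if (cand < t) { t = cand; surf = 1; }
      }
      cand = dist_plane(p.z, p.uz, geo.z_mid_bot);
      if (cand < t) { t = cand; surf = 2; }
      if (geo.wb > 0.0) {
        cand = dist_plane(p.z, p.uz, geo.z_bot);
        if (cand < t) { t = cand; surf = 3; }
      }
      cand = dist_cyl(p.x, p.y, p.ux, p.uy, geo.rs);
      if (cand < t) { t = cand; surf = 4; }
      cand = dist_cyl(p.x, p.y, p.ux, p.uy, geo.rh);
      if (cand < t) { t = cand; surf = 5; }
      if (geo.cut_k > 0.0) {
        double den = geo.cut_k * p.ux + p.uz;
        if (std::fabs(den) > 1e-300) {
          double tc = -geo.cut_f(p.x, p.z) / den;
          if (tc > EPS && tc < t) { t = tc; surf = 6; }
        }
      }

      if (s < t) {
        // interaction inside the medium
        p.x += s * p.ux; p.y += s * p.uy; p.z += s * p.uz;
        double dep = p.w * m.mua / mut;
        if (reg == SAMPLE) A_sample += dep; else A_other += dep;
        p.w -= dep;
        if (m.mus <= 0.0) {  // pure absorber: nothing left to scatter
          if (p.w > 0) A_other += p.w;  // numerically zero
          break;
        }
        double u = rng.runif();
        double ct;
        if (m.g == 0.0) ct = 2.0 * u - 1.0;
        else {
          double f = (1.0 - m.g * m.g) / (1.0 - m.g + 2.0 * m.g * u);
          ct = (1.0 + m.g * m.g - f * f) / (2.0 * m.g);
          if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
        }
        deflect(p, ct, 2.0 * M_PI * rng.runif());
        p.scattered = true;

        if (p.w < roulette_wmin) {
          if (rng.runif() < roulette_p) {
            double w_old = p.w;
            p.w /= roulette_p;
            roulette_net -= (p.w - w_old);
          } else {
            roulette_net += p.w;
            break;
          }
        }
        continue;
      }

      // move to the boundary and resolve the interface
      p.x += t * p.ux; p.y += t * p.uy; p.z += t * p.uz;

      // surface normal (pointing against the photon, i.e. -cos incidence > 0)
      double nx = 0, ny = 0, nz = 0;
      if (surf <= 3) { nz = (p.uz > 0) ? -1.0 : 1.0; }
      else if (surf == 4 || surf == 5) {
        double rr = std::sqrt(p.x * p.x + p.y * p.y);
        nx = p.x / rr; ny = p.y / rr;
        if (nx * p.ux + ny * p.uy > 0) { nx = -nx; ny = -ny; }
      } else {  // cut plane, gradient (cut_k, 0, 1)
        double nn = std::sqrt(geo.cut_k * geo.cut_k + 1.0);
        nx = geo.cut_k / nn; nz = 1.0 / nn;
        if (nx * p.ux + nz * p.uz > 0) { nx = -nx; nz = -nz; }
      }

      double ci = -(p.ux * nx + p.uy * ny + p.uz * nz);  // cos incidence
      if (ci < 0) ci = 0; if (ci > 1) ci = 1;

      // media on either side
      int reg2 = geo.region_of(p.x + 10 * EPS * p.ux,
                               p.y + 10 * EPS * p.uy,
                               p.z + 10 * EPS * p.uz);
      double n1 = med[reg].n;
      double n2 = (reg2 == WALL) ? med[reg].n : med[reg2].n;

      if (reg2 == WALL) {  // absorbing holder wall
        side_loss += p.w;
        break;
      }

      bool bottom_face = (surf == 6) ||
        (surf == 2 && geo.cut_k == 0.0 &&
         (reg == SAMPLE || reg2 == SAMPLE));

      if (geo.lambertian_bottom && bottom_face) {
        // maximal roughness: the surface decorrelates the photon direction.
        // The Fresnel split is decided at a cosine-weighted local incidence
        // angle (microfacet average) and both the reflected and the
        // transmitted photon leave with a Lambertian direction.
        double ci_local = std::sqrt(1.0 - rng.runif());  // cosine-weighted
        double R = fresnel(n1, n2, ci_local);
        p.scattered = true;
        if (rng.runif() < R) {
          lambertian_about(p, nx, ny, nz, rng);
        } else {
          lambertian_about(p, -nx, -ny, -nz, rng);
        }
        p.x += 10 * EPS * p.ux; p.y += 10 * EPS * p.uy; p.z += 10 * EPS * p.uz;
        continue;
      }

      if (n1 == n2) {  // index-matched: pass through
        p.x += 10 * EPS * p.ux; p.y += 10 * EPS * p.uy; p.z += 10 * EPS * p.uz;
        continue;
      }

      double R = fresnel(n1, n2, ci);
      if (rng.runif() < R) {
        // specular reflection
        double dot = p.ux * nx + p.uy * ny + p.uz * nz;
        p.ux -= 2.0 * dot * nx; p.uy -= 2.0 * dot * ny; p.uz -= 2.0 * dot * nz;
      } else {
        // Snell refraction
        double eta = n1 / n2;
        double k = 1.0 - eta * eta * (1.0 - ci * ci);
        double ct = std::sqrt(std::max(0.0, k));
        p.ux = eta * p.ux + (eta * ci - ct) * nx;
        p.uy = eta * p.uy + (eta * ci - ct) * ny;
        p.uz = eta * p.uz + (eta * ci - ct) * nz;
        double nrm = std::sqrt(p.ux * p.ux + p.uy * p.uy + p.uz * p.uz);
        p.ux /= nrm; p.uy /= nrm; p.uz /= nrm;
      }
      p.x += 10 * EPS * p.ux; p.y += 10 * EPS * p.uy; p.z += 10 * EPS * p.uz;
    }

    sum_r += phot_r; sum_r2 += phot_r * phot_r;
    sum_t += phot_t; sum_t2 += phot_t * phot_t;
  }

  double N = static_cast<double>(n_photons);
  double mr = sum_r / N, mt = sum_t / N;
  double se_r = std::sqrt(std::max(0.0, sum_r2 / N - mr * mr) / N);
  double se_t = std::sqrt(std::max(0.0, sum_t2 / N - mt * mt) / N);

  return Rcpp::List::create(
    Rcpp::Named("R_diffuse") = R_diffuse / N,
    Rcpp::Named("R_specular") = R_specular / N,
    Rcpp::Named("T_total") = T_total / N,
    Rcpp::Named("A_sample") = A_sample / N,
    Rcpp::Named("A_other") = A_other / N,
    Rcpp::Named("side_loss") = side_loss / N,
    Rcpp::Named("roulette_net") = roulette_net / N,
    Rcpp::Named("se_R") = se_r,
    Rcpp::Named("se_T") = se_t);
}
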