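// Weighted photon-packet Monte Carlo transport in a layered slab with an
// embedded cylindrical artery (axis parallel to y at x = ax, z = az).
//
// Conventions: lengths in mm, optical coefficients in mm^-1, z increases
// with depth from the irradiated surface at z = 0.  Packets carry a
// continuous weight reduced by the single-scattering albedo at each
// collision; low weights are terminated by Russian roulette with exact
// bookkeeping so injected = detected + absorbed + escaped to float rounding.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// --- counter-based per-packet RNG: splitmix64-seeded xoshiro256++ ---------
// Packet i gets the same substream for a given global seed regardless of
// batch partitioning, which both guarantees reproducibility and makes
// common-random-number sweeps effective.
struct PacketRNG {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t global, uint64_t packet) {
    uint64_t x = global * 0x9E3779B97F4A7C15ULL + (packet ^ 0x632BE59BD9B4E019ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform in the open interval (0, 1)
  inline double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

constexpr double EPS_STEP = 1e-7;   // nudge across geometric boundaries (mm)
constexpr double BIG = 1e30;

inline int layer_of(double z, const std::vector<double> &zb) {
  // zb: internal boundaries (ascending); layer k occupies [zb[k-1], zb[k})
  int k = 0;
  while (k < (int)zb.size() && z >= zb[k]) ++k;
  return k;
}

// Fresnel reflectance, unpolarised, internal index n -> 1 at the surface
inline double fresnelR(double cosi, double n) {
  double sint2 = n * n * (1.0 - cosi * cosi);
  if (sint2 >= 1.0) return 1.0;  // total internal reflection
  double cost = std::sqrt(1.0 - sint2);
  double rs = (n * cosi - cost) / (n * cosi + cost);
  double rp = (n * cost - cosi) / (n * cost + cosi);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// [[Rcpp::export]]
List mc_transport_cpp(List geom, List src, List det, List opt, List rec) {
  // --- geometry -----------------------------------------------------------
  std::vector<double> zb  = as<std::vector<double>>(geom["zb"]);    // internal boundaries
  std::vector<double> mua = as<std::vector<double>>(geom["mua"]);   // per layer, mm^-1
  std::vector<double> mus = as<std::vector<double>>(geom["mus"]);
  const double g = as<double>(geom["g"]);
  const bool  artery_on = as<bool>(geom["artery_on"]);
  const double art_ax = as<double>(geom["artery_ax"]);
  const double art_az = as<double>(geom["artery_az"]);
  const double art_r  = as<double>(geom["artery_r"]);
  const double art_r2 = art_r * art_r;
  const double mua_b  = as<double>(geom["artery_mua"]);
  const double mus_b  = as<double>(geom["artery_mus"]);
  const double xlo = as<double>(geom["xlo"]), xhi = as<double>(geom["xhi"]);
  const double ylo = as<double>(geom["ylo"]), yhi = as<double>(geom["yhi"]);
  const double zmax = as<double>(geom["zmax"]);
  const bool voxel_mode = as<bool>(geom["voxel_mode"]);
  const double h = as<double>(geom["voxel_mm"]);

  // --- source / detector --------------------------------------------------
  const double sx = as<double>(src["x"]), sy = as<double>(src["y"]);
  const int src_type = as<int>(src["type"]);            // 0 pencil, 1 cone
  const double cos_half = std::cos(as<double>(src["half_angle"]));
  const double dcx = as<double>(det["cx"]), dcy = as<double>(det["cy"]);
  const int det_shape = as<int>(det["shape"]);          // 0 square, 1 disc
  const double dhalf = as<double>(det["half"]);         // half-side or radius
  const double dhalf2 = dhalf * dhalf;

  // --- options ------------------------------------------------------------
  const double n_photons_d = as<double>(opt["n_photons"]);
  const long long n_photons = (long long)n_photons_d;
  const uint64_t seed = (uint64_t)as<double>(opt["seed"]);
  const uint64_t packet_offset = (uint64_t)as<double>(opt["packet_offset"]);
  const double w_thresh = as<double>(opt["w_threshold"]);
  const double p_surv = as<double>(opt["p_survival"]);
  const int boundary = as<int>(opt["boundary"]);        // 0 matched, 1 Fresnel
  const double n_tissue = as<double>(opt["n_tissue"]);
  const long long max_steps = (long long)as<double>(opt["max_steps"]);

  // --- recording ----------------------------------------------------------
  // mode 0: none; mode 1: path length / collisions inside the active artery
  // (per detected packet); mode 2: same for a grid of cylinders (axes x radii)
  const int rec_mode = as<int>(rec["mode"]);
  std::vector<double> rec_az, rec_radii;
  if (rec_mode == 2) {
    rec_az = as<std::vector<double>>(rec["axes_z"]);
    rec_radii = as<std::vector<double>>(rec["radii"]);
  }
  const double rec_ax = (rec_mode == 2) ? as<double>(rec["axes_x"]) : art_ax;
  const int n_ax = (rec_mode == 2) ? (int)rec_az.size() : 1;
  const int n_rad = (rec_mode == 2) ? (int)rec_radii.size() : 1;
  const int n_cyl = (rec_mode > 0) ? n_ax * n_rad : 0;
  double rec_rmax = art_r;
  if (rec_mode == 2) { rec_rmax = 0.0; for (double r : rec_radii) rec_rmax = std::max(rec_rmax, r); }
  const double rec_rmax2 = rec_rmax * rec_rmax;

  // per-packet scratch
  std::vector<double> path_l(std::max(n_cyl, 1), 0.0);
  std::vector<int>    path_k(std::max(n_cyl, 1), 0);

  // per-detected-packet records
  std::vector<double> det_w, det_x, det_y, det_id;
  std::vector<double> det_l;   // n_det x n_cyl, row-major
  std::vector<int>    det_k;

  // --- tallies ------------------------------------------------------------
  double detected = 0.0, absorbed = 0.0, escaped = 0.0, escaped_bottom = 0.0;
  double det_sumw2 = 0.0;
  long long n_detected = 0, n_lost = 0;

  const double entry_R = (boundary == 1)
    ? std::pow((n_tissue - 1.0) / (n_tissue + 1.0), 2.0) : 0.0;

  PacketRNG rng;

  for (long long p = 0; p < n_photons; ++p) {
    rng.seed(seed, packet_offset + (uint64_t)p);
    double x = sx, y = sy, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    if (src_type == 1) {
      double ct = 1.0 - rng.unif() * (1.0 - cos_half);
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * rng.unif();
      ux = st * std::cos(phi); uy = st * std::sin(phi); uz = ct;
    }
    double w = 1.0;
    if (boundary == 1) { absorbed += 0.0; escaped += entry_R; w -= entry_R; }
    z = EPS_STEP;  // just inside the medium
    if (rec_mode > 0) { std::fill(path_l.begin(), path_l.end(), 0.0);
                        std::fill(path_k.begin(), path_k.end(), 0); }

    long long steps = 0;
    bool alive = true;
    while (alive) {
      if (++steps > max_steps) { escaped += w; ++n_lost; break; }

      // material at current position
      int lay;
      double zq = z, xq = x;
      if (voxel_mode) {  // material of the containing voxel, queried at its centre
        zq = (std::floor(z / h) + 0.5) * h;
        xq = (std::floor(x / h) + 0.5) * h;
      }
      lay = layer_of(zq, zb);
      double m_a = mua[lay], m_s = mus[lay];
      if (artery_on) {
        double dx0 = xq - art_ax, dz0 = zq - art_az;
        if (dx0 * dx0 + dz0 * dz0 <= art_r2) { m_a = mua_b; m_s = mus_b; }
      }
      const double mut = m_a + m_s;

      // distance to nearest geometric boundary along the direction;
      // the free surface is checked first so exact ties resolve to an exit
      double tb = BIG;
      int hit = -1;  // 0 top, 1 bottom/lateral escape, 2 internal (re-enter loop)
      if (uz < 0) { tb = -z / uz; hit = 0; }
      if (voxel_mode) {
        // next voxel face in x, y(none: material y-invariant), z
        if (ux > 0)      { double t = ((std::floor(x / h) + 1.0) * h - x) / ux; if (t < tb) { tb = t; hit = 2; } }
        else if (ux < 0) { double t = (std::floor(x / h) * h - x) / ux;         if (t < tb) { tb = t; hit = 2; } }
        if (uz > 0)      { double t = ((std::floor(z / h) + 1.0) * h - z) / uz; if (t < tb) { tb = t; hit = 2; } }
        else if (uz < 0) { double t = (std::floor(z / h) * h - z) / uz;         if (t < tb) { tb = t; hit = 2; } }
      } else {
        // layer planes
        if (uz > 0) {
          for (double b : zb) if (b > z) { double t = (b - z) / uz; if (t < tb) { tb = t; hit = 2; } break; }
        } else if (uz < 0) {
          for (int k = (int)zb.size() - 1; k >= 0; --k)
            if (zb[k] < z) { double t = (zb[k] - z) / uz; if (t < tb) { tb = t; hit = 2; } break; }
        }
        // artery cylinder surface
        if (artery_on) {
          double dx0 = x - art_ax, dz0 = z - art_az;
          double a = ux * ux + uz * uz;
          if (a > 1e-14) {
            double b2 = dx0 * ux + dz0 * uz;
            double c = dx0 * dx0 + dz0 * dz0 - art_r2;
            double disc = b2 * b2 - a * c;
            if (disc > 0.0) {
              double sq = std::sqrt(disc);
              double t1 = (-b2 - sq) / a, t2 = (-b2 + sq) / a;
              if (t1 > 1e-12 && t1 < tb) { tb = t1; hit = 2; }
              else if (t2 > 1e-12 && t2 < tb) { tb = t2; hit = 2; }
            }
          }
        }
      }
      // domain walls
      if (uz > 0) { double t = (zmax - z) / uz; if (t < tb) { tb = t; hit = 1; } }
      if (ux > 0) { double t = (xhi - x) / ux; if (t < tb) { tb = t; hit = 1; } }
      else if (ux < 0) { double t = (xlo - x) / ux; if (t < tb) { tb = t; hit = 1; } }
      if (uy > 0) { double t = (yhi - y) / uy; if (t < tb) { tb = t; hit = 1; } }
      else if (uy < 0) { double t = (ylo - y) / uy; if (t < tb) { tb = t; hit = 1; } }

      // sampled free path (infinite in a void)
      double s = (mut > 0.0) ? -std::log(rng.unif()) / mut : BIG;
      const bool interact = (s < tb);
      const double move = interact ? s : tb;

      // path-length recording over this segment
      if (rec_mode > 0) {
        double dx0 = x - rec_ax;
        double sxmin = std::min(dx0, dx0 + ux * move), sxmax = std::max(dx0, dx0 + ux * move);
        if (sxmax >= -rec_rmax && sxmin <= rec_rmax) {
          double a = ux * ux + uz * uz;
          for (int ia = 0; ia < n_ax; ++ia) {
            double azc = (rec_mode == 2) ? rec_az[ia] : art_az;
            double dz0 = z - azc;
            double szmin = std::min(dz0, dz0 + uz * move), szmax = std::max(dz0, dz0 + uz * move);
            if (szmax < -rec_rmax || szmin > rec_rmax) continue;
            double b2 = dx0 * ux + dz0 * uz;
            double c0 = dx0 * dx0 + dz0 * dz0;
            for (int ir = 0; ir < n_rad; ++ir) {
              double r2 = (rec_mode == 2) ? rec_radii[ir] * rec_radii[ir] : art_r2;
              int idx = ia * n_rad + ir;
              if (a < 1e-14) { if (c0 <= r2) path_l[idx] += move; continue; }
              double disc = b2 * b2 - a * (c0 - r2);
              if (disc <= 0.0) continue;
              double sq = std::sqrt(disc);
              double lo = std::max((-b2 - sq) / a, 0.0);
              double hi = std::min((-b2 + sq) / a, move);
              if (hi > lo) path_l[idx] += hi - lo;
            }
          }
        }
      }

      x += ux * move; y += uy * move; z += uz * move;

      if (!interact) {
        if (hit == 0) {
          // reached the free surface
          double cosi = -uz;
          if (boundary == 1) {
            double R = fresnelR(cosi, n_tissue);
            if (rng.unif() < R) { uz = -uz; z = EPS_STEP; continue; }
          }
          bool in_det;
          if (det_shape == 0)
            in_det = std::fabs(x - dcx) <= dhalf && std::fabs(y - dcy) <= dhalf;
          else {
            double ddx = x - dcx, ddy = y - dcy;
            in_det = ddx * ddx + ddy * ddy <= dhalf2;
          }
          if (in_det) {
            detected += w; det_sumw2 += w * w; ++n_detected;
            if (rec_mode > 0) {
              det_w.push_back(w); det_x.push_back(x); det_y.push_back(y);
              det_id.push_back((double)(packet_offset + (uint64_t)p));
              for (int j = 0; j < n_cyl; ++j) { det_l.push_back(path_l[j]); det_k.push_back(path_k[j]); }
            }
          } else escaped += w;
          alive = false;
        } else if (hit == 1) {
          escaped += w;
          if (z >= zmax - 1e-9) escaped_bottom += w;
          alive = false;
        } else {
          // internal boundary: nudge across and resample (exponential is memoryless)
          x += ux * EPS_STEP; y += uy * EPS_STEP; z += uz * EPS_STEP;
        }
        continue;
      }

      // collision: albedo weighting + Henyey-Greenstein scatter
      if (mut <= 0.0) { escaped += w; alive = false; continue; }  // unreachable guard
      if (rec_mode > 0) {
        double dx0 = x - rec_ax;
        if (dx0 * dx0 <= rec_rmax2) {
          for (int ia = 0; ia < n_ax; ++ia) {
            double azc = (rec_mode == 2) ? rec_az[ia] : art_az;
            double dz0 = z - azc;
            double d2 = dx0 * dx0 + dz0 * dz0;
            for (int ir = 0; ir < n_rad; ++ir) {
              double r2 = (rec_mode == 2) ? rec_radii[ir] * rec_radii[ir] : art_r2;
              if (d2 <= r2) ++path_k[ia * n_rad + ir];
            }
          }
        }
      }
      double dw = w * m_a / mut;
      absorbed += dw;
      w -= dw;

      double ct;
      if (g != 0.0) {
        double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
        ct = (1.0 + g * g - f * f) / (2.0 * g);
        if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      } else ct = 2.0 * rng.unif() - 1.0;
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      // uniform azimuth via rejection (Marsaglia): cheaper than cos/sin
      double cp, sp;
      for (;;) {
        double v1 = 2.0 * rng.unif() - 1.0, v2 = 2.0 * rng.unif() - 1.0;
        double s2 = v1 * v1 + v2 * v2;
        if (s2 > 0.0 && s2 < 1.0) {
          cp = (v1 * v1 - v2 * v2) / s2; sp = 2.0 * v1 * v2 / s2; break;
        }
      }
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = (uz >= 0.0) ? ct : -ct;
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nz = -st * cp * den + uz * ct;
        double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
        ux = nx / norm; uy = ny / norm; uz = nz / norm;
      }

      // Russian roulette with exact weight bookkeeping
      if (w < w_thresh) {
        if (rng.unif() < p_surv) {
          absorbed -= w * (1.0 / p_surv - 1.0);
          w /= p_surv;
        } else { absorbed += w; alive = false; }
      }
    }
  }

  List out = List::create(
    _["injected"] = (double)n_photons,
    _["detected"] = detected,
    _["absorbed"] = absorbed,
    _["escaped"] = escaped,
    _["escaped_bottom"] = escaped_bottom,
    _["n_detected"] = (double)n_detected,
    _["det_sumw2"] = det_sumw2,
    _["n_lost"] = (double)n_lost);
  if (rec_mode > 0) {
    out["rec_w"] = NumericVector(det_w.begin(), det_w.end());
    out["rec_x"] = NumericVector(det_x.begin(), det_x.end());
    out["rec_y"] = NumericVector(det_y.begin(), det_y.end());
    out["rec_packet"] = NumericVector(det_id.begin(), det_id.end());
    NumericMatrix L((int)det_w.size(), n_cyl);
    IntegerMatrix K((int)det_w.size(), n_cyl);
    for (int i = 0; i < (int)det_w.size(); ++i)
      for (int j = 0; j < n_cyl; ++j) {
        L(i, j) = det_l[(size_t)i * n_cyl + j];
        K(i, j) = det_k[(size_t)i * n_cyl + j];
      }
    out["rec_l"] = L; out["rec_k"] = K;
  }
  return out;
}
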