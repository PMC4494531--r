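#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weight-tracking Monte-Carlo photon transport in a two-layer slab:
// soft tissue of finite thickness over semi-infinite bone, matched-index
// top boundary (a photon crossing z = 0 upward exits and is scored).
// z grows downward into the tissue; the beam axis passes through the
// origin with direction (sin(theta), 0, cos(theta)).

struct Medium {
  double mua, mus, g, mut, albedo;
};

static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - tmp * tmp) / (2.0 * g);
}

// rotate direction (ux,uy,uz) by polar angle acos(ct) and azimuth phi
static inline void spin(double &ux, double &uy, double &uz,
                        double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// [[Rcpp::export]]
List mc_backscatter_cpp(double tissue_mua, double tissue_mus, double tissue_g,
                        double bone_mua, double bone_mus, double bone_g,
                        double thickness, double beam_radius,
                        double incidence_deg, int n_photons,
                        double bin_width, double max_radius,
                        double roulette_threshold, double roulette_survival,
                        double z_cutoff, int max_steps,
                        double depth_bin_width, double depth_max) {
  if (tissue_mus <= 0.0 || bone_mus <= 0.0)
    stop("scattering coefficient must be positive");
  if (n_photons < 1) stop("n_photons must be >= 1");
  if (thickness < 0.0) stop("thickness must be >= 0");

  Medium tis { tissue_mua, tissue_mus, tissue_g,
               tissue_mua + tissue_mus, tissue_mus / (tissue_mua + tissue_mus) };
  Medium bon { bone_mua, bone_mus, bone_g,
               bone_mua + bone_mus, bone_mus / (bone_mua + bone_mus) };

  int n_bins = (int)std::ceil(max_radius / bin_width);
  NumericVector radial(n_bins + 1);           // last bin = overflow
  int n_depth = (int)std::ceil(depth_max / depth_bin_width);
  NumericVector depth_hist(n_depth + 1);      // exit-weighted max-depth
  double w_exit = 0.0, w_abs = 0.0, w_kill = 0.0, w_lost = 0.0;
  double max_depth_exit = 0.0;
  R_xlen_t n_exit = 0;

  const double th = incidence_deg * M_PI / 180.0;
  const double ax = std::sin(th), az = std::cos(th); // beam axis (ax,0,az)

  for (int ip = 0; ip < n_photons; ++ip) {
    // launch uniformly over the beam disc, offset in the surface plane
    double r0 = beam_radius * std::sqrt(unif_rand());
    double phi0 = 2.0 * M_PI * unif_rand();
    double x = r0 * std::cos(phi0), y = r0 * std::sin(phi0), z = 0.0;
    double ux = ax, uy = 0.0, uz = az;
    double w = 1.0, zmax = 0.0;
    bool alive = true;
    int steps = 0;

    while (alive) {
      if (++steps > max_steps) { w_lost += w; break; }
      double tau = -std::log(unif_rand());     // optical depth to travel
      while (tau > 1e-12) {
        const Medium &m = (z < thickness) ? tis : bon;
        double s = tau / m.mut;
        // distance to nearest z-boundary along the path
        double db = R_PosInf;
        int which = 0; // 1 = top exit, 2 = layer interface
        if (uz < 0.0) {
          db = -z / uz; which = 1;
          if (z >= thickness && thickness > 0.0) {
            db = (thickness - z) / uz; which = 2;  // bone -> tissue interface
          }
        } else if (uz > 0.0) {
          if (z < thickness) { db = (thickness - z) / uz; which = 2; }
        }
        if (s < db || !R_FINITE(db)) {
          x += ux * s; y += uy * s; z += uz * s;
          if (z > zmax) zmax = z;
          tau = 0.0;
        } else {
          x += ux * db; y += uy * db; z += uz * db;
          tau -= db * m.mut;
          if (z > zmax) zmax = z;
          if (which == 1 && z <= 1e-12) {
            // exits the top surface: score radial distance from beam axis
            double px = x, py = y, pz = z;
            double t = px * ax + pz * az;
            double dx = px - t * ax, dy = py, dz = pz - t * az;
            double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            int b = (int)(r / bin_width);
            if (b >= n_bins) b = n_bins;
            radial[b] += w;
            w_exit += w; ++n_exit;
            if (zmax > max_depth_exit) max_depth_exit = zmax;
            int bd = (int)(zmax / depth_bin_width);
            if (bd > n_depth) bd = n_depth;
            depth_hist[bd] += w;
            alive = false;
            break;
          }
          // interface crossing: matched index, direction unchanged;
          // nudge past the boundary to avoid re-detection
          z += (uz > 0 ? 1e-9 : -1e-9);
        }
      }
      if (!alive) break;
      if (z > z_cutoff) { w_lost += w; break; }   // transmitted deep
      const Medium &m = (z < thickness) ? tis : bon;
      w_abs += w * (m.mua / m.mut);
      w *= m.albedo;
      double ct = hg_cos(m.g, unif_rand());
      spin(ux, uy, uz, ct, 2.0 * M_PI * unif_rand());
      if (w < roulette_threshold) {
        // net roulette ledger: survivor boosts are debited against kills
        // so launched = exited + absorbed + killed + lost exactly per run
        if (unif_rand() < roulette_survival) {
          w_kill -= w * (1.0 / roulette_survival - 1.0);
          w /= roulette_survival;
        } else { w_kill += w; break; }
      }
    }
  }

  return List::create(
    _["radial"] = radial,
    _["depth_hist"] = depth_hist,
    _["exited"] = w_exit,
    _["absorbed"] = w_abs,
    _["killed"] = w_kill,
    _["lost"] = w_lost,
    _["n_exited"] = (double)n_exit,
    _["max_depth_exit"] = max_depth_exit);
}
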