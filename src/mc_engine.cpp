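// Monte Carlo photon-packet transport through a stack of horizontal turbid
// layers (hop-drop-spin with implicit capture, unpolarized Fresnel boundary
// events, Henyey-Greenstein scattering, Russian roulette) with cylindrical
// (r,z) scoring of absorption and of the downward partial current at planes
// z = (j+1/2)*dz.
//
// The RNG is a MINSTD Lehmer generator evaluated in double arithmetic so the
// deviate stream is reproducible exactly by the pure-R reference
// implementation (R/mc-reference.R). Keep every formula here in sync with
// that file: the two are compared tally-for-tally in the test suite.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  double s; // state in [1, 2^31-2]
  explicit Rng(double state) : s(state) {}
  double next() {
    // floor-based remainder: 48271 * s < 2^53, so every term is exact
    double a = 48271.0 * s;
    double r = a - std::floor(a / 2147483647.0) * 2147483647.0;
    if (r < 0.0) r += 2147483647.0;
    else if (r >= 2147483647.0) r -= 2147483647.0;
    s = r;
    return s / 2147483647.0; // in (0, 1)
  }
};

double fresnel(double n1, double n2, double cos_i) {
  if (n1 == n2) return 0.0;
  double sin_i = std::sqrt(1.0 - cos_i * cos_i);
  double sin_t = n1 / n2 * sin_i;
  if (sin_t >= 1.0) return 1.0; // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// [[Rcpp::export]]
List mc_engine(int n_photons, double seed_state, NumericMatrix layers,
               double n_above, double n_below,
               double beam_radius, double beam_cx, double beam_cy,
               double focus_depth, int nr, int nz, double dr, double dz,
               double roulette_threshold, double roulette_m) {
  const int nlay = layers.nrow();
  // columns: mu_a, mu_s, g, n, z_top, z_bot
  NumericVector mu_a = layers(_, 0), mu_s = layers(_, 1), gg = layers(_, 2),
                nn = layers(_, 3), z_top = layers(_, 4), z_bot = layers(_, 5);
  for (int i = 0; i < nlay; ++i) {
    if (mu_a[i] + mu_s[i] <= 0.0)
      stop("layer %d has non-positive total interaction coefficient", i + 1);
  }

  NumericMatrix A(nr, nz);     // absorbed weight per (r,z) cell
  NumericMatrix F(nr, nz);     // downward crossings per (r, plane) cell
  NumericVector F_over(nz);    // downward crossings beyond the radial grid
  NumericVector T_r(nr);       // bottom-exit weight per radial bin
  double A_over = 0.0, T_over = 0.0;
  double specular = 0.0, diffuse_refl = 0.0, lost = 0.0;

  Rng rng(seed_state);
  const double TWO_PI = 6.283185307179586;
  const long max_events = 1000000L;

  for (int ip = 0; ip < n_photons; ++ip) {
    // launch: uniform over the spot disc
    double u_r = rng.next(), u_phi = rng.next();
    double rl = beam_radius * std::sqrt(u_r);
    double phl = TWO_PI * u_phi;
    double rx = rl * std::cos(phl), ry = rl * std::sin(phl);
    double x = beam_cx + rx, y = beam_cy + ry, z = 0.0;
    double ux, uy, uz;
    if (focus_depth != 0.0) {
      double sgn = focus_depth > 0.0 ? 1.0 : -1.0;
      double vx = -rx * sgn, vy = -ry * sgn, vz = std::fabs(focus_depth);
      double nrm = std::sqrt(vx * vx + vy * vy + vz * vz);
      ux = vx / nrm; uy = vy / nrm; uz = vz / nrm;
    } else {
      ux = 0.0; uy = 0.0; uz = 1.0;
    }
    // specular entry reflection (implicit: weight split, no draw)
    double rsp = fresnel(n_above, nn[0], uz);
    double w = 1.0 - rsp;
    specular += rsp;
    {
      double scale = n_above / nn[0];
      ux *= scale; uy *= scale;
      uz = std::sqrt(1.0 - (ux * ux + uy * uy));
    }
    int layer = 0;
    bool alive = true;
    double s_left = 0.0; // dimensionless remaining step
    long events = 0;

    while (alive) {
      if (++events > max_events) { lost += w; alive = false; break; }
      double mt = mu_a[layer] + mu_s[layer];
      if (s_left <= 0.0) s_left = -std::log(rng.next());
      double step = s_left / mt;
      // distance to the layer boundary along the flight direction
      double db;
      if (uz > 0.0)      db = (z_bot[layer] - z) / uz;
      else if (uz < 0.0) db = (z_top[layer] - z) / uz;
      else               db = 1.0e30;
      if (db < 0.0) db = 0.0;

      bool hit = db < step;
      double travel = hit ? db : step;
      double z_new = hit ? (uz > 0.0 ? z_bot[layer] : z_top[layer])
                         : z + uz * travel;
      // score downward plane crossings along the segment
      if (uz > 0.0) {
        int j0 = (int)std::floor(z / dz - 0.5) + 1;
        int j1 = (int)std::floor(z_new / dz - 0.5);
        if (j0 < 0) j0 = 0;
        if (j1 > nz - 1) j1 = nz - 1;
        for (int j = j0; j <= j1; ++j) {
          double zp = (j + 0.5) * dz;
          double t = (zp - z) / uz;
          double xx = x + ux * t, yy = y + uy * t;
          double rr = std::sqrt(xx * xx + yy * yy);
          int ir = (int)(rr / dr);
          if (ir < nr) F(ir, j) += w; else F_over[j] += w;
        }
      }
      x += ux * travel; y += uy * travel; z = z_new;

      if (hit) {
        s_left -= travel * mt;
        bool down = uz > 0.0;
        double n1 = nn[layer];
        double n2;
        if (down) n2 = (layer == nlay - 1) ? n_below : nn[layer + 1];
        else      n2 = (layer == 0) ? n_above : nn[layer - 1];
        double ci = std::fabs(uz);
        double rf = fresnel(n1, n2, ci);
        double u_b = rng.next();
        if (u_b <= rf) {
          uz = -uz; // internal reflection
        } else {
          // refract across the interface
          double scale = n1 / n2;
          double uxn = ux * scale, uyn = uy * scale;
          double st2 = uxn * uxn + uyn * uyn;
          double uzn = std::sqrt(st2 < 1.0 ? 1.0 - st2 : 0.0);
          if (down) {
            if (layer == nlay - 1) { // bottom escape (finite stack only)
              int ir = (int)(std::sqrt(x * x + y * y) / dr);
              if (ir < nr) T_r[ir] += w; else T_over += w;
              alive = false;
            } else {
              ux = uxn; uy = uyn; uz = uzn; layer += 1;
            }
          } else {
            if (layer == 0) { // top escape
              diffuse_refl += w;
              alive = false;
            } else {
              ux = uxn; uy = uyn; uz = -uzn; layer -= 1;
            }
          }
        }
      } else {
        s_left = 0.0;
        // drop: implicit capture
        double dw = w * mu_a[layer] / mt;
        {
          int iz = (int)(z / dz);
          int ir = (int)(std::sqrt(x * x + y * y) / dr);
          if (ir < nr && iz < nz) A(ir, iz) += dw; else A_over += dw;
        }
        w -= dw;
        if (w <= 0.0) { alive = false; continue; } // fully captured
        // spin: Henyey-Greenstein deflection
        double g = gg[layer];
        double u1 = rng.next(), u2 = rng.next();
        double cost;
        if (g == 0.0) {
          cost = 2.0 * u1 - 1.0;
        } else {
          double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u1);
          cost = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        }
        if (cost > 1.0) cost = 1.0;
        if (cost < -1.0) cost = -1.0;
        double sint = std::sqrt(1.0 - cost * cost);
        double phi = TWO_PI * u2;
        double cosp = std::cos(phi), sinp = std::sin(phi);
        if (std::fabs(uz) > 0.99999) {
          ux = sint * cosp;
          uy = sint * sinp;
          uz = cost * (uz >= 0.0 ? 1.0 : -1.0);
        } else {
          double den = std::sqrt(1.0 - uz * uz);
          double uxn = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
          double uyn = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
          double uzn = -den * sint * cosp + uz * cost;
          ux = uxn; uy = uyn; uz = uzn;
        }
        // roulette
        if (w < roulette_threshold) {
          double u3 = rng.next();
          if (u3 < 1.0 / roulette_m) w *= roulette_m;
          else { w = 0.0; alive = false; }
        }
      }
    }
  }

  return List::create(
    _["absorbed"] = A, _["flux"] = F, _["flux_overflow"] = F_over,
    _["transmit_r"] = T_r, _["transmit_overflow"] = T_over,
    _["absorbed_overflow"] = A_over, _["specular"] = specular,
    _["diffuse_reflectance"] = diffuse_refl, _["lost"] = lost,
    _["launched"] = (double)n_photons);
}
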