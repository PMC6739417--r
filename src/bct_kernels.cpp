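// Computational kernels: Monte-Carlo photon transport in a homogeneous
// cylinder (normalized glandular dose coefficient), pixel-driven FBP
// backprojection, and Joseph-projector SART/SIRT iterative reconstruction.
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

namespace {

// Deterministic, platform-independent RNG (mt19937_64 sequence is fixed by
// the C++ standard); uniforms are built from the top 53 bits.
struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t s) : g(s) {}
  double u() { return ((g() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

// linear interpolation on an equally spaced ascending grid, clamped
inline double lin1(const double* x, const double* y, int n, double q) {
  double f = (q - x[0]) / (x[1] - x[0]);
  if (f <= 0.0) return y[0];
  if (f >= n - 1) return y[n - 1];
  int i = static_cast<int>(f);
  double t = f - i;
  return y[i] * (1.0 - t) + y[i + 1] * t;
}

// sample E'/E from the Klein-Nishina distribution (composition-rejection)
inline double sample_kn(Rng& rng, double E_keV, double& cos_theta) {
  const double eps = E_keV / 510.99895;
  const double x0 = 1.0 / (1.0 + 2.0 * eps);
  const double a1 = -std::log(x0), a2 = 0.5 * (1.0 - x0 * x0);
  double x, ct, sin2;
  do {
    if (rng.u() * (a1 + a2) < a1) x = std::exp(-a1 * rng.u());
    else x = std::sqrt(x0 * x0 + (1.0 - x0 * x0) * rng.u());
    ct = 1.0 - (1.0 - x) / (eps * x);
    if (ct < -1.0) ct = -1.0;
    if (ct > 1.0) ct = 1.0;
    sin2 = 1.0 - ct * ct;
  } while (rng.u() > 1.0 - x * sin2 / (1.0 + x * x));
  cos_theta = ct;
  return x;
}

// rotate direction (u,v,w) by polar angle (cos ct) and azimuth phi
inline void rotate_dir(double& u, double& v, double& w, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double denom = std::sqrt(std::max(0.0, 1.0 - w * w));
  double u2, v2, w2;
  if (denom > 1e-10) {
    u2 = u * ct + st * (u * w * cp - v * sp) / denom;
    v2 = v * ct + st * (v * w * cp + u * sp) / denom;
    w2 = w * ct - st * denom * cp;
  } else {
    u2 = st * cp; v2 = st * sp; w2 = (w >= 0.0 ? ct : -ct);
  }
  double nrm = std::sqrt(u2 * u2 + v2 * v2 + w2 * w2);
  u = u2 / nrm; v = v2 / nrm; w = w2 / nrm;
}

// distance along (u,v,w) from (x,y,z) to the boundary of the cylinder
// radius R, 0 <= z <= H (point assumed inside)
inline double exit_distance(double x, double y, double z,
                            double u, double v, double w,
                            double R, double H) {
  double t_rad = std::numeric_limits<double>::infinity();
  double a = u * u + v * v;
  if (a > 1e-14) {
    double b = x * u + y * v;
    double c = x * x + y * y - R * R;
    double disc = b * b - a * c;
    if (disc > 0.0) t_rad = (-b + std::sqrt(disc)) / a;
    if (t_rad < 0.0) t_rad = 0.0;
  }
  double t_z = std::numeric_limits<double>::infinity();
  if (std::isfinite(H)) {
    if (w > 1e-14) t_z = (H - z) / w;
    else if (w < -1e-14) t_z = -z / w;
  }
  return std::min(t_rad, t_z);
}

}  // namespace

// Monte-Carlo photon transport in a homogeneous cylinder (radius R_cm,
// height H_cm, axis z), irradiated by a parallel beam along +x of width 2R
// and height h_cm (z-centered). Interaction coefficients (1/cm) are given
// on an equally spaced energy grid: total, photoelectric-like absorption,
// incoherent (Klein-Nishina) and coherent. 'wgt' is the glandular dose
// weight applied to each energy deposit. Returns per-photon statistics of
// the glandular-weighted deposited energy (keV) plus an energy audit.
// [[Rcpp::export]]
List cpp_mc_cylinder(double R_cm, double H_cm, double h_cm, double E0_keV,
                     double n_photons, NumericVector e_grid,
                     NumericVector mu_tot, NumericVector mu_abs,
                     NumericVector mu_inc, NumericVector mu_coh,
                     NumericVector wgt, double seed1, double seed2) {
  const int ng = e_grid.size();
  const double* eg = e_grid.begin();
  const double E_CUT = 1.0;  // keV; below this, deposit locally
  Rng rng(static_cast<uint64_t>(seed1) * 2654435761ULL +
          static_cast<uint64_t>(seed2) + 0x9E3779B97F4A7C15ULL);
  // infinite cylinder (translational symmetry): beam occupies a unit slab
  // at z in [0, h]; deposits are scored wherever they land
  const bool finite_H = std::isfinite(H_cm);
  const double z0 = finite_H ? 0.5 * (H_cm - h_cm) : 0.0;
  const long long N = static_cast<long long>(n_photons);
  double S1 = 0.0, S2 = 0.0, dep_tot = 0.0, esc_tot = 0.0;

  for (long long ip = 0; ip < N; ++ip) {
    double y = R_cm * (2.0 * rng.u() - 1.0);
    double z = z0 + h_cm * rng.u();
    double r2 = R_cm * R_cm - y * y;
    if (r2 <= 0.0) { esc_tot += E0_keV; continue; }
    double x = -std::sqrt(r2);
    double u = 1.0, v = 0.0, w = 0.0;
    double E = E0_keV, c = 0.0;
    for (int step = 0; step < 100000; ++step) {
      double mt = lin1(eg, mu_tot.begin(), ng, E);
      double t = -std::log(rng.u()) / mt;
      double t_exit = exit_distance(x, y, z, u, v, w, R_cm, H_cm);
      if (t >= t_exit) { esc_tot += E; break; }
      x += t * u; y += t * v; z += t * w;
      double xi = rng.u() * mt;
      double m_abs = lin1(eg, mu_abs.begin(), ng, E);
      double m_inc = lin1(eg, mu_inc.begin(), ng, E);
      if (xi < m_abs) {                    // photoelectric-like absorption
        c += E * lin1(eg, wgt.begin(), ng, E);
        dep_tot += E;
        E = 0.0;
        break;
      } else if (xi < m_abs + m_inc) {     // incoherent (Compton) scatter
        double ct;
        double frac = sample_kn(rng, E, ct);
        double dep = E * (1.0 - frac);
        c += dep * lin1(eg, wgt.begin(), ng, E);
        dep_tot += dep;
        E *= frac;
        rotate_dir(u, v, w, ct, 2.0 * M_PI * rng.u());
        if (E < E_CUT) {                   // terminal local deposit
          c += E * lin1(eg, wgt.begin(), ng, E);
          dep_tot += E;
          E = 0.0;
          break;
        }
      } else {                             // coherent (elastic) scatter
        double ct;
        do { ct = 2.0 * rng.u() - 1.0; }
        while (rng.u() > 0.5 * (1.0 + ct * ct));
        rotate_dir(u, v, w, ct, 2.0 * M_PI * rng.u());
      }
    }
    S1 += c;
    S2 += c * c;
  }
  return List::create(_["mean_c"] = S1 / N,
                      _["var_c"] = (S2 - S1 * S1 / N) / (N - 1.0),
                      _["deposited"] = dep_tot, _["escaped"] = esc_tot,
                      _["n"] = static_cast<double>(N));
}

// Pixel-driven parallel-beam backprojection with linear detector
// interpolation. filtered: n_proj x n_det matrix of filtered projections.
// Returns an n_det x n_det image; scaling by pi/n_proj included.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix filtered, NumericVector angles,
                              double dx) {
  const int np = filtered.nrow(), nd = filtered.ncol();
  const double c = 0.5 * (nd - 1);
  NumericMatrix img(nd, nd);
  double* im = img.begin();
  std::vector<double> row(nd);
  // view-major accumulation: the filtered row is contiguous in cache and
  // the detector coordinate advances incrementally along each image row
  for (int j = 0; j < np; ++j) {
    const double ca = std::cos(angles[j]), sa = std::sin(angles[j]);
    for (int k = 0; k < nd; ++k) row[k] = filtered(j, k);
    for (int iy = 0; iy < nd; ++iy) {
      double f0 = (iy - c) * sa + (0 - c) * ca + c;  // s/dx + c at ix = 0
      // valid ix range solves 0 <= f0 + ix*ca <= nd-1 in closed form
      int lo = 0, hi = nd - 1;
      if (ca > 1e-12) {
        lo = std::max(lo, (int)std::ceil((0.0 - f0) / ca));
        hi = std::min(hi, (int)std::floor((nd - 1.0 - f0) / ca));
      } else if (ca < -1e-12) {
        lo = std::max(lo, (int)std::ceil((nd - 1.0 - f0) / ca));
        hi = std::min(hi, (int)std::floor((0.0 - f0) / ca));
      } else if (f0 < 0.0 || f0 > nd - 1) {
        continue;
      }
      double f = f0 + lo * ca;
      double* imcol = im + static_cast<size_t>(nd) * iy;
      for (int ix = lo; ix <= hi; ++ix, f += ca) {
        int k = static_cast<int>(f);
        if (k >= nd - 1) k = nd - 2;
        if (k < 0) k = 0;
        double t = f - k;
        imcol[ix] += row[k] * (1.0 - t) + row[k + 1] * t;
      }
    }
  }
  const double scale = M_PI / np;
  for (int i = 0; i < nd * nd; ++i) im[i] *= scale;
  return img;
}

namespace {

// Joseph ray trace through an n x n image with pixel size dx, for the ray
// x cos(th) + y sin(th) = s. mode 0: forward (returns weighted sum, out_row
// gets the ray measure). mode 1: adjoint: adds val * w to img_w and w to
// colsum (if not null).
struct Ray {
  double cth, sth, s;
  int n;
  double dx, c;
};

inline double trace_forward(const Ray& r, const double* img, double* measure) {
  double acc = 0.0, meas = 0.0;
  if (std::fabs(r.sth) >= std::fabs(r.cth)) {
    double step = r.dx / std::fabs(r.sth);
    for (int ix = 0; ix < r.n; ++ix) {
      double x = (ix - r.c) * r.dx;
      double y = (r.s - x * r.cth) / r.sth;
      double f = y / r.dx + r.c;
      if (f < 0.0 || f > r.n - 1) continue;
      int iy = static_cast<int>(f);
      if (iy == r.n - 1) iy = r.n - 2;
      double t = f - iy;
      acc += step * (img[ix + r.n * iy] * (1.0 - t) + img[ix + r.n * (iy + 1)] * t);
      meas += step;
    }
  } else {
    double step = r.dx / std::fabs(r.cth);
    for (int iy = 0; iy < r.n; ++iy) {
      double y = (iy - r.c) * r.dx;
      double x = (r.s - y * r.sth) / r.cth;
      double f = x / r.dx + r.c;
      if (f < 0.0 || f > r.n - 1) continue;
      int ix = static_cast<int>(f);
      if (ix == r.n - 1) ix = r.n - 2;
      double t = f - ix;
      acc += step * (img[ix + r.n * iy] * (1.0 - t) + img[ix + 1 + r.n * iy] * t);
      meas += step;
    }
  }
  if (measure) *measure = meas;
  return acc;
}

inline void trace_adjoint(const Ray& r, double val, double* img, double* colsum) {
  if (std::fabs(r.sth) >= std::fabs(r.cth)) {
    double step = r.dx / std::fabs(r.sth);
    for (int ix = 0; ix < r.n; ++ix) {
      double x = (ix - r.c) * r.dx;
      double y = (r.s - x * r.cth) / r.sth;
      double f = y / r.dx + r.c;
      if (f < 0.0 || f > r.n - 1) continue;
      int iy = static_cast<int>(f);
      if (iy == r.n - 1) iy = r.n - 2;
      double t = f - iy;
      img[ix + r.n * iy] += val * step * (1.0 - t);
      img[ix + r.n * (iy + 1)] += val * step * t;
      if (colsum) {
        colsum[ix + r.n * iy] += step * (1.0 - t);
        colsum[ix + r.n * (iy + 1)] += step * t;
      }
    }
  } else {
    double step = r.dx / std::fabs(r.cth);
    for (int iy = 0; iy < r.n; ++iy) {
      double y = (iy - r.c) * r.dx;
      double x = (r.s - y * r.sth) / r.cth;
      double f = x / r.dx + r.c;
      if (f < 0.0 || f > r.n - 1) continue;
      int ix = static_cast<int>(f);
      if (ix == r.n - 1) ix = r.n - 2;
      double t = f - ix;
      img[ix + r.n * iy] += val * step * (1.0 - t);
      img[ix + 1 + r.n * iy] += val * step * t;
      if (colsum) {
        colsum[ix + r.n * iy] += step * (1.0 - t);
        colsum[ix + 1 + r.n * iy] += step * t;
      }
    }
  }
}

}  // namespace

// Forward projection (Joseph) of an n x n image for the given angles.
// Returns an n_proj x n_det sinogram of line integrals (same length units
// as dx).
// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, NumericVector angles,
                                  double dx) {
  const int n = img.nrow(), np = angles.size();
  NumericMatrix out(np, n);
  const double c = 0.5 * (n - 1);
  for (int j = 0; j < np; ++j) {
    Ray r{std::cos(angles[j]), std::sin(angles[j]), 0.0, n, dx, c};
    for (int k = 0; k < n; ++k) {
      r.s = (k - c) * dx;
      out(j, k) = trace_forward(r, img.begin(), nullptr);
    }
  }
  return out;
}

// SART: sequential per-projection updates with relaxation lambda. One
// "iteration" processes one projection (row of the sinogram), in sequential
// angle order. Returns the image and the RMS update norm per iteration.
// [[Rcpp::export]]
List cpp_sart(NumericMatrix p, NumericVector angles, double dx, int n_iter,
              double lambda) {
  const int np = p.nrow(), nd = p.ncol();
  const double c = 0.5 * (nd - 1);
  NumericMatrix img(nd, nd);
  NumericVector rms(n_iter);
  std::vector<double> upd(nd * nd), cs(nd * nd), q(nd), meas(nd);
  for (int it = 0; it < n_iter; ++it) {
    int j = it % np;
    Ray r{std::cos(angles[j]), std::sin(angles[j]), 0.0, nd, dx, c};
    std::fill(upd.begin(), upd.end(), 0.0);
    std::fill(cs.begin(), cs.end(), 0.0);
    for (int k = 0; k < nd; ++k) {
      r.s = (k - c) * dx;
      q[k] = trace_forward(r, img.begin(), &meas[k]);
    }
    for (int k = 0; k < nd; ++k) {
      if (meas[k] < 1e-12) continue;
      r.s = (k - c) * dx;
      trace_adjoint(r, (p(j, k) - q[k]) / meas[k], upd.data(), cs.data());
    }
    double ss = 0.0;
    for (int i = 0; i < nd * nd; ++i) {
      if (cs[i] < 1e-12) continue;
      double d = lambda * upd[i] / cs[i];
      img[i] += d;
      ss += d * d;
    }
    rms[it] = std::sqrt(ss / (nd * nd));
  }
  return List::create(_["image"] = img, _["rms_update"] = rms);
}

// SIRT: simultaneous updates with standard row/column-sum normalization.
// One iteration uses all projections. Returns image and RMS update norms.
// [[Rcpp::export]]
List cpp_sirt(NumericMatrix p, NumericVector angles, double dx, int n_iter,
              double lambda) {
  const int np = p.nrow(), nd = p.ncol();
  const double c = 0.5 * (nd - 1);
  NumericMatrix img(nd, nd);
  NumericVector rms(n_iter);
  std::vector<double> upd(nd * nd), cs(nd * nd), rowsum(np * nd);
  std::vector<Ray> rays(np);
  for (int j = 0; j < np; ++j)
    rays[j] = Ray{std::cos(angles[j]), std::sin(angles[j]), 0.0, nd, dx, c};
  // ray measures and column sums (geometry only, computed once)
  for (int j = 0; j < np; ++j)
    for (int k = 0; k < nd; ++k) {
      Ray r = rays[j]; r.s = (k - c) * dx;
      double m; trace_forward(r, img.begin(), &m);
      rowsum[j + np * k] = m;
      if (m > 1e-12) trace_adjoint(r, 0.0, upd.data(), cs.data());
    }
  std::fill(upd.begin(), upd.end(), 0.0);
  for (int it = 0; it < n_iter; ++it) {
    std::fill(upd.begin(), upd.end(), 0.0);
    for (int j = 0; j < np; ++j)
      for (int k = 0; k < nd; ++k) {
        double m = rowsum[j + np * k];
        if (m < 1e-12) continue;
        Ray r = rays[j]; r.s = (k - c) * dx;
        double q = trace_forward(r, img.begin(), nullptr);
        trace_adjoint(r, (p(j, k) - q) / m, upd.data(), nullptr);
      }
    double ss = 0.0;
    for (int i = 0; i < nd * nd; ++i) {
      if (cs[i] < 1e-12) continue;
      double d = lambda * upd[i] / cs[i];
      img[i] += d;
      ss += d * d;
    }
    rms[it] = std::sqrt(ss / (nd * nd));
  }
  return List::create(_["image"] = img, _["rms_update"] = rms);
}
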