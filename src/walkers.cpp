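#include <Rcpp.h>
using namespace Rcpp;

// Random-walk phase-integral kernels for PGSE Monte-Carlo simulation.
// Positions in um, time in ms. Each walker returns the signed integral
// of position over the two gradient pulses (weights w in [-1, 1] per
// step, from pulse overlap); the caller maps integrals to phases per
// measurement. Uses R's RNG so seeding follows set.seed().

static inline double norm2(const double *x) {
  return x[0] * x[0] + x[1] * x[1] + x[2] * x[2];
}

// reflect proposed step b (from a) back into the sphere of radius R,
// specular reflection with sub-step splitting, multiple bounces
static void reflect_sphere(double *a, double *b, double R) {
  for (int bounce = 0; bounce < 64; ++bounce) {
    if (norm2(b) <= R * R) return;
    double d[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double dd = norm2(d);
    if (dd < 1e-300) break;
    double ad = a[0] * d[0] + a[1] * d[1] + a[2] * d[2];
    double aa = norm2(a);
    double disc = ad * ad - dd * (aa - R * R);
    if (disc < 0) disc = 0;
    double s = (-ad + std::sqrt(disc)) / dd;
    if (s < 0) s = 0;
    if (s > 1) s = 1;
    double p[3], rem[3];
    for (int j = 0; j < 3; ++j) {
      p[j] = a[j] + s * d[j];
      rem[j] = b[j] - p[j];
    }
    double pn = std::sqrt(norm2(p));
    if (pn < 1e-300) break;
    double n[3] = {p[0] / pn, p[1] / pn, p[2] / pn};
    double rn = rem[0] * n[0] + rem[1] * n[1] + rem[2] * n[2];
    for (int j = 0; j < 3; ++j) {
      a[j] = p[j] * (1.0 - 1e-12);
      b[j] = a[j] + rem[j] - 2.0 * rn * n[j];
    }
  }
  // numerical fallback: project onto the sphere
  double bn = std::sqrt(norm2(b));
  if (bn > R) {
    for (int j = 0; j < 3; ++j) b[j] *= (R / bn) * (1.0 - 1e-12);
  }
}

// [[Rcpp::export]]
NumericMatrix mc_sphere_integrals_cpp(int n_walkers, double R, double D,
                                      double dt, NumericVector w) {
  int n_steps = w.size();
  double sd_step = std::sqrt(2.0 * D * dt);
  NumericMatrix I(n_walkers, 3);
  double max_r2 = 0.0;  // largest post-step squared radius, for testing
  RNGScope scope;
  for (int i = 0; i < n_walkers; ++i) {
    // uniform position inside the sphere
    double x[3];
    double u;
    do {
      for (int j = 0; j < 3; ++j) x[j] = 2.0 * unif_rand() - 1.0;
      u = norm2(x);
    } while (u > 1.0 || u < 1e-12);
    for (int j = 0; j < 3; ++j) x[j] *= R;
    double acc[3] = {0.0, 0.0, 0.0};
    for (int k = 0; k < n_steps; ++k) {
      double x1[3];
      for (int j = 0; j < 3; ++j) x1[j] = x[j] + sd_step * norm_rand();
      double x0[3] = {x[0], x[1], x[2]};
      reflect_sphere(x0, x1, R);
      double r2 = norm2(x1);
      if (r2 > max_r2) max_r2 = r2;
      if (w[k] != 0.0) {
        double c = w[k] * dt * 0.5;
        for (int j = 0; j < 3; ++j) acc[j] += c * (x[j] + x1[j]);
      }
      for (int j = 0; j < 3; ++j) x[j] = x1[j];
    }
    for (int j = 0; j < 3; ++j) I(i, j) = acc[j];
  }
  I.attr("max_radius") = std::sqrt(max_r2);
  return I;
}

// [[Rcpp::export]]
NumericMatrix mc_stick_integrals_cpp(int n_walkers, double D, double dt,
                                     NumericVector w) {
  int n_steps = w.size();
  double sd_step = std::sqrt(2.0 * D * dt);
  NumericMatrix I(n_walkers, 3);
  RNGScope scope;
  for (int i = 0; i < n_walkers; ++i) {
    // random orientation, uniform on the sphere
    double uvec[3], un;
    do {
      for (int j = 0; j < 3; ++j) uvec[j] = norm_rand();
      un = std::sqrt(norm2(uvec));
    } while (un < 1e-12);
    for (int j = 0; j < 3; ++j) uvec[j] /= un;
    double s = 0.0, acc = 0.0;
    for (int k = 0; k < n_steps; ++k) {
      double s1 = s + sd_step * norm_rand();
      if (w[k] != 0.0) acc += w[k] * dt * 0.5 * (s + s1);
      s = s1;
    }
    for (int j = 0; j < 3; ++j) I(i, j) = acc * uvec[j];
  }
  return I;
}
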