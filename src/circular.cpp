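#include <Rcpp.h>
using namespace Rcpp;

// von Mises kernel density, overflow-safe for large kappa:
// dvm(theta; mu, kappa) = exp(kappa * (cos(theta - mu) - 1)) / (2*pi*I0e(kappa))
// where I0e is the exponentially scaled modified Bessel function.
static inline double i0e(double kappa) {
  return R::bessel_i(kappa, 0.0, 2.0);
}

static inline double wrap2pi(double x) {
  x -= 2.0 * M_PI * std::floor(x / (2.0 * M_PI));
  return x;
}

// A(kappa) = I1(kappa)/I0(kappa), computed with scaled Bessel functions.
static double vmA(double kappa) {
  return R::bessel_i(kappa, 1.0, 2.0) / R::bessel_i(kappa, 0.0, 2.0);
}

// ML von Mises concentration given the mean resultant length rbar:
// solves A(kappa) = rbar (Fisher starting value + Newton refinement).
static double kappa_from_rbar(double rbar) {
  if (rbar < 1e-10) return 0.0;
  if (rbar >= 1.0 - 1e-12) return 1e5;
  double k;
  if (rbar < 0.53) k = 2.0 * rbar + rbar * rbar * rbar + 5.0 * std::pow(rbar, 5) / 6.0;
  else if (rbar < 0.85) k = -0.4 + 1.39 * rbar + 0.43 / (1.0 - rbar);
  else k = 1.0 / (rbar * rbar * rbar - 4.0 * rbar * rbar + 3.0 * rbar);
  if (k < 1e-8) k = 1e-8;
  for (int it = 0; it < 50; ++it) {
    const double A = vmA(k);
    const double Ap = 1.0 - A / k - A * A;  // d A / d kappa
    if (Ap <= 0.0) break;
    const double step = (A - rbar) / Ap;
    k -= step;
    if (k < 1e-10) k = 1e-10;
    if (k > 1e6) { k = 1e6; break; }
    if (std::fabs(step) < 1e-10 * (1.0 + k)) break;
  }
  return k;
}

// [[Rcpp::export]]
double cpp_kappa_ml(NumericVector theta) {
  double c = 0.0, s = 0.0;
  const int n = theta.size();
  for (int i = 0; i < n; ++i) { c += std::cos(theta[i]); s += std::sin(theta[i]); }
  return kappa_from_rbar(std::sqrt(c * c + s * s) / n);
}

// Inverts the k-th order Bessel ratio Ak(kappa) = Ik(kappa)/I0(kappa) = r
// by bisection (Ak is monotone increasing in kappa).
static double kappa_from_rbar_k(double rbar, int k) {
  if (k == 1) return kappa_from_rbar(rbar);
  if (rbar < 1e-10) return 0.0;
  double lo = 1e-8, hi = 5e3;
  const double Ahi = R::bessel_i(hi, k, 2.0) / R::bessel_i(hi, 0.0, 2.0);
  if (rbar >= Ahi) return hi;
  for (int it = 0; it < 80; ++it) {
    const double mid = 0.5 * (lo + hi);
    const double A = R::bessel_i(mid, k, 2.0) / R::bessel_i(mid, 0.0, 2.0);
    if (A < rbar) lo = mid; else hi = mid;
    if (hi - lo < 1e-10 * (1.0 + lo)) break;
  }
  return 0.5 * (lo + hi);
}

// Plug-in kernel concentration for the von Mises KDE: the sample
// concentration kappa maximises, over k = 1..kmax, the concentration
// implied by the k-th trigonometric moment (solve Ik(kappa)/I0(kappa) =
// k-fold resultant length). A k-modal density of von Mises components has
// a near-zero first resultant but its k-th moment recovers the component
// concentration, so bimodal dawn/dusk samples are not oversmoothed. Then
//   nu = [ 3 n kappa^2 I2(2 kappa) / (4 sqrt(pi) I0(kappa)^2) ]^(2/5),
// finally multiplied by `adjust`.
// [[Rcpp::export]]
double cpp_bandwidth(NumericVector theta, int kmax, double adjust) {
  const int n = theta.size();
  double kappa = 0.0;
  for (int k = 1; k <= kmax; ++k) {
    double c = 0.0, s = 0.0;
    for (int i = 0; i < n; ++i) {
      c += std::cos(k * theta[i]);
      s += std::sin(k * theta[i]);
    }
    const double kk = kappa_from_rbar_k(std::sqrt(c * c + s * s) / n, k);
    if (kk > kappa) kappa = kk;
  }
  if (kappa < 1e-8) kappa = 1e-8;
  if (kappa > 5e3) kappa = 5e3;  // keep the Bessel ratio finite
  const double ratio = R::bessel_i(2.0 * kappa, 2.0, 2.0) /
    (i0e(kappa) * i0e(kappa));
  const double nu = std::pow(3.0 * n * kappa * kappa * ratio / (4.0 * std::sqrt(M_PI)), 0.4);
  return nu * adjust;
}

// Mean of von Mises kernels centred at `centers`, evaluated at `theta`.
// [[Rcpp::export]]
NumericVector cpp_vm_kde(NumericVector theta, NumericVector centers, double kappa) {
  const int m = theta.size(), n = centers.size();
  const double norm = 1.0 / (2.0 * M_PI * i0e(kappa) * n);
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i)
      acc += std::exp(kappa * (std::cos(theta[j] - centers[i]) - 1.0));
    out[j] = acc * norm;
  }
  return out;
}

// Dhat1: integral over a regular grid of min(fhat, ghat) (periodic
// trapezoid = midpoint sum).
static double dhat1(const std::vector<double>& a, const std::vector<double>& b,
                    double ka, double kb, int ngrid) {
  const double step = 2.0 * M_PI / ngrid;
  const double na = 1.0 / (2.0 * M_PI * i0e(ka) * a.size());
  const double nb = 1.0 / (2.0 * M_PI * i0e(kb) * b.size());
  double acc = 0.0;
  for (int j = 0; j < ngrid; ++j) {
    const double t = j * step;
    double f = 0.0, g = 0.0;
    for (size_t i = 0; i < a.size(); ++i) f += std::exp(ka * (std::cos(t - a[i]) - 1.0));
    for (size_t i = 0; i < b.size(); ++i) g += std::exp(kb * (std::cos(t - b[i]) - 1.0));
    acc += std::min(f * na, g * nb);
  }
  double d = acc * step;
  return d < 0.0 ? 0.0 : (d > 1.0 ? 1.0 : d);
}

// Dhat4: 0.5 * [ mean_i min(1, g(a_i)/f(a_i)) + mean_j min(1, f(b_j)/g(b_j)) ].
// `floor_` guards the denominator; the ratio is clamped by min(1, .) anyway.
static double dhat4(const std::vector<double>& a, const std::vector<double>& b,
                    double ka, double kb, double floor_) {
  const int n1 = a.size(), n2 = b.size();
  const double na = 1.0 / (2.0 * M_PI * i0e(ka) * n1);
  const double nb = 1.0 / (2.0 * M_PI * i0e(kb) * n2);
  double s1 = 0.0, s2 = 0.0;
  for (int j = 0; j < n1; ++j) {
    double f = 0.0, g = 0.0;
    for (int i = 0; i < n1; ++i) f += std::exp(ka * (std::cos(a[j] - a[i]) - 1.0));
    for (int i = 0; i < n2; ++i) g += std::exp(kb * (std::cos(a[j] - b[i]) - 1.0));
    const double fv = std::max(f * na, floor_);
    s1 += std::min(1.0, g * nb / fv);
  }
  for (int j = 0; j < n2; ++j) {
    double f = 0.0, g = 0.0;
    for (int i = 0; i < n1; ++i) f += std::exp(ka * (std::cos(b[j] - a[i]) - 1.0));
    for (int i = 0; i < n2; ++i) g += std::exp(kb * (std::cos(b[j] - b[i]) - 1.0));
    const double gv = std::max(g * nb, floor_);
    s2 += std::min(1.0, f * na / gv);
  }
  double d = 0.5 * (s1 / n1 + s2 / n2);
  return d < 0.0 ? 0.0 : (d > 1.0 ? 1.0 : d);
}

// [[Rcpp::export]]
double cpp_dhat1(NumericVector a, NumericVector b, double ka, double kb, int ngrid) {
  return dhat1(as<std::vector<double>>(a), as<std::vector<double>>(b), ka, kb, ngrid);
}

// [[Rcpp::export]]
double cpp_dhat4(NumericVector a, NumericVector b, double ka, double kb, double floor_) {
  return dhat4(as<std::vector<double>>(a), as<std::vector<double>>(b), ka, kb, floor_);
}

// single von Mises draw, Best & Fisher (1979) wrapped-Cauchy rejection,
// using R's RNG (set.seed() governs reproducibility)
static double rvm1(double mu, double kappa) {
  if (kappa < 1e-10) return R::runif(0.0, 2.0 * M_PI);
  const double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  const double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  const double r = (1.0 + b * b) / (2.0 * b);
  double f;
  for (;;) {
    const double u1 = R::unif_rand();
    const double z = std::cos(M_PI * u1);
    f = (1.0 + r * z) / (r + z);
    const double c = kappa * (r - f);
    const double u2 = R::unif_rand();
    if (c * (2.0 - c) - u2 > 0.0 || std::log(c / u2) + 1.0 - c >= 0.0) break;
  }
  const double u3 = R::unif_rand();
  return wrap2pi((u3 > 0.5 ? 1.0 : -1.0) * std::acos(f) + mu);
}

// [[Rcpp::export]]
NumericVector cpp_rvm(int n, double mu, double kappa) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rvm1(mu, kappa);
  return out;
}

// Smoothed bootstrap for the overlap coefficient: each resample draws n1
// and n2 points from the fitted kernel densities (a resampled kernel
// centre plus von Mises noise with the kernel concentration), re-estimates
// both bandwidths, and recomputes the estimator. Returns the resampled
// delta values.
// [[Rcpp::export]]
NumericVector cpp_boot_deltas(NumericVector a, NumericVector b, bool use_dhat1,
                              int resamples, int ngrid, double adjust, int kmax,
                              double floor_) {
  const int n1 = a.size(), n2 = b.size();
  const double ka = cpp_bandwidth(a, kmax, adjust);
  const double kb = cpp_bandwidth(b, kmax, adjust);
  std::vector<double> ra(n1), rb(n2);
  NumericVector ra_v(n1), rb_v(n2);
  NumericVector out(resamples);
  for (int r = 0; r < resamples; ++r) {
    for (int i = 0; i < n1; ++i) {
      const int idx = std::min(n1 - 1, (int)(R::unif_rand() * n1));
      ra[i] = ra_v[i] = wrap2pi(a[idx] + rvm1(0.0, ka));
    }
    for (int i = 0; i < n2; ++i) {
      const int idx = std::min(n2 - 1, (int)(R::unif_rand() * n2));
      rb[i] = rb_v[i] = wrap2pi(b[idx] + rvm1(0.0, kb));
    }
    const double kra = cpp_bandwidth(ra_v, kmax, adjust);
    const double krb = cpp_bandwidth(rb_v, kmax, adjust);
    out[r] = use_dhat1 ? dhat1(ra, rb, kra, krb, ngrid)
                       : dhat4(ra, rb, kra, krb, floor_);
  }
  return out;
}
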