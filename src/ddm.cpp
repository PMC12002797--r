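#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a constant-drift Wiener process between
// absorbing boundaries at 0 and a, start point w*a, evaluated at decision
// time t for the LOWER boundary. Density for the upper boundary is obtained
// by the reflection (v, w) -> (-v, 1 - w). The noise scale sigma is removed
// by rescaling (v, a) -> (v/sigma, a/sigma), which leaves the first-passage
// time unchanged.
//
// The dimensionless kernel f(tau | w) (a = 1, v = 0) is evaluated with the
// small-time or large-time series, choosing whichever needs fewer terms for
// a truncation error below `err`.

static double wfpt_kernel(const double tau, const double w, const double err) {
  // number of terms required by each expansion
  double ks = 2.0, kl = 3.0 / sqrt(tau);
  if (2.0 * sqrt(2.0 * M_PI * tau) * err < 1.0) {
    ks = 2.0 + sqrt(-2.0 * tau * log(2.0 * err * sqrt(2.0 * M_PI * tau)));
    ks = std::max(ks, sqrt(tau) + 1.0);
  }
  if (M_PI * tau * err < 1.0) {
    kl = sqrt(-2.0 * log(M_PI * tau * err) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * sqrt(tau)));
  }

  double f = 0.0;
  if (ks < kl) {
    const int K = static_cast<int>(ceil(ks));
    for (int k = -((K - 1) / 2); k <= ((K - 1) / 2) + ((K - 1) % 2); ++k) {
      const double wk = w + 2.0 * k;
      f += wk * exp(-wk * wk / (2.0 * tau));
    }
    f /= sqrt(2.0 * M_PI * tau * tau * tau);
  } else {
    const int K = static_cast<int>(ceil(kl));
    for (int k = 1; k <= K; ++k) {
      f += k * exp(-k * k * M_PI * M_PI * tau / 2.0) * sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f;
}

// log density at the lower boundary for decision time t (already ndt-free)
static double wfpt_logdensity_lower(const double t, const double v,
                                    const double a, const double w,
                                    const double sigma, const double err) {
  if (!(t > 0.0)) return R_NegInf;
  const double an = a / sigma;
  const double vn = v / sigma;
  const double tau = t / (an * an);
  const double kern = wfpt_kernel(tau, w, err);
  if (!(kern > 0.0)) return R_NegInf;  // series noise below machine precision
  return -vn * an * w - vn * vn * t / 2.0 - 2.0 * log(an) + log(kern);
}

// [[Rcpp::export]]
NumericVector cpp_wfpt_logdensity(const NumericVector t, const LogicalVector upper,
                                  const NumericVector v, const NumericVector a,
                                  const NumericVector w, const NumericVector ndt,
                                  const double sigma, const double err) {
  const R_xlen_t n = t.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double td = t[i] - ndt[i];
    if (upper[i]) {
      out[i] = wfpt_logdensity_lower(td, -v[i], a[i], 1.0 - w[i], sigma, err);
    } else {
      out[i] = wfpt_logdensity_lower(td, v[i], a[i], w[i], sigma, err);
    }
  }
  return out;
}

// Euler-Maruyama simulation of the two-boundary diffusion. Uses R's RNG so
// results are reproducible under set.seed(). boundary: 1 = upper, 0 = lower,
// NA = no crossing before max_time (flagged, never dropped).
// [[Rcpp::export]]
List cpp_ddm_simulate(const NumericVector v, const double a, const double w,
                      const double ndt, const double sigma, const double dt,
                      const double max_time, const bool correct_boundary) {
  const R_xlen_t n = v.size();
  IntegerVector boundary(n);
  NumericVector rt(n);
  const double sdt = sigma * sqrt(dt);
  // Broadie-Glasserman-Kou continuity correction: a discretely monitored
  // path behaves like a continuous one with boundaries pushed outward by
  // beta*sigma*sqrt(dt), beta = -zeta(1/2)/sqrt(2*pi); testing against
  // inward-shifted thresholds removes the O(sqrt(dt)) crossing bias.
  const double shift = correct_boundary ? 0.5826 * sdt : 0.0;
  const double hi = a - shift, lo = shift;
  const long max_steps = static_cast<long>(ceil(max_time / dt));
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = w * a;
    const double vdt = v[i] * dt;
    long step = 0;
    int b = NA_INTEGER;
    if (x >= hi) b = 1; else if (x <= lo) b = 0;
    while (b == NA_INTEGER && step < max_steps) {
      x += vdt + sdt * norm_rand();
      ++step;
      if (x >= hi) { b = 1; break; }
      if (x <= lo) { b = 0; break; }
    }
    boundary[i] = b;
    rt[i] = (b == NA_INTEGER) ? NA_REAL : step * dt + ndt;
  }
  return List::create(_["boundary"] = boundary, _["rt"] = rt);
}
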