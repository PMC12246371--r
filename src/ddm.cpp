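#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a unit-diffusion Wiener process between
// absorbing boundaries 0 and a, drift v, relative start z in (0,1).
// Lower-boundary density at normalized time tt = (rt - t0) / a^2 uses the
// Navarro & Fuss switch between the small-time and large-time series; the
// upper-boundary density follows from reflection (v -> -v, z -> 1 - z).

static const double LOG_SQRT_2PI = 0.9189385332046727; // log(sqrt(2*pi))

// log f0(tt, w): standardized (v = 0, a = 1) lower-boundary FPT density.
static double log_f0(double tt, double w, double eps) {
  // number of terms needed by each expansion
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tt * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }

  double p = 0.0;
  if (ks < kl) {
    // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(K - 1) / 2, hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      double u = w + 2.0 * k;
      p += u * std::exp(-u * u / (2.0 * tt));
    }
    if (p <= 0.0) return R_NegInf;
    return std::log(p) - LOG_SQRT_2PI - 1.5 * std::log(tt);
  } else {
    // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
    }
    if (p <= 0.0) return R_NegInf;
    return std::log(p) + std::log(M_PI);
  }
}

static double wfpt_ld_one(double rt, int upper, double v, double a, double z,
                          double t0, double eps) {
  if (!(a > 0.0) || !(z > 0.0) || !(z < 1.0) || !(t0 >= 0.0)) return NA_REAL;
  double td = rt - t0;
  if (td <= 0.0) return R_NegInf;
  double vv = v, w = z;
  if (upper) { vv = -v; w = 1.0 - z; } // reflection: upper = lower of mirrored process
  double tt = td / (a * a);
  double lf0 = log_f0(tt, w, eps);
  if (lf0 == R_NegInf) return R_NegInf;
  return lf0 - 2.0 * std::log(a) - vv * a * w - vv * vv * td / 2.0;
}

// [[Rcpp::export]]
NumericVector wfpt_logdens_cpp(NumericVector rt, IntegerVector upper,
                               NumericVector v, NumericVector a,
                               NumericVector z, NumericVector t0,
                               double eps = 1e-7) {
  R_xlen_t n = rt.size();
  NumericVector out(n);
  R_xlen_t nv = v.size(), na = a.size(), nz = z.size(), nt = t0.size(),
           nu = upper.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = wfpt_ld_one(rt[i], upper[nu == 1 ? 0 : i], v[nv == 1 ? 0 : i],
                         a[na == 1 ? 0 : i], z[nz == 1 ? 0 : i],
                         t0[nt == 1 ? 0 : i], eps);
  }
  return out;
}

// [[Rcpp::export]]
double wfpt_loglik_sum_cpp(NumericVector rt, IntegerVector upper,
                           NumericVector v, NumericVector a,
                           NumericVector z, NumericVector t0,
                           double eps = 1e-7) {
  NumericVector ld = wfpt_logdens_cpp(rt, upper, v, a, z, t0, eps);
  double s = 0.0;
  for (R_xlen_t i = 0; i < ld.size(); ++i) {
    if (ld[i] == R_NegInf || NumericVector::is_na(ld[i])) return R_NegInf;
    s += ld[i];
  }
  return s;
}

// Euler-Maruyama with Brownian-bridge boundary-crossing correction.
// Plain Euler misses within-step crossings, inflating RTs and biasing choice
// fractions by O(sqrt(dt)); the bridge probabilities remove that bias.
// [[Rcpp::export]]
List ddm_simulate_cpp(int n, NumericVector v, NumericVector a, NumericVector z,
                      NumericVector t0, double dt, double max_time = 20.0) {
  NumericVector rt(n);
  IntegerVector boundary(n); // 1 = upper, 0 = lower
  R_xlen_t nv = v.size(), na = a.size(), nz = z.size(), nt = t0.size();
  double sdt = std::sqrt(dt);
  int max_steps = (int)(max_time / dt);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double vi = v[nv == 1 ? 0 : i], ai = a[na == 1 ? 0 : i];
    double zi = z[nz == 1 ? 0 : i], ti = t0[nt == 1 ? 0 : i];
    double x = zi * ai;
    int step = 0, hit = -1;
    while (step < max_steps) {
      ++step;
      double x1 = x + vi * dt + sdt * norm_rand();
      if (x1 >= ai) { hit = 1; x = x1; break; }
      if (x1 <= 0.0) { hit = 0; x = x1; break; }
      // within-step crossing of either boundary via Brownian bridge
      double pu = std::exp(-2.0 * (ai - x) * (ai - x1) / dt);
      if (unif_rand() < pu) { hit = 1; x = x1; break; }
      double pl = std::exp(-2.0 * x * x1 / dt);
      if (unif_rand() < pl) { hit = 0; x = x1; break; }
      x = x1;
    }
    if (hit < 0) hit = (x >= ai / 2.0) ? 1 : 0; // censored at max_time (rare)
    boundary[i] = hit;
    rt[i] = ti + step * dt;
  }
  return List::create(_["boundary"] = boundary, _["rt"] = rt);
}

// Single evidence path on a fixed grid (for plotting simulated decisions).
// [[Rcpp::export]]
List ddm_simulate_path_cpp(double v, double a, double z, double t0, double dt,
                           double max_time = 20.0) {
  int max_steps = (int)(max_time / dt);
  std::vector<double> ev;
  ev.reserve(1024);
  double x = z * a;
  ev.push_back(x);
  int step = 0, hit = -1;
  RNGScope scope;
  while (step < max_steps) {
    ++step;
    x += v * dt + std::sqrt(dt) * norm_rand();
    ev.push_back(x);
    if (x >= a) { hit = 1; break; }
    if (x <= 0.0) { hit = 0; break; }
  }
  if (hit < 0) hit = (x >= a / 2.0) ? 1 : 0;
  return List::create(_["evidence"] = NumericVector(ev.begin(), ev.end()),
                      _["boundary"] = hit, _["rt"] = t0 + step * dt,
                      _["dt"] = dt);
}
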