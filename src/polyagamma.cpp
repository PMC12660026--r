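// Polya-gamma random variates, PG(b, psi), for positive integer b.
//
// PG(1, psi) is drawn by Devroye's alternating-series rejection sampler
// applied to the tilted Jacobi variable J*(1, psi/2); PG(1, psi) = J*/4.
// Integer b <= PG_NORMAL_CUTOFF is handled by summing b independent
// PG(1, psi) draws (additivity in the shape parameter).  Above the
// cutoff a moment-matched Gaussian is used: a PG(b, psi) draw is already
// a sum of b iid variables, so at shape 50 the CLT error is far below
// Monte-Carlo noise at any realistic chain length.
//
// All randomness flows through R's RNG so draws are reproducible under
// set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;           // series split point t
static const int    PG_NORMAL_CUTOFF = 50;  // shape above which CLT kicks in

static double exp_rand1() { return ::exp_rand(); }

// inverse-Gaussian(mu = 1/z, lambda = 1) CDF at x, valid for z >= 0
static double pigauss(double x, double z) {
  double rx = std::sqrt(1.0 / x);
  return R::pnorm(rx * (x * z - 1.0), 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(-rx * (x * z + 1.0), 0.0, 1.0, 1, 0);
}

// piecewise coefficients a_n(x) of the Jacobi density series
static double a_coef(int n, double x) {
  double np = n + 0.5;
  if (x <= TRUNC) {
    return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * np * np / x);
  }
  return M_PI * np * std::exp(-np * np * M_PI * M_PI * x / 2.0);
}

// inverse-Gaussian(1/z, 1) truncated to (0, t); Devroye's two-case scheme
static double rtigauss(double z, double t) {
  double x;
  if (1.0 / z > t) {
    // heavy truncation: start from the z = 0 (Levy-type) sampler and
    // thin by the exp(-z^2 x / 2) tilt
    for (;;) {
      double e1, e2;
      do {
        e1 = exp_rand1();
        e2 = exp_rand1();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  // ordinary IG sampler, rejecting draws beyond t
  double mu = 1.0 / z;
  for (;;) {
    double y = norm_rand();
    y = y * y;
    x = mu + 0.5 * mu * mu * y -
        0.5 * mu * std::sqrt(4.0 * mu * y + mu * mu * y * y);
    if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    if (x < t) return x;
  }
}

// one PG(1, psi) draw
static double pg1_draw(double psi) {
  double z = std::fabs(psi) * 0.5;
  double k = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p = (M_PI / (2.0 * k)) * std::exp(-k * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  for (;;) {
    double x;
    if (unif_rand() < p / (p + q)) {
      x = TRUNC + exp_rand1() / k;          // exponential right tail
    } else {
      x = rtigauss(z, TRUNC);               // truncated IG left piece
    }
    // alternating-series accept/reject (squeeze on partial sums)
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x);
        if (y > s) break;                   // reject, draw a new x
      }
    }
  }
}

// closed-form mean of PG(b, psi)
static double pg_mean(double b, double psi) {
  double ap = std::fabs(psi);
  if (ap < 1e-4) return b * (0.25 - ap * ap / 48.0);
  return b * std::tanh(ap / 2.0) / (2.0 * ap);
}

// closed-form variance of PG(b, psi)
static double pg_var(double b, double psi) {
  double ap = std::fabs(psi);
  if (ap < 1e-4) return b / 24.0;
  double ch = std::cosh(ap / 2.0);
  return b * (std::sinh(ap) - ap) / (4.0 * ap * ap * ap * ch * ch);
}

// [[Rcpp::export(name = ".rpg_cpp")]]
NumericVector rpg_cpp(IntegerVector b, NumericVector psi, bool exact) {
  R_xlen_t n = b.size();
  if (psi.size() != n) stop("b and psi must have equal length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int bi = b[i];
    if (bi <= 0) stop("PG shape b must be a positive integer");
    double z = psi[i];
    if (!R_finite(z)) stop("non-finite PG tilt psi");
    if (!exact && bi > PG_NORMAL_CUTOFF) {
      double m = pg_mean((double)bi, z);
      double sd = std::sqrt(pg_var((double)bi, z));
      double d;
      do {
        d = m + sd * norm_rand();
      } while (d <= 0.0);
      out[i] = d;
    } else {
      double acc = 0.0;
      for (int j = 0; j < bi; ++j) acc += pg1_draw(z);
      out[i] = acc;
    }
  }
  return out;
}
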