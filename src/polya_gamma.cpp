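// Polya-Gamma PG(b, c) sampling: Devroye-type exact sampler for PG(1, c),
// summation for integer b, moment-matched normal approximation for large b.
// Used by the exact-augmentation backend of the binomial mixed model.

#include <Rcpp.h>
using namespace Rcpp;

static const double PG_TRUNC = 0.64;

// series coefficients a_n(x) of the Jacobi J*(1) density
static double pg_a_coef(int n, double x) {
  double npi = (n + 0.5) * M_PI;
  if (x > PG_TRUNC)
    return npi * std::exp(-0.5 * npi * npi * x);
  return std::pow(2.0 / (M_PI * x), 1.5) * npi *
         std::exp(-2.0 * (n + 0.5) * (n + 0.5) / x);
}

// P(IG(mu = 1/z, lambda = 1) <= t), in the z-parameterization
static double pigauss(double t, double z) {
  double rt = std::sqrt(t);
  double a = R::pnorm((t * z - 1.0) / rt, 0.0, 1.0, 1, 0);
  double b = 0.0;
  if (z > 0) {
    // exp(2z) * Phi(-(tz+1)/sqrt(t)) computed on the log scale
    double lb = 2.0 * z + R::pnorm(-(t * z + 1.0) / rt, 0.0, 1.0, 1, 1);
    b = std::exp(lb);
  } else {
    b = R::pnorm(-1.0 / rt, 0.0, 1.0, 1, 0);
  }
  return a + b;
}

// inverse-Gaussian(mu, 1) truncated to (0, PG_TRUNC); mu may be +Inf (z = 0)
static double rtinvgauss(double mu) {
  double X;
  if (!(mu < PG_TRUNC)) {
    // mu large: rejection from the inverse-chi-square-like proposal
    for (;;) {
      double E1 = R::exp_rand(), E2 = R::exp_rand();
      while (E1 * E1 > 2.0 * E2 / PG_TRUNC) {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      }
      X = PG_TRUNC / ((1.0 + PG_TRUNC * E1) * (1.0 + PG_TRUNC * E1));
      double lalpha = (std::isfinite(mu)) ? -X / (2.0 * mu * mu) : 0.0;
      if (std::log(unif_rand()) <= lalpha) break;
    }
  } else {
    for (;;) {
      double Y = norm_rand();
      Y = Y * Y;
      double muY = mu * Y;
      X = mu + 0.5 * mu * (muY - std::sqrt(4.0 * muY + muY * muY));
      if (X <= 0 || !std::isfinite(X)) continue;
      if (unif_rand() > mu / (mu + X)) X = mu * mu / X;
      if (X < PG_TRUNC) break;
    }
  }
  return X;
}

// exact draw from PG(1, c)
double rpg1(double c) {
  double z = std::fabs(c) * 0.5;
  double K = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p = (M_PI / (2.0 * K)) * std::exp(-K * PG_TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(PG_TRUNC, z);
  for (;;) {
    double X;
    if (unif_rand() < p / (p + q)) {
      X = PG_TRUNC + R::exp_rand() / K;
    } else {
      X = rtinvgauss(z > 0 ? 1.0 / z : R_PosInf);
    }
    double S = pg_a_coef(0, X);
    double Y = unif_rand() * S;
    int n = 0;
    bool accept = false;
    for (;;) {
      n++;
      if (n % 2 == 1) {
        S -= pg_a_coef(n, X);
        if (Y <= S) { accept = true; break; }
      } else {
        S += pg_a_coef(n, X);
        if (Y > S) { accept = false; break; }
      }
    }
    if (accept) return X / 4.0;
  }
}

// PG(b, c) for integer b; normal approximation beyond b_exact draws
double rpg(int b, double c, int b_exact) {
  if (b <= 0) return 0.0;
  if (b <= b_exact) {
    double s = 0.0;
    for (int i = 0; i < b; i++) s += rpg1(c);
    return s;
  }
  // moment-matched normal approximation for large trial counts
  double z = std::fabs(c);
  double mean, var;
  if (z < 1e-8) {
    mean = b / 4.0;
    var = b / 24.0;
  } else {
    mean = b / (2.0 * z) * std::tanh(z / 2.0);
    double ch = std::cosh(z / 2.0);
    var = b / (4.0 * z * z * z) * (std::sinh(z) - z) / (ch * ch);
  }
  double x = mean + std::sqrt(var) * norm_rand();
  return x > 0 ? x : mean;
}

// [[Rcpp::export(name = ".rpg_cpp")]]
NumericVector rpg_cpp(IntegerVector b, NumericVector c, int b_exact = 200) {
  int n = b.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = rpg(b[i], c[i], b_exact);
  return out;
}
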