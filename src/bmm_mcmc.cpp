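// MCMC for the per-site binomial mixed model
//   y_i ~ Bin(r_i, pi_i),  logit(pi_i) = x_i' theta + g_i + e_i,
//   g ~ MVN(0, s2 h2 K),   e ~ MVN(0, s2 (1-h2) I)
// via data augmentation.  Two backends:
//   0: aggregated random-utility augmentation with the negative log-gamma
//      residual approximated by an r-keyed finite normal mixture, giving a
//      Gaussian pseudo-datum with heteroscedastic known noise;
//   1: Polya-Gamma augmentation (exact), used as a correctness oracle.
// The genetic effect is parameterized in the eigenbasis of K (g = U a),
// restricted to the span of positive eigenvalues, and updated coordinate
// by coordinate with a running residual so one sweep costs O(n * rank),
// after the one-time O(n^3) eigendecomposition done per dataset in R.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

double rpg(int b, double c, int b_exact); // polya_gamma.cpp

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Fast counter-free RNG for the sampler's inner loops (xoshiro256++),
// seeded from R's RNG stream so set.seed() still controls the chain.
struct FastRng {
  uint64_t s[4];
  typedef uint64_t result_type;
  static constexpr uint64_t min() { return 0; }
  static constexpr uint64_t max() { return UINT64_MAX; }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t operator()() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  void seed_from_r() {
    uint64_t z = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
                 (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; i++) {  // splitmix64 expansion
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      s[i] = x ^ (x >> 31);
    }
  }
  double runif() { return ((*this)() >> 11) * 0x1.0p-53; }
};

// [[Rcpp::export(name = ".bmm_mcmc_cpp")]]
List bmm_mcmc_cpp(const arma::ivec& y, const arma::ivec& r,
                  const arma::mat& X,
                  const arma::mat& U, const arma::vec& d,
                  const arma::ivec& mix_idx, const arma::ivec& mix_k,
                  const arma::ivec& mix_off, const arma::vec& mix_w,
                  const arma::vec& mix_mu, const arma::vec& mix_s2,
                  int n_iter, int n_burnin, int thin,
                  const arma::vec& theta_init,
                  double h2_init, double s2_init,
                  bool fix_h2, bool fix_s2,
                  int prior_s2_type, double prior_s2_lo, double prior_s2_hi,
                  int backend, double mh_step, int pg_exact) {
  const int n = y.n_elem;
  const int q = X.n_cols;
  const int m = U.n_cols;

  FastRng rng;
  rng.seed_from_r();
  std::normal_distribution<double> N01;
  arma::vec theta = theta_init;
  arma::vec a(m, arma::fill::zeros);
  arma::vec e(n, arma::fill::zeros);
  arma::vec g(n, arma::fill::zeros);
  double h2 = h2_init, s2 = s2_init;

  arma::vec zt(n), v(n), psi(n), rho(n);
  arma::vec logd = arma::log(d);
  double sum_logd = arma::accu(logd);

  const int n_keep = (n_iter - n_burnin + thin - 1) / thin;
  arma::vec beta_draws(n_keep), h2_draws(n_keep), s2_draws(n_keep);
  arma::vec theta_sum(q, arma::fill::zeros);
  int keep = 0;
  double mh_tries = 0.0, mh_acc = 0.0;
  double ops = 0.0;

  // log conditional of (h2, s2) given quadratic forms, on the
  // (logit h2, log s2) sampling scale, including transform Jacobians
  auto lp_hyper = [&](double h2_, double s2_, double Sa, double Se) -> double {
    if (h2_ <= 1e-8 || h2_ >= 1.0 - 1e-8 || s2_ <= 0) return -INFINITY;
    if (prior_s2_type == 0) {
      if (s2_ <= prior_s2_lo || s2_ >= prior_s2_hi) return -INFINITY;
    } else {
      double ls = std::log(s2_);
      if (ls <= prior_s2_lo || ls >= prior_s2_hi) return -INFINITY;
    }
    double vg = s2_ * h2_, ve = s2_ * (1.0 - h2_);
    double lp = -0.5 * (m * std::log(vg) + sum_logd + Sa / vg)
                -0.5 * (n * std::log(ve) + Se / ve);
    lp += std::log(h2_) + std::log(1.0 - h2_);      // logit Jacobian
    if (prior_s2_type == 0) lp += std::log(s2_);    // log Jacobian
    return lp;
  };

  for (int it = 0; it < n_iter; it++) {
    // --- (i) augmentation -------------------------------------------
    psi = X * theta + g + e;
    for (int i = 0; i < n; i++) {
      double ps = clamp(psi[i], -30.0, 30.0);
      if (backend == 0) {
        double lam = std::exp(ps);
        double T = std::gamma_distribution<double>(
            (double)r[i], 1.0 / (1.0 + lam))(rng);
        if (r[i] - y[i] > 0)
          T += std::gamma_distribution<double>(
              (double)(r[i] - y[i]), 1.0 / lam)(rng);
        double z = -std::log(T);
        double eps = z - ps;
        // draw mixture component given the realized residual
        int mi = mix_idx[i], k = mix_k[mi], off = mix_off[mi];
        double wsum = 0.0;
        double wk[16];
        for (int c = 0; c < k; c++) {
          double dd = eps - mix_mu[off + c];
          wk[c] = mix_w[off + c] *
                  std::exp(-0.5 * dd * dd / mix_s2[off + c]) /
                  std::sqrt(mix_s2[off + c]);
          wsum += wk[c];
        }
        int c = k - 1;
        if (wsum > 0) {
          double uu = rng.runif() * wsum, acc = 0.0;
          for (int cc = 0; cc < k; cc++) {
            acc += wk[cc];
            if (uu <= acc) { c = cc; break; }
          }
        } else {
          // far-tail residual: fall back to the nearest component
          double bd = INFINITY;
          for (int cc = 0; cc < k; cc++) {
            double dd = std::fabs(eps - mix_mu[off + cc]);
            if (dd < bd) { bd = dd; c = cc; }
          }
        }
        zt[i] = z - mix_mu[off + c];
        v[i] = mix_s2[off + c];
      } else {
        double om = rpg(r[i], ps, pg_exact);
        if (om < 1e-12) om = 1e-12;
        zt[i] = (y[i] - r[i] / 2.0) / om;
        v[i] = 1.0 / om;
      }
      ops += 8;
    }

    // --- (ii) fixed effects (alpha, beta) jointly, with the
    // independent effect e integrated into the observation noise
    // (partially collapsed update; e is redrawn fresh below)
    double ve = s2 * (1.0 - h2);
    arma::vec vtot = v + ve;
    {
      arma::mat Xw = X.each_col() / vtot;
      arma::mat A = X.t() * Xw;
      A.diag() += 0.01;                      // N(0, 100) working prior
      arma::vec b = Xw.t() * (zt - g);
      arma::mat R_ = arma::chol(A);
      arma::vec mu_t = arma::solve(arma::trimatu(R_),
                       arma::solve(arma::trimatl(R_.t()), b));
      arma::vec zr(q);
      for (int j = 0; j < q; j++) zr[j] = N01(rng);
      theta = mu_t + arma::solve(arma::trimatu(R_), zr);
      ops += (double)n * q * q + (double)q * q * q;
    }
    arma::vec xb = X * theta;

    // --- (iii) genetic effects in the eigenbasis, e marginalized ----
    double vg = s2 * h2;
    if (vg > 1e-12) {
      rho = zt - xb - g;
      for (int j = 0; j < m; j++) {
        double Sj = 0.0, bj = 0.0;
        for (int i = 0; i < n; i++) {
          double uij = U(i, j);
          Sj += uij * uij / vtot[i];
          bj += uij * rho[i] / vtot[i];
        }
        double prec = 1.0 / (vg * d[j]) + Sj;
        double mu_a = (bj + a[j] * Sj) / prec;
        double a_new = mu_a + N01(rng) / std::sqrt(prec);
        double delta = a_new - a[j];
        for (int i = 0; i < n; i++) rho[i] -= U(i, j) * delta;
        a[j] = a_new;
        ops += 3.0 * n;
      }
      g = U * a;
      ops += (double)n * m;
    } else {
      a.zeros();
      g.zeros();
    }

    // --- (iv) independent effects e, conditional on theta, g --------
    if (ve > 1e-12) {
      for (int i = 0; i < n; i++) {
        double prec = 1.0 / v[i] + 1.0 / ve;
        double mu_e = ((zt[i] - xb[i] - g[i]) / v[i]) / prec;
        e[i] = mu_e + N01(rng) / std::sqrt(prec);
      }
    } else {
      e.zeros();
    }
    ops += n;

    // --- (v) variance components by random-walk Metropolis ----------
    if (!(fix_h2 && fix_s2)) {
      double Sa = 0.0;
      for (int j = 0; j < m; j++) Sa += a[j] * a[j] / d[j];
      double Se = arma::dot(e, e);
      double xi = std::log(h2 / (1.0 - h2));
      double phi = std::log(s2);
      double lp0 = lp_hyper(h2, s2, Sa, Se);
      for (int rep = 0; rep < 2; rep++) {
        double xi_p = fix_h2 ? xi : xi + mh_step * N01(rng);
        double phi_p = fix_s2 ? phi : phi + mh_step * N01(rng);
        double h2_p = 1.0 / (1.0 + std::exp(-xi_p));
        double s2_p = std::exp(phi_p);
        double lp1 = lp_hyper(h2_p, s2_p, Sa, Se);
        mh_tries += 1.0;
        if (std::log(rng.runif()) < lp1 - lp0) {
          h2 = h2_p; s2 = s2_p; xi = xi_p; phi = phi_p; lp0 = lp1;
          mh_acc += 1.0;
        }
      }
      ops += m + n;
    }

    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      beta_draws[keep] = theta[q - 1];
      h2_draws[keep] = h2;
      s2_draws[keep] = s2;
      theta_sum += theta;
      keep++;
    }
  }

  return List::create(
    _["beta"] = beta_draws, _["h2"] = h2_draws, _["s2"] = s2_draws,
    _["theta_mean"] = theta_sum / std::max(keep, 1),
    _["mh_accept"] = mh_tries > 0 ? mh_acc / mh_tries : NA_REAL,
    _["ops_per_iter"] = ops / n_iter);
}

// single-site augmentation draw, exposed for validation
// [[Rcpp::export(name = ".augment_cpp")]]
List augment_cpp(const arma::ivec& y, const arma::ivec& r,
                 const arma::vec& psi,
                 const arma::ivec& mix_idx, const arma::ivec& mix_k,
                 const arma::ivec& mix_off, const arma::vec& mix_w,
                 const arma::vec& mix_mu, const arma::vec& mix_s2) {
  int n = y.n_elem;
  arma::vec z(n), zt(n), vv(n);
  arma::ivec comp(n);
  for (int i = 0; i < n; i++) {
    double ps = clamp(psi[i], -30.0, 30.0);
    double lam = std::exp(ps);
    double T = R::rgamma((double)r[i], 1.0 / (1.0 + lam));
    if (r[i] - y[i] > 0) T += R::rgamma((double)(r[i] - y[i]), 1.0 / lam);
    z[i] = -std::log(T);
    double eps = z[i] - ps;
    int mi = mix_idx[i], k = mix_k[mi], off = mix_off[mi];
    double wsum = 0.0;
    double wk[16];
    for (int c = 0; c < k; c++) {
      double dd = eps - mix_mu[off + c];
      wk[c] = mix_w[off + c] *
              std::exp(-0.5 * dd * dd / mix_s2[off + c]) /
              std::sqrt(mix_s2[off + c]);
      wsum += wk[c];
    }
    int c = k - 1;
    if (wsum > 0) {
      double uu = unif_rand() * wsum, acc = 0.0;
      for (int cc = 0; cc < k; cc++) {
        acc += wk[cc];
        if (uu <= acc) { c = cc; break; }
      }
    }
    comp[i] = c + 1;
    zt[i] = z[i] - mix_mu[off + c];
    vv[i] = mix_s2[off + c];
  }
  return List::create(_["z"] = z, _["z_centered"] = zt, _["v"] = vv,
                      _["component"] = comp);
}

// beta-binomial negative log-likelihood and analytic gradient for
// parameters (coef on logit-mean scale, eta = logit(phi))
// [[Rcpp::export(name = ".bb_negll_cpp")]]
double bb_negll_cpp(const arma::vec& par, const arma::ivec& y,
                    const arma::ivec& r, const arma::mat& X) {
  int n = y.n_elem, q = X.n_cols;
  arma::vec eta = X * par.head(q);
  double phi = 1.0 / (1.0 + std::exp(-par[q]));
  double s = (1.0 - phi) / phi;   // total concentration
  double nll = 0.0;
  for (int i = 0; i < n; i++) {
    double mu = 1.0 / (1.0 + std::exp(-clamp(eta[i], -30.0, 30.0)));
    double a = mu * s, b = (1.0 - mu) * s;
    nll -= R::lbeta(y[i] + a, r[i] - y[i] + b) - R::lbeta(a, b);
  }
  return nll;
}

// [[Rcpp::export(name = ".bb_grad_cpp")]]
arma::vec bb_grad_cpp(const arma::vec& par, const arma::ivec& y,
                      const arma::ivec& r, const arma::mat& X) {
  int n = y.n_elem, q = X.n_cols;
  arma::vec eta = X * par.head(q);
  double phi = 1.0 / (1.0 + std::exp(-par[q]));
  double s = (1.0 - phi) / phi;   // s = exp(-logit(phi)), so ds/dlogit(phi) = -s
  double ds_deta_phi = -s;
  arma::vec grad(q + 1, arma::fill::zeros);
  for (int i = 0; i < n; i++) {
    double mu = 1.0 / (1.0 + std::exp(-clamp(eta[i], -30.0, 30.0)));
    double a = mu * s, b = (1.0 - mu) * s;
    double dga = R::digamma(y[i] + a) - R::digamma(a);
    double dgb = R::digamma(r[i] - y[i] + b) - R::digamma(b);
    double dgs = R::digamma(r[i] + s) - R::digamma(s);
    // d nll / d a = -(dga - dgs_part) etc., with lbeta(a,b)=lg(a)+lg(b)-lg(a+b)
    double dl_da = dga - dgs;
    double dl_db = dgb - dgs;
    double dmu = mu * (1.0 - mu);
    for (int j = 0; j < q; j++)
      grad[j] -= (dl_da - dl_db) * s * dmu * X(i, j);
    grad[q] -= (dl_da * mu + dl_db * (1.0 - mu)) * ds_deta_phi;
  }
  return grad;
}
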