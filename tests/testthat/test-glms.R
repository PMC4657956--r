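test_that("binomial GLM matches a direct likelihood-maximization oracle", {
  set.seed(40)
  n <- 20
  x <- rnorm(n)
  r <- rpois(n, 25) + 5L
  y <- rbinom(n, r, plogis(-0.5 + 0.8 * x))
  fit <- binomial_glm_site(y, r, x)
  nll <- function(par)
    -sum(dbinom(y, r, plogis(par[1] + par[2] * x), log = TRUE))
  o <- optim(c(0, 0), nll, method = "BFGS",
             control = list(reltol = 1e-14))
  expect_equal(fit$beta_hat, o$par[2], tolerance = 1e-6)

  expect_error(binomial_glm_site(y, r, rep(1, n)), "constant")

  y2 <- as.integer(r / 2)
  r2 <- as.integer(2 * (r %/% 2))
  f2 <- binomial_glm_site(as.integer(r2 / 2), r2, x)
  expect_lt(abs(f2$beta_hat), 0.05)
  expect_gt(f2$p, 0.5)
})

test_that("perfect separation is flagged with a missing p-value", {
  x <- c(rep(-2, 5), rep(2, 5))
  r <- rep(10L, 10)
  y <- c(rep(0L, 5), rep(10L, 5))
  fit <- binomial_glm_site(y, r, x)
  expect_false(fit$converged)
  expect_true(is.na(fit$p))
})

test_that("beta-binomial likelihood tends to the binomial as phi -> 0", {
  set.seed(41)
  n <- 15
  x <- rnorm(n)
  r <- rpois(n, 12) + 3L
  y <- rbinom(n, r, plogis(0.3 * x))
  par <- c(0.1, 0.3)
  ll_bb <- betabinom_loglik(c(par, qlogis(1e-8)), y, r, x)
  # the beta-binomial kernel omits the binomial coefficient (constant in
  # the parameters); add it back for the comparison
  ll_bin <- sum(dbinom(y, r, plogis(par[1] + par[2] * x), log = TRUE)) -
    sum(lchoose(r, y))
  expect_equal(ll_bb, ll_bin, tolerance = 1e-6)
})

test_that("intercept-only beta-binomial ML matches a dense grid search", {
  y <- c(2L, 9L, 4L, 7L)
  r <- c(12L, 11L, 13L, 10L)
  X <- matrix(1, 4, 1)
  grid_mu <- seq(0.05, 0.95, by = 1e-3)
  grid_phi <- seq(1e-3, 0.6, by = 1e-3)
  ll <- function(mu, phi) {
    s <- (1 - phi) / phi
    sum(lbeta(y + mu * s, r - y + (1 - mu) * s) - lbeta(mu * s, (1 - mu) * s))
  }
  vals <- outer(grid_mu, grid_phi, Vectorize(ll))
  best <- arrayInd(which.max(vals), dim(vals))
  mu_g <- grid_mu[best[1]]; phi_g <- grid_phi[best[2]]

  o <- optim(c(qlogis(mean(y / r)), qlogis(0.1)),
             fn = bsbmm:::.bb_negll_cpp, gr = bsbmm:::.bb_grad_cpp,
             y = y, r = r, X = X, method = "BFGS",
             control = list(reltol = 1e-12))
  expect_lt(abs(plogis(o$par[1]) - mu_g), 1.5e-3)
  expect_lt(abs(plogis(o$par[2]) - phi_g), 1.5e-3)
})

test_that("analytic beta-binomial gradient matches finite differences", {
  set.seed(42)
  n <- 12
  x <- rnorm(n)
  X <- cbind(1, x)
  r <- rpois(n, 15) + 2L
  y <- rbinom(n, r, 0.4)
  par <- c(0.2, -0.4, qlogis(0.15))
  g_an <- as.numeric(bsbmm:::.bb_grad_cpp(par, y, r, X))
  g_fd <- numeric(3)
  h <- 1e-6
  for (j in 1:3) {
    e <- rep(0, 3); e[j] <- h
    g_fd[j] <- (bsbmm:::.bb_negll_cpp(par + e, y, r, X) -
                bsbmm:::.bb_negll_cpp(par - e, y, r, X)) / (2 * h)
  }
  expect_equal(g_an, g_fd, tolerance = 1e-5)
})

test_that("over-dispersion phi is recovered from simulated data", {
  set.seed(43)
  n <- 100
  x <- rnorm(n)
  phis <- replicate(200, {
    r <- rpois(n, 30) + 5L
    mu <- plogis(0.2)
    s <- (1 - 0.1) / 0.1
    pi_i <- rbeta(n, mu * s, (1 - mu) * s)
    y <- rbinom(n, r, pi_i)
    betabinom_site(y, r, x)$phi
  })
  expect_gte(median(phis), 0.07)
  expect_lte(median(phis), 0.13)
})

test_that("beta-binomial p-values are uniform under a permuted predictor", {
  set.seed(44)
  n <- 50
  x <- runif(n, 2, 18)
  ps <- replicate(400, {
    r <- rpois(n, 20) + 2L
    mu <- plogis(runif(1, -1.5, 1.5) + 0.1 * scale(x))
    s <- (1 - 0.08) / 0.08
    y <- rbinom(n, r, rbeta(n, mu * s, (1 - mu) * s))
    betabinom_site(y, r, sample(x))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("binomial test statistics inflate under over-dispersion", {
  set.seed(45)
  sim <- simulate_dataset(n = 40, n_sites = 150, n_true = 0, pve = 0,
                          h2 = 0, sigma2 = 0.5, seed = 46)
  res <- binomial_scan(sim$dataset, sim$x)
  expect_gt(genomic_control(res$p), 1.5)
})

test_that("Fisher's exact test on pooled counts behaves symmetrically", {
  g <- rep(c(0, 1), each = 2)
  p1 <- fisher_exact_group_test(c(3, 2, 3, 2), c(5, 5, 5, 5), g)
  expect_equal(p1, 1)
  p2 <- fisher_exact_group_test(c(5, 5, 0, 0), c(5, 5, 5, 5), g)
  expect_equal(p2, 2 / choose(20, 10), tolerance = 1e-12)
  p3 <- fisher_exact_group_test(c(5, 5, 0, 0), c(5, 5, 5, 5), 1 - g)
  expect_equal(p2, p3)
  expect_error(fisher_exact_group_test(c(1, 2), c(3, 3), c(0, 0)),
               "two non-empty")
})
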