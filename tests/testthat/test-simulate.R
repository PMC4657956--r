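test_that("baboon-like kinship hits the relatedness composition targets", {
  set.seed(50)
  K <- simulate_kinship(80, "baboon_like")$K
  off <- K - diag(diag(K))
  max_r <- apply(off, 1, max)
  expect_gte(mean(max_r >= 0.25), 0.05)
  expect_lte(mean(max_r >= 0.25), 0.15)
  expect_gte(mean(max_r < 0.05), 0.40)
  expect_lte(mean(max_r < 0.05), 0.60)
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values
                  > -1e-10))
  expect_equal(sum(diag(K)) / 80, 1, tolerance = 1e-12)
})

test_that("a forced dyad at n = 2 carries close relatedness and is PSD", {
  set.seed(51)
  K <- simulate_kinship(2, "baboon_like")$K
  expect_true(K[1, 2] %in% c(0.25, 0.5))
  expect_true(min(eigen(K, only.values = TRUE)$values) > 0)
})

test_that("two-population genotypes produce block kinship and a bimodal PC1", {
  set.seed(52)
  K <- simulate_kinship(60, "two_pop")
  G <- attr(K, "G")
  pop <- attr(G, "pop")
  pc1 <- genotype_pca(G, k = 1)$scores[, 1]
  expect_gt(summary(lm(pc1 ~ factor(pop)))$r.squared, 0.8)
})

test_that("age-like predictors respect the observed age range", {
  set.seed(53)
  x <- simulate_predictor(200, "age_like")
  expect_gte(min(x), 1.76)
  expect_lte(max(x), 18.01)
})

test_that("confounded predictors realize the target R2 with PC1", {
  set.seed(54)
  pc1 <- rnorm(100)
  x <- simulate_predictor(100, "confounded", pc1 = pc1, target_r2 = 0.5)
  expect_equal(unname(cor(x, pc1)^2), 0.5, tolerance = 0.02)
  expect_equal(attr(x, "r2"), 0.5, tolerance = 1e-6)
  # noise-dominated limit: huge added noise drives R2 to zero
  x2 <- scale(pc1) + 1e4 * rnorm(100)
  expect_lt(cor(x2, pc1)^2, 0.05)
  expect_error(simulate_predictor(100, "confounded", pc1 = pc1,
                                  target_r2 = 1.2), "target_r2")
})

test_that("true-negative sites carry beta = 0 and PVE is exact by construction", {
  set.seed(55)
  K <- simulate_kinship(30)
  x <- simulate_predictor(30, "age_like")
  sim <- simulate_sites(50, 10, pve = 0.1, h2 = 0.3, sigma2 = 0.5,
                        K = K, x = x)
  expect_true(all(sim$truth$beta[!sim$truth$is_true_positive] == 0))
  b <- sim$truth$beta[sim$truth$is_true_positive][1]
  expect_equal(b^2 * var(x) / (b^2 * var(x) + 0.5), 0.1, tolerance = 1e-12)
  expect_true(all(sim$dataset$y <= sim$dataset$r, na.rm = TRUE))
})

test_that("effect size is recovered in the noiseless large-coverage limit", {
  set.seed(56)
  n <- 400
  K <- relatedness_matrix(diag(n))
  x <- simulate_predictor(n, "age_like")
  pool <- data.frame(size = 1e6, mu = 1e6, prob = 0.5, near_poisson = TRUE)
  class(pool) <- c("coverage_pool", "data.frame")
  sim <- simulate_sites(5, 5, pve = 0, h2 = 0, sigma2 = 0, K = K, x = x,
                        pool = pool, beta = 0.05)
  for (s in 1:5) {
    z <- qlogis(sim$dataset$y[s, ] / sim$dataset$r[s, ])
    slope <- coef(lm(z ~ x))[2]
    expect_equal(unname(slope), 0.05, tolerance = 0.01)
  }
})

test_that("genetic effects covary more for close relatives", {
  set.seed(57)
  K <- simulate_kinship(40)
  x <- simulate_predictor(40, "age_like")
  sim <- simulate_sites(400, 0, pve = 0, h2 = 0.6, sigma2 = 1, K = K,
                        x = x, return_latent = TRUE)
  off <- K$K - diag(diag(K$K))
  close <- which(off >= 0.25, arr.ind = TRUE)
  far <- which(off == 0, arr.ind = TRUE)
  cor_close <- mean(vapply(seq_len(nrow(close)), function(k)
    cor(sim$g[, close[k, 1]], sim$g[, close[k, 2]]), 0))
  far <- far[sample(nrow(far), 40), , drop = FALSE]
  cor_far <- mean(vapply(seq_len(nrow(far)), function(k)
    cor(sim$g[, far[k, 1]], sim$g[, far[k, 2]]), 0))
  expect_gt(cor_close, cor_far + 0.1)
})

test_that("negative-binomial coverage fits recover pool parameters", {
  set.seed(58)
  r_mat <- matrix(rnbinom(40 * 200, size = 5, prob = 0.3), 40, 200)
  pool <- fit_nb_coverage_pool(r_mat)
  expect_gte(median(pool$size), 3.5)
  expect_lte(median(pool$size), 7)
  expect_gte(median(pool$prob), 0.2)
  expect_lte(median(pool$prob), 0.4)
  expect_false(any(pool$near_poisson))

  r_pois <- matrix(rpois(5 * 300, 20), 5, 300)
  pool2 <- fit_nb_coverage_pool(r_pois)
  expect_true(any(pool2$near_poisson))

  expect_error(fit_nb_coverage_pool(matrix(0L, 3, 10)), "no usable")
})

test_that("default coverage pool matches the calibration targets", {
  set.seed(59)
  pool <- default_coverage_pool(5000)
  expect_equal(unname(quantile(pool$mu, 0.25)), 4.7, tolerance = 0.5)
  expect_gt(max(pool$mu) / min(pool$mu), 100)  # spans orders of magnitude
  # realized site mean coverage in a simulated dataset
  K <- relatedness_matrix(diag(30))
  x <- simulate_predictor(30, "age_like")
  sim <- simulate_sites(800, 0, 0, 0, 0.5, K, x, pool = pool)
  q25 <- unname(quantile(rowMeans(sim$dataset$r), 0.25))
  expect_gt(q25, 3)
  expect_lt(q25, 6.5)
})

test_that("dataset simulation is seed-deterministic end to end", {
  s1 <- simulate_dataset(20, n_sites = 15, n_true = 5, pve = 0.1,
                         h2 = 0.3, seed = 60)
  s2 <- simulate_dataset(20, n_sites = 15, n_true = 5, pve = 0.1,
                         h2 = 0.3, seed = 60)
  expect_identical(s1$dataset$y, s2$dataset$y)
  expect_identical(s1$truth$nb_size, s2$truth$nb_size)
  expect_identical(s1$x, s2$x)
})
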