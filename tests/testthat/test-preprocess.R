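test_that("methylation proportions come from counts; zero coverage is NA", {
  ds <- make_dataset(rbind(c(5, 50), c(0, 0)), rbind(c(10, 100), c(3, 0)))
  p <- meth_proportions(ds)
  expect_equal(p[1, ], c(s1 = 0.5, s2 = 0.5))  # 5/10 same as 50/100
  expect_equal(unname(p[2, 1]), 0)
  expect_true(is.na(p[2, 2]))
})

test_that("filtering drops one site per rule on a constructed fixture", {
  n <- 8
  mk <- function(pi, cov) {
    r <- rep(cov, n)
    y <- round(pi * r)
    list(y = y, r = r)
  }
  # exactly one site violates each rule: 1 = low observation,
  # 2 = hypermethylated, 4 = near-zero SD, 5 = low coverage;
  # sites 3, 6, 7, 8 survive
  pi_clean <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.45, 0.55)
  rows <- list(
    mk(pi_clean, 20), mk(rep(0.95, n), 20), mk(pi_clean, 20),
    mk(rep(0.500, n), 20), mk(pi_clean, 2), mk(pi_clean + 0.05, 25),
    mk(rev(pi_clean), 30), mk(pi_clean * 0.9, 22))
  y <- do.call(rbind, lapply(rows, `[[`, "y"))
  r <- do.call(rbind, lapply(rows, `[[`, "r"))
  y[1, 1:5] <- NA; r[1, 1:5] <- NA       # observed in 3/8 < 50%
  ds <- make_dataset(y, r)
  out <- filter_sites(ds, filter_config())
  rep <- out$report
  expect_equal(rep$dropped_low_obs, 1)
  expect_equal(rep$dropped_hyper_hypo, 1)
  expect_equal(rep$dropped_low_sd, 1)
  expect_equal(rep$dropped_low_coverage, 1)
  expect_equal(rep$n_kept, 4)
  # the realized coverage cutoff is the lowest quartile of the sites
  # surviving the earlier rules
  expect_equal(rep$coverage_cutoff,
               unname(quantile(c(20, 2, 25, 30, 22), 0.25)))
})

test_that("a site with mean proportion 0.95 is dropped by the hyper rule", {
  y <- rbind(c(19, 19, 19), c(10, 10, 10))
  r <- rbind(c(20, 20, 20), c(20, 20, 20))
  ds <- make_dataset(y, r)
  out <- filter_sites(ds, filter_config(sd_quantile_drop = 0,
                                        coverage_quantile_drop = 0))
  expect_equal(out$report$dropped_hyper_hypo, 1)
  expect_equal(out$dataset$site_ids, ds$site_ids[2])
})

test_that("filtering is idempotent", {
  set.seed(7)
  sim <- tiny_sim(n = 20, n_sites = 80, n_true = 0, pve = 0, h2 = 0)
  f1 <- filter_sites(sim$dataset)
  f2 <- filter_sites(f1$dataset,
                     filter_config(sd_quantile_drop = 0,
                                   coverage_quantile_drop = 0))
  expect_identical(f2$dataset$site_ids, f1$dataset$site_ids)
})

test_that("transforms match closed forms", {
  ds <- make_dataset(rbind(c(5, 5, 2)), rbind(c(10, 20, 8)))
  m <- transform_methylation(ds, "m_value")
  expect_equal(unname(m[1, 1]), log2((5 + 0.01) / (5 + 0.01)))  # = 0
  expect_equal(unname(m[1, 2]), log2(5.01 / 15.01))
  a <- transform_methylation(ds, "arcsin_sqrt")
  expect_equal(unname(a[1, 3]), asin(sqrt(0.25)))
  expect_equal(asin(sqrt(0.25)), pi / 6, tolerance = 1e-12)

  ds3 <- make_dataset(rbind(c(1, 2, 3)), rbind(c(6, 6, 6)))
  qn <- transform_methylation(ds3, "quantile_normal")
  expect_equal(unname(qn[1, ]), qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  expect_equal(unname(qn[1, 2]), 0)
})

test_that("quantile normalization is centred and monotone", {
  set.seed(8)
  for (i in 1:5) {
    n <- 2 * sample(5:15, 1) + 1   # odd n, distinct values: no ties
    y <- sample(0:1000, n)
    ds <- make_dataset(matrix(y, 1), matrix(1000L, 1, n))
    z <- transform_methylation(ds, "quantile_normal")[1, ]
    expect_lt(abs(mean(z)), 1e-8)
    expect_equal(order(z), order(y / 1000))
  }
})

test_that("logit transform clamps by the site's maximum coverage", {
  ds <- make_dataset(rbind(c(0, 10)), rbind(c(10, 10)))
  lg <- transform_methylation(ds, "logit")
  eps <- 1 / (2 * 10)
  expect_equal(unname(lg[1, ]), qlogis(c(eps, 1 - eps)))
})

test_that("knn imputation: identity, twin-site, and brute-force oracle", {
  m0 <- matrix(rnorm(12), 3, 4)
  expect_identical(knn_impute(m0), m0)

  tw <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(9, 9, 9, 9))
  tw[1, 2] <- NA
  expect_equal(knn_impute(tw, k = 1)[1, 2], 2)

  set.seed(9)
  m <- matrix(rnorm(5 * 6), 5, 6)
  m[2, 4] <- NA
  imp <- knn_impute(m, k = 2)
  d <- sapply(seq_len(5), function(i)
    mean((m[i, -4] - m[2, -4])^2))
  d[2] <- Inf
  nb <- order(d)[1:2]
  expect_equal(imp[2, 4], mean(m[nb, 4]))
  expect_error(knn_impute(rbind(c(1, NA, NA), c(1, 2, 3))), "fewer than 2")
})
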