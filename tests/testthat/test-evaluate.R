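test_that("exchangeable null yields zero empirical-FDR detections", {
  set.seed(70)
  p <- runif(1000)
  det <- empirical_fdr_detections(p, list(p), level = 0.10)
  expect_length(det, 0)
})

test_that("planted signals are detected against permutation nulls", {
  set.seed(71)
  p_real <- c(rep(1e-6, 10), runif(990))
  nulls <- replicate(4, runif(1000), simplify = FALSE)
  det <- empirical_fdr_detections(p_real, nulls, level = 0.10)
  expect_true(all(1:10 %in% det))
  expect_lte(length(det), 20)
  # averaging invariance: duplicating every permutation changes nothing
  det2 <- empirical_fdr_detections(p_real, c(nulls, nulls), level = 0.10)
  expect_identical(sort(det), sort(det2))
})

test_that("empirical-FDR detections nest across levels", {
  set.seed(72)
  p_real <- c(rbeta(200, 0.3, 1), runif(800))
  nulls <- replicate(4, runif(1000), simplify = FALSE)
  d05 <- empirical_fdr_detections(p_real, nulls, level = 0.05)
  d20 <- empirical_fdr_detections(p_real, nulls, level = 0.20)
  expect_true(all(d05 %in% d20))
})

test_that("truth-based FDR power matches an exhaustive threshold scan", {
  set.seed(73)
  truth <- c(rep(TRUE, 30), rep(FALSE, 270))
  p <- c(rbeta(30, 0.2, 1), runif(270))
  got <- truth_fdr_power(p, truth, level = 0.10)
  # oracle: scan every threshold, monotonize, take the largest passing
  thr <- sort(p)
  fdr <- vapply(thr, function(t) sum(p <= t & !truth) /
                  max(1, sum(p <= t)), 0)
  fdr <- rev(cummin(rev(fdr)))
  ok <- which(fdr <= 0.10)
  pow_o <- if (length(ok)) sum(truth & p <= thr[max(ok)]) / 30 else 0
  expect_equal(got$power, pow_o)

  expect_equal(truth_fdr_power(c(rep(1e-12, 30), runif(270)), truth,
                               0.10)$power, 1)
  expect_lt(truth_fdr_power(runif(300), truth, 0.10)$power, 0.2)
  expect_error(truth_fdr_power(p, rep(FALSE, 300)), "no true positives")
})

test_that("q-values equal pi0-scaled Benjamini-Hochberg", {
  set.seed(74)
  p <- c(rbeta(300, 0.2, 1), runif(9700))
  q <- storey_qvalues(p)
  pi0 <- attr(q, "pi0")
  expect_equal(as.numeric(q), pmin(pi0 * p.adjust(p, "BH"), 1),
               tolerance = 1e-12)
  expect_true(all(diff(q[order(p)]) >= -1e-12))

  expect_true(all(storey_qvalues(rep(1, 500)) == 1))
  q_unif <- storey_qvalues(runif(10000))
  expect_gte(attr(q_unif, "pi0"), 0.9)
  expect_lte(attr(q_unif, "pi0"), 1.0)
  expect_warning(q_small <- storey_qvalues(runif(50)), "fewer than 100")
  expect_equal(attr(q_small, "pi0"), 1)
})

test_that("genomic control equals its definitional cases", {
  expect_equal(genomic_control(rep(0.5, 100)), 1, tolerance = 1e-12)
  set.seed(75)
  expect_equal(genomic_control(runif(1e5)), 1, tolerance = 0.02)
  expect_gt(genomic_control(runif(5000)^2), 1.5)
})

test_that("AUC is rank-based with the expected symmetries", {
  truth <- c(rep(TRUE, 50), rep(FALSE, 50))
  p <- c(runif(50, 0, 0.1), runif(50, 0.5, 1))
  expect_equal(auc_from_pvalues(truth, p), 1)
  set.seed(76)
  truth2 <- sample(c(TRUE, FALSE), 5000, replace = TRUE)
  p2 <- runif(5000)
  a <- auc_from_pvalues(truth2, p2)
  expect_equal(a, 0.5, tolerance = 0.02)
  expect_equal(auc_from_pvalues(truth2, p2) +
                 auc_from_pvalues(truth2, 1 - p2), 1, tolerance = 1e-12)
  expect_error(auc_from_pvalues(rep(TRUE, 10), runif(10)), "both classes")
})

test_that("KS uniformity statistic matches closed forms", {
  m <- 100
  grid <- (seq_len(m) - 0.5) / m
  expect_equal(ks_uniform(grid)$D, 0.5 / m, tolerance = 1e-12)
  expect_equal(ks_uniform(rep(0.2, 50))$D, 0.8, tolerance = 1e-12)
  set.seed(77)
  rej <- mean(replicate(60, ks_uniform(runif(4000))$p <= 0.01))
  expect_lte(rej, 0.05)
})

test_that("DMR calling matches the stated criteria on canonical cases", {
  # three significant sites, gaps under 1 kb: one region
  d1 <- call_dmrs(rep("c", 3), c(100, 300, 500), rep(TRUE, 3))
  expect_equal(nrow(d1), 1)
  expect_equal(c(d1$start, d1$end), c(100, 500))

  # a 1.5 kb gap breaks the chain: no region
  d2 <- call_dmrs(rep("c", 3), c(100, 300, 1800), rep(TRUE, 3))
  expect_equal(nrow(d2), 0)

  # S N S N S N N: region closes before the fourth non-significant site
  sig <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  pos <- seq(100, by = 400, length.out = 7)
  d3 <- call_dmrs(rep("c", 7), pos, sig)
  expect_equal(nrow(d3), 1)
  expect_equal(c(d3$start, d3$end), c(pos[1], pos[5]))
  expect_equal(d3$n_sig, 3)

  expect_error(call_dmrs(rep("c", 3), c(5, 2, 9), rep(TRUE, 3)),
               "sorted")
})

test_that("DMR calling agrees with an exhaustive-window oracle", {
  oracle_dmrs <- function(pos, sig, gap = 1000) {
    n <- length(pos)
    valid <- function(i, j) {
      if (!sig[i] || !sig[j]) return(FALSE)
      if (j > i && any(diff(pos[i:j]) > gap)) return(FALSE)
      sum(sig[i:j]) >= 3 && sum(!sig[i:j]) <= 3
    }
    out <- NULL
    i <- 1
    while (i <= n) {
      jbest <- NA
      for (j in i:n) if (valid(i, j)) jbest <- j
      if (!is.na(jbest)) {
        out <- rbind(out, c(pos[i], pos[jbest]))
        i <- jbest + 1
      } else i <- i + 1
    }
    out
  }
  set.seed(78)
  for (rep in 1:40) {
    n <- sample(8:20, 1)
    pos <- cumsum(sample(c(200, 600, 1500), n, replace = TRUE,
                         prob = c(.5, .3, .2)))
    sig <- runif(n) < 0.55
    got <- call_dmrs(rep("c", n), pos, sig)
    want <- oracle_dmrs(pos, sig)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(as.matrix(got[, c("start", "end")]), want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("experiment harness produces a reproducible tidy summary", {
  g1 <- run_experiment("power_no_structure", n = 20, pve = 0.15, h2 = 0,
                       methods = c("betabinom", "linear"),
                       n_sites = 150, n_true = 30, scale = 1,
                       replicates = 1, seed = 5)
  g2 <- run_experiment("power_no_structure", n = 20, pve = 0.15, h2 = 0,
                       methods = c("betabinom", "linear"),
                       n_sites = 150, n_true = 30, scale = 1,
                       replicates = 1, seed = 5)
  expect_identical(g1, g2)
  expect_setequal(g1$method, c("betabinom", "linear"))
  expect_true(all(g1$power >= 0 & g1$power <= 1))
  expect_true(all(c("power", "lambda_null", "auc") %in% names(g1)))
})
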