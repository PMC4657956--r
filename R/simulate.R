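# Generative simulator: kinship structure, predictors, negative-binomial
# read depth, and logit-scale methylation with heritable and independent
# over-dispersion.

#' Simulate a relatedness matrix
#'
#' \code{"baboon_like"} emulates a wild-primate social group: roughly half
#' the individuals have no relative in the sample, a small fraction
#' (about 10 percent) belong to closely related dyads (r of 0.25-0.5,
#' parent-offspring / full or half sibs), and the remainder carry distant
#' relatives (r = 0.125).  \code{"two_pop"} builds population structure
#' from a synthetic genotype matrix with divergent allele frequencies
#' (see [simulate_genotypes()]).
#'
#' @param n number of individuals.
#' @param mode \code{"baboon_like"} or \code{"two_pop"}.
#' @param high_frac target fraction of individuals in close dyads.
#' @param unrelated_frac target fraction with no relative.
#' @return a [relatedness_matrix()] (for \code{"two_pop"}, with the
#'   genotype matrix attached as attribute \code{"G"}).
#' @export
simulate_kinship <- function(n, mode = c("baboon_like", "two_pop"),
                             high_frac = 0.10, unrelated_frac = 0.50) {
  mode <- match.arg(mode)
  if (n < 2) stop("need n >= 2")
  if (mode == "two_pop") {
    G <- simulate_genotypes(n, p = max(200, 2 * n))
    K <- kinship_from_genotypes(G)
    attr(K, "G") <- G
    return(K)
  }
  K <- diag(n)
  n_high <- max(if (high_frac > 0) 2 else 0, round(high_frac * n / 2) * 2)
  n_single <- round(unrelated_frac * n)
  n_fam <- n - n_single
  if (n_fam < n_high) { n_single <- n - n_high; n_fam <- n_high }
  idx <- sample.int(n)
  pos <- 1
  take <- function(k) {
    out <- idx[pos:(pos + k - 1)]
    pos <<- pos + k
    out
  }
  # matrilines: related individuals live in family groups (size 3-8)
  # sharing distant relatedness (r = 0.125); close dyads
  # (parent-offspring / full sibs r = 0.5, or half sibs r = 0.25) are
  # nested inside matrilines until the target fraction of closely
  # related individuals is met
  left <- n_fam
  fams <- list()
  while (left > 0) {
    s <- min(left, sample(3:8, 1))
    if (left - s == 1) s <- s + 1
    fams[[length(fams) + 1L]] <- take(min(s, left))
    left <- left - min(s, left)
  }
  for (fam in fams) {
    for (i in seq_along(fam)) for (j in seq_along(fam)) {
      if (i < j) K[fam[i], fam[j]] <- K[fam[j], fam[i]] <- 0.125
    }
  }
  fi <- 1
  while (n_high >= 2 && fi <= length(fams)) {
    fam <- fams[[fi]]
    if (length(fam) >= 2) {
      pair <- fam[1:2]
      rr <- sample(c(0.5, 0.25), 1)
      K[pair[1], pair[2]] <- K[pair[2], pair[1]] <- rr
      n_high <- n_high - 2
    }
    fi <- fi + 1
  }
  relatedness_matrix(K)
}

#' Simulate a structured genotype matrix
#'
#' Two subpopulations of equal size with Balding-Nichols allele
#' frequencies: for each SNP an ancestral frequency
#' \eqn{f \sim U(0.1, 0.9)} and subpopulation frequencies
#' \eqn{f_k \sim Beta(f(1-F)/F, (1-f)(1-F)/F)}.
#'
#' @param n individuals.
#' @param p SNPs.
#' @param fst divergence parameter F.
#' @return n x p integer matrix of 0/1/2 genotypes with a \code{"pop"}
#'   attribute giving the subpopulation labels.
#' @export
simulate_genotypes <- function(n, p = 500, fst = 0.15) {
  f <- stats::runif(p, 0.1, 0.9)
  shp <- (1 - fst) / fst
  f1 <- stats::rbeta(p, f * shp, (1 - f) * shp)
  f2 <- stats::rbeta(p, f * shp, (1 - f) * shp)
  f1 <- pmin(pmax(f1, 0.02), 0.98)
  f2 <- pmin(pmax(f2, 0.02), 0.98)
  pop <- rep(1:2, length.out = n)
  G <- matrix(0L, n, p)
  for (k in 1:2) {
    rows <- which(pop == k)
    fk <- if (k == 1) f1 else f2
    G[rows, ] <- matrix(
      stats::rbinom(length(rows) * p, 2, rep(fk, each = length(rows))),
      length(rows), p)
  }
  colnames(G) <- paste0("snp", seq_len(p))
  attr(G, "pop") <- pop
  G
}

#' Simulate the predictor of interest
#'
#' \code{"age_like"}: i.i.d. uniform ages on [1.76, 18.01] years (the
#' span observed in wild baboon samples).  \code{"confounded"}: the first
#' principal component of genetic structure plus zero-centred Gaussian
#' noise whose scale is solved (given the realized noise draw) so the
#' squared correlation between the predictor and PC1 equals
#' \code{target_r2} essentially exactly.
#'
#' @param n individuals.
#' @param mode \code{"age_like"} or \code{"confounded"}.
#' @param pc1 numeric vector: PC1 of the genotype matrix or the top
#'   eigenvector of the relatedness matrix (confounded mode).
#' @param target_r2 target squared correlation with PC1.
#' @param age_range age bounds for \code{"age_like"}.
#' @return numeric predictor of length \code{n}; for confounded mode the
#'   realized R2 is attached as attribute \code{"r2"}.
#' @export
simulate_predictor <- function(n, mode = c("age_like", "confounded"),
                               pc1 = NULL, target_r2 = 0.5,
                               age_range = c(1.76, 18.01)) {
  mode <- match.arg(mode)
  if (mode == "age_like")
    return(stats::runif(n, age_range[1], age_range[2]))
  if (is.null(pc1) || length(pc1) != n)
    stop("confounded mode requires pc1 of length n")
  if (target_r2 <= 0 || target_r2 >= 1)
    stop("target_r2 must lie in (0, 1)")
  pc1 <- as.numeric(scale(pc1))
  eta <- as.numeric(scale(stats::rnorm(n)))
  r2c <- function(cc) stats::cor(pc1 + cc * eta, pc1)^2
  cc <- stats::uniroot(function(cc) r2c(cc) - target_r2,
                       lower = 0, upper = 1e3, tol = 1e-12)$root
  x <- pc1 + cc * eta
  attr(x, "r2") <- r2c(cc)
  x
}

#' Fit a negative-binomial coverage pool from observed total counts
#'
#' Per-site maximum-likelihood negative binomial fits (size \eqn{t},
#' probability \eqn{p = t/(t + \mu)}) to total read counts; the simulator
#' samples one (t, p) pair per simulated site with replacement.
#'
#' @param r_matrix matrix of total read counts (sites x samples).
#' @param min_nonzero skip sites with fewer non-zero counts.
#' @return data.frame of class \code{"coverage_pool"} with columns
#'   \code{size}, \code{mu}, \code{prob}, and a \code{near_poisson} flag
#'   (very large size estimates).
#' @export
fit_nb_coverage_pool <- function(r_matrix, min_nonzero = 5) {
  fits <- lapply(seq_len(nrow(r_matrix)), function(i) {
    cnt <- r_matrix[i, ]
    cnt <- cnt[!is.na(cnt)]
    if (sum(cnt > 0) < min_nonzero || stats::var(cnt) == 0) return(NULL)
    f <- tryCatch(
      suppressWarnings(MASS::fitdistr(cnt, "negative binomial")),
      error = function(e) NULL)
    if (is.null(f)) {
      # variance at or below the mean: effectively Poisson
      return(data.frame(size = 1e4, mu = mean(cnt),
                        prob = 1e4 / (1e4 + mean(cnt))))
    }
    t <- unname(f$estimate["size"]); mu <- unname(f$estimate["mu"])
    data.frame(size = t, mu = mu, prob = t / (t + mu))
  })
  pool <- do.call(rbind, fits)
  if (is.null(pool) || nrow(pool) == 0)
    stop("no usable sites for the coverage pool")
  pool$near_poisson <- pool$size > 1e3
  class(pool) <- c("coverage_pool", "data.frame")
  pool
}

#' Default synthetic coverage pool
#'
#' A parametric stand-in (synthetic) for a coverage pool fitted to a real
#' bisulfite data set: per-site mean coverage is log-normal, spanning
#' orders of magnitude across sites, calibrated so the lowest quartile of
#' site mean coverage is about 4.7 reads; per-site negative-binomial size
#' parameters are log-normal around 3, giving moderate extra-Poisson
#' spread across individuals.
#'
#' @param n_pool number of (t, p) parameter pairs.
#' @param meanlog,sdlog log-normal parameters of per-site mean coverage.
#' @param mu_max cap on per-site mean coverage.
#' @return a \code{"coverage_pool"} data.frame.
#' @export
default_coverage_pool <- function(n_pool = 10000, meanlog = 2.43,
                                  sdlog = 1.3, mu_max = 1000) {
  mu <- pmin(pmax(stats::rlnorm(n_pool, meanlog, sdlog), 1), mu_max)
  size <- stats::rlnorm(n_pool, log(3), 0.7)
  pool <- data.frame(size = size, mu = mu, prob = size / (size + mu),
                     near_poisson = FALSE)
  class(pool) <- c("coverage_pool", "data.frame")
  pool
}

#' Simulate methylation count data from the generative model
#'
#' For each site: intercept \eqn{a_0 \sim U(logit(0.10), logit(0.90))};
#' for true-positive sites the predictor effect is
#' \eqn{\beta = \sqrt{pve \cdot \sigma^2 / ((1 - pve) Var(x))}}, so the
#' variance explained by the predictor relative to the total random
#' variation is exactly \code{pve}; genetic effects
#' \eqn{g \sim MVN(0, \sigma^2 h^2 K)} and independent noise
#' \eqn{e \sim N(0, \sigma^2 (1 - h^2))} enter through the logit link;
#' total read counts come from a negative binomial with per-site (t, p)
#' sampled from the coverage pool; methylated counts are binomial.
#'
#' @param n_sites total sites; \code{n_true} of them carry a real effect.
#' @param n_true number of true-positive sites (placed first).
#' @param pve per-site percent variance explained by the predictor (0-1
#'   scale) at true-positive sites.
#' @param h2 heritability of the logit methylation level.
#' @param sigma2 total over-dispersion variance on the logit scale.
#' @param K a [relatedness_matrix()].
#' @param x predictor vector.
#' @param pool a \code{"coverage_pool"}; default [default_coverage_pool()].
#' @param beta optional fixed effect size overriding the PVE-derived value.
#' @param return_latent also return the matrix of genetic effects
#'   \code{g} (sites x individuals) for diagnostics.
#' @return list with \code{dataset} (a [methylation_dataset()] with
#'   positions on one synthetic chromosome, 1 kb apart) and \code{truth}
#'   (per-site \code{is_true_positive}, \code{beta}, \code{a0}, and the
#'   NB parameters used).
#' @export
simulate_sites <- function(n_sites, n_true, pve, h2, sigma2, K, x,
                           pool = NULL, beta = NULL,
                           return_latent = FALSE) {
  stopifnot(n_true <= n_sites, pve >= 0, pve < 1, h2 >= 0, h2 <= 1)
  if (is.null(pool)) pool <- default_coverage_pool()
  n <- length(x)
  if (!inherits(K, "relatedness_matrix")) K <- relatedness_matrix(K)
  if (K$n != n) stop("K dimension does not match predictor length")
  beta0 <- if (!is.null(beta)) beta
    else if (pve > 0) sqrt(pve * sigma2 / ((1 - pve) * stats::var(x)))
    else 0
  is_tp <- c(rep(TRUE, n_true), rep(FALSE, n_sites - n_true))
  beta <- ifelse(is_tp, beta0, 0)
  a0 <- stats::runif(n_sites, stats::qlogis(0.10), stats::qlogis(0.90))
  pick <- sample.int(nrow(pool), n_sites, replace = TRUE)
  tpar <- pool$size[pick]; ppar <- pool$prob[pick]

  sdg <- sqrt(pmax(sigma2 * h2, 0) * K$d)
  y <- r <- matrix(0L, n_sites, n)
  gmat <- if (return_latent) matrix(0, n_sites, n) else NULL
  for (s in seq_len(n_sites)) {
    g <- if (h2 > 0) as.numeric(K$U %*% (sdg * stats::rnorm(length(K$d))))
         else numeric(n)
    e <- stats::rnorm(n, 0, sqrt(sigma2 * (1 - h2)))
    pi_s <- stats::plogis(a0[s] + x * beta[s] + g + e)
    r_s <- stats::rnbinom(n, size = tpar[s], prob = ppar[s])
    y[s, ] <- as.integer(stats::rbinom(n, r_s, pi_s))
    r[s, ] <- as.integer(r_s)
    if (return_latent) gmat[s, ] <- g
  }
  ids <- sprintf("site%05d", seq_len(n_sites))
  dataset <- methylation_dataset(
    y, r, site_ids = ids,
    sample_ids = paste0("ind", seq_len(n)),
    chrom = rep("chrS", n_sites), pos = seq_len(n_sites) * 1000L)
  truth <- data.frame(site_id = ids, is_true_positive = is_tp,
                      beta = beta, a0 = a0, nb_size = tpar,
                      nb_prob = ppar, stringsAsFactors = FALSE)
  out <- list(dataset = dataset, truth = truth)
  if (return_latent) out$g <- gmat
  out
}

#' One-call simulated study
#'
#' Convenience wrapper generating kinship, predictor, and count data for a
#' complete simulated experiment.
#'
#' @param n individuals.
#' @param n_sites,n_true,pve,h2,sigma2 passed to [simulate_sites()].
#' @param predictor_mode \code{"age_like"} or \code{"confounded"}.
#' @param kinship_mode \code{"baboon_like"} or \code{"two_pop"}.
#' @param target_r2 confounding strength (confounded mode).
#' @param pool coverage pool (default [default_coverage_pool()]).
#' @param seed optional seed set before generation.
#' @return list: \code{dataset}, \code{truth}, \code{x}, \code{K},
#'   \code{pc1} (when available).
#' @export
simulate_dataset <- function(n, n_sites = 5000, n_true = 500, pve = 0.10,
                             h2 = 0.6, sigma2 = 0.5,
                             predictor_mode = c("age_like", "confounded"),
                             kinship_mode = c("baboon_like", "two_pop"),
                             target_r2 = 0.5, pool = NULL, seed = NULL) {
  predictor_mode <- match.arg(predictor_mode)
  kinship_mode <- match.arg(kinship_mode)
  if (!is.null(seed)) set.seed(seed)
  K <- simulate_kinship(n, kinship_mode)
  pc1 <- if (kinship_mode == "two_pop")
    genotype_pca(attr(K, "G"), k = 1)$scores[, 1]
  else K$U[, 1]
  x <- if (predictor_mode == "age_like") simulate_predictor(n, "age_like")
       else simulate_predictor(n, "confounded", pc1 = pc1,
                               target_r2 = target_r2)
  sim <- simulate_sites(n_sites, n_true, pve, h2, sigma2, K, x,
                        pool = pool)
  list(dataset = sim$dataset, truth = sim$truth, x = as.numeric(x),
       K = K, pc1 = pc1, realized_r2 = attr(x, "r2"))
}
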