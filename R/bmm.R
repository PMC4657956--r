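# The binomial mixed model: per-site MCMC fit and dataset-level scan.

#' Control parameters for the binomial mixed model sampler
#'
#' @param n_iter total MCMC iterations (including burn-in).
#' @param n_burnin burn-in iterations discarded before summarizing.
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param backend \code{"aux_mixture"} for the aggregated random-utility
#'   augmentation with the normal-mixture approximation of the negative
#'   log-gamma residual (fast, approximate), or \code{"polya_gamma"} for
#'   exact Polya-Gamma augmentation (slower; used as a correctness oracle).
#' @param prior_sigma2 prior on the total over-dispersion variance
#'   \eqn{\sigma^2}: \code{list(type = "uniform", min, max)} for a flat
#'   prior on \eqn{\sigma^2}, or \code{list(type = "log_uniform", min,
#'   max)} for a flat prior on \eqn{\log \sigma^2} over \code{[min, max]}.
#'   The heritability \eqn{h^2} always carries a Uniform(0, 1) prior.
#' @param mh_step random-walk Metropolis step size for
#'   \eqn{(\mathrm{logit}\, h^2, \log \sigma^2)}.
#' @param kl_tol KL tolerance of the normal-mixture table.
#' @param pg_exact Polya-Gamma draws with trial count at or below this use
#'   exact summation; larger counts use a moment-matched normal.
#' @param fix_h2,fix_sigma2 optionally fix a variance component at its
#'   initial value (used for validation against brute-force posteriors).
#' @param h2_init,sigma2_init initial values.
#' @return list of class \code{"bmm_control"}.
#' @export
bmm_control <- function(n_iter = 10000, n_burnin = 1000, thin = 1,
                        backend = c("aux_mixture", "polya_gamma"),
                        prior_sigma2 = list(type = "uniform", min = 0,
                                            max = 10),
                        mh_step = 0.6, kl_tol = 5e-4, pg_exact = 200,
                        fix_h2 = FALSE, fix_sigma2 = FALSE,
                        h2_init = 0.5, sigma2_init = 0.5) {
  stopifnot(n_iter > n_burnin, n_burnin >= 0, thin >= 1)
  backend <- match.arg(backend)
  if (!prior_sigma2$type %in% c("uniform", "log_uniform"))
    stop("prior_sigma2$type must be 'uniform' or 'log_uniform'")
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 backend = backend, prior_sigma2 = prior_sigma2,
                 mh_step = mh_step, kl_tol = kl_tol,
                 pg_exact = as.integer(pg_exact),
                 fix_h2 = fix_h2, fix_sigma2 = fix_sigma2,
                 h2_init = h2_init, sigma2_init = sigma2_init),
            class = "bmm_control")
}

.as_eig <- function(K, n) {
  if (is.null(K)) {
    list(U = diag(n), d = rep(1, n))
  } else if (inherits(K, "relatedness_matrix")) {
    list(U = K$U, d = K$d)
  } else {
    K <- relatedness_matrix(K)
    list(U = K$U, d = K$d)
  }
}

.design_matrix <- function(W, x, n) {
  if (is.null(W)) {
    W <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  } else {
    W <- as.matrix(W)
    if (!all(W[, 1] == 1))
      stop("first column of W must be an all-ones intercept")
    if (qr(W)$rank < ncol(W)) stop("W is rank deficient")
  }
  if (nrow(W) != n || length(x) != n)
    stop("predictor/covariate dimensions do not match the data")
  cbind(W, x = x)
}

#' Fit the binomial mixed model at a single site
#'
#' Fits, by auxiliary-variable MCMC,
#' \deqn{y_i \sim Bin(r_i, \pi_i), \quad
#'   \mathrm{logit}(\pi_i) = w_i^T\alpha + x_i\beta + g_i + e_i,}
#' \deqn{g \sim MVN(0, \sigma^2 h^2 K), \quad
#'   e \sim MVN(0, \sigma^2(1 - h^2) I),}
#' where \eqn{K} is a known relatedness matrix standardized to
#' \eqn{tr(K)/n = 1}, \eqn{h^2} is the heritability of the logit
#' methylation level and \eqn{\sigma^2} the total over-dispersion variance.
#' Approximate Wald inference uses the posterior mean and standard
#' deviation of \eqn{\beta}: the squared t-ratio is referred to
#' \eqn{\chi^2_1}.
#'
#' Individuals with zero or missing total count are dropped.  The genetic
#' random effect is sampled in the eigenbasis of \eqn{K}, restricted to
#' eigenvectors with positive eigenvalue, so a sweep costs
#' \eqn{O(n \cdot rank(K))} after the one-time eigendecomposition.
#'
#' @param y integer vector of methylated read counts.
#' @param r integer vector of total read counts.
#' @param x numeric predictor of interest.
#' @param W optional covariate matrix whose first column is an intercept;
#'   defaults to an intercept only.
#' @param K relatedness: a [relatedness_matrix()], a plain symmetric
#'   matrix, or \code{NULL} for the identity.
#' @param control a [bmm_control()].
#' @return object of class \code{"bmm"} with posterior draws of
#'   \eqn{\beta}, \eqn{h^2}, \eqn{\sigma^2}, Wald summaries, and fit
#'   metadata.
#' @examples
#' set.seed(1)
#' n <- 30
#' x <- rnorm(n)
#' r <- rpois(n, 30) + 1
#' y <- rbinom(n, r, plogis(-0.5 + 0.4 * x))
#' fit <- bmm(y, r, x, control = bmm_control(n_iter = 1500, n_burnin = 300))
#' summary(fit)
#' @export
bmm <- function(y, r, x, W = NULL, K = NULL, control = bmm_control()) {
  n_all <- length(y)
  eig <- .as_eig(K, n_all)
  X <- .design_matrix(W, x, n_all)
  use <- which(!is.na(r) & !is.na(y) & r > 0)
  if (length(use) < ncol(X) + 1)
    stop("too few individuals with positive coverage")
  y <- as.integer(y[use]); r <- as.integer(r[use])
  X <- X[use, , drop = FALSE]
  if (stats::sd(X[, ncol(X)]) == 0)
    stop("predictor is constant among usable individuals")
  pos <- which(eig$d > 1e-8)
  U <- eig$U[use, pos, drop = FALSE]
  d <- eig$d[pos]

  mix <- mixture_table(unique(r), kl_tol = control$kl_tol)
  fl <- .flatten_mixtures(mix)
  mix_idx <- match(r, fl$rs) - 1L

  p0 <- (sum(y) + 0.5) / (sum(r) + 1)
  theta_init <- c(stats::qlogis(p0), rep(0, ncol(X) - 1))

  ps <- control$prior_sigma2
  prior_type <- if (ps$type == "uniform") 0L else 1L

  res <- .bmm_mcmc_cpp(
    y, r, X, U, d,
    mix_idx, fl$k, fl$offset, fl$w, fl$mu, fl$s2,
    control$n_iter, control$n_burnin, control$thin,
    theta_init, control$h2_init, control$sigma2_init,
    control$fix_h2, control$fix_sigma2,
    prior_type, ps$min, ps$max,
    if (control$backend == "aux_mixture") 0L else 1L,
    control$mh_step, control$pg_exact)

  wald <- wald_from_chain(res$beta)
  out <- list(beta = as.numeric(res$beta), h2 = as.numeric(res$h2),
              sigma2 = as.numeric(res$s2),
              coefficients = stats::setNames(as.numeric(res$theta_mean),
                                             colnames(X)),
              beta_hat = wald$beta_hat, se = wald$se, wald = wald$wald,
              p = wald$p,
              h2_hat = mean(res$h2), sigma2_hat = mean(res$s2),
              n_used = length(use), mh_accept = res$mh_accept,
              ops_per_iter = res$ops_per_iter,
              ess = .ess(as.numeric(res$beta)),
              backend = control$backend, control = control)
  class(out) <- "bmm"
  out
}

# effective sample size from the initial positive sequence of
# autocorrelations (Geyer-style truncation)
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] <= 0) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

#' Wald summary from a posterior chain of beta
#'
#' The approximate maximum-likelihood estimate is the posterior mean, its
#' standard error the posterior standard deviation; the Wald statistic
#' \eqn{(\hat\beta/se)^2} is referred to \eqn{\chi^2_1}.
#'
#' @param chain numeric vector of post-burn-in posterior draws.
#' @return list with \code{beta_hat}, \code{se}, \code{wald}, \code{p}.
#' @export
wald_from_chain <- function(chain) {
  chain <- as.numeric(chain)
  if (length(chain) < 100)
    stop("need at least 100 post-burn-in draws for Wald summaries")
  se <- stats::sd(chain)
  if (se == 0) stop("degenerate (constant) chain: standard error is zero")
  beta_hat <- mean(chain)
  wald <- (beta_hat / se)^2
  list(beta_hat = beta_hat, se = se, wald = wald,
       p = max(stats::pchisq(wald, df = 1, lower.tail = FALSE), 1e-300))
}

#' @export
print.bmm <- function(x, ...) {
  cat(sprintf("Binomial mixed model fit (%s backend), n = %d\n",
              x$backend, x$n_used))
  cat(sprintf("  beta = %.4f (se %.4f), Wald p = %.3g\n",
              x$beta_hat, x$se, x$p))
  cat(sprintf("  h2 = %.3f, sigma2 = %.3f\n", x$h2_hat, x$sigma2_hat))
  invisible(x)
}

#' @export
summary.bmm <- function(object, ...) {
  q <- stats::quantile(object$beta, c(0.025, 0.5, 0.975))
  out <- list(
    coefficients = object$coefficients,
    beta = c(estimate = object$beta_hat, se = object$se,
             `2.5%` = unname(q[1]), median = unname(q[2]),
             `97.5%` = unname(q[3])),
    wald = object$wald, p = object$p,
    h2 = c(mean = object$h2_hat,
           stats::quantile(object$h2, c(0.025, 0.975))),
    sigma2 = c(mean = object$sigma2_hat,
               stats::quantile(object$sigma2, c(0.025, 0.975))),
    ess = object$ess, mh_accept = object$mh_accept,
    n_used = object$n_used, backend = object$backend)
  class(out) <- "summary.bmm"
  out
}

#' @export
print.summary.bmm <- function(x, ...) {
  cat(sprintf("Binomial mixed model (%s backend), n = %d\n",
              x$backend, x$n_used))
  cat("\nPredictor effect (logit scale):\n")
  print(round(x$beta, 4))
  cat(sprintf("Wald statistic = %.3f, p = %.3g\n", x$wald, x$p))
  cat("\nVariance components:\n")
  print(round(rbind(h2 = x$h2, sigma2 = x$sigma2), 4))
  cat(sprintf("\nESS(beta) = %.0f, MH acceptance = %.2f\n",
              x$ess, x$mh_accept))
  invisible(x)
}

#' @export
coef.bmm <- function(object, ...) object$coefficients

#' @export
plot.bmm <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  graphics::plot(x$beta, type = "l", xlab = "iteration", ylab = "beta",
                 main = "trace: beta", ...)
  graphics::plot(density(x$beta), main = "posterior: beta", xlab = "beta")
  graphics::plot(x$h2, type = "l", xlab = "iteration", ylab = "h2",
                 main = "trace: h2")
  graphics::plot(x$sigma2, type = "l", xlab = "iteration",
                 ylab = "sigma2", main = "trace: sigma2")
  invisible(x)
}

#' Draw the auxiliary pseudo-data for one site (one augmentation step)
#'
#' Exposes a single augmentation sweep: for each individual, conditional on
#' the current linear predictor, draws the aggregated random utility
#' \eqn{z_i = -\log T_i} (where \eqn{T_i} is a sum of conditional gamma
#' variables with shapes tied to \eqn{y_i} and \eqn{r_i - y_i}) whose
#' residual about \eqn{\psi_i} follows \eqn{-\log \Gamma(r_i, 1)}
#' marginally, then draws a normal-mixture component to yield a Gaussian
#' pseudo-datum with known heteroscedastic noise.  Individuals with
#' \eqn{r_i = 0} are skipped.
#'
#' @param y,r integer count vectors.
#' @param psi current linear predictor values.
#' @param kl_tol mixture table tolerance.
#' @return list with \code{z} (raw utilities), \code{z_centered}
#'   (component-mean-corrected pseudo-data), \code{v} (pseudo-datum
#'   variances), \code{component} (mixture component indices); skipped
#'   individuals carry \code{NA}.
#' @export
augment_site <- function(y, r, psi, kl_tol = 5e-4) {
  stopifnot(length(y) == length(r), length(psi) == length(y))
  use <- which(!is.na(r) & r > 0)
  mix <- mixture_table(unique(r[use]), kl_tol = kl_tol)
  fl <- .flatten_mixtures(mix)
  res <- .augment_cpp(as.integer(y[use]), as.integer(r[use]), psi[use],
                      match(r[use], fl$rs) - 1L,
                      fl$k, fl$offset, fl$w, fl$mu, fl$s2)
  out <- list(z = rep(NA_real_, length(y)),
              z_centered = rep(NA_real_, length(y)),
              v = rep(NA_real_, length(y)),
              component = rep(NA_integer_, length(y)))
  out$z[use] <- res$z
  out$z_centered[use] <- res$z_centered
  out$v[use] <- res$v
  out$component[use] <- res$component
  out
}

#' Binomial mixed model association scan over all sites
#'
#' Runs [bmm()] independently at every site of a dataset.  Per-site seeds
#' are derived deterministically from \code{seed} and the site index, so
#' results are reproducible and independent of execution order.
#' Per-site failures are recorded as non-converged rows rather than
#' aborting the scan.
#'
#' @param dataset a [methylation_dataset()].
#' @param x numeric predictor of interest (one value per sample).
#' @param W optional covariate matrix (first column all-ones).
#' @param K relatedness ([relatedness_matrix()] or matrix) or \code{NULL}.
#' @param control a [bmm_control()].
#' @param seed master seed for the per-site chains.
#' @param verbose print progress every 200 sites.
#' @return data.frame with columns \code{site_id, chrom, pos, n_used,
#'   beta_hat, se, wald, p, h2_hat, sigma2_hat, converged}.
#' @export
bmm_scan <- function(dataset, x, W = NULL, K = NULL,
                     control = bmm_control(), seed = 1,
                     verbose = FALSE) {
  n <- ncol(dataset$y)
  eig <- .as_eig(K, n)
  Kobj <- structure(list(K = NULL, U = eig$U, d = eig$d, n = n),
                    class = "relatedness_matrix")
  # prefit the mixture table once for all coverages in the dataset
  if (control$backend == "aux_mixture") {
    rs <- unique(dataset$r[!is.na(dataset$r) & dataset$r > 0])
    invisible(mixture_table(rs, kl_tol = control$kl_tol))
  }
  m <- nrow(dataset$y)
  out <- .empty_results(dataset)
  for (i in seq_len(m)) {
    set.seed(.site_seed(seed, i))
    fit <- tryCatch(
      bmm(dataset$y[i, ], dataset$r[i, ], x, W, Kobj, control),
      error = function(e) e)
    if (inherits(fit, "error")) {
      out$converged[i] <- FALSE
    } else {
      out[i, c("n_used", "beta_hat", "se", "wald", "p",
               "h2_hat", "sigma2_hat")] <-
        list(fit$n_used, fit$beta_hat, fit$se, fit$wald, fit$p,
             fit$h2_hat, fit$sigma2_hat)
      out$converged[i] <- TRUE
    }
    if (verbose && i %% 200 == 0)
      message(sprintf("  bmm_scan: %d / %d sites", i, m))
  }
  out
}

.site_seed <- function(master, i) {
  (as.integer(master) + 7919 * as.integer(i)) %% 2147483647
}

.empty_results <- function(dataset) {
  m <- nrow(dataset$y)
  data.frame(
    site_id = dataset$site_ids,
    chrom = if (!is.null(dataset$chrom)) dataset$chrom else NA,
    pos = if (!is.null(dataset$pos)) dataset$pos else NA,
    n_used = NA_integer_, beta_hat = NA_real_, se = NA_real_,
    wald = NA_real_, p = NA_real_, h2_hat = NA_real_,
    sigma2_hat = NA_real_, converged = NA,
    stringsAsFactors = FALSE)
}
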