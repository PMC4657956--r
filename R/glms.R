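# Count-based baselines: binomial GLM, beta-binomial regression, and
# Fisher's exact test on pooled counts.

#' Binomial GLM at a single site
#'
#' Logistic regression with binomial totals fitted by iteratively
#' reweighted least squares (\code{stats::glm}); Wald p-value for the
#' predictor.  Perfect separation (divergent estimate) is flagged and the
#' p-value set missing.
#'
#' @param y,r integer count vectors (individuals with \code{r = 0} or
#'   missing are dropped).
#' @param x numeric predictor of interest.
#' @param W optional covariate matrix (intercept first column).
#' @return list with \code{beta_hat}, \code{se}, \code{wald}, \code{p},
#'   \code{n_used}, \code{converged}.
#' @export
binomial_glm_site <- function(y, r, x, W = NULL) {
  use <- which(!is.na(r) & !is.na(y) & r > 0)
  X <- .design_matrix(W, x, length(y))[use, , drop = FALSE]
  y <- y[use]; r <- r[use]
  if (stats::sd(X[, ncol(X)]) == 0) stop("predictor is constant")
  fit <- suppressWarnings(
    stats::glm.fit(X, cbind(y, r - y), family = stats::binomial()))
  q <- ncol(X)
  b <- fit$coefficients[q]
  covb <- chol2inv(fit$qr$qr[seq_len(q), seq_len(q), drop = FALSE])
  se <- sqrt(covb[q, q])
  # divergent estimates (perfect separation) show up as a huge
  # coefficient and/or standard error on the logit scale
  sep <- !fit$converged || !is.finite(b) || abs(b) > 10 ||
    !is.finite(se) || se > 10
  if (sep) {
    return(list(beta_hat = unname(b), se = NA_real_, wald = NA_real_,
                p = NA_real_, n_used = length(use), converged = FALSE))
  }
  wald <- (b / se)^2
  list(beta_hat = unname(b), se = se, wald = wald,
       p = max(stats::pchisq(wald, 1, lower.tail = FALSE), 1e-300),
       n_used = length(use), converged = TRUE)
}

#' Beta-binomial regression at a single site
#'
#' Maximum likelihood for
#' \deqn{y_i \sim BetaBin(r_i, a_i, b_i), \quad a_i = \mu_i(1-\phi)/\phi,
#'   \quad b_i = (1-\mu_i)(1-\phi)/\phi,}
#' with \eqn{\mathrm{logit}(\mu_i) = w_i^T\alpha + x_i\beta} and a single
#' over-dispersion parameter \eqn{\phi \in [0, 1)} on the intraclass
#' correlation scale.  Joint quasi-Newton optimization with \eqn{\phi} on
#' the logit scale and analytic gradients; the Wald standard error comes
#' from the observed information, with a likelihood-ratio test available
#' via \code{test = "lrt"}.
#'
#' @param y,r integer count vectors.
#' @param x predictor of interest.
#' @param W optional covariates (intercept first column).
#' @param test \code{"wald"} (default) or \code{"lrt"}.
#' @param phi_init initial dispersion values tried in turn on
#'   non-convergence.
#' @return object of class \code{"betabinom_fit"}: coefficients,
#'   \code{phi}, \code{beta_hat}, \code{se}, \code{wald}, \code{p},
#'   \code{loglik}, \code{converged}.
#' @export
betabinom_site <- function(y, r, x, W = NULL, test = c("wald", "lrt"),
                           phi_init = c(0.05, 0.2, 0.01)) {
  test <- match.arg(test)
  use <- which(!is.na(r) & !is.na(y) & r > 0)
  X <- .design_matrix(W, x, length(y))[use, , drop = FALSE]
  y <- as.integer(y[use]); r <- as.integer(r[use])
  q <- ncol(X)
  if (length(y) < q + 2) stop("too few individuals for beta-binomial fit")
  glm0 <- suppressWarnings(
    stats::glm.fit(X, cbind(y, r - y), family = stats::binomial()))
  co0 <- glm0$coefficients
  co0[!is.finite(co0)] <- 0
  co0 <- pmin(pmax(co0, -8), 8)

  fitfun <- function(par0, Xm) {
    stats::optim(par0, fn = .bb_negll_cpp, gr = .bb_grad_cpp,
                 y = y, r = r, X = Xm, method = "BFGS",
                 control = list(maxit = 300, reltol = 1e-10))
  }
  best <- NULL
  for (ph in phi_init) {
    o <- tryCatch(fitfun(c(co0, stats::qlogis(ph)), X),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) {
    return(structure(list(beta_hat = NA_real_, se = NA_real_,
                          wald = NA_real_, p = NA_real_, phi = NA_real_,
                          loglik = NA_real_, n_used = length(use),
                          converged = FALSE),
                     class = "betabinom_fit"))
  }
  par <- best$par
  phi <- stats::plogis(par[q + 1])
  ll <- -best$value
  b <- par[q]
  if (test == "wald") {
    H <- tryCatch(
      stats::optimHess(par, fn = .bb_negll_cpp, gr = .bb_grad_cpp,
                       y = y, r = r, X = X),
      error = function(e) NULL)
    covb <- if (!is.null(H))
      tryCatch(solve(H), error = function(e) NULL) else NULL
    if (is.null(covb) || covb[q, q] <= 0) {
      se <- NA_real_; wald <- NA_real_; p <- NA_real_; conv <- FALSE
    } else {
      se <- sqrt(covb[q, q])
      wald <- (b / se)^2
      p <- max(stats::pchisq(wald, 1, lower.tail = FALSE), 1e-300)
      conv <- best$convergence == 0
    }
  } else {
    X0 <- X[, -q, drop = FALSE]
    glm00 <- suppressWarnings(
      stats::glm.fit(X0, cbind(y, r - y), family = stats::binomial()))
    co00 <- pmin(pmax(ifelse(is.finite(glm00$coefficients),
                             glm00$coefficients, 0), -8), 8)
    o0 <- fitfun(c(co00, stats::qlogis(phi)), X0)
    lrt <- 2 * (ll - (-o0$value))
    se <- NA_real_
    wald <- max(lrt, 0)
    p <- max(stats::pchisq(wald, 1, lower.tail = FALSE), 1e-300)
    conv <- best$convergence == 0 && o0$convergence == 0
  }
  structure(list(beta_hat = unname(b), se = se, wald = wald, p = p,
                 phi = phi,
                 coefficients = stats::setNames(par[seq_len(q)],
                                                colnames(X)),
                 loglik = ll, n_used = length(use), converged = conv),
            class = "betabinom_fit")
}

#' @export
print.betabinom_fit <- function(x, ...) {
  cat(sprintf(
    "Beta-binomial fit: beta = %.4f (se %.4f), p = %.3g, phi = %.4f\n",
    x$beta_hat, x$se, x$p, x$phi))
  invisible(x)
}

#' Beta-binomial log-likelihood
#'
#' Direct evaluation of the beta-binomial log-likelihood at given
#' parameters (used by tests and sensitivity checks).
#'
#' @param par parameter vector: coefficients then \code{logit(phi)}.
#' @param y,r counts; \code{x}, \code{W} as in [betabinom_site()].
#' @return log-likelihood value.
#' @export
betabinom_loglik <- function(par, y, r, x, W = NULL) {
  use <- which(!is.na(r) & !is.na(y) & r > 0)
  X <- .design_matrix(W, x, length(y))[use, , drop = FALSE]
  -.bb_negll_cpp(par, as.integer(y[use]), as.integer(r[use]), X)
}

#' Fisher's exact test on group-pooled counts
#'
#' Pools methylated / unmethylated counts within each of two groups into a
#' 2 x 2 table and computes the two-sided exact p-value.
#'
#' @param y,r integer count vectors.
#' @param group binary group labels (two levels).
#' @return two-sided p-value.
#' @export
fisher_exact_group_test <- function(y, r, group) {
  use <- which(!is.na(r) & !is.na(y) & r > 0 & !is.na(group))
  g <- factor(group[use])
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("group must have exactly two non-empty levels")
  y <- y[use]; r <- r[use]
  tab <- rbind(tapply(y, g, sum), tapply(r - y, g, sum))
  stats::fisher.test(tab)$p.value
}

#' Per-site scans for the count-based baselines
#'
#' @param dataset a [methylation_dataset()].
#' @param x predictor (continuous for \code{binomial_scan} /
#'   \code{betabinom_scan}; binary for \code{fisher_scan}).
#' @param W optional covariates.
#' @param test test variant for the beta-binomial.
#' @return standard site association data.frame.
#' @export
betabinom_scan <- function(dataset, x, W = NULL, test = "wald") {
  out <- .empty_results(dataset)
  for (i in seq_len(nrow(dataset$y))) {
    fit <- tryCatch(
      betabinom_site(dataset$y[i, ], dataset$r[i, ], x, W, test = test),
      error = function(e) e)
    if (inherits(fit, "error") || !isTRUE(fit$converged)) {
      out$converged[i] <- FALSE
      if (!inherits(fit, "error")) {
        out$beta_hat[i] <- fit$beta_hat
        out$n_used[i] <- fit$n_used
      }
    } else {
      out[i, c("n_used", "beta_hat", "se", "wald", "p")] <-
        list(fit$n_used, fit$beta_hat, fit$se, fit$wald, fit$p)
      out$sigma2_hat[i] <- fit$phi
      out$converged[i] <- TRUE
    }
  }
  out
}

#' @rdname betabinom_scan
#' @export
binomial_scan <- function(dataset, x, W = NULL) {
  out <- .empty_results(dataset)
  for (i in seq_len(nrow(dataset$y))) {
    fit <- tryCatch(binomial_glm_site(dataset$y[i, ], dataset$r[i, ], x, W),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      out$converged[i] <- FALSE
    } else {
      out[i, c("n_used", "beta_hat", "se", "wald", "p")] <-
        list(fit$n_used, fit$beta_hat, fit$se, fit$wald, fit$p)
      out$converged[i] <- fit$converged
    }
  }
  out
}

#' @rdname betabinom_scan
#' @export
fisher_scan <- function(dataset, x) {
  out <- .empty_results(dataset)
  for (i in seq_len(nrow(dataset$y))) {
    p <- tryCatch(
      fisher_exact_group_test(dataset$y[i, ], dataset$r[i, ], x),
      error = function(e) e)
    if (inherits(p, "error")) {
      out$converged[i] <- FALSE
    } else {
      out$p[i] <- p
      out$n_used[i] <- sum(!is.na(dataset$r[i, ]) & dataset$r[i, ] > 0)
      out$converged[i] <- TRUE
    }
  }
  out
}
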