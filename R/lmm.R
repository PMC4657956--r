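# Single-variance-component linear mixed model on transformed methylation
# levels: ML fit by 1-D profile over the variance fraction in the
# eigenbasis of the relatedness matrix, with a Wald test on the predictor.

# profile ML log-likelihood at a given variance fraction h2, on rotated
# data (zs, Xs) with eigenvalues dv
.lmm_profile <- function(h2, zs, Xs, dv) {
  n <- length(zs)
  v <- h2 * dv + (1 - h2)
  wt <- 1 / v
  XtWX <- crossprod(Xs, Xs * wt)
  XtWz <- crossprod(Xs, zs * wt)
  bh <- solve(XtWX, XtWz)
  rss <- sum(wt * (zs - Xs %*% bh)^2)
  s2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(v)) + n)
  list(ll = ll, beta = bh, s2 = s2, XtWX = XtWX)
}

#' Fit the linear mixed model at a single site
#'
#' Maximum-likelihood fit of
#' \deqn{z = W\alpha + x\beta + u, \quad
#'   Var(u) = \sigma^2 (h^2 K + (1 - h^2) I)}
#' by rotating into the eigenbasis of \eqn{K} and profiling the
#' log-likelihood over \eqn{h^2 \in [0, 1]} with Brent optimization on the
#' logit scale (multi-start at 0.1/0.5/0.9, boundaries checked).  Wald
#' p-value for \eqn{\beta} from \eqn{\chi^2_1}.
#'
#' @param z complete numeric response vector (one value per sample).
#' @param x numeric predictor of interest.
#' @param W covariate matrix with intercept first column, or \code{NULL}.
#' @param K a [relatedness_matrix()], plain matrix, or \code{NULL} for
#'   identity (ordinary least squares limit).
#' @param h2_fixed optionally fix \eqn{h^2} instead of profiling.
#' @return list of class \code{"lmm_fit"}: \code{beta_hat}, \code{se},
#'   \code{wald}, \code{p}, \code{h2_hat}, \code{sigma2_hat},
#'   \code{loglik}, \code{coefficients}.
#' @export
fit_lmm_site <- function(z, x, W = NULL, K = NULL, h2_fixed = NULL) {
  n <- length(z)
  if (anyNA(z)) stop("z must be complete; impute missing values first")
  eig <- .as_eig(K, n)
  X <- .design_matrix(W, x, n)
  if (qr(X)$rank < ncol(X)) stop("predictor collinear with covariates")
  zs <- crossprod(eig$U, z)
  Xs <- crossprod(eig$U, X)
  dv <- eig$d

  obj <- function(lg) -.lmm_profile(stats::plogis(lg), zs, Xs, dv)$ll
  if (is.null(h2_fixed)) {
    best <- NULL
    for (start in c(0.1, 0.5, 0.9)) {
      o <- stats::optim(stats::qlogis(start), obj, method = "Brent",
                        lower = -12, upper = 12)
      if (is.null(best) || o$value < best$value) best <- o
    }
    h2_hat <- stats::plogis(best$par)
    # boundary check: the profile likelihood must beat both endpoints
    for (h2b in c(1e-8, 1 - 1e-8)) {
      llb <- .lmm_profile(h2b, zs, Xs, dv)$ll
      if (llb > -best$value) {
        best$value <- -llb
        h2_hat <- h2b
      }
    }
  } else {
    h2_hat <- h2_fixed
  }
  fit <- .lmm_profile(h2_hat, zs, Xs, dv)
  q <- ncol(X)
  covb <- fit$s2 * solve(fit$XtWX)
  se <- sqrt(covb[q, q])
  beta_hat <- fit$beta[q]
  wald <- (beta_hat / se)^2
  structure(list(beta_hat = beta_hat, se = se, wald = wald,
                 p = max(stats::pchisq(wald, 1, lower.tail = FALSE), 1e-300),
                 h2_hat = min(max(h2_hat, 0), 1), sigma2_hat = fit$s2,
                 loglik = fit$ll,
                 coefficients = stats::setNames(as.numeric(fit$beta),
                                                colnames(X))),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("LMM fit: beta = %.4f (se %.4f), p = %.3g, h2 = %.3f\n",
              x$beta_hat, x$se, x$p, x$h2_hat))
  invisible(x)
}

#' Linear mixed model scan over transformed methylation levels
#'
#' @param zmat complete matrix (sites x samples) of transformed
#'   methylation levels (see [transform_methylation()] and
#'   [knn_impute()]).
#' @param x predictor of interest.
#' @param W optional covariates (intercept first column).
#' @param K relatedness.
#' @param site_info optional data.frame with \code{site_id, chrom, pos}.
#' @return standard site association data.frame.
#' @export
lmm_scan <- function(zmat, x, W = NULL, K = NULL, site_info = NULL) {
  n <- ncol(zmat)
  eig <- .as_eig(K, n)
  Kobj <- structure(list(K = NULL, U = eig$U, d = eig$d, n = n),
                    class = "relatedness_matrix")
  out <- .scan_frame(zmat, site_info)
  for (i in seq_len(nrow(zmat))) {
    fit <- tryCatch(fit_lmm_site(zmat[i, ], x, W, Kobj),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      out$converged[i] <- FALSE
    } else {
      out[i, c("n_used", "beta_hat", "se", "wald", "p",
               "h2_hat", "sigma2_hat")] <-
        list(n, fit$beta_hat, fit$se, fit$wald, fit$p,
             fit$h2_hat, fit$sigma2_hat)
      out$converged[i] <- TRUE
    }
  }
  out
}

#' Ordinary linear model scan (no random effect)
#'
#' Simple per-site linear regression of the transformed methylation level
#' on the predictor and covariates.
#'
#' @inheritParams lmm_scan
#' @return standard site association data.frame.
#' @export
linear_scan <- function(zmat, x, W = NULL, site_info = NULL) {
  n <- ncol(zmat)
  X <- .design_matrix(W, x, n)
  q <- ncol(X)
  out <- .scan_frame(zmat, site_info)
  for (i in seq_len(nrow(zmat))) {
    z <- zmat[i, ]
    obs <- !is.na(z)
    fit <- tryCatch(stats::lm.fit(X[obs, , drop = FALSE], z[obs]),
                    error = function(e) e)
    if (inherits(fit, "error") || fit$rank < q) {
      out$converged[i] <- FALSE
      next
    }
    rss <- sum(fit$residuals^2)
    df <- sum(obs) - q
    XtX_inv <- chol2inv(chol(crossprod(X[obs, , drop = FALSE])))
    se <- sqrt(rss / df * XtX_inv[q, q])
    b <- fit$coefficients[q]
    tt <- b / se
    out[i, c("n_used", "beta_hat", "se", "wald", "p")] <-
      list(sum(obs), b, se, tt^2,
           max(2 * stats::pt(-abs(tt), df), 1e-300))
    out$converged[i] <- TRUE
  }
  out
}

.scan_frame <- function(zmat, site_info = NULL) {
  m <- nrow(zmat)
  out <- data.frame(
    site_id = if (!is.null(site_info)) site_info$site_id else
      if (!is.null(rownames(zmat))) rownames(zmat) else
        paste0("site", seq_len(m)),
    chrom = if (!is.null(site_info$chrom)) site_info$chrom else NA,
    pos = if (!is.null(site_info$pos)) site_info$pos else NA,
    n_used = NA_integer_, beta_hat = NA_real_, se = NA_real_,
    wald = NA_real_, p = NA_real_, h2_hat = NA_real_,
    sigma2_hat = NA_real_, converged = NA, stringsAsFactors = FALSE)
  out
}
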