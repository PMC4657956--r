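# Finite normal-mixture approximations to the negative log-gamma
# distribution -log Gamma(r, 1), the residual law of the aggregated
# random-utility pseudo-datum in the binomial-logit augmentation.

.mixture_cache <- new.env(parent = emptyenv())

# Density of (-log G + digamma(r)) / sqrt(trigamma(r)), G ~ Gamma(r, 1),
# i.e. the standardized negative log-gamma target on the t scale.
.nlg_density_std <- function(t, r) {
  mu <- -digamma(r)
  s <- sqrt(trigamma(r))
  x <- mu + s * t
  s * exp(-r * x - exp(-x) - lgamma(r))
}

.dmix <- function(t, w, m, s2) {
  q <- 0
  for (c in seq_along(w)) q <- q + w[c] * stats::dnorm(t, m[c], sqrt(s2[c]))
  q
}

#' Fit a normal-mixture approximation to -log Gamma(r, 1)
#'
#' Approximates the distribution of \eqn{-\log G}, \eqn{G \sim \Gamma(r, 1)},
#' by a finite mixture of normals on the standardized scale
#' \eqn{t = (x + \Psi(r)) / \sqrt{\Psi'(r)}}, where \eqn{\Psi} and
#' \eqn{\Psi'} are the digamma and trigamma functions.  The number of
#' components is increased until the Kullback-Leibler divergence from the
#' target to the mixture falls below \code{kl_tol}; a small internal safety
#' factor is applied so the fitted divergence clears the tolerance with
#' margin.  After fitting, components are affinely corrected so the
#' de-standardized mixture mean and variance equal \eqn{-\Psi(r)} and
#' \eqn{\Psi'(r)} exactly.
#'
#' For large \code{r} a single normal already meets the tolerance (the
#' target is asymptotically Gaussian), and the fit returns \code{k = 1}
#' with exact moments.
#'
#' @param r positive integer shape (in the sampler, the total read count).
#' @param kl_tol KL divergence tolerance in nats.
#' @param k_max maximum number of mixture components to try.
#' @return An object of class \code{"nlg_mixture"}: a list with elements
#'   \code{r}, \code{k}, \code{w} (weights), \code{m}, \code{s2}
#'   (standardized component means/variances), \code{mean_ref}
#'   (\eqn{-\Psi(r)}), \code{var_ref} (\eqn{\Psi'(r)}), and \code{kl}
#'   (grid-quadrature KL divergence of the final fit).
#' @seealso [kl_neg_log_gamma()] for an independent quadrature check.
#' @export
fit_neg_log_gamma_mixture <- function(r, kl_tol = 5e-4, k_max = 10L) {
  stopifnot(length(r) == 1L, r >= 1, r == round(r))
  r <- as.integer(r)
  key <- as.character(r)
  hit <- .mixture_cache[[key]]
  if (!is.null(hit) && hit$kl_tol_used <= kl_tol) return(hit)

  # fit against a slightly tighter tolerance so that independent
  # quadrature cannot land on the wrong side of kl_tol
  tol_fit <- 0.9 * kl_tol

  # density-weighted grid between extreme quantiles of the target
  mu <- -digamma(r)
  sdv <- sqrt(trigamma(r))
  lim <- sort((-log(stats::qgamma(c(1e-10, 1 - 1e-10), r,
                                  lower.tail = FALSE)) - mu) / sdv)
  t <- seq(lim[1], lim[2], length.out = 1500L)
  dt <- t[2L] - t[1L]
  f <- .nlg_density_std(t, r)
  p <- f * dt
  p <- p / sum(p)

  best <- NULL
  for (k in seq_len(k_max)) {
    if (k == 1L) {
      w <- 1; m <- 0; s2 <- 1
    } else {
      cw <- cumsum(p)
      m <- vapply((seq_len(k) - 0.5) / k,
                  function(q) t[which.min(abs(cw - q))], 0)
      s2 <- rep(0.09 * (1 + 4 / k), k)
      w <- rep(1 / k, k)
      prev <- Inf
      for (it in seq_len(400L)) {
        R <- vapply(seq_len(k),
                    function(c) w[c] * stats::dnorm(t, m[c], sqrt(s2[c])),
                    numeric(length(t)))
        rs <- pmax(rowSums(R), 1e-300)
        wp <- p * R / rs
        w <- colSums(wp)
        m <- colSums(wp * t) / w
        s2 <- pmax(vapply(seq_len(k),
                          function(c) sum(wp[, c] * (t - m[c])^2), 0) / w,
                   1e-8)
        w <- w / sum(w)
        if (it %% 25L == 0L) {
          kl_now <- sum(f * dt * log(pmax(f, 1e-300) /
                                     pmax(.dmix(t, w, m, s2), 1e-300)))
          if (prev - kl_now < 1e-7) break
          prev <- kl_now
        }
      }
    }
    # exact moment correction on the standardized scale (target: 0 / 1)
    M <- sum(w * m)
    Vm <- sum(w * (s2 + m^2)) - M^2
    m <- (m - M) / sqrt(Vm)
    s2 <- s2 / Vm
    kl <- sum(f * dt * log(pmax(f, 1e-300) /
                           pmax(.dmix(t, w, m, s2), 1e-300)))
    best <- list(r = r, k = k, w = as.numeric(w), m = as.numeric(m),
                 s2 = as.numeric(s2),
                 mean_ref = mu, var_ref = trigamma(r), kl = kl,
                 kl_tol_used = kl_tol)
    if (kl <= tol_fit) break
  }
  if (best$kl > kl_tol) {
    stop(sprintf(
      "could not reach KL tolerance %.1e for r = %d with k <= %d (best KL %.2e)",
      kl_tol, r, k_max, best$kl))
  }
  class(best) <- "nlg_mixture"
  .mixture_cache[[key]] <- best
  best
}

#' KL divergence of a fitted mixture from -log Gamma(r, 1) by quadrature
#'
#' Computes \eqn{KL(f \| q)} between the exact negative log-gamma density
#' and the fitted normal mixture with adaptive quadrature
#' (\code{stats::integrate}).  This is an independent check of the
#' grid-based divergence minimized during fitting.
#'
#' @param mix an \code{"nlg_mixture"} object.
#' @return KL divergence in nats.
#' @export
kl_neg_log_gamma <- function(mix) {
  stopifnot(inherits(mix, "nlg_mixture"))
  r <- mix$r
  mu <- -digamma(r)
  sdv <- sqrt(trigamma(r))
  integrand <- function(x) {
    lf <- -r * x - exp(-x) - lgamma(r)
    tt <- (x - mu) / sdv
    q <- .dmix(tt, mix$w, mix$m, mix$s2) / sdv
    f <- exp(lf)
    out <- f * (lf - log(pmax(q, 1e-300)))
    out[f == 0] <- 0
    out
  }
  lo <- -log(stats::qgamma(1e-12, r, lower.tail = FALSE))
  hi <- -log(stats::qgamma(1e-12, r))
  stats::integrate(integrand, lo, hi, rel.tol = 1e-9,
                   subdivisions = 2000L)$value
}

#' Build (and cache) the mixture table for a set of trial counts
#'
#' @param rs integer vector of trial counts (total read counts).
#' @param kl_tol KL tolerance passed to [fit_neg_log_gamma_mixture()].
#' @return named list of \code{"nlg_mixture"} objects keyed by r.
#' @export
mixture_table <- function(rs, kl_tol = 5e-4) {
  rs <- sort(unique(as.integer(rs)))
  rs <- rs[rs >= 1L]
  out <- lapply(rs, fit_neg_log_gamma_mixture, kl_tol = kl_tol)
  names(out) <- as.character(rs)
  out
}

#' @export
print.nlg_mixture <- function(x, ...) {
  cat(sprintf(
    "Normal mixture approximation to -log Gamma(%d, 1): k = %d, KL = %.2e\n",
    x$r, x$k, x$kl))
  tab <- data.frame(weight = x$w, mean = x$m, var = x$s2)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

# Flatten a mixture table into parallel arrays for the C++ sampler:
# for each r, component weights / de-standardized means and variances.
.flatten_mixtures <- function(tab) {
  rs <- as.integer(names(tab))
  k <- vapply(tab, function(m) m$k, 0L)
  offs <- c(0L, cumsum(k))
  w <- unlist(lapply(tab, `[[`, "w"), use.names = FALSE)
  mu <- unlist(lapply(tab, function(m) m$mean_ref + sqrt(m$var_ref) * m$m),
               use.names = FALSE)
  s2 <- unlist(lapply(tab, function(m) m$var_ref * m$s2), use.names = FALSE)
  list(rs = rs, k = k, offset = offs[-length(offs)], w = w, mu = mu, s2 = s2)
}
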