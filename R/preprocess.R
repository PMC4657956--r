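# Site filtering and the proportion transformations / imputation used by
# the linear-model baselines.

#' Site filtering configuration
#'
#' Thresholds for the standard CpG filtering pipeline: minimum fraction of
#' samples with coverage, constitutive hyper/hypo-methylation bounds on the
#' mean methylation proportion, the quantile of least-variable sites to
#' drop, and the quantile of lowest mean coverage to drop.
#'
#' @param min_sample_fraction keep sites observed in at least this fraction
#'   of samples.
#' @param hyper_threshold drop sites with mean methylation above this.
#' @param hypo_threshold drop sites with mean methylation below this.
#' @param sd_quantile_drop drop sites whose methylation SD is in this
#'   lowest quantile of the surviving sites.
#' @param coverage_quantile_drop drop sites whose mean coverage is in this
#'   lowest quantile of the surviving sites.
#' @param quantiles_on either \code{"surviving"} (quantile cutoffs computed
#'   on sites surviving the earlier rules) or \code{"all"} (computed on the
#'   full input site set).
#' @return list of class \code{"filter_config"}.
#' @export
filter_config <- function(min_sample_fraction = 0.5,
                          hyper_threshold = 0.90,
                          hypo_threshold = 0.10,
                          sd_quantile_drop = 0.05,
                          coverage_quantile_drop = 0.25,
                          quantiles_on = c("surviving", "all")) {
  vals <- c(min_sample_fraction, hyper_threshold, hypo_threshold,
            sd_quantile_drop, coverage_quantile_drop)
  if (any(vals < 0 | vals > 1)) stop("all thresholds must lie in [0, 1]")
  structure(list(min_sample_fraction = min_sample_fraction,
                 hyper_threshold = hyper_threshold,
                 hypo_threshold = hypo_threshold,
                 sd_quantile_drop = sd_quantile_drop,
                 coverage_quantile_drop = coverage_quantile_drop,
                 quantiles_on = match.arg(quantiles_on)),
            class = "filter_config")
}

#' Methylation proportions (per-cell methylation levels)
#'
#' Per-cell methylation level \eqn{\hat p = y / r}.  Cells with zero or
#' missing coverage propagate as \code{NA}.
#'
#' @param dataset a [methylation_dataset()].
#' @return numeric matrix of proportions in [0, 1], sites x samples.
#' @export
meth_proportions <- function(dataset) {
  p <- dataset$y / dataset$r
  p[!is.finite(p)] <- NA_real_
  p
}

#' Filter CpG sites
#'
#' Applies, in order: (1) drop sites covered in fewer than
#' \code{min_sample_fraction} of samples; (2) drop constitutively
#' hypermethylated (mean proportion above \code{hyper_threshold}) or
#' hypomethylated (below \code{hypo_threshold}) sites; (3) drop sites whose
#' methylation-proportion SD falls in the lowest \code{sd_quantile_drop}
#' quantile; (4) drop sites whose mean coverage falls in the lowest
#' \code{coverage_quantile_drop} quantile.  Quantile cutoffs for rules 3-4
#' are computed on the sites surviving the previous rules (configurable).
#'
#' @param dataset a [methylation_dataset()].
#' @param config a [filter_config()].
#' @return list with \code{dataset} (filtered) and \code{report}: per-rule
#'   drop counts and the realized SD and coverage cutoffs.
#' @export
filter_sites <- function(dataset, config = filter_config()) {
  p <- meth_proportions(dataset)
  n_samp <- ncol(p)
  obs_frac <- rowMeans(!is.na(p) & !is.na(dataset$r) & dataset$r > 0)
  mean_p <- rowMeans(p, na.rm = TRUE)
  sd_p <- apply(p, 1, stats::sd, na.rm = TRUE)
  mean_cov <- rowMeans(dataset$r, na.rm = TRUE)

  keep <- rep(TRUE, nrow(p))
  drop1 <- keep & (obs_frac < config$min_sample_fraction)
  keep <- keep & !drop1
  drop2 <- keep & (is.na(mean_p) | mean_p > config$hyper_threshold |
                   mean_p < config$hypo_threshold)
  keep <- keep & !drop2

  pool_sd <- if (config$quantiles_on == "surviving") sd_p[keep] else sd_p
  sd_cut <- stats::quantile(pool_sd, config$sd_quantile_drop,
                            na.rm = TRUE, names = FALSE)
  drop3 <- keep & (is.na(sd_p) | sd_p <= sd_cut)
  if (config$sd_quantile_drop == 0) drop3 <- keep & FALSE
  keep <- keep & !drop3

  pool_cov <- if (config$quantiles_on == "surviving") mean_cov[keep] else mean_cov
  cov_cut <- stats::quantile(pool_cov, config$coverage_quantile_drop,
                             na.rm = TRUE, names = FALSE)
  drop4 <- keep & (mean_cov < cov_cut)
  if (config$coverage_quantile_drop == 0) drop4 <- keep & FALSE
  keep <- keep & !drop4

  if (!any(keep)) {
    stop(sprintf(
      "all sites removed by filtering (rule counts: %d, %d, %d, %d)",
      sum(drop1), sum(drop2), sum(drop3), sum(drop4)))
  }
  report <- list(
    n_input = nrow(p), n_kept = sum(keep),
    dropped_low_obs = sum(drop1),
    dropped_hyper_hypo = sum(drop2),
    dropped_low_sd = sum(drop3),
    dropped_low_coverage = sum(drop4),
    sd_cutoff = sd_cut, coverage_cutoff = cov_cut)
  list(dataset = subset(dataset, sites = which(keep)), report = report)
}

#' Transform methylation measurements for linear modelling
#'
#' Per-site transformations of methylation level: \code{quantile_normal}
#' maps within-site ranks (ties averaged) to standard normal quantiles via
#' \eqn{\Phi^{-1}((rank - 0.5)/n_{obs})}; \code{logit} applies the logit to
#' proportions clamped into \eqn{[1/(2 r_{max}), 1 - 1/(2 r_{max})]} where
#' \eqn{r_{max}} is the site's maximum coverage; \code{m_value} computes
#' \eqn{\log_2((y + \alpha)/(r - y + \alpha))} with \eqn{\alpha = 0.01}
#' from the counts; \code{arcsin_sqrt} applies
#' \eqn{\arcsin\sqrt{\hat p}}.  Missing entries propagate.
#'
#' @param dataset a [methylation_dataset()].
#' @param method one of \code{"quantile_normal"}, \code{"logit"},
#'   \code{"m_value"}, \code{"arcsin_sqrt"}.
#' @param alpha offset for the M-value transform.
#' @return numeric matrix, sites x samples.
#' @export
transform_methylation <- function(dataset,
                                  method = c("quantile_normal", "logit",
                                             "m_value", "arcsin_sqrt"),
                                  alpha = 0.01) {
  method <- match.arg(method)
  p <- meth_proportions(dataset)
  out <- switch(method,
    quantile_normal = t(apply(p, 1, function(z) {
      obs <- !is.na(z)
      n <- sum(obs)
      if (n > 0)
        z[obs] <- stats::qnorm((rank(z[obs], ties.method = "average") - 0.5) / n)
      z
    })),
    logit = NULL,
    m_value = log2((dataset$y + alpha) / (dataset$r - dataset$y + alpha)),
    arcsin_sqrt = asin(sqrt(p)))
  if (method == "logit") {
    out <- p
    for (i in seq_len(nrow(p))) {
      rmax <- suppressWarnings(max(dataset$r[i, ], na.rm = TRUE))
      if (!is.finite(rmax) || rmax < 1) rmax <- 1
      eps <- 1 / (2 * rmax)
      out[i, ] <- stats::qlogis(pmin(pmax(p[i, ], eps), 1 - eps))
    }
  }
  dimnames(out) <- dimnames(p)
  out
}

#' K-nearest-neighbour imputation of missing cells
#'
#' Missing cells are replaced by the mean of the \code{k} nearest sites
#' (rows), with distance defined as mean squared difference over the
#' samples observed in both sites; neighbours must themselves be observed
#' in the target sample.  Ties are broken by site order, so the result is
#' deterministic.
#'
#' @param mat numeric matrix (sites x samples) with \code{NA} missing cells.
#' @param k number of neighbouring sites to average.
#' @return complete matrix.
#' @export
knn_impute <- function(mat, k = 10) {
  mat <- as.matrix(mat)
  n_obs <- rowSums(!is.na(mat))
  if (any(n_obs < 2))
    stop("sites with fewer than 2 observed values cannot be imputed; filter first")
  miss_rows <- which(rowSums(is.na(mat)) > 0)
  if (!length(miss_rows)) return(mat)
  out <- mat
  for (i in miss_rows) {
    di <- rowMeans((mat - matrix(mat[i, ], nrow(mat), ncol(mat),
                                 byrow = TRUE))^2, na.rm = TRUE)
    di[i] <- Inf
    for (j in which(is.na(mat[i, ]))) {
      cand <- which(!is.na(mat[, j]) & is.finite(di))
      if (!length(cand)) {
        out[i, j] <- mean(mat[i, ], na.rm = TRUE)
        next
      }
      ord <- cand[order(di[cand], cand)]
      nb <- ord[seq_len(min(k, length(ord)))]
      out[i, j] <- mean(mat[nb, j])
    }
  }
  out
}
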