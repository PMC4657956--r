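# Evaluation machinery: permutation-based empirical FDR, truth-based FDR
# and power, Storey q-values, genomic control, AUC, KS calibration, and
# differentially methylated region calling.

#' Detections at a permutation-based empirical FDR level
#'
#' Scans the observed p-values as candidate thresholds.  At threshold t
#' the empirical FDR is the average number of permutation p-values at or
#' below t divided by the number of observed p-values at or below t; the
#' curve is monotonized by a running minimum from the largest threshold
#' downward, and all sites at or below the largest threshold with
#' monotonized FDR at or below \code{level} are returned.
#'
#' @param p_real numeric vector of observed p-values.
#' @param p_null_sets list of one or more permutation p-value vectors.
#' @param level target FDR level.
#' @return integer indices of detected sites, with attributes
#'   \code{threshold} (realized p-value cutoff, \code{NA} if none) and
#'   \code{fdr_curve} (data.frame of threshold / raw and monotonized FDR).
#' @export
empirical_fdr_detections <- function(p_real, p_null_sets, level = 0.10) {
  if (!is.list(p_null_sets)) p_null_sets <- list(p_null_sets)
  p_real_c <- p_real[!is.na(p_real)]
  if (!length(p_real_c) || !length(p_null_sets))
    stop("empty p-value inputs")
  thr <- sort(unique(p_real_c))
  n_real <- cumsum(tabulate(match(sort(p_real_c), thr), length(thr)))
  n_null <- rep(0, length(thr))
  for (pn in p_null_sets) {
    pn <- pn[!is.na(pn)]
    n_null <- n_null + findInterval(thr, sort(pn))
  }
  n_null <- n_null / length(p_null_sets)
  fdr_raw <- n_null / pmax(n_real, 1)
  fdr <- rev(cummin(rev(fdr_raw)))
  ok <- which(fdr <= level)
  if (!length(ok)) {
    out <- integer(0)
    attr(out, "threshold") <- NA_real_
  } else {
    cut <- thr[max(ok)]
    out <- which(!is.na(p_real) & p_real <= cut)
    attr(out, "threshold") <- cut
  }
  attr(out, "fdr_curve") <- data.frame(threshold = thr, fdr_raw = fdr_raw,
                                       fdr = fdr)
  out
}

#' Power and detections at a truth-based empirical FDR level
#'
#' With known truth labels (simulation mode), the FDR at threshold t is
#' the number of false positives at or below t over all detections at or
#' below t (monotonized from the largest threshold downward); power is the
#' fraction of true-positive sites detected at the chosen threshold.
#'
#' @param p numeric p-values.
#' @param truth logical vector: \code{TRUE} for true-positive sites.
#' @param level target FDR level.
#' @return list with \code{power}, \code{detected} (indices),
#'   \code{threshold}, \code{n_detected}, \code{realized_fdr}.
#' @export
truth_fdr_power <- function(p, truth, level = 0.10) {
  stopifnot(length(p) == length(truth))
  n_true <- sum(truth)
  if (n_true == 0) stop("no true positives in truth labels")
  ok <- !is.na(p)
  ord <- order(p[ok])
  p_s <- p[ok][ord]
  tp <- cumsum(truth[ok][ord])
  fp <- seq_along(p_s) - tp
  fdr <- rev(cummin(rev(fp / pmax(seq_along(p_s), 1))))
  pass <- which(fdr <= level)
  if (!length(pass)) {
    return(list(power = 0, detected = integer(0), threshold = NA_real_,
                n_detected = 0L, realized_fdr = NA_real_))
  }
  k <- max(pass)
  cut <- p_s[k]
  detected <- which(ok & p <= cut)
  list(power = tp[k] / n_true, detected = detected, threshold = cut,
       n_detected = length(detected), realized_fdr = fdr[k])
}

#' Storey q-values
#'
#' Estimates the null proportion \eqn{\pi_0} on the usual lambda grid
#' (0.05 to 0.95) with a cubic smoothing spline evaluated at the largest
#' lambda, then computes monotone q-values
#' \eqn{q_{(i)} = \min_{j \ge i} \pi_0 m p_{(j)} / j}.  With fewer than
#' 100 p-values the estimate is unstable and the function falls back to
#' Benjamini-Hochberg (\eqn{\pi_0 = 1}) with a warning.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric q-values (same order as input), with attribute
#'   \code{pi0}.
#' @export
storey_qvalues <- function(p) {
  ok <- !is.na(p)
  m <- sum(ok)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  pi0 <- 1
  if (m < 100) {
    warning("fewer than 100 p-values; using pi0 = 1 (Benjamini-Hochberg)")
  } else {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_lam <- vapply(lam, function(l) sum(p[ok] > l) / (m * (1 - l)), 0)
    sp <- stats::smooth.spline(lam, pi0_lam, df = 3)
    pi0 <- min(max(stats::predict(sp, x = 0.95)$y, 1e-8), 1)
  }
  q <- rep(NA_real_, length(p))
  ord <- order(p[ok])
  p_s <- p[ok][ord]
  q_s <- pi0 * m * p_s / seq_len(m)
  q_s <- rev(cummin(rev(q_s)))
  q_s <- pmin(q_s, 1)
  tmp <- q[ok]
  tmp[ord] <- q_s
  q[ok] <- tmp
  attr(q, "pi0") <- pi0
  q
}

#' Genomic control inflation factor
#'
#' \eqn{\lambda} is the median of the \eqn{\chi^2_1} quantiles of the
#' p-values divided by the theoretical null median (0.4549); values near 1
#' indicate calibrated tests, values above 1 inflation.
#'
#' @param p numeric vector of p-values.
#' @return lambda.
#' @export
genomic_control <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 10) warning("fewer than 10 p-values; lambda is unstable")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Area under the ROC curve from p-values
#'
#' Rank-based (Mann-Whitney) AUC with ties averaged, scoring sites by
#' \code{-p} so smaller p-values rank as more positive.
#'
#' @param truth logical labels (\code{TRUE} = real effect).
#' @param p p-values.
#' @return AUC in [0, 1].
#' @export
auc_from_pvalues <- function(truth, p) {
  ok <- !is.na(p) & !is.na(truth)
  truth <- as.logical(truth[ok])
  score <- -p[ok]
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  rk <- rank(score, ties.method = "average")
  (sum(rk[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kolmogorov-Smirnov test of p-value uniformity
#'
#' @param p numeric p-values.
#' @return list with statistic \code{D} and p-value \code{p}.
#' @export
ks_uniform <- function(p) {
  p <- p[!is.na(p)]
  kt <- suppressWarnings(stats::ks.test(p, "punif"))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Call differentially methylated regions
#'
#' Greedy left-to-right chaining of per-site significance calls: starting
#' at a significant site, a candidate region extends while consecutive
#' analyzed CpGs are at most \code{max_gap} apart; it closes when a fourth
#' non-significant site would be included or the gap is exceeded.
#' Regions are emitted when they contain at least \code{min_sig}
#' significant sites, with bounds at the first and last significant CpG.
#'
#' @param chrom,pos per-site coordinates, sorted within chromosome.
#' @param significant logical per-site significance labels (e.g. the 10
#'   percent FDR set).
#' @param max_gap maximum inter-CpG distance in bp.
#' @param min_sig minimum number of significant sites per region.
#' @param max_nonsig maximum non-significant sites tolerated inside a
#'   region.
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{n_sig}, \code{n_nonsig}.
#' @export
call_dmrs <- function(chrom, pos, significant, max_gap = 1000,
                      min_sig = 3, max_nonsig = 3) {
  stopifnot(length(chrom) == length(pos),
            length(pos) == length(significant))
  out <- list()
  for (ch in unique(chrom)) {
    ii <- which(chrom == ch)
    if (is.unsorted(pos[ii])) stop("positions must be sorted within chromosome")
    ps <- pos[ii]; sig <- significant[ii]
    i <- 1L
    while (i <= length(ii)) {
      if (!sig[i]) { i <- i + 1L; next }
      j <- i
      nonsig <- 0L
      while (j < length(ii)) {
        if (ps[j + 1L] - ps[j] > max_gap) break
        add_nonsig <- nonsig + as.integer(!sig[j + 1L])
        if (add_nonsig > max_nonsig) break
        j <- j + 1L
        nonsig <- add_nonsig
      }
      while (j > i && !sig[j]) j <- j - 1L   # trim trailing non-significant
      n_sig <- sum(sig[i:j])
      if (n_sig >= min_sig) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = ps[i], end = ps[j], n_sig = n_sig,
          n_nonsig = sum(!sig[i:j]), stringsAsFactors = FALSE)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_sig = integer(),
                      n_nonsig = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summary report for one method's scan results
#'
#' Computes, from a scan result and simulation truth, the standard
#' evaluation summary: power and detections at a truth-based empirical
#' FDR, q-value detections, genomic control on the null sites, AUC, and
#' KS uniformity of the null p-values.
#'
#' @param results site association data.frame (needs column \code{p}).
#' @param truth truth data.frame with \code{is_true_positive}.
#' @param level FDR level.
#' @return one-row data.frame.
#' @export
evaluate_scan <- function(results, truth, level = 0.10) {
  p <- results$p
  tp <- truth$is_true_positive
  null_p <- p[!tp & !is.na(p)]
  pw <- if (any(tp)) truth_fdr_power(p, tp, level)
        else list(power = NA_real_, n_detected = NA_integer_)
  q <- storey_qvalues(p)
  ks <- ks_uniform(null_p)
  data.frame(
    power = pw$power,
    n_detected_fdr = pw$n_detected,
    n_detected_q = sum(q <= level, na.rm = TRUE),
    lambda_null = genomic_control(null_p),
    lambda_all = genomic_control(p),
    auc = if (any(tp) && any(!tp)) auc_from_pvalues(tp, p) else NA_real_,
    ks_D = ks$D, ks_p = ks$p,
    n_failed = sum(is.na(p)))
}
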