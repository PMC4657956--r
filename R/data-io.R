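# Core data containers and file I/O for site-by-sample methylation counts.

#' Construct a methylation count dataset
#'
#' Bundles the per-site methylated read counts \code{y} and total read
#' counts \code{r} (sites in rows, samples in columns) with site and sample
#' identifiers.  Entries that are \code{NA} in both matrices mark
#' (site, sample) pairs with no measurement; they are carried as missing,
#' never imputed here.
#'
#' @param y integer matrix of methylated read counts (sites x samples).
#' @param r integer matrix of total read counts, same shape as \code{y}.
#' @param site_ids character vector of unique site identifiers (defaults
#'   to rownames of \code{y}).
#' @param sample_ids character vector of sample identifiers.
#' @param chrom,pos optional per-site chromosome and 1-based position of
#'   the cytosine.
#' @return object of class \code{"methylation_dataset"}.
#' @export
methylation_dataset <- function(y, r, site_ids = rownames(y),
                                sample_ids = colnames(y),
                                chrom = NULL, pos = NULL) {
  y <- as.matrix(y)
  r <- as.matrix(r)
  if (!all(dim(y) == dim(r)))
    stop("y and r must have the same dimensions")
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(nrow(y)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(y)))
  site_ids <- as.character(site_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(site_ids))
    stop("duplicate site_ids: ",
         paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  if (length(site_ids) != nrow(y) || length(sample_ids) != ncol(y))
    stop("identifier lengths do not match matrix dimensions")
  miss_y <- is.na(y)
  miss_r <- is.na(r)
  if (!identical(miss_y, miss_r))
    stop("missingness masks of y and r differ")
  ok <- !miss_y
  if (any(y[ok] != round(y[ok])) || any(r[ok] != round(r[ok])))
    stop("counts must be integers")
  if (any(r[ok] < 0) || any(y[ok] < 0))
    stop("counts must be non-negative")
  bad <- which(ok & y > r, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "methylated count exceeds total count at site '%s', sample '%s' (%d > %d)",
      site_ids[bad[1, 1]], sample_ids[bad[1, 2]],
      y[bad[1, , drop = FALSE]], r[bad[1, , drop = FALSE]]))
  }
  storage.mode(y) <- "integer"
  storage.mode(r) <- "integer"
  dimnames(y) <- dimnames(r) <- list(site_ids, sample_ids)
  structure(list(y = y, r = r, site_ids = site_ids,
                 sample_ids = sample_ids,
                 chrom = chrom, pos = pos),
            class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  n_miss <- sum(is.na(x$y))
  cat(sprintf(
    "methylation_dataset: %d sites x %d samples (%d missing cells, %.1f%%)\n",
    nrow(x$y), ncol(x$y), n_miss, 100 * n_miss / length(x$y)))
  cat(sprintf("  median site coverage: %.1f reads\n",
              stats::median(rowMeans(x$r, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.methylation_dataset <- function(x) dim(x$y)

#' Subset a methylation dataset by sites and/or samples
#' @param x a \code{methylation_dataset}.
#' @param sites,samples index vectors (integer, logical, or names).
#' @param ... unused.
#' @export
subset.methylation_dataset <- function(x, sites = NULL, samples = NULL, ...) {
  if (is.null(sites)) sites <- seq_len(nrow(x$y))
  if (is.null(samples)) samples <- seq_len(ncol(x$y))
  if (is.character(sites)) sites <- match(sites, x$site_ids)
  if (is.character(samples)) samples <- match(samples, x$sample_ids)
  methylation_dataset(
    x$y[sites, samples, drop = FALSE], x$r[sites, samples, drop = FALSE],
    site_ids = x$site_ids[sites], sample_ids = x$sample_ids[samples],
    chrom = if (!is.null(x$chrom)) x$chrom[sites],
    pos = if (!is.null(x$pos)) x$pos[sites])
}

#' Read a methylation count table
#'
#' Two dialects are accepted.  Wide: one row per site with a site id column
#' (named \code{site} or \code{site_id}; optional \code{chrom} and
#' \code{pos} columns) and two paired columns per sample named
#' \code{<sample>.meth} and \code{<sample>.total}.  Long: columns
#' \code{site}, \code{sample}, \code{meth}, \code{total}.  \code{NA} cells
#' denote missing (unmeasured) entries.
#'
#' @param path TSV file path.
#' @return a [methylation_dataset()].
#' @export
read_count_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  nms <- names(tab)
  long <- all(c("site", "sample", "meth", "total") %in% nms)
  if (long) {
    sites <- unique(tab$site)
    samples <- unique(tab$sample)
    y <- r <- matrix(NA_real_, length(sites), length(samples),
                     dimnames = list(sites, samples))
    ij <- cbind(match(tab$site, sites), match(tab$sample, samples))
    y[ij] <- tab$meth
    r[ij] <- tab$total
    return(methylation_dataset(y, r, sites, samples))
  }
  idcol <- intersect(c("site", "site_id"), nms)[1]
  if (is.na(idcol)) stop("no site id column ('site' or 'site_id') found")
  meth_cols <- grep("\\.meth$", nms, value = TRUE)
  tot_cols <- grep("\\.total$", nms, value = TRUE)
  samples <- sub("\\.meth$", "", meth_cols)
  if (!setequal(samples, sub("\\.total$", "", tot_cols)))
    stop("unpaired .meth/.total columns")
  tot_cols <- paste0(samples, ".total")
  meth_cols <- paste0(samples, ".meth")
  y <- as.matrix(tab[, meth_cols, drop = FALSE])
  r <- as.matrix(tab[, tot_cols, drop = FALSE])
  colnames(y) <- colnames(r) <- samples
  methylation_dataset(
    y, r, site_ids = as.character(tab[[idcol]]), sample_ids = samples,
    chrom = if ("chrom" %in% nms) tab$chrom,
    pos = if ("pos" %in% nms) tab$pos)
}

#' Write a methylation dataset as a wide count table
#' @param dataset a [methylation_dataset()].
#' @param path output TSV path.
#' @export
write_count_table <- function(dataset, path) {
  out <- data.frame(site = dataset$site_ids, stringsAsFactors = FALSE)
  if (!is.null(dataset$chrom)) out$chrom <- dataset$chrom
  if (!is.null(dataset$pos)) out$pos <- dataset$pos
  for (s in dataset$sample_ids) {
    out[[paste0(s, ".meth")]] <- dataset$y[, s]
    out[[paste0(s, ".total")]] <- dataset$r[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standardize a relatedness (kinship) matrix
#'
#' Symmetrizes \code{K}, eigendecomposes it, clips small negative
#' eigenvalues at zero, and rescales so that \eqn{tr(K)/n = 1} exactly,
#' which makes the heritability parameter of the mixed models
#' interpretable on the 0-1 scale.  The eigendecomposition is cached on the
#' returned object so model fits can reuse it.
#'
#' @param K square numeric matrix.
#' @param sym_tol maximum tolerated relative asymmetry.
#' @return object of class \code{"relatedness_matrix"} with elements
#'   \code{K} (standardized matrix), \code{U} (eigenvectors), \code{d}
#'   (eigenvalues, clipped and rescaled), \code{n}.
#' @export
relatedness_matrix <- function(K, sym_tol = 1e-6) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  sc <- max(abs(K), 1e-12)
  if (max(abs(K - t(K))) > sym_tol * sc)
    stop("K is asymmetric beyond tolerance")
  K <- (K + t(K)) / 2
  eg <- eigen(K, symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-6 * max(abs(d), 1e-12))
    stop("K has substantially negative eigenvalues; not a valid relatedness matrix")
  clipped <- any(d < 0)
  d[d < 0] <- 0
  tr <- sum(d)
  if (tr <= 0) stop("K has zero trace")
  scale_f <- nrow(K) / tr
  d <- d * scale_f
  if (!clipped && abs(scale_f - 1) < 1e-12) {
    Kstd <- K                 # already standardized: keep entries exact
  } else {
    Kstd <- eg$vectors %*% (d * t(eg$vectors))
    dimnames(Kstd) <- dimnames(K)
  }
  structure(list(K = Kstd, U = eg$vectors, d = d, n = nrow(K)),
            class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat(sprintf("relatedness_matrix: n = %d, rank = %d, tr(K)/n = %g\n",
              x$n, sum(x$d > 1e-10), sum(x$d) / x$n))
  invisible(x)
}

#' Read a relatedness matrix from a delimited file
#'
#' @param path whitespace- or tab-delimited n x n numeric matrix, no header.
#' @param n expected dimension (optional check).
#' @return a [relatedness_matrix()].
#' @export
read_relatedness <- function(path, n = NULL) {
  K <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(K) != ncol(K)) stop("relatedness file is not square")
  if (!is.null(n) && nrow(K) != n)
    stop(sprintf("expected %d x %d relatedness matrix, got %d x %d",
                 n, n, nrow(K), ncol(K)))
  dimnames(K) <- NULL
  relatedness_matrix(K)
}

.result_cols <- c("site_id", "chrom", "pos", "n_used", "beta_hat", "se",
                  "wald", "p", "h2_hat", "sigma2_hat", "converged")

#' Write per-site association results to a TSV file
#'
#' Column order is fixed (\code{site_id, chrom, pos, n_used, beta_hat, se,
#' wald, p, h2_hat, sigma2_hat, converged}) and rows keep the input site
#' order, so output is deterministic.
#'
#' @param results a site association data.frame as produced by the
#'   \code{*_scan} functions.
#' @param path output TSV path.
#' @export
write_results <- function(results, path) {
  out <- as.data.frame(results)
  for (cc in .result_cols) if (is.null(out[[cc]])) out[[cc]] <- NA
  out <- out[, .result_cols]
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-site association results file written by [write_results()]
#' @param path TSV path.
#' @return data.frame with the standard result columns.
#' @export
read_results <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out$converged <- as.logical(out$converged)
  out
}
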