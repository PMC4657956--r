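# Relatedness from genotypes and principal components of genotype data.

.standardize_genotypes <- function(G, maf_min = 0.05) {
  G <- as.matrix(G)
  if (ncol(G) < 1) stop("genotype matrix needs at least one SNP")
  ok <- !is.na(G)
  if (any(!(G[ok] %in% 0:2)))
    stop("genotypes must be coded 0/1/2 (reference allele count)")
  f <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- which(maf > maf_min & !is.na(maf))
  if (length(keep) < 1) stop("no polymorphic SNPs left after MAF filter")
  G <- G[, keep, drop = FALSE]
  # mean-impute missing genotypes per SNP, then center and scale
  cm <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx)) G[idx] <- cm[idx[, 2]]
  X <- scale(G, center = TRUE, scale = TRUE)
  sds <- attr(X, "scaled:scale")
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) < 2) stop("fewer than two polymorphic SNPs after filtering")
  attr(X, "kept") <- keep[sds > 0]
  X
}

#' Relatedness matrix from a genotype matrix
#'
#' Computes \eqn{K = XX^T/p} from the column-standardized genotype matrix
#' \eqn{X} (entries 0/1/2 = reference allele count; SNPs below the minor
#' allele frequency threshold removed, missing genotypes mean-imputed per
#' SNP), then standardizes so that \eqn{tr(K)/n = 1}.
#'
#' @param G n x p genotype matrix, entries in \{0, 1, 2\} or \code{NA}.
#' @param maf_min minor allele frequency threshold; SNPs with MAF at or
#'   below it are dropped.
#' @return a [relatedness_matrix()].
#' @export
kinship_from_genotypes <- function(G, maf_min = 0.05) {
  X <- .standardize_genotypes(G, maf_min)
  K <- tcrossprod(X) / ncol(X)
  relatedness_matrix(K)
}

#' Principal components of a genotype matrix
#'
#' PCA of the standardized genotype matrix (same preprocessing as
#' [kinship_from_genotypes()]).  PC1 is the major axis of population
#' structure.  The sign of each component is fixed so that its largest
#' magnitude SNP loading is positive, making scores reproducible.
#'
#' @param G n x p genotype matrix.
#' @param k number of components.
#' @param maf_min minor allele frequency threshold.
#' @return list with \code{scores} (n x k), \code{var_frac} (variance
#'   fractions), \code{loadings} (p_kept x k).
#' @export
genotype_pca <- function(G, k = 2, maf_min = 0.05) {
  X <- .standardize_genotypes(G, maf_min)
  if (k > min(dim(X)))
    stop(sprintf("k = %d exceeds min(n, p) = %d", k, min(dim(X))))
  sv <- svd(X, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  loadings <- sweep(sv$v, 2, flip, `*`)
  list(scores = scores,
       var_frac = sv$d[seq_len(k)]^2 / sum(sv$d^2),
       loadings = loadings)
}

#' Read a genotype matrix from a TSV file
#'
#' @param path TSV with a header of SNP ids; rows are individuals unless
#'   \code{transposed = TRUE}, in which case rows are SNPs.
#' @param transposed set to \code{TRUE} if the file is SNPs x individuals.
#' @return numeric matrix of 0/1/2 genotypes (individuals x SNPs).
#' @export
read_genotypes <- function(path, transposed = FALSE) {
  G <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  if (transposed) G <- t(G)
  G
}
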