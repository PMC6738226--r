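#' Principal component analysis of SNP genotypes
#'
#' Ordination of strains from a haploid SNP matrix: missing calls are
#' mean-imputed per locus, the 0/1 allele matrix is column-centered (no
#' scaling: allele indicators share a common scale), and the sample covariance
#' is eigendecomposed. Scores are the projections of the strains onto the
#' principal axes; percent variance explained is each eigenvalue over the
#' total variance. Axis signs are fixed by making the largest-magnitude
#' loading of each axis positive, so outputs are reproducible.
#'
#' @param matrix A [genotype_matrix()] with biallelic 0/1 calls.
#' @param n_axes Number of axes to return (clipped with a warning when it
#'   exceeds `min(n_samples - 1, n_loci)`).
#' @return Object of class `snp_pca`: list with `scores` (samples x axes),
#'   `loadings` (loci x axes), `eigenvalues` (all axes), `percent_variance`
#'   (all axes), `n_axes`.
#' @export
snp_pca <- function(matrix, n_axes = 2L) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  x <- matrix$calls
  n <- nrow(x)
  if (n < 2L) stop("PCA needs at least two samples")
  if (ncol(x) == 0L) stop("PCA needs at least one locus")
  storage.mode(x) <- "double"
  ## mean imputation per locus
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2L]]
  }
  xc <- sweep(x, 2L, colMeans(x))
  max_axes <- min(n - 1L, ncol(x))
  if (n_axes > max_axes) {
    warning(sprintf("n_axes clipped from %d to %d", n_axes, max_axes))
    n_axes <- max_axes
  }
  ## eigendecompose the n x n sample covariance (loci can vastly outnumber
  ## samples)
  cv <- tcrossprod(xc) / (n - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  total <- sum(ev)
  pct <- if (total > 0) 100 * ev / total else rep(0, length(ev))
  keep <- seq_len(n_axes)
  scores <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ev[keep] * (n - 1L)), n_axes, n_axes)
  ## axes with (numerically) zero variance carry no information: zero them
  ## so outputs are deterministic
  scores[, ev[keep] <= 1e-12 * max(total, 1)] <- 0
  ## loadings (locus-space axes); zero eigenvalues give zero loadings
  loadings <- matrix(0, ncol(x), n_axes)
  pos <- ev[keep] > 1e-12
  if (any(pos)) {
    loadings[, pos] <- crossprod(xc, scores[, pos, drop = FALSE]) %*%
      diag(1 / (ev[keep][pos] * (n - 1L)), sum(pos), sum(pos))
  }
  ## sign convention: largest-magnitude loading positive
  for (k in seq_len(n_axes)) {
    if (any(loadings[, k] != 0)) {
      s <- sign(loadings[which.max(abs(loadings[, k])), k])
      if (s < 0) {
        loadings[, k] <- -loadings[, k]
        scores[, k] <- -scores[, k]
      }
    }
  }
  rownames(scores) <- matrix$sample_ids
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  structure(list(scores = scores, loadings = loadings, eigenvalues = ev,
                 percent_variance = pct, n_axes = n_axes),
            class = "snp_pca")
}

#' @export
print.snp_pca <- function(x, ...) {
  cat(sprintf("SNP PCA: %d strains, %d axes returned\n", nrow(x$scores),
              x$n_axes))
  shown <- seq_len(min(4L, length(x$percent_variance)))
  cat("  % variance:", paste(sprintf("PC%d %.1f%%", shown,
                                     x$percent_variance[shown]),
                             collapse = ", "), "\n")
  invisible(x)
}
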