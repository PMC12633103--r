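#' Impute missing genotypes by iterative low-rank (PCA) completion
#'
#' Missing cells are initialized at the column (variant) mean, then the
#' matrix is alternately centered, approximated by its rank-`n_components`
#' truncated SVD, and the missing cells refilled from the reconstruction,
#' until the largest refill change drops below `tol` or `max_iter` is hit.
#' Observed cells are never altered; imputed dosages are clipped to
#' `[0, 2]` on output.
#'
#' @param genotypes numeric samples x variants matrix with `NA` for missing
#'   calls; every variant should already pass the missingness filter.
#' @param n_components rank of the truncated SVD (default 10)
#' @param tol convergence tolerance on the maximum absolute refill change
#'   (default 1e-4, dosage units)
#' @param max_iter iteration cap (default 200)
#' @return completed numeric matrix, same dimnames; attribute `iterations`
#'   records the number of refinement sweeps run.
#' @export
impute_genotypes_pca <- function(genotypes, n_components = 10, tol = 1e-4,
                                 max_iter = 200) {
  x <- as.matrix(genotypes)
  if (n_components >= min(dim(x))) {
    stop("n_components must be smaller than both matrix dimensions")
  }
  miss <- is.na(x)
  if (!any(miss)) {
    attr(x, "iterations") <- 0L
    return(x)
  }
  cm <- colMeans(x, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  filled <- x
  filled[miss] <- cm[col(x)[miss]]
  it <- 0L
  repeat {
    it <- it + 1L
    mu <- colMeans(filled)
    centered <- sweep(filled, 2, mu)
    sv <- svd(centered, nu = n_components, nv = n_components)
    d <- sv$d[seq_len(n_components)]
    recon <- sweep(sv$u %*% (d * t(sv$v)), 2, mu, `+`)
    delta <- max(abs(recon[miss] - filled[miss]))
    filled[miss] <- recon[miss]
    if (delta < tol || it >= max_iter) break
  }
  filled[miss] <- pmin(pmax(filled[miss], 0), 2)
  attr(filled, "iterations") <- it
  filled
}
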