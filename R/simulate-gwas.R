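#' Simulate GWAS summary statistics under an LD structure
#'
#' Draws joint association z-scores from a multivariate normal with mean
#' `R %*% lambda` and covariance `R`, where `R` is the variant correlation
#' (LD) matrix and `lambda` holds the non-centrality of causal variants
#' (zero elsewhere). Two-sided p-values come from the normal tail. This is
#' the standard summary-statistic model used to construct shared- versus
#' distinct-causal-variant colocalization test cases.
#'
#' @param R positive semi-definite correlation matrix (variants x variants)
#' @param lambda non-centrality vector (length = ncol(R)); entries are the
#'   expected z-score at causal variants
#' @param n GWAS sample size attached to every variant
#' @param maf per-variant MAF column; drawn `U(0.05, 0.5)` when `NULL`
#' @param chrom,pos variant coordinates (defaults: `chr1`, 10 kb spacing)
#' @param ids variant ids
#' @param seed integer seed
#' @return data.frame with `variant`, `chrom`, `pos`, `z`, `p`, `maf`, `n`
#' @export
simulate_gwas_summary <- function(R, lambda = rep(0, ncol(R)), n = 10000,
                                  maf = NULL, chrom = "chr1", pos = NULL,
                                  ids = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  p_var <- ncol(R)
  stopifnot(nrow(R) == p_var, length(lambda) == p_var)
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("R is not positive semi-definite")
  ch <- chol((R + t(R)) / 2 + diag(1e-10, p_var))
  z <- as.numeric(R %*% lambda) + as.numeric(t(ch) %*% stats::rnorm(p_var))
  pval <- 2 * stats::pnorm(-abs(z))
  if (is.null(maf)) maf <- stats::runif(p_var, 0.05, 0.5)
  if (is.null(pos)) pos <- seq_len(p_var) * 10000L
  if (is.null(ids)) ids <- sprintf("rs%05d", seq_len(p_var))
  data.frame(variant = ids, chrom = chrom, pos = pos, z = z, p = pval,
             maf = maf, n = n, stringsAsFactors = FALSE)
}
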