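#' Squared genotype correlation between two variants
#'
#' Squared Pearson correlation computed over pairwise-complete entries.
#' Symmetric in its arguments and invariant to affine recoding of either
#' dosage vector (so `g` and `2 - g` give identical r-squared).
#'
#' @param g1,g2 numeric dosage vectors of equal length (>= 3), `NA` = missing
#' @return r-squared in `[0, 1]`, or `NA` (with a warning) when either vector
#'   is constant over the jointly observed entries.
#' @export
genotype_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("vectors must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3) stop("need at least 3 jointly observed genotypes")
  a <- g1[ok]; b <- g2[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant genotype vector; r2 undefined")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Best-tagging SNV for a structural variant
#'
#' Finds the LD proxy: among SNVs whose position lies within `window_bp` of
#' the SV interval, the SNV with the highest squared genotype correlation to
#' the SV. Ties are broken by smallest distance to the SV interval, then by
#' lexicographic id.
#'
#' @param sv single-row variant record (or a `variant_callset` with one
#'   variant) for the SV
#' @param sv_genotypes dosage vector for the SV, aligned to `snv_callset`
#'   samples
#' @param snv_callset `variant_callset` of candidate SNVs
#' @param window_bp search window around the SV interval (default 100 kb)
#' @return data.frame with `snv_id`, `r2`, `distance`; zero rows (with a
#'   warning) when no SNV lies in the window.
#' @export
best_tag_snv <- function(sv, sv_genotypes, snv_callset, window_bp = 1e5) {
  if (inherits(sv, "variant_callset")) {
    if (n_variants(sv) != 1) stop("sv must contain exactly one variant")
    sv_genotypes <- as.numeric(sv$genotypes[, 1])
    sv <- sv$records
  }
  r <- snv_callset$records
  same_chrom <- r$chrom == sv$chrom
  dist <- pmax(0, pmax(sv$start - r$end, r$start - sv$end))
  in_window <- same_chrom & dist <= window_bp
  if (!any(in_window)) {
    warning("no SNV within window of SV ", sv$id)
    return(data.frame(snv_id = character(0), r2 = numeric(0),
                      distance = numeric(0)))
  }
  idx <- which(in_window)
  r2 <- vapply(idx, function(j) {
    suppressWarnings(genotype_r2(sv_genotypes, snv_callset$genotypes[, j]))
  }, numeric(1))
  cand <- data.frame(snv_id = r$id[idx], r2 = r2, distance = dist[idx])
  cand <- cand[!is.na(cand$r2), , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("all candidate SNVs constant; no tag for SV ", sv$id)
    return(data.frame(snv_id = character(0), r2 = numeric(0),
                      distance = numeric(0)))
  }
  ord <- order(-cand$r2, cand$distance, cand$snv_id)
  cand[ord[1], , drop = FALSE]
}

#' Maximum attainable r-squared between two biallelic variants
#'
#' With allele frequencies `p` and `q`, perfect coupling of the rarer allele
#' bounds the squared correlation at `(p (1-q)) / (q (1-p))` for `p <= q`
#' (allele-frequency mismatch caps LD). Used to reject infeasible simulated
#' LD targets.
#'
#' @param p,q allele frequencies in `(0, 1)`
#' @return upper bound on r-squared
#' @export
ld_r2_bound <- function(p, q) {
  lo <- pmin(p, q); hi <- pmax(p, q)
  (lo * (1 - hi)) / (hi * (1 - lo))
}
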