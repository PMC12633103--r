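#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults emulate a
#' population-scale long-read aging/neurodegeneration cohort: 551 diploid
#' genomes, a rare-shifted MAF spectrum (about 40% of SVs below 1% MAF), SV
#' lengths with mobile-element peaks near 300 bp (Alu), 2.5 kb (SVA) and
#' 6 kb (LINE-1), ages 55-90, balanced sex, and a case/control-style
#' diagnosis mix.
#'
#' @param n_samples number of diploid genomes (default 551)
#' @param n_svs,n_snvs numbers of structural variants and SNVs
#' @param maf_spectrum list describing the MAF distribution over
#'   `(maf_min, 0.5]`: either `list(dist = "beta", shape1, shape2, maf_min)`
#'   or `list(dist = "point", maf)` for a point mass.
#' @param ld_targets list of `list(sv =, snv =, r2 =, snv_maf = NULL)` pairs:
#'   the named SNV's genotypes are rebuilt as a perturbed copy of the SV's to
#'   hit the target r-squared (copy-then-perturb).
#' @param sv_type_probs named probabilities over `INS`/`DEL`/`DUP`/`INV`
#' @param sv_length_model list of mixture components
#'   `list(weight, meanlog, sdlog)` plus a background component; defaults
#'   place modes at ~300, ~2500 and ~6000 bp.
#' @param qtl_effects data.frame (`variant_id`, `feature_id`, `beta`) of
#'   planted cis effects on the standardized-genotype scale
#' @param rare_outlier_effects list passed to [plant_rare_outliers()]
#' @param n_genes,n_aptamers phenotype feature counts
#' @param n_hidden_factors hidden phenotype factors shared across features
#' @param factor_sd loading scale of hidden factors
#' @param covariate_effects named list `list(age =, sex =, dx =)` of betas on
#'   standardized covariates (dx: named vector per non-reference level)
#' @param noise_sd residual phenotype noise SD (default 1)
#' @param missing_rate genotype missingness injected uniformly at random
#'   (default 0.02)
#' @param chrom,region_bp synthetic chromosome name and length
#' @param seed integer seed; fully determines every generated object
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_samples = 551,
                       n_svs = 500,
                       n_snvs = 2000,
                       maf_spectrum = list(dist = "beta", shape1 = 0.22,
                                           shape2 = 1, maf_min = 0.001),
                       ld_targets = list(),
                       sv_type_probs = c(INS = 0.48, DEL = 0.42,
                                         DUP = 0.05, INV = 0.05),
                       sv_length_model = list(
                         alu = list(weight = 0.35, meanlog = log(300), sdlog = 0.1),
                         sva = list(weight = 0.08, meanlog = log(2500), sdlog = 0.15),
                         line1 = list(weight = 0.05, meanlog = log(6000), sdlog = 0.1),
                         background = list(weight = 0.52, meanlog = log(200), sdlog = 1.3)
                       ),
                       qtl_effects = NULL,
                       rare_outlier_effects = list(),
                       n_genes = 200,
                       n_aptamers = 200,
                       n_hidden_factors = 0,
                       factor_sd = 0.5,
                       covariate_effects = list(age = 0, sex = 0, dx = c(AD = 0, PD = 0, MCI = 0)),
                       noise_sd = 1,
                       missing_rate = 0.02,
                       chrom = "chr1",
                       region_bp = 1e8,
                       seed = 1L) {
  stopifnot(n_samples >= 2, n_svs >= 1, n_snvs >= 0,
            noise_sd >= 0, missing_rate >= 0, missing_rate < 1)
  if (maf_spectrum$dist == "point") {
    if (maf_spectrum$maf <= 0 || maf_spectrum$maf > 0.5) {
      stop("point-mass MAF must lie in (0, 0.5]")
    }
  } else if (maf_spectrum$dist == "beta") {
    if (maf_spectrum$maf_min <= 0 || maf_spectrum$maf_min >= 0.5) {
      stop("maf_min must lie in (0, 0.5)")
    }
  } else stop("unknown maf_spectrum dist: ", maf_spectrum$dist)
  for (t in ld_targets) {
    if (t$r2 < 0 || t$r2 > 1) stop("LD target r2 must lie in [0, 1]")
  }
  w <- vapply(sv_length_model, function(m) m$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("sv_length_model weights must sum to 1")
  if (!is.null(qtl_effects)) {
    stopifnot(all(c("variant_id", "feature_id", "beta") %in% names(qtl_effects)))
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples, "samples,", x$n_svs, "SVs,",
      x$n_snvs, "SNVs, seed", x$seed, "\n")
  invisible(x)
}

# Draw MAFs from the configured spectrum.
.draw_mafs <- function(spectrum, n) {
  if (spectrum$dist == "point") return(rep(spectrum$maf, n))
  spectrum$maf_min + (0.5 - spectrum$maf_min) * stats::rbeta(n, spectrum$shape1, spectrum$shape2)
}
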