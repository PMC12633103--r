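#' Simulate expression and protein phenotypes with known ground truth
#'
#' Generates a latent Gaussian phenotype per feature as the sum of planted
#' additive genotype effects (betas act on the standardized dosage),
#' covariate effects (standardized age, sex, diagnosis indicators), hidden
#' factors with Gaussian loadings, and residual noise. Expression features
#' are then mapped to counts through a per-gene log base mean plus the latent
#' value, exponentiated and Poisson-sampled; protein features stay on the
#' latent (log-abundance) scale.
#'
#' Feature anchors (TSS-style point coordinates) are placed near the middle
#' of the planted variant's interval for features that carry a planted
#' effect, and uniformly along the region otherwise, so cis-window machinery
#' finds the planted pairs.
#'
#' @param genotypes output of [simulate_genotypes()]
#' @param config a [sim_config()]
#' @return list with `expression` and `protein` (each an [omics_matrix()]),
#'   `covariates` (data.frame: sample, age, sex, dx), `latent` (the
#'   pre-count latent matrix for expression), and `truth` (planted effects,
#'   factor scores and loadings).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_samples
  if (n_samples(genotypes$svs) != n) {
    stop("genotype sample count does not match config n_samples")
  }
  sample_ids <- genotypes$svs$sample_ids

  covariates <- data.frame(
    sample = sample_ids,
    age = stats::runif(n, 55, 90),
    sex = stats::rbinom(n, 1, 0.5),
    dx = sample(c("CN", "MCI", "AD", "PD"), n, replace = TRUE,
                prob = c(0.45, 0.2, 0.25, 0.1)),
    stringsAsFactors = FALSE
  )

  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  apt_ids <- sprintf("apt%04d", seq_len(config$n_aptamers))

  all_geno <- cbind(genotypes$svs$genotypes, genotypes$snvs$genotypes)
  all_rec <- rbind(genotypes$svs$records[, c("id", "chrom", "start", "end")],
                   genotypes$snvs$records[, c("id", "chrom", "start", "end")])

  build_ome <- function(feature_ids) {
    k <- config$n_hidden_factors
    latent <- matrix(stats::rnorm(n * length(feature_ids), 0, config$noise_sd),
                     nrow = n, dimnames = list(sample_ids, feature_ids))
    # covariate effects on standardized covariates
    ce <- config$covariate_effects
    if (!is.null(ce$age) && ce$age != 0) {
      latent <- latent + ce$age * as.numeric(scale(covariates$age))
    }
    if (!is.null(ce$sex) && ce$sex != 0) {
      latent <- latent + ce$sex * (covariates$sex - mean(covariates$sex))
    }
    if (!is.null(ce$dx)) {
      for (lv in names(ce$dx)) {
        if (ce$dx[[lv]] != 0) {
          latent <- latent + ce$dx[[lv]] * (covariates$dx == lv)
        }
      }
    }
    factors <- loadings <- NULL
    if (k > 0) {
      factors <- matrix(stats::rnorm(n * k), nrow = n)
      loadings <- matrix(stats::rnorm(k * length(feature_ids), 0, config$factor_sd),
                         nrow = k)
      latent <- latent + factors %*% loadings
    }
    list(latent = latent, factors = factors, loadings = loadings)
  }

  expr <- build_ome(gene_ids)
  prot <- build_ome(apt_ids)

  # planted cis effects
  planted <- config$qtl_effects
  anchors_expr <- .feature_anchors(gene_ids, planted, all_rec, config)
  anchors_prot <- .feature_anchors(apt_ids, planted, all_rec, config)
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      v <- planted$variant_id[i]; f <- planted$feature_id[i]
      if (!v %in% colnames(all_geno)) stop("planted effect references unknown variant ", v)
      g <- all_geno[, v]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      gs <- if (stats::sd(g) > 0) as.numeric(scale(g)) else g * 0
      if (f %in% gene_ids) {
        expr$latent[, f] <- expr$latent[, f] + planted$beta[i] * gs
      } else if (f %in% apt_ids) {
        prot$latent[, f] <- prot$latent[, f] + planted$beta[i] * gs
      } else {
        stop("planted effect references unknown feature ", f)
      }
    }
  }

  base_log_mean <- stats::rnorm(config$n_genes, log(50), 0.7)
  counts <- matrix(
    stats::rpois(n * config$n_genes,
                 exp(rep(base_log_mean, each = n) + as.numeric(expr$latent))),
    nrow = n, dimnames = list(sample_ids, gene_ids))

  truth <- list(
    qtl_effects = planted,
    expr_factors = expr$factors, expr_loadings = expr$loadings,
    prot_factors = prot$factors, prot_loadings = prot$loadings,
    base_log_mean = base_log_mean
  )
  list(
    expression = omics_matrix(counts, anchors_expr, state = "raw_counts"),
    protein = omics_matrix(prot$latent, anchors_prot, state = "log_norm"),
    covariates = covariates,
    latent = expr$latent,
    truth = truth
  )
}

# Anchor planted features near their variant; others uniformly at random.
.feature_anchors <- function(feature_ids, planted, all_rec, config) {
  pos <- sample.int(config$region_bp, length(feature_ids))
  names(pos) <- feature_ids
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      f <- planted$feature_id[i]
      if (f %in% feature_ids) {
        j <- match(planted$variant_id[i], all_rec$id)
        if (!is.na(j)) {
          pos[f] <- floor((all_rec$start[j] + all_rec$end[j]) / 2) + 1000
        }
      }
    }
  }
  data.frame(feature_id = feature_ids, chrom = config$chrom,
             start = as.integer(pos), end = as.integer(pos),
             stringsAsFactors = FALSE)
}

#' Plant rare-SV outlier effects into a phenotype matrix
#'
#' Selects carriers of designated rare SVs and shifts their values on linked
#' features so that the expected exposure-to-outlier odds ratio over
#' (feature, sample) pairs equals a configured value. With baseline outlier
#' probability `p0 = 2 * pnorm(-z_threshold)` under unit-Gaussian noise and
#' a target odds ratio `OR`, the exposed outlier probability is
#' `p1 = OR * p0 / (1 - p0 + OR * p0)` and each exposed pair receives a
#' large z-shift with probability `(p1 - p0) / (1 - p0)`, leaving the rest
#' at the baseline rate.
#'
#' @param values samples x features matrix on a z-like scale (unit noise)
#' @param exposure logical samples x features matrix: TRUE where the sample
#'   carries a rare SV linked to the feature
#' @param odds_ratio target exposure-outlier odds ratio (default 5)
#' @param z_shift magnitude of the planted shift (default 6)
#' @param direction `"under"`, `"over"` or `"both"` (sign of the shift;
#'   `"both"` draws the sign at random per planted cell)
#' @param z_threshold outlier threshold the odds ratio is calibrated against
#'   (default 2)
#' @param seed integer seed
#' @return list with `values` (modified matrix) and `truth` (data.frame of
#'   planted cells: sample index, feature index, shift)
#' @export
plant_rare_outliers <- function(values, exposure, odds_ratio = 5,
                                z_shift = 6, direction = c("both", "under", "over"),
                                z_threshold = 2, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(identical(dim(values), dim(exposure)))
  set.seed(as.integer(seed))
  p0 <- 2 * stats::pnorm(-z_threshold)
  p1 <- odds_ratio * p0 / (1 - p0 + odds_ratio * p0)
  prob_shift <- (p1 - p0) / (1 - p0)
  exp_idx <- which(exposure)
  if (odds_ratio != 1 && length(exp_idx) == 0) {
    stop("requested odds ratio unreachable: no exposed (carrier, feature) pairs")
  }
  if (prob_shift < 0) {
    stop("requested odds ratio below the achievable range (protective planting not supported)")
  }
  shifted <- exp_idx[stats::runif(length(exp_idx)) < prob_shift]
  sgn <- switch(direction,
                under = rep(-1, length(shifted)),
                over = rep(1, length(shifted)),
                both = sample(c(-1, 1), length(shifted), replace = TRUE))
  values[shifted] <- values[shifted] + sgn * z_shift
  truth <- data.frame(
    sample = row(values)[shifted],
    feature = col(values)[shifted],
    shift = sgn * z_shift
  )
  list(values = values, truth = truth,
       p0 = p0, p1 = p1, prob_shift = prob_shift)
}

#' Exposure matrix: which samples carry a rare SV near each feature
#'
#' @param sv_callset a `variant_callset`
#' @param anchors feature anchor data.frame (`feature_id`, `chrom`, `start`,
#'   `end`)
#' @param af_max maximum AF for a variant to count as rare (default 0.01)
#' @param window_bp linking window between SV interval and feature anchor
#'   (default 100 kb)
#' @return logical samples x features matrix
#' @export
rare_sv_exposure <- function(sv_callset, anchors, af_max = 0.01,
                             window_bp = 1e5) {
  aft <- allele_frequencies(sv_callset)
  rare <- which(!aft$all_missing & aft$maf <= af_max & aft$ac > 0)
  expo <- matrix(FALSE, nrow = n_samples(sv_callset), ncol = nrow(anchors),
                 dimnames = list(sv_callset$sample_ids, anchors$feature_id))
  if (length(rare) == 0) return(expo)
  sv_gr <- callset_granges(subset_callset(sv_callset, variants = rare))
  anchor_gr <- GenomicRanges::GRanges(
    anchors$chrom, IRanges::IRanges(anchors$start, anchors$end))
  hits <- GenomicRanges::findOverlaps(sv_gr, anchor_gr, maxgap = window_bp)
  g <- sv_callset$genotypes[, rare, drop = FALSE]
  for (h in seq_along(hits)) {
    v <- S4Vectors::queryHits(hits)[h]
    f <- S4Vectors::subjectHits(hits)[h]
    carriers <- !is.na(g[, v]) & g[, v] >= 1
    expo[carriers, f] <- TRUE
  }
  expo
}
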