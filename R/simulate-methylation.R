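#' Simulate segment-structured CpG methylation
#'
#' CpGs are organized into non-overlapping genomic segments; all CpGs of a
#' segment share a latent per-sample methylation level (the segment's mean
#' beta plus per-sample variation), to which independent CpG-level noise is
#' added. Optional planted effects: an mQTL shifts the latent level by
#' genotype dosage, and planted outliers shift one sample's latent level in
#' one segment by at least a configured delta. All betas are clipped to
#' `[0, 1]`; the number of clipped cells is reported.
#'
#' @param n_samples number of samples
#' @param n_segments number of true segments
#' @param cpgs_per_segment CpGs per segment (recycled)
#' @param segment_sd per-sample latent variation of a segment's level
#'   (default 0.05)
#' @param cpg_noise_sd CpG-level noise around the latent level (default 0.03)
#' @param gap_within_bp,gap_between_bp CpG spacing within a segment and gap
#'   separating consecutive segments (defaults 100 and 5000 bp)
#' @param mqtl optional list `list(genotypes =, segment =, beta =)`: dosage
#'   vector, target segment index, per-allele latent shift
#' @param outliers optional data.frame (`sample`, `segment`, `delta`) of
#'   planted outlier shifts
#' @param chrom chromosome label
#' @param seed integer seed
#' @return list with `betas` (samples x CpGs), `positions` (chrom, pos,
#'   cpg_id), `truth` (segment membership, latent matrix, planted outliers)
#'   and `n_clipped`.
#' @export
simulate_methylation <- function(n_samples = 100, n_segments = 50,
                                 cpgs_per_segment = 8,
                                 segment_sd = 0.05, cpg_noise_sd = 0.03,
                                 gap_within_bp = 100, gap_between_bp = 5000,
                                 mqtl = NULL, outliers = NULL,
                                 chrom = "chr1", seed = 1L) {
  set.seed(as.integer(seed))
  sizes <- rep_len(cpgs_per_segment, n_segments)
  seg_of_cpg <- rep(seq_len(n_segments), sizes)
  n_cpgs <- length(seg_of_cpg)

  pos <- integer(n_cpgs)
  cur <- 10000L
  for (i in seq_len(n_cpgs)) {
    if (i > 1 && seg_of_cpg[i] != seg_of_cpg[i - 1]) {
      cur <- cur + gap_between_bp
    } else if (i > 1) {
      cur <- cur + gap_within_bp
    }
    pos[i] <- cur
  }

  seg_mean <- stats::runif(n_segments, 0.08, 0.92)
  latent <- matrix(stats::rnorm(n_samples * n_segments,
                                rep(seg_mean, each = n_samples), segment_sd),
                   nrow = n_samples)
  if (!is.null(mqtl)) {
    g <- mqtl$genotypes
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    latent[, mqtl$segment] <- latent[, mqtl$segment] + mqtl$beta * g
  }
  if (!is.null(outliers)) {
    for (i in seq_len(nrow(outliers))) {
      latent[outliers$sample[i], outliers$segment[i]] <-
        latent[outliers$sample[i], outliers$segment[i]] + outliers$delta[i]
    }
  }
  betas <- latent[, seg_of_cpg, drop = FALSE] +
    matrix(stats::rnorm(n_samples * n_cpgs, 0, cpg_noise_sd), nrow = n_samples)
  n_clipped <- sum(betas < 0 | betas > 1)
  betas <- pmin(pmax(betas, 0), 1)
  cpg_ids <- sprintf("cpg%05d", seq_len(n_cpgs))
  colnames(betas) <- cpg_ids
  rownames(betas) <- sprintf("S%04d", seq_len(n_samples))
  list(
    betas = betas,
    positions = data.frame(chrom = chrom, pos = pos, cpg_id = cpg_ids,
                           stringsAsFactors = FALSE),
    truth = list(segment = seg_of_cpg, latent = latent,
                 segment_mean = seg_mean, outliers = outliers),
    n_clipped = n_clipped
  )
}
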