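#' Fisher's exact enrichment of an outcome given an exposure
#'
#' Builds the 2x2 table (a = exposed & outcome, b = exposed only, c =
#' outcome only, d = neither) and reports the cross-product odds ratio
#' `(a d) / (b c)` with a Haldane correction (+0.5 on all cells) applied iff
#' any cell is zero, a 95% Woolf confidence interval
#' `exp(log OR +/- 1.96 sqrt(sum 1/cell))`, and the two-sided exact
#' hypergeometric p-value.
#'
#' @param exposure,outcome equal-length logical vectors over analysis units
#' @param stratum optional named list of stratum labels carried through
#' @return one-row data.frame: `a`, `b`, `c`, `d`, `or`, `ci_lo`, `ci_hi`,
#'   `p`, `haldane`, plus any stratum columns
#' @export
fisher_enrichment <- function(exposure, outcome, stratum = NULL) {
  stopifnot(length(exposure) == length(outcome), length(exposure) > 0)
  exposure <- as.logical(exposure); outcome <- as.logical(outcome)
  a <- sum(exposure & outcome)
  b <- sum(exposure & !outcome)
  cc <- sum(!exposure & outcome)
  d <- sum(!exposure & !outcome)
  haldane <- any(c(a, b, cc, d) == 0)
  cells <- c(a, b, cc, d) + if (haldane) 0.5 else 0
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se_log <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1.96, 1.96) * se_log)
  p <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2))$p.value
  out <- data.frame(a = a, b = b, c = cc, d = d, or = or,
                    ci_lo = ci[1], ci_hi = ci[2], p = p, haldane = haldane)
  if (!is.null(stratum)) out <- cbind(as.data.frame(stratum), out)
  out
}

#' Enrichment of molecular outliers near rare SVs
#'
#' The analysis unit is the (feature, sample) pair. A pair is exposed iff
#' the sample carries (dosage >= 1) a rare SV — AF below the stratum's
#' threshold, or a singleton (allele count 1) — whose interval lies within
#' `window_bp` of the feature anchor. A pair is an outcome iff it is an
#' outlier at the stratum's z threshold and direction. One Fisher test per
#' stratum combination.
#'
#' @param sv_callset a `variant_callset`
#' @param zmatrix samples x features outlier z matrix (shared sample set)
#' @param anchors feature anchor data.frame (`feature_id`, `chrom`,
#'   `start`, `end`) for the z-matrix features
#' @param window_bp SV-to-feature linking window (default 100 kb)
#' @param af_thresholds numeric AF ceilings; the special value `"singleton"`
#'   (allele count 1) may be included (default `c(0.01, "singleton")`)
#' @param directions subset of `c("both", "under", "over")`
#' @param z_thresholds outlier |z| thresholds (default 2)
#' @param ome label carried into the output
#' @return data.frame of [fisher_enrichment()] rows, one per stratum;
#'   strata without exposed pairs are skipped with a note column.
#' @export
rare_sv_outlier_enrichment <- function(sv_callset, zmatrix, anchors,
                                       window_bp = 1e5,
                                       af_thresholds = list(0.01, "singleton"),
                                       directions = c("both", "under", "over"),
                                       z_thresholds = 2,
                                       ome = "omics") {
  common <- intersect(rownames(zmatrix), sv_callset$sample_ids)
  if (length(common) == 0) stop("no shared samples between SVs and z matrix")
  z <- zmatrix[common, anchors$feature_id, drop = FALSE]
  cs <- subset_callset(sv_callset,
                       samples = match(common, sv_callset$sample_ids))
  aft <- allele_frequencies(cs)
  out <- list()
  for (af_t in af_thresholds) {
    if (identical(af_t, "singleton")) {
      expo <- .exposure_for(cs, anchors, which(aft$ac == 1), window_bp)
      af_label <- "singleton"
    } else {
      expo <- .exposure_for(cs, anchors,
                            which(!aft$all_missing & aft$maf < as.numeric(af_t) & aft$ac > 0),
                            window_bp)
      af_label <- as.character(af_t)
    }
    for (z_t in z_thresholds) {
      for (dir in directions) {
        outcome <- switch(dir,
                          both = abs(z) >= z_t,
                          under = z <= -z_t,
                          over = z >= z_t)
        if (!any(expo)) next
        out[[length(out) + 1L]] <- fisher_enrichment(
          as.vector(expo), as.vector(outcome),
          stratum = list(ome = ome, af_threshold = af_label,
                         direction = dir, z_threshold = z_t,
                         window_bp = window_bp))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(note = "no exposed pairs in any stratum"))
  }
  do.call(rbind, out)
}

.exposure_for <- function(cs, anchors, variant_idx, window_bp) {
  expo <- matrix(FALSE, nrow = n_samples(cs), ncol = nrow(anchors),
                 dimnames = list(cs$sample_ids, anchors$feature_id))
  if (length(variant_idx) == 0) return(expo)
  sub <- subset_callset(cs, variants = variant_idx)
  sv_gr <- callset_granges(sub)
  anchor_gr <- GenomicRanges::GRanges(
    anchors$chrom, IRanges::IRanges(anchors$start, anchors$end))
  hits <- GenomicRanges::findOverlaps(sv_gr, anchor_gr, maxgap = window_bp)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (h in seq_along(qh)) {
    gv <- sub$genotypes[, qh[h]]
    carriers <- !is.na(gv) & gv >= 1
    expo[carriers, sh[h]] <- TRUE
  }
  expo
}

#' Cross-omic outlier concordance
#'
#' For each pair of signed z thresholds, tests whether being an outlier in
#' the discovery ome predicts being an outlier in the comparison ome over
#' linked (feature, sample) pairs. A negative threshold `x` means
#' `z < x` (under-outliers); a positive threshold means `z > x`
#' (over-outliers).
#'
#' @param zA,zB samples x features z matrices for discovery and comparison
#'   omes (shared sample names)
#' @param feature_map data.frame (`feature_a`, `feature_b`) linking features
#' @param thresholds_a,thresholds_b signed z thresholds (defaults
#'   `c(-2, 2)`)
#' @param omes length-2 character labels
#' @return data.frame of Fisher results per threshold pair
#' @export
cross_omic_concordance <- function(zA, zB, feature_map,
                                   thresholds_a = c(-2, 2),
                                   thresholds_b = c(-2, 2),
                                   omes = c("omeA", "omeB")) {
  if (nrow(feature_map) == 0) stop("empty feature map")
  common <- intersect(rownames(zA), rownames(zB))
  if (length(common) == 0) stop("no shared samples")
  a <- zA[common, feature_map$feature_a, drop = FALSE]
  b <- zB[common, feature_map$feature_b, drop = FALSE]
  out <- list()
  for (ta in thresholds_a) {
    fa <- if (ta < 0) a < ta else a > ta
    for (tb in thresholds_b) {
      fb <- if (tb < 0) b < tb else b > tb
      out[[length(out) + 1L]] <- fisher_enrichment(
        as.vector(fa), as.vector(fb),
        stratum = list(discovery_ome = omes[1], comparison_ome = omes[2],
                       threshold_a = ta, threshold_b = tb))
    }
  }
  do.call(rbind, out)
}

#' Tiered prioritization of rare SV-gene pairs
#'
#' Triage cascade for candidate functional rare variants. Tier conditions
#' are cumulative filters applied to each rare SV-gene pair:
#' tier 1 = rare SV near the gene (every input pair); tier 2 = the gene is
#' a molecular outlier in the carrier (`|z| > 2`); tier 3 = tier 2 and the
#' gene is in the risk-gene list; tier 4 = tier 1 and posterior score
#' strictly above `posterior_min`; tier 5 = tier 4 and risk gene.
#'
#' @param pairs data.frame (`sv_id`, `feature_id`, `sample`) of rare SV-gene
#'   pairs (one row per carrier)
#' @param outlier_z named lookup of `|z|` per (feature, sample): a samples x
#'   features matrix
#' @param posterior_scores optional named numeric vector keyed by
#'   `paste(sv_id, feature_id)` with scores in `[0, 1]`
#' @param risk_genes character vector of risk-gene feature ids
#' @param posterior_min score cut-off, strict (default 0.6)
#' @param z_min outlier gate (default 2)
#' @return input data.frame with logical tier columns `tier1`..`tier5` plus
#'   per-sample tier counts in the `per_sample` attribute
#' @export
prioritize_rare_svs <- function(pairs, outlier_z, posterior_scores = NULL,
                                risk_genes = character(0),
                                posterior_min = 0.6, z_min = 2) {
  if (!is.null(posterior_scores) &&
      any(posterior_scores < 0 | posterior_scores > 1)) {
    stop("posterior scores must lie in [0, 1]")
  }
  zval <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$sample[i]; f <- pairs$feature_id[i]
    if (s %in% rownames(outlier_z) && f %in% colnames(outlier_z)) {
      zval[i] <- outlier_z[s, f]
    }
  }
  score <- rep(NA_real_, nrow(pairs))
  if (!is.null(posterior_scores)) {
    score <- unname(posterior_scores[paste(pairs$sv_id, pairs$feature_id)])
  }
  pairs$z <- zval
  pairs$score <- score
  pairs$tier1 <- TRUE
  pairs$tier2 <- !is.na(zval) & abs(zval) > z_min
  pairs$tier3 <- pairs$tier2 & pairs$feature_id %in% risk_genes
  pairs$tier4 <- !is.na(score) & score > posterior_min
  pairs$tier5 <- pairs$tier4 & pairs$feature_id %in% risk_genes
  per_sample <- do.call(rbind, lapply(split(pairs, pairs$sample), function(d) {
    data.frame(sample = d$sample[1],
               tier1 = sum(d$tier1), tier2 = sum(d$tier2),
               tier3 = sum(d$tier3), tier4 = sum(d$tier4),
               tier5 = sum(d$tier5))
  }))
  attr(pairs, "per_sample") <- per_sample
  pairs
}
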