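#' Define colocalization test loci from GWAS and QTL summary statistics
#'
#' Windows of `window_bp` are drawn around every variant surpassing the
#' GWAS threshold (`p < p_gwas`) or QTL threshold (`p < p_qtl`);
#' overlapping windows are merged; only merged loci containing BOTH a
#' qualifying GWAS variant and a qualifying QTL variant are retained.
#'
#' @param gwas,qtl summary data.frames with `variant`, `chrom`, `pos`, `p`
#' @param window_bp window half-width (default 100 kb)
#' @param p_gwas,p_qtl significance thresholds (defaults 1e-5 and 1e-4)
#' @return data.frame (`chrom`, `start`, `end`, `n_gwas_hits`,
#'   `n_qtl_hits`); zero rows when no locus qualifies
#' @export
define_loci <- function(gwas, qtl, window_bp = 1e5,
                        p_gwas = 1e-5, p_qtl = 1e-4) {
  g_hit <- gwas[gwas$p < p_gwas, , drop = FALSE]
  q_hit <- qtl[qtl$p < p_qtl, , drop = FALSE]
  if (nrow(g_hit) == 0 || nrow(q_hit) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_gwas_hits = integer(0),
                      n_qtl_hits = integer(0)))
  }
  all_hits <- rbind(
    data.frame(chrom = g_hit$chrom, pos = g_hit$pos, src = "gwas"),
    data.frame(chrom = q_hit$chrom, pos = q_hit$pos, src = "qtl"))
  gr <- GenomicRanges::GRanges(
    all_hits$chrom,
    IRanges::IRanges(pmax(1, all_hits$pos - window_bp),
                     all_hits$pos + window_bp))
  merged <- GenomicRanges::reduce(gr)
  pt <- GenomicRanges::GRanges(all_hits$chrom,
                               IRanges::IRanges(all_hits$pos, all_hits$pos))
  ov <- GenomicRanges::findOverlaps(pt, merged)
  locus_of <- rep(NA_integer_, length(pt))
  locus_of[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  res <- do.call(rbind, lapply(seq_along(merged), function(i) {
    src <- all_hits$src[which(locus_of == i)]
    data.frame(chrom = as.character(GenomicRanges::seqnames(merged)[i]),
               start = GenomicRanges::start(merged)[i],
               end = GenomicRanges::end(merged)[i],
               n_gwas_hits = sum(src == "gwas"),
               n_qtl_hits = sum(src == "qtl"),
               stringsAsFactors = FALSE)
  }))
  res[res$n_gwas_hits > 0 & res$n_qtl_hits > 0, , drop = FALSE]
}

#' Wakefield approximate Bayes factor from a p-value
#'
#' Recovers `|z|` from the two-sided p-value, approximates the effect-size
#' variance as `V = 1 / (2 N MAF (1 - MAF))` for a quantitative trait
#' (divided additionally by `s (1 - s)` for a case-control trait with case
#' fraction `s`), sets the shrinkage ratio `r = W / (W + V)` with prior
#' effect variance `W = prior_sd^2`, and returns
#' `log ABF = 0.5 log(1 - r) + 0.5 z^2 r`.
#'
#' @param p two-sided p-value(s); exact zeros are clipped to the smallest
#'   positive double and flagged with a warning
#' @param maf minor allele frequency in `(0, 0.5]`
#' @param n sample size
#' @param trait_type `"quant"` (default) or `"cc"`
#' @param case_fraction case fraction for `"cc"` traits
#' @param prior_sd prior effect SD; defaults 0.15 (quant) / 0.2 (cc)
#' @return log approximate Bayes factor (natural log), vectorized
#' @export
abf_from_pvalue <- function(p, maf, n, trait_type = c("quant", "cc"),
                            case_fraction = NULL, prior_sd = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(prior_sd)) prior_sd <- if (trait_type == "quant") 0.15 else 0.2
  if (any(p <= 0)) {
    warning(sum(p <= 0), " zero p-values clipped")
    p <- pmax(p, .Machine$double.xmin)
  }
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  v <- 1 / (2 * n * maf * (1 - maf))
  if (trait_type == "cc") {
    if (is.null(case_fraction)) stop("case_fraction required for cc traits")
    v <- v / (case_fraction * (1 - case_fraction))
  }
  r <- prior_sd^2 / (prior_sd^2 + v)
  0.5 * log(1 - r) + 0.5 * z^2 * r
}

#' Enumeration colocalization from two sets of summary statistics
#'
#' Computes posterior probabilities of the five colocalization hypotheses
#' for a locus shared between two traits: H0 no association, H1/H2
#' association in one trait only, H3 two distinct causal variants, H4 one
#' shared causal variant. Per-variant log ABFs enter sums over causal
#' configurations (log-sum-exp throughout): H1 and H2 sum single-trait
#' ABFs, H4 sums the product ABF at the same variant, H3 sums products
#' over distinct variant pairs.
#'
#' @param gwas,qtl summary data.frames sharing variants (matched by
#'   `chrom`+`pos`, with `variant` id fallback), columns `variant`,
#'   `chrom`, `pos`, `p`, `maf`, `n` (optional `trait_type`,
#'   `case_fraction`)
#' @param p1,p2,p12 prior probabilities that a variant is causal for trait
#'   1 only, trait 2 only, or both (defaults 1e-4, 1e-4, 1e-5)
#' @param prior_sd_gwas,prior_sd_qtl Wakefield prior SDs (defaults by
#'   trait type)
#' @param gwas_type,qtl_type trait types (default `"quant"`)
#' @param gwas_case_fraction case fraction when `gwas_type = "cc"`
#' @return object of class `coloc_result`: named `pp` vector
#'   (`PP.H0`..`PP.H4`), `n_variants`, `top_gwas`, `top_qtl`, `locus`
#' @export
coloc_abf <- function(gwas, qtl, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd_gwas = NULL, prior_sd_qtl = NULL,
                      gwas_type = "quant", qtl_type = "quant",
                      gwas_case_fraction = NULL) {
  key_g <- paste(gwas$chrom, gwas$pos)
  key_q <- paste(qtl$chrom, qtl$pos)
  if (anyDuplicated(key_g) || anyDuplicated(key_q)) {
    key_g <- gwas$variant; key_q <- qtl$variant
    if (anyDuplicated(key_g) || anyDuplicated(key_q)) {
      stop("duplicated variant keys")
    }
  }
  shared <- intersect(key_g, key_q)
  if (length(shared) < 2) stop("need at least 2 shared variants")
  g <- gwas[match(shared, key_g), , drop = FALSE]
  q <- qtl[match(shared, key_q), , drop = FALSE]
  l1 <- abf_from_pvalue(g$p, g$maf, g$n, gwas_type,
                        case_fraction = gwas_case_fraction,
                        prior_sd = prior_sd_gwas)
  l2 <- abf_from_pvalue(q$p, q$maf, q$n, qtl_type, prior_sd = prior_sd_qtl)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  lsum1 <- lse(l1)
  lsum2 <- lse(l2)
  lsum12 <- lse(l1 + l2)
  lh0 <- 0
  lh1 <- log(p1) + lsum1
  lh2 <- log(p2) + lsum2
  # sum over ordered distinct pairs = (sum_i e^{l1_i})(sum_j e^{l2_j}) - sum_i e^{l1_i + l2_i}
  tmp <- lsum1 + lsum2
  frac <- exp(lsum12 - tmp)
  lh3 <- if (frac >= 1) -Inf else log(p1) + log(p2) + tmp + log1p(-frac)
  lh4 <- log(p12) + lsum12
  lh <- c(lh0, lh1, lh2, lh3, lh4)
  pp <- exp(lh - lse(lh))
  names(pp) <- paste0("PP.H", 0:4)
  structure(list(
    pp = pp,
    n_variants = length(shared),
    top_gwas = g$variant[which.min(g$p)],
    top_qtl = q$variant[which.min(q$p)],
    locus = c(chrom = as.character(g$chrom[1]),
              start = min(g$pos), end = max(g$pos)),
    lbf_gwas = stats::setNames(l1, g$variant),
    lbf_qtl = stats::setNames(l2, q$variant)
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("coloc_result over", x$n_variants, "shared variants\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Filter and annotate colocalizations; derive risk genes
#'
#' Retains colocalizations with `PP.H4 > pp4_min` (strict), annotates each
#' with whether the QTL feature's fine-mapped credible set contains an SV
#' and whether the SV is the lead variant, and derives the risk-gene list
#' as the features whose maximum PP.H4 across contexts exceeds `pp4_min`.
#'
#' @param results data.frame with one row per tested (feature, context)
#'   pair: columns `feature_id`, `context`, `pp_h4`
#' @param credible_sets named list (by feature id) of credible-set lists
#'   from [credible_sets()]
#' @param pp4_min retention threshold, strict (default 0.5)
#' @return list with `colocalized` (annotated retained rows) and
#'   `risk_genes` (character vector)
#' @export
coloc_report <- function(results, credible_sets = list(), pp4_min = 0.5) {
  keep <- results[results$pp_h4 > pp4_min, , drop = FALSE]
  sv_in_cs <- logical(nrow(keep))
  sv_is_lead <- logical(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    f <- keep$feature_id[i]
    if (f %in% names(credible_sets)) {
      for (cs in credible_sets[[f]]) {
        if (!is.null(cs$class) && !is.na(cs$class)) {
          if (cs$class %in% c("SV-led", "contains-SV")) sv_in_cs[i] <- TRUE
          if (cs$class == "SV-led") sv_is_lead[i] <- TRUE
        }
      }
    }
  }
  keep$sv_in_credible_set <- sv_in_cs
  keep$sv_is_lead <- sv_is_lead
  max_pp4 <- tapply(results$pp_h4, results$feature_id, max)
  risk_genes <- names(max_pp4)[max_pp4 > pp4_min]
  list(colocalized = keep, risk_genes = risk_genes)
}
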