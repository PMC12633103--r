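#' Pair SVs between two call sets
#'
#' Simplified cross-technology merge: two records pair iff they share
#' chromosome and variant type, their start positions differ by at most
#' `pos_tol_bp` (boundary inclusive), and their reciprocal size ratio
#' `min(len)/max(len)` is at least `min_size_ratio`. Candidate pairs are
#' taken greedily by smallest start distance; each record pairs at most
#' once.
#'
#' @param a,b `variant_callset` objects on the same reference naming
#' @param pos_tol_bp start-position tolerance (default 500)
#' @param min_size_ratio reciprocal length ratio floor (default 0.7)
#' @return list (`merge_report`): `pairs` (data.frame id_a, id_b),
#'   `shared_count`, `unique_a`, `unique_b`, and per-vtype tallies.
#' @export
merge_callsets <- function(a, b, pos_tol_bp = 500, min_size_ratio = 0.7) {
  ra <- a$records; rb <- b$records
  cand <- list()
  for (vt in intersect(unique(ra$vtype), unique(rb$vtype))) {
    ia <- which(ra$vtype == vt); ib <- which(rb$vtype == vt)
    for (i in ia) {
      same <- ib[rb$chrom[ib] == ra$chrom[i]]
      if (length(same) == 0) next
      dd <- abs(rb$start[same] - ra$start[i])
      ok <- dd <= pos_tol_bp
      if (!any(ok)) next
      j <- same[ok]
      ratio <- pmin(ra$length[i], rb$length[j]) /
        pmax(ra$length[i], rb$length[j])
      keep <- ratio >= min_size_ratio
      if (any(keep)) {
        cand[[length(cand) + 1L]] <- data.frame(
          i = i, j = j[keep], d = dd[ok][keep])
      }
    }
  }
  pairs <- data.frame(id_a = character(0), id_b = character(0))
  if (length(cand) > 0) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$d, ra$id[cand$i], rb$id[cand$j]), , drop = FALSE]
    used_a <- logical(nrow(ra)); used_b <- logical(nrow(rb))
    sel <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (!used_a[cand$i[k]] && !used_b[cand$j[k]]) {
        sel[k] <- TRUE
        used_a[cand$i[k]] <- TRUE
        used_b[cand$j[k]] <- TRUE
      }
    }
    pairs <- data.frame(id_a = ra$id[cand$i[sel]], id_b = rb$id[cand$j[sel]],
                        stringsAsFactors = FALSE)
  }
  vt_a <- ra$vtype[match(pairs$id_a, ra$id)]
  by_type <- lapply(split(seq_len(nrow(pairs)), factor(vt_a, levels = unique(c(ra$vtype, rb$vtype)))), length)
  structure(list(
    pairs = pairs,
    shared_count = nrow(pairs),
    unique_a = nrow(ra) - nrow(pairs),
    unique_b = nrow(rb) - nrow(pairs),
    shared_by_type = unlist(by_type)
  ), class = "merge_report")
}

#' SV discovery saturation by cumulative genome count
#'
#' For each of `n_orders` random orderings of the cohort, accumulates the
#' number of distinct variants carried (dosage >= 1) by at least one
#' sampled genome, per allele-frequency stratum, and reports the mean
#' curve. The saturation point of a stratum is the smallest n after which
#' the mean marginal gain stays below `rate_threshold` new variants per
#' genome over a `lookahead`-genome window; strata that never meet the rule
#' report `NA`.
#'
#' @param callset a `variant_callset`
#' @param af_bins breakpoints over `(0, 0.5]` partitioning MAF strata
#'   (default `c(0, 0.01, 0.05, 0.5)`)
#' @param n_orders number of random sample orderings averaged (default 100)
#' @param rate_threshold marginal-gain threshold (default 0.5 variants per
#'   genome)
#' @param lookahead window over which the marginal gain is averaged
#'   (default 20 genomes)
#' @param seed integer seed
#' @return object of class `saturation_curve`: `curves` (long data.frame:
#'   stratum, n_genomes, mean_cumulative), `saturation_n` per stratum,
#'   `marginal_rate` per stratum at the cohort end, and `af` (per-variant
#'   MAF used for stratification).
#' @export
saturation_curve <- function(callset, af_bins = c(0, 0.01, 0.05, 0.5),
                             n_orders = 100, rate_threshold = 0.5,
                             lookahead = 20, seed = 1L) {
  if (n_orders < 1) stop("n_orders must be at least 1")
  set.seed(as.integer(seed))
  g <- callset$genotypes
  n <- nrow(g); p <- ncol(g)
  aft <- allele_frequencies(callset)
  stratum <- cut(aft$maf, af_bins, include.lowest = FALSE,
                 labels = FALSE)
  carrier <- !is.na(g) & g >= 1
  strata <- sort(unique(stratum[!is.na(stratum)]))
  acc <- matrix(0, nrow = n, ncol = length(strata))
  for (o in seq_len(n_orders)) {
    ord <- sample.int(n)
    # first index in the ordering at which each variant is seen
    first <- rep(NA_integer_, p)
    for (k in seq_len(n)) {
      newly <- which(is.na(first) & carrier[ord[k], ])
      if (length(newly)) first[newly] <- k
    }
    for (si in seq_along(strata)) {
      f <- first[!is.na(first) & !is.na(stratum) & stratum == strata[si]]
      cum <- cumsum(tabulate(f, nbins = n))
      acc[, si] <- acc[, si] + cum
    }
  }
  acc <- acc / n_orders
  labels <- paste0("(", af_bins[strata], ",", af_bins[strata + 1], "]")
  curves <- do.call(rbind, lapply(seq_along(strata), function(si) {
    data.frame(stratum = labels[si], n_genomes = seq_len(n),
               mean_cumulative = acc[, si], stringsAsFactors = FALSE)
  }))
  sat <- stats::setNames(rep(NA_real_, length(strata)), labels)
  rate <- stats::setNames(rep(NA_real_, length(strata)), labels)
  for (si in seq_along(strata)) {
    cum <- acc[, si]
    for (k in seq_len(n - 1)) {
      horizon <- min(n, k + lookahead)
      gain <- (cum[horizon] - cum[k]) / (horizon - k)
      if (gain < rate_threshold) { sat[si] <- k; break }
    }
    tail_start <- max(1, n - lookahead)
    rate[si] <- (cum[n] - cum[tail_start]) / (n - tail_start)
  }
  structure(list(curves = curves, saturation_n = sat, marginal_rate = rate,
                 af = aft$maf, af_bins = af_bins),
            class = "saturation_curve")
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat("saturation_curve over", max(x$curves$n_genomes), "genomes\n")
  print(data.frame(stratum = names(x$saturation_n),
                   saturation_n = unname(x$saturation_n),
                   marginal_rate = round(unname(x$marginal_rate), 2)))
  invisible(x)
}

#' Project the cohort size needed to saturate discovery above an AF
#'
#' Under a binomial detection model, a variant of allele frequency `f` is
#' detected in `n` diploid genomes with probability `1 - (1 - f)^(2 n)`.
#' Integrating over the empirical AF density of variants at or above
#' `target_af`, the function returns the smallest `n` at which the expected
#' undiscovered fraction drops below `undiscovered_max`.
#'
#' @param curve a [saturation_curve()] (its `af` slot supplies the
#'   empirical AF density), or a bare numeric vector of allele frequencies
#' @param target_af only variants with AF >= `target_af` count
#' @param undiscovered_max tolerated expected undiscovered fraction
#'   (default 0.01)
#' @param n_max search cap (default 1e6)
#' @return projected number of genomes (0 when no variant exceeds
#'   `target_af`)
#' @export
extrapolate_saturation <- function(curve, target_af,
                                   undiscovered_max = 0.01, n_max = 1e6) {
  af <- if (inherits(curve, "saturation_curve")) curve$af else as.numeric(curve)
  af <- af[!is.na(af) & af >= target_af]
  if (length(af) == 0) return(0)
  if (all(af <= 0) || all(af >= 1)) stop("degenerate AF density")
  undisc <- function(n) mean((1 - af)^(2 * n))
  lo <- 0; hi <- 1
  while (undisc(hi) >= undiscovered_max && hi < n_max) hi <- hi * 2
  if (undisc(hi) >= undiscovered_max) return(Inf)
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (undisc(mid) < undiscovered_max) hi <- mid else lo <- mid
  }
  hi
}

#' SV burden near anchor loci at distance thresholds
#'
#' Counts SVs whose interval lies within each distance `d` of each anchor
#' (gap-based: 0 for overlap, boundary inclusive). Counts are stratified by
#' MAF class (`rare` = MAF < `rare_af`, otherwise `common`) and, when a
#' `lrgs_specific` logical vector is supplied, by platform specificity.
#'
#' @param callset a `variant_callset`
#' @param anchors data.frame (`anchor_id`, `chrom`, `start`, `end`); point
#'   anchors use `start == end`
#' @param distances numeric vector of distance thresholds in bp
#' @param rare_af rare-variant MAF boundary (default 0.01)
#' @param lrgs_specific optional logical per variant
#' @return long data.frame: anchor_id, distance, maf_class, lrgs_class,
#'   count
#' @export
locus_burden <- function(callset, anchors, distances = c(1e4, 1e5),
                         rare_af = 0.01, lrgs_specific = NULL) {
  aft <- allele_frequencies(callset)
  maf_class <- ifelse(!is.na(aft$maf) & aft$maf < rare_af, "rare", "common")
  lr <- if (is.null(lrgs_specific)) rep("all", n_variants(callset))
        else ifelse(lrgs_specific, "lrgs_specific", "shared")
  sv_gr <- callset_granges(callset)
  anchor_gr <- GenomicRanges::GRanges(
    anchors$chrom, IRanges::IRanges(anchors$start, anchors$end))
  out <- list()
  for (d in distances) {
    hits <- GenomicRanges::findOverlaps(anchor_gr, sv_gr, maxgap = d)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    full <- expand.grid(anchor_id = anchors$anchor_id,
                        maf_class = unique(maf_class),
                        lrgs_class = unique(lr),
                        stringsAsFactors = FALSE)
    if (length(qh) > 0) {
      key <- data.frame(anchor_id = anchors$anchor_id[qh],
                        maf_class = maf_class[sh], lrgs_class = lr[sh])
      tab <- stats::aggregate(list(count = rep(1L, nrow(key))), key, sum)
      tab <- merge(full, tab, all.x = TRUE)
      tab$count[is.na(tab$count)] <- 0L
    } else {
      tab <- full
      tab$count <- 0L
    }
    tab$distance <- d
    out[[length(out) + 1L]] <- tab
  }
  res <- do.call(rbind, out)
  res[order(res$distance, res$anchor_id), c("anchor_id", "distance",
                                            "maf_class", "lrgs_class", "count")]
}
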