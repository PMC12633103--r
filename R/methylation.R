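#' Segment CpGs into correlated clusters
#'
#' Greedy left-to-right segmentation within each chromosome: the next CpG
#' joins the open segment iff its Pearson correlation (across samples) with
#' the segment's running mean profile is at least `r_min` (boundary
#' inclusive) AND its genomic gap to the previous CpG is at most
#' `max_gap_bp`; otherwise a new segment opens. Singleton segments are
#' allowed. Deterministic and invariant to sample order.
#'
#' @param betas samples x CpGs beta matrix in `[0, 1]`
#' @param positions data.frame (`chrom`, `pos`) per CpG, sorted by position
#'   within chromosome
#' @param r_min correlation threshold for joining (default 0.5)
#' @param max_gap_bp maximum gap to the previous CpG (default 1000)
#' @return data.frame with one row per segment: `segment_id`, `chrom`,
#'   `start`, `end`, `n_cpgs`; attribute `cpg_segment` gives each CpG's
#'   segment index.
#' @export
segment_cpgs <- function(betas, positions, r_min = 0.5, max_gap_bp = 1000) {
  stopifnot(ncol(betas) == nrow(positions))
  assign_seg <- integer(ncol(betas))
  seg_id <- 0L
  for (chr in unique(positions$chrom)) {
    idx <- which(positions$chrom == chr)
    if (is.unsorted(positions$pos[idx])) {
      stop("CpG positions must be sorted within chromosome ", chr)
    }
    profile <- NULL
    members <- 0L
    for (i in idx) {
      join <- FALSE
      if (!is.null(profile)) {
        gap <- positions$pos[i] - prev_pos
        if (gap <= max_gap_bp) {
          r <- suppressWarnings(stats::cor(betas[, i], profile))
          join <- !is.na(r) && r >= r_min
        }
      }
      if (join) {
        profile <- (profile * members + betas[, i]) / (members + 1L)
        members <- members + 1L
      } else {
        seg_id <- seg_id + 1L
        profile <- betas[, i]
        members <- 1L
      }
      assign_seg[i] <- seg_id
      prev_pos <- positions$pos[i]
    }
  }
  segs <- do.call(rbind, lapply(seq_len(seg_id), function(s) {
    ix <- which(assign_seg == s)
    data.frame(segment_id = sprintf("seg%05d", s),
               chrom = positions$chrom[ix[1]],
               start = min(positions$pos[ix]),
               end = max(positions$pos[ix]),
               n_cpgs = length(ix), stringsAsFactors = FALSE)
  }))
  attr(segs, "cpg_segment") <- assign_seg
  segs
}

#' Aggregate CpG betas to segment-level betas
#'
#' Per sample and segment, the mean beta over member CpGs with non-missing
#' values. Cells where every member CpG is missing stay `NA` and are
#' counted in the `n_all_missing` attribute.
#'
#' @param betas samples x CpGs beta matrix
#' @param segments output of [segment_cpgs()] (its `cpg_segment` attribute
#'   defines membership)
#' @return samples x segments matrix of mean betas
#' @export
segment_betas <- function(betas, segments) {
  assign_seg <- attr(segments, "cpg_segment")
  stopifnot(!is.null(assign_seg), length(assign_seg) == ncol(betas))
  out <- vapply(seq_len(nrow(segments)), function(s) {
    rowMeans(betas[, assign_seg == s, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(betas)))
  out <- matrix(out, nrow = nrow(betas),
                dimnames = list(rownames(betas), segments$segment_id))
  out[is.nan(out)] <- NA_real_
  attr(out, "n_all_missing") <- sum(is.na(out))
  out
}

#' Symmetrized logit transform of methylation betas
#'
#' `t(beta) = logit(1 - |0.5 - beta|)`: hyper- and hypomethylation map to
#' the same value (`t(b) == t(1 - b)`), values near the extremes 0 and 1 map
#' close to zero, and betas near 0.5 map to large positive values. The
#' transform argument is clamped to at most `1 - eps` to avoid the
#' singularity at beta = 0.5.
#'
#' @param beta numeric vector/matrix in `[0, 1]`
#' @param eps clamp width (default 1e-3)
#' @return transformed values, `>= 0`
#' @export
beta_symmetry_transform <- function(beta, eps = 1e-3) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  arg <- pmin(1 - abs(0.5 - b), 1 - eps)
  stats::qlogis(arg)
}

#' Flag variable methylation segments
#'
#' Transforms segment betas with [beta_symmetry_transform()], computes each
#' segment's squared coefficient of variation of the transformed values
#' across samples, fits a loess trend of log CV^2 on log mean, and flags
#' segments whose standardized residual exceeds `sd_resid`.
#'
#' @param seg_betas samples x segments beta matrix
#' @param sd_resid flagging threshold in residual standard deviations
#'   (default 3)
#' @param span loess span (default 0.75)
#' @return logical vector per segment (`TRUE` = variable); attributes
#'   `cv2`, `resid_sd_units` expose the intermediates.
#' @export
variability_filter <- function(seg_betas, sd_resid = 3, span = 0.75) {
  if (ncol(seg_betas) < 50) stop("need at least 50 segments to fit the trend")
  t_mat <- beta_symmetry_transform(seg_betas)
  mu <- colMeans(t_mat, na.rm = TRUE)
  v <- apply(t_mat, 2, stats::var, na.rm = TRUE)
  cv2 <- v / pmax(mu, 1e-8)^2
  ok <- is.finite(cv2) & cv2 > 0 & mu > 0
  if (sum(ok) < 50 || stats::sd(log(mu[ok])) == 0) {
    stop("degenerate mean-variability trend")
  }
  fit <- stats::loess(log(cv2[ok]) ~ log(mu[ok]), span = span, degree = 1)
  resid <- stats::residuals(fit)
  su <- resid / stats::sd(resid)
  flags <- rep(FALSE, ncol(seg_betas))
  flags[ok] <- su > sd_resid
  names(flags) <- colnames(seg_betas)
  attr(flags, "cv2") <- cv2
  std_units <- rep(NA_real_, ncol(seg_betas)); std_units[ok] <- su
  attr(flags, "resid_sd_units") <- std_units
  flags
}

#' Call methylation outliers on variable segments
#'
#' Per variable segment, z-scores come from centering/scaling the segment
#' betas and delta is the sample beta minus the cohort median beta. A
#' (sample, segment) cell is called iff `|z| >= z_min` AND
#' `|delta| >= delta_min`. Samples whose total call count exceeds the upper
#' Tukey fence (Q3 + 1.5 IQR) are then removed as global outliers and the
#' calls re-emitted without them.
#'
#' @param seg_betas samples x segments beta matrix
#' @param variable_flags logical per segment (from [variability_filter()]);
#'   only flagged segments are scored
#' @param z_min minimum absolute z (default 2.5)
#' @param delta_min minimum absolute delta (default 0.25)
#' @return list with `calls` (data.frame: sample, segment, z, delta,
#'   direction), `removed_samples`, and `all_calls` (before global-sample
#'   removal).
#' @export
methylation_outliers <- function(seg_betas, variable_flags,
                                 z_min = 2.5, delta_min = 0.25) {
  use <- which(variable_flags)
  v <- seg_betas[, use, drop = FALSE]
  z <- scale(v)
  z[, attr(z, "scaled:scale") == 0 | is.nan(attr(z, "scaled:scale"))] <- 0
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  delta <- sweep(v, 2, med)
  hit <- abs(z) >= z_min & abs(delta) >= delta_min & !is.na(z) & !is.na(delta)
  idx <- which(hit, arr.ind = TRUE)
  samples <- rownames(seg_betas)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(seg_betas)))
  calls <- data.frame(
    sample = samples[idx[, 1]],
    segment = colnames(v)[idx[, 2]],
    z = z[idx], delta = delta[idx],
    direction = ifelse(z[idx] < 0, "under", "over"),
    stringsAsFactors = FALSE
  )
  counts <- stats::setNames(rep(0L, length(samples)), samples)
  tab <- table(calls$sample)
  counts[names(tab)] <- as.integer(tab)
  removed <- character(0)
  if (length(samples) >= 8) {
    q <- stats::quantile(counts, c(0.25, 0.75), names = FALSE)
    fence <- q[2] + 1.5 * (q[2] - q[1])
    removed <- samples[counts > fence]
  }
  list(calls = calls[!calls$sample %in% removed, , drop = FALSE],
       removed_samples = removed,
       all_calls = calls)
}
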