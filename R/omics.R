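#' Construct an omics matrix
#'
#' Samples x features molecular phenotype matrix with genomic feature
#' anchors and a normalization-state tag. State moves only along
#' `raw_counts -> log_norm -> {rank_norm | zscore}`.
#'
#' @param values numeric samples x features matrix
#' @param anchors data.frame (`feature_id`, `chrom`, `start`, `end`), one
#'   row per feature; `NULL` allowed for anchorless use.
#' @param state one of `"raw_counts"`, `"log_norm"`, `"rank_norm"`,
#'   `"zscore"`
#' @return an object of class `omics_matrix`
#' @export
omics_matrix <- function(values, anchors = NULL,
                         state = c("raw_counts", "log_norm", "rank_norm", "zscore")) {
  state <- match.arg(state)
  stopifnot(is.matrix(values))
  if (!is.null(anchors)) {
    stopifnot(all(c("feature_id", "chrom", "start", "end") %in% names(anchors)))
    if (nrow(anchors) != ncol(values)) {
      stop("anchors rows must match feature columns")
    }
    if (is.null(colnames(values))) colnames(values) <- anchors$feature_id
  }
  if (state != "raw_counts" && anyNA(values)) {
    stop("normalized omics matrices must not contain NAs")
  }
  structure(list(values = values, anchors = anchors, state = state),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat("omics_matrix [", x$state, "]: ", nrow(x$values), " samples x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

.check_state <- function(x, allowed) {
  if (!x$state %in% allowed) {
    stop("omics matrix is in state '", x$state, "'; expected ",
         paste(allowed, collapse = " or "))
  }
}

#' Aggregate single-cell counts into pseudobulk profiles
#'
#' Sums gene read counts over each sample's barcodes. When a subject was
#' assayed at multiple time points, only the sample with the largest library
#' size (total aggregated counts) is retained per subject.
#'
#' @param cell_counts genes x barcodes count matrix
#' @param barcode_to_sample named character vector mapping barcode to sample
#' @param sample_to_subject optional named vector mapping sample to subject;
#'   when given, duplicate-subject samples are resolved by library size.
#' @param anchors optional feature anchors passed through
#' @return an [omics_matrix()] in `raw_counts` state (samples x genes);
#'   attribute `n_unmapped` counts barcodes without a sample assignment.
#' @export
pseudobulk_aggregate <- function(cell_counts, barcode_to_sample,
                                 sample_to_subject = NULL, anchors = NULL) {
  bc <- colnames(cell_counts)
  if (is.null(bc)) stop("cell_counts must have barcode column names")
  samp <- barcode_to_sample[bc]
  unmapped <- is.na(samp)
  n_unmapped <- sum(unmapped)
  if (n_unmapped > 0) {
    cell_counts <- cell_counts[, !unmapped, drop = FALSE]
    samp <- samp[!unmapped]
  }
  samples <- unique(samp)
  agg <- vapply(samples, function(s) {
    rowSums(cell_counts[, samp == s, drop = FALSE])
  }, numeric(nrow(cell_counts)))
  agg <- t(agg)  # samples x genes
  rownames(agg) <- samples
  if (!is.null(sample_to_subject)) {
    subject <- sample_to_subject[samples]
    libsize <- rowSums(agg)
    keep <- unlist(lapply(split(seq_along(samples), subject), function(ix) {
      ix[which.max(libsize[ix])]
    }), use.names = FALSE)
    agg <- agg[sort(keep), , drop = FALSE]
  }
  out <- omics_matrix(agg, anchors, state = "raw_counts")
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Library-size normalize and log-transform counts
#'
#' Log2 counts-per-million with a small prior count, via edgeR.
#'
#' @param x an `omics_matrix` in `raw_counts` state
#' @return an `omics_matrix` in `log_norm` state
#' @export
log_normalize <- function(x) {
  .check_state(x, "raw_counts")
  lcpm <- t(edgeR::cpm(t(x$values), log = TRUE, prior.count = 1))
  dimnames(lcpm) <- dimnames(x$values)
  omics_matrix(lcpm, x$anchors, state = "log_norm")
}

#' Feature filtering for expression and protein matrices
#'
#' Expression features are dropped only when they fail BOTH tests:
#' (a) a squared-coefficient-of-variation trend test — the residual of
#' log CV^2 above a loess trend on log mean exceeds zero (high-variance
#' genes pass), and (b) a minimum-expression rule (detected at
#' `>= min_count` in `>= min_frac` of samples). Protein features use the
#' minimum-expression rule only.
#'
#' @param x an `omics_matrix` (`raw_counts` for expression, `log_norm` for
#'   protein)
#' @param kind `"expression"` or `"protein"`
#' @param min_frac minimum detected-sample fraction (default 0.2)
#' @param min_count minimum count (expression) or minimum log intensity
#'   (protein) to call a feature detected in a sample (defaults 5 and 0)
#' @param cv2_resid_min minimum standardized log-CV^2 residual above the
#'   trend for the variance test to pass (default 0)
#' @return character vector of retained feature ids
#' @export
filter_features <- function(x, kind = c("expression", "protein"),
                            min_frac = 0.2, min_count = if (kind == "expression") 5 else 0,
                            cv2_resid_min = 0) {
  kind <- match.arg(kind)
  v <- x$values
  if (ncol(v) < 50 && kind == "expression") {
    stop("need at least 50 features to fit the CV^2 trend")
  }
  detected <- colMeans(v >= min_count) >= min_frac
  if (kind == "protein") {
    return(colnames(v)[detected])
  }
  mu <- colMeans(v)
  cv2 <- apply(v, 2, stats::var) / pmax(mu, 1e-8)^2
  usable <- mu > 0 & cv2 > 0
  if (sum(usable) < 50 || stats::sd(log(mu[usable])) == 0) {
    stop("degenerate mean-CV^2 trend: cannot fit")
  }
  lmu <- log(mu[usable]); lcv2 <- log(cv2[usable])
  fit <- stats::loess(lcv2 ~ lmu, span = 0.75, degree = 1)
  resid <- stats::residuals(fit)
  std_resid <- resid / stats::sd(resid)
  high_var <- rep(FALSE, ncol(v))
  high_var[usable] <- std_resid > cv2_resid_min
  keep <- detected | high_var
  colnames(v)[keep]
}

#' Rank-based inverse-normal transform
#'
#' Per feature, replaces values by `qnorm((rank - 0.5) / n)` with average
#' ranks for ties, yielding identical marginal distributions across
#' features.
#'
#' @param x an `omics_matrix` in `log_norm` state (or a bare matrix)
#' @return an `omics_matrix` in `rank_norm` state; constant features are
#'   zeroed and flagged in the `constant_features` attribute.
#' @export
rank_normalize <- function(x) {
  bare <- is.matrix(x)
  v <- if (bare) x else { .check_state(x, "log_norm"); x$values }
  n <- nrow(v)
  const <- apply(v, 2, function(col) stats::sd(col) == 0)
  out <- apply(v, 2, function(col) {
    stats::qnorm((rank(col, ties.method = "average") - 0.5) / n)
  })
  out[, const] <- 0
  dimnames(out) <- dimnames(v)
  res <- if (bare) out else omics_matrix(out, x$anchors, state = "rank_norm")
  attr(res, "constant_features") <- if (bare) colnames(v)[const] else colnames(v)[const]
  res
}

#' Covariate- and PC-residualized outlier z-scores
#'
#' Per feature, values are centered and scaled to z-scores; the top
#' principal components of that z matrix are computed by SVD; each feature
#' is then residualized by OLS against the top `n_pcs` PCs together with any
#' supplied covariates (age, sex), and the residuals are re-centered and
#' re-scaled. The result is the z matrix used for molecular-outlier calling.
#'
#' @param x an `omics_matrix` in `log_norm` state (or a bare matrix)
#' @param covariates optional data.frame aligned to samples; numeric columns
#'   (e.g. `age`, `sex`) enter the residualization design
#' @param n_pcs number of principal components to remove (default 0)
#' @return an `omics_matrix` in `zscore` state
#' @export
outlier_zscores <- function(x, covariates = NULL, n_pcs = 0) {
  bare <- is.matrix(x)
  v <- if (bare) x else { .check_state(x, c("log_norm")); x$values }
  n <- nrow(v)
  if (n_pcs >= n) stop("n_pcs must be smaller than the number of samples")
  z <- scale(v)
  z[, attr(z, "scaled:scale") == 0] <- 0
  design <- NULL
  if (n_pcs > 0) {
    sv <- svd(z, nu = n_pcs, nv = 0)
    design <- sv$u[, seq_len(n_pcs), drop = FALSE]
  }
  if (!is.null(covariates)) {
    num <- covariates[, vapply(covariates, is.numeric, logical(1)), drop = FALSE]
    if (ncol(num) > 0) design <- cbind(design, as.matrix(num))
  }
  if (!is.null(design)) {
    fit <- stats::lm.fit(cbind(1, design), z)
    z <- fit$residuals
  }
  z <- scale(z)
  z[, attr(z, "scaled:scale") == 0 | is.nan(attr(z, "scaled:scale"))] <- 0
  z <- z[, , drop = FALSE]
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  dimnames(z) <- dimnames(v)
  if (bare) z else omics_matrix(z, x$anchors, state = "zscore")
}

#' Remove samples with an excessive molecular-outlier burden
#'
#' Counts, per sample, the features with `|z| > abs_z` and removes samples
#' whose count exceeds the upper Tukey fence (Q3 + 1.5 IQR) of the
#' count distribution.
#'
#' @param z an `omics_matrix` in `zscore` state, or a bare z matrix
#' @param abs_z per-feature outlier threshold feeding the burden count
#'   (default 3)
#' @return list with `retained` (sample names kept), `removed`, `counts`
#'   (per-sample burden) and `fence`.
#' @export
remove_global_outlier_samples <- function(z, abs_z = 3) {
  v <- if (is.matrix(z)) z else { .check_state(z, "zscore"); z$values }
  samples <- rownames(v)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(v)))
  if (ncol(v) == 0) {
    return(list(retained = samples, removed = character(0),
                counts = stats::setNames(rep(0L, nrow(v)), samples), fence = Inf))
  }
  counts <- rowSums(abs(v) > abs_z)
  names(counts) <- samples
  if (nrow(v) < 8) {
    warning("fewer than 8 samples: Tukey fence unstable, skipping removal")
    return(list(retained = samples, removed = character(0),
                counts = counts, fence = Inf))
  }
  q <- stats::quantile(counts, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  removed <- samples[counts > fence]
  list(retained = setdiff(samples, removed), removed = removed,
       counts = counts, fence = fence)
}

#' Call molecular outliers from a z matrix
#'
#' One call per (sample, feature) cell with `|z| >= abs_z`; direction is the
#' sign of z (`under` for negative, `over` for positive).
#'
#' @param z an `omics_matrix` in `zscore` state, or a bare z matrix
#' @param abs_z calling threshold (default 2)
#' @param ome label attached to each call (default `"omics"`)
#' @return data.frame with `sample`, `feature`, `z`, `direction`, `ome`
#' @export
call_outliers <- function(z, abs_z = 2, ome = "omics") {
  v <- if (is.matrix(z)) z else { .check_state(z, "zscore"); z$values }
  idx <- which(abs(v) >= abs_z, arr.ind = TRUE)
  samples <- rownames(v); features <- colnames(v)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(v)))
  if (is.null(features)) features <- paste0("F", seq_len(ncol(v)))
  data.frame(
    sample = samples[idx[, 1]],
    feature = features[idx[, 2]],
    z = v[idx],
    direction = ifelse(v[idx] < 0, "under", "over"),
    ome = ome,
    stringsAsFactors = FALSE
  )
}
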