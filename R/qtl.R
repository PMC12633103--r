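#' Enumerate cis feature-variant pairs
#'
#' A pair is included iff the SV's full interval intersects the window
#' `[anchor_start - window_bp, anchor_end + window_bp]` around the feature
#' anchor. This interval-aware rule keeps multi-base SVs whose breakpoint
#' lies outside the window but whose body reaches into it. The reported
#' distance is the gap between the SV interval and the anchor interval
#' (0 when they overlap).
#'
#' @param anchors feature anchor data.frame (`feature_id`, `chrom`,
#'   `start`, `end`); rows with missing coordinates are skipped and counted
#' @param sv_callset a `variant_callset`
#' @param window_bp cis-window half-width (default 1 Mb)
#' @return data.frame (`feature_id`, `variant_id`, `distance`); attribute
#'   `n_anchorless` counts skipped features.
#' @export
cis_pairs <- function(anchors, sv_callset, window_bp = 1e6) {
  anchorless <- is.na(anchors$start) | is.na(anchors$chrom)
  use <- anchors[!anchorless, , drop = FALSE]
  sv_gr <- callset_granges(sv_callset)
  anchor_gr <- GenomicRanges::GRanges(
    use$chrom, IRanges::IRanges(use$start, use$end))
  # window intersection (SV reaches [anchor - W, anchor + W]) corresponds to
  # an inter-range gap of at most W - 1 positions
  hits <- GenomicRanges::findOverlaps(anchor_gr, sv_gr, maxgap = window_bp - 1)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  dist <- rep(0, length(qh))
  if (length(qh) > 0) {
    a_start <- use$start[qh]; a_end <- use$end[qh]
    v_start <- sv_callset$records$start[sh]
    v_end <- sv_callset$records$end[sh]
    dist <- pmax(0, pmax(a_start - v_end, v_start - a_end))
  }
  out <- data.frame(feature_id = use$feature_id[qh],
                    variant_id = sv_callset$records$id[sh],
                    distance = dist, stringsAsFactors = FALSE)
  attr(out, "n_anchorless") <- sum(anchorless)
  out
}

#' Fit one cis-QTL linear model
#'
#' OLS of the (rank-normalized) phenotype on genotype dosage plus an
#' intercept and covariates; returns the genotype coefficient, its standard
#' error and the two-sided t-test p-value on `n - k - 1` residual degrees
#' of freedom.
#'
#' @param phenotype numeric response vector
#' @param genotype complete (imputed) dosage vector, non-constant
#' @param covariates optional numeric design matrix (samples x covariates)
#' @return named vector `c(beta, se, p, n_used)`
#' @export
fit_qtl <- function(phenotype, genotype, covariates = NULL) {
  ok <- !is.na(phenotype) & !is.na(genotype)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  y <- phenotype[ok]; g <- genotype[ok]
  if (stats::sd(g) == 0) stop("constant genotype")
  X <- cbind(intercept = 1, genotype = g,
             if (!is.null(covariates)) as.matrix(covariates)[ok, , drop = FALSE])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient design")
  fit <- stats::lm.fit(X, y)
  df <- length(y) - ncol(X)
  if (df <= 0) stop("not enough samples for the design")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  beta <- unname(fit$coefficients["genotype"])
  p <- 2 * stats::pt(-abs(beta / se), df)
  c(beta = beta, se = se, p = p, n_used = length(y))
}

# Build the numeric covariate design used by map_qtls: age, sex, one-hot
# diagnosis (first level = reference) and phenotype PCs.
.qtl_design <- function(covariates, pheno_values, n_pcs) {
  design <- NULL
  if (!is.null(covariates)) {
    cols <- list()
    if ("age" %in% names(covariates)) cols$age <- covariates$age
    if ("sex" %in% names(covariates)) cols$sex <- as.numeric(covariates$sex)
    if ("dx" %in% names(covariates)) {
      lv <- sort(unique(as.character(covariates$dx)))
      ref <- if ("CN" %in% lv) "CN" else lv[1]
      for (l in setdiff(lv, ref)) {
        cols[[paste0("dx_", l)]] <- as.numeric(covariates$dx == l)
      }
    }
    if (length(cols)) design <- do.call(cbind, cols)
  }
  if (n_pcs > 0) {
    z <- scale(pheno_values)
    z[, attr(z, "scaled:scale") == 0 | is.nan(attr(z, "scaled:scale"))] <- 0
    sv <- svd(z, nu = n_pcs, nv = 0)
    pcs <- sv$u[, seq_len(n_pcs), drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(n_pcs))
    design <- cbind(design, pcs)
  }
  design
}

#' Map cis SV-QTLs across an ome
#'
#' Fits every cis pair by OLS with covariates (age, sex, one-hot diagnosis)
#' and `n_pcs` phenotype principal components. Fitting uses the
#' Frisch-Waugh decomposition: phenotypes and genotypes are residualized
#' against the shared covariate design once, after which each pair reduces
#' to a simple regression with the full model's degrees of freedom — the
#' coefficient, SE and p equal the full OLS fit.
#'
#' Multiple testing is controlled per ome across all tested pairs:
#' Bonferroni (`p_adj = min(1, p * n_tests)`, the default) or
#' Benjamini-Hochberg (`correction = "bh"`).
#'
#' @param omics an [omics_matrix()] in `rank_norm` state
#' @param sv_callset a `variant_callset`; missing genotypes are imputed
#'   with [impute_genotypes_pca()]
#' @param covariates data.frame aligned to the omics samples (columns
#'   `age`, `sex`, `dx` used when present)
#' @param n_pcs phenotype PCs added to the design (default 0)
#' @param alpha adjusted-p threshold for the retained set (default 0.05)
#' @param correction `"bonferroni"` (default), `"bh"` or `"none"`
#' @param window_bp cis-window (default 1 Mb)
#' @param return_all return every tested pair rather than the retained set
#' @return data.frame with `feature_id`, `variant_id`, `vtype`, `maf`,
#'   `distance`, `beta`, `se`, `p`, `p_adj`, `n_used`, `significant`;
#'   attribute `n_tests` records the family size.
#' @export
map_qtls <- function(omics, sv_callset, covariates = NULL, n_pcs = 0,
                     alpha = 0.05, correction = c("bonferroni", "bh", "none"),
                     window_bp = 1e6, return_all = FALSE) {
  correction <- match.arg(correction)
  .check_state(omics, "rank_norm")
  pairs <- cis_pairs(omics$anchors, sv_callset, window_bp)
  if (nrow(pairs) == 0) stop("no cis pairs to test")
  g <- sv_callset$genotypes
  if (anyNA(g)) {
    g <- impute_genotypes_pca(g, n_components = min(10, min(dim(g)) - 1))
  }
  y <- omics$values
  design <- .qtl_design(covariates, y, n_pcs)
  n <- nrow(y)
  k <- if (is.null(design)) 0 else ncol(design)
  df <- n - k - 2  # intercept + genotype
  if (df <= 0) stop("not enough samples for the covariate design")
  X <- if (is.null(design)) matrix(1, n, 1) else cbind(1, design)
  # residualize both sides once (Frisch-Waugh)
  qr_x <- qr(X)
  y_res <- qr.resid(qr_x, y)
  g_res <- qr.resid(qr_x, g)
  fi <- match(pairs$feature_id, colnames(y))
  vi <- match(pairs$variant_id, colnames(g))
  gy <- colSums(g_res[, vi, drop = FALSE] * y_res[, fi, drop = FALSE])
  gg <- colSums(g_res[, vi, drop = FALSE]^2)
  yy <- colSums(y_res[, fi, drop = FALSE]^2)
  const <- gg < 1e-12
  beta <- gy / gg
  rss <- yy - beta^2 * gg
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / gg)
  p <- 2 * stats::pt(-abs(beta / se), df)
  beta[const] <- NA; se[const] <- NA; p[const] <- NA
  n_tests <- sum(!const)
  p_adj <- switch(correction,
                  bonferroni = pmin(1, p * n_tests),
                  bh = stats::p.adjust(p, method = "BH"),
                  none = p)
  aft <- allele_frequencies(sv_callset)
  res <- data.frame(
    feature_id = pairs$feature_id,
    variant_id = pairs$variant_id,
    vtype = sv_callset$records$vtype[vi],
    maf = aft$maf[vi],
    sv_length = sv_callset$records$length[vi],
    distance = pairs$distance,
    beta = beta, se = se, p = p, p_adj = p_adj,
    n_used = n,
    stringsAsFactors = FALSE
  )
  res <- res[!const, , drop = FALSE]
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  attr(res, "n_tests") <- n_tests
  attr(res, "n_skipped_constant") <- sum(const)
  if (return_all || (correction == "none" && alpha >= 1)) return(res)
  res[res$significant, , drop = FALSE]
}

#' Choose the phenotype-PC count that maximizes QTL yield
#'
#' Runs [map_qtls()] at each candidate PC count and returns the count with
#' the most significant associations; ties go to the smallest count.
#'
#' @param omics,sv_callset,covariates,alpha,correction,window_bp passed to
#'   [map_qtls()]
#' @param pc_grid integer vector of candidate PC counts
#' @return list with `best_n_pcs` and `yield` (data.frame n_pcs, n_signif)
#' @export
optimize_pcs <- function(omics, sv_callset, covariates = NULL,
                         pc_grid = c(0, 5, 10, 20), alpha = 0.05,
                         correction = "bonferroni", window_bp = 1e6) {
  if (length(pc_grid) == 0) stop("empty PC grid")
  yield <- vapply(pc_grid, function(k) {
    nrow(map_qtls(omics, sv_callset, covariates, n_pcs = k, alpha = alpha,
                  correction = correction, window_bp = window_bp))
  }, numeric(1))
  best <- pc_grid[order(-yield, pc_grid)][1]
  list(best_n_pcs = best,
       yield = data.frame(n_pcs = pc_grid, n_signif = yield))
}

#' Effect-size trends of significant QTLs
#'
#' Summaries of `|beta|` by MAF bin, SV-length bin and log10 distance, with
#' linear trend estimates (slope, SE, p) of `|beta|` on log10(distance + 1)
#' and on MAF. Optionally compares effect signs against an external effect
#' table stratified by LD (r-squared) bin.
#'
#' @param qtl_table output of [map_qtls()] (significant rows)
#' @param maf_bins,length_bins bin breakpoints
#' @param external optional data.frame (`feature_id`, `variant_id`, `beta`,
#'   `r2`) to compute sign-concordance per LD bin
#' @param r2_bins LD bin breakpoints for the concordance comparison
#' @return list with `by_maf`, `by_length`, `distance_trend`, `maf_trend`
#'   and (when `external` given) `ld_concordance`
#' @export
effect_trends <- function(qtl_table,
                          maf_bins = c(0.02, 0.05, 0.1, 0.2, 0.5),
                          length_bins = c(50, 300, 1000, 10000, Inf),
                          external = NULL,
                          r2_bins = c(0, 0.2, 0.5, 0.8, 1)) {
  if (nrow(qtl_table) == 0) stop("empty QTL table")
  ab <- abs(qtl_table$beta)
  maf_bin <- cut(qtl_table$maf, maf_bins, include.lowest = TRUE)
  len_bin <- cut(qtl_table$sv_length, length_bins, include.lowest = TRUE)
  by_maf <- stats::aggregate(list(mean_abs_beta = ab),
                             list(maf_bin = maf_bin), mean)
  by_length <- stats::aggregate(list(mean_abs_beta = ab),
                                list(length_bin = len_bin), mean)
  dist_fit <- stats::lm(ab ~ log10(qtl_table$distance + 1))
  maf_fit <- stats::lm(ab ~ qtl_table$maf)
  trend <- function(fit) {
    s <- summary(fit)$coefficients
    c(slope = s[2, 1], se = s[2, 2], p = s[2, 4])
  }
  out <- list(by_maf = by_maf, by_length = by_length,
              distance_trend = trend(dist_fit),
              maf_trend = trend(maf_fit))
  if (!is.null(external)) {
    m <- merge(qtl_table, external, by = c("feature_id", "variant_id"),
               suffixes = c("", "_ext"))
    if (nrow(m) > 0) {
      bin <- cut(m$r2, r2_bins, include.lowest = TRUE)
      sp <- split(m, bin)
      conc <- do.call(rbind, lapply(names(sp), function(lbl) {
        d <- sp[[lbl]]
        if (nrow(d) == 0) return(NULL)
        data.frame(r2_bin = lbl, n = nrow(d),
                   sign_concordance = mean(sign(d$beta) == sign(d$beta_ext)),
                   cor = if (nrow(d) > 2) stats::cor(d$beta, d$beta_ext) else NA_real_)
      }))
      out$ld_concordance <- conc
    }
  }
  out
}
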