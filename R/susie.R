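#' Sum-of-Single-Effects fine-mapping (IBSS)
#'
#' Fits the sum-of-single-effects regression model by iterative Bayesian
#' stepwise selection. The model expresses the phenotype as a sum of `L`
#' single-effect vectors, each placing posterior mass `alpha_l` over which
#' one variant carries that effect. Each sweep removes one effect from the
#' fitted values, performs a single-effect Bayesian regression on the
#' residual (per-variant Bayes factors under a normal effect prior), and
#' updates the effect's inclusion probabilities and posterior moments. The
#' per-effect prior variance is estimated by maximizing the single-effect
#' marginal likelihood (an estimate of zero switches the effect off), and
#' the residual variance by its closed-form ELBO maximizer. Iteration stops
#' when the evidence lower bound (ELBO) changes by less than `tol`.
#'
#' Per-variant posterior inclusion probabilities are
#' `PIP_v = 1 - prod_l (1 - alpha_lv)`.
#'
#' @param X numeric n x p genotype matrix; columns are centered and scaled
#'   internally (`standardize = TRUE`); zero-variance columns are dropped
#'   with the index mapping preserved
#' @param y numeric response; centered and scaled internally
#' @param L maximum number of effects (default 10)
#' @param prior_variance initial/fixed prior effect variance, as a fraction
#'   of `var(y)` (default 0.2)
#' @param estimate_prior_variance maximize the single-effect likelihood
#'   over the prior variance per effect (default TRUE)
#' @param max_iter,tol IBSS iteration cap and ELBO convergence tolerance
#' @param standardize center/scale X and y internally (default TRUE)
#' @return object of class `susie_fit`: `alpha` (L x p), `mu`, `mu2`
#'   (posterior moments of the effect given inclusion), `pip`, `V`
#'   (per-effect prior variances), `sigma2`, `elbo` (trace), `converged`,
#'   `variant_ids`, `dropped` (zero-variance column names).
#' @export
susie_fit <- function(X, y, L = 10, prior_variance = 0.2,
                      estimate_prior_variance = TRUE,
                      max_iter = 100, tol = 1e-3, standardize = TRUE) {
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("X and y must be finite")
  }
  n <- nrow(X)
  if (n < 10) stop("need at least 10 samples")
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  dropped <- ids[sds == 0]
  keep <- sds > 0
  X <- X[, keep, drop = FALSE]
  ids_kept <- ids[keep]
  p <- ncol(X)
  if (p == 0) stop("no non-constant variants")
  if (standardize) {
    X <- scale(X)
    y <- as.numeric(scale(y))
  } else {
    y <- as.numeric(y)
  }
  d <- colSums(X^2)
  vy <- stats::var(y)
  sigma2 <- vy
  V <- rep(prior_variance * vy, L)
  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p)
  mu2 <- matrix(0, L, p)
  lbf_model <- rep(0, L)
  kl <- rep(0, L)
  Xr <- as.numeric(X %*% colSums(alpha * mu))
  elbo <- numeric(0)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    for (l in seq_len(L)) {
      b_l <- alpha[l, ] * mu[l, ]
      Xr <- Xr - as.numeric(X %*% b_l)
      r_l <- y - Xr
      Xty <- as.numeric(crossprod(X, r_l))
      shat2 <- sigma2 / d
      z2 <- (Xty / d)^2 / shat2
      if (estimate_prior_variance) {
        V[l] <- .optimize_prior_variance(z2, shat2, V[l])
      }
      if (V[l] > 0) {
        lbf <- 0.5 * log(shat2 / (shat2 + V[l])) +
          0.5 * z2 * V[l] / (V[l] + shat2)
        m <- max(lbf)
        w <- exp(lbf - m)
        alpha[l, ] <- w / sum(w)
        post_var <- 1 / (1 / V[l] + d / sigma2)
        mu[l, ] <- post_var * Xty / sigma2
        mu2[l, ] <- post_var + mu[l, ]^2
        lbf_model[l] <- m + log(mean(w))
      } else {
        alpha[l, ] <- 1 / p
        mu[l, ] <- 0
        mu2[l, ] <- 0
        lbf_model[l] <- 0
      }
      b_l <- alpha[l, ] * mu[l, ]
      Xb_l <- as.numeric(X %*% b_l)
      Xr <- Xr + Xb_l
      # KL divergence of this effect, via the SER marginal-likelihood
      # identity, evaluated at its update residual
      kl[l] <- -lbf_model[l] +
        (2 * sum(r_l * Xb_l) - sum(alpha[l, ] * mu2[l, ] * d)) / (2 * sigma2)
    }
    resid <- y - Xr
    erss <- sum(resid^2) +
      sum(vapply(seq_len(L), function(l) {
        b_l <- alpha[l, ] * mu[l, ]
        sum(alpha[l, ] * mu2[l, ] * d) - sum((X %*% b_l)^2)
      }, numeric(1)))
    obj <- -n / 2 * log(2 * pi * sigma2) - erss / (2 * sigma2) - sum(kl)
    elbo <- c(elbo, obj)
    if (it > 1 && abs(elbo[it] - elbo[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    sigma2 <- erss / n
  }

  pip <- 1 - apply(1 - alpha, 2, prod)
  dimnames(alpha) <- dimnames(mu) <- dimnames(mu2) <-
    list(NULL, ids_kept)
  names(pip) <- ids_kept
  structure(list(alpha = alpha, mu = mu, mu2 = mu2, pip = pip, V = V,
                 sigma2 = sigma2, elbo = elbo, converged = converged,
                 n = n, variant_ids = ids_kept, dropped = dropped,
                 kept_idx = which(keep)),
            class = "susie_fit")
}

# Maximize the single-effect log marginal likelihood over the prior
# variance: loglik(V) = log mean_j BF_j(V) with
# log BF_j = 0.5 log(shat2/(shat2+V)) + 0.5 z2 V/(V+shat2).
# Returns 0 when no V beats the null (all-BF-one) model.
.optimize_prior_variance <- function(z2, shat2, v_init) {
  loglik <- function(lv) {
    v <- exp(lv)
    lbf <- 0.5 * log(shat2 / (shat2 + v)) + 0.5 * z2 * v / (v + shat2)
    m <- max(lbf)
    m + log(mean(exp(lbf - m)))
  }
  opt <- stats::optimize(loglik, interval = c(-30, 15), maximum = TRUE)
  if (opt$objective > loglik(-30) + 1e-10 && opt$objective > 0) {
    exp(opt$maximum)
  } else {
    0
  }
}

#' @export
print.susie_fit <- function(x, ...) {
  cat("susie_fit:", length(x$pip), "variants, L =", nrow(x$alpha),
      ", active effects:", sum(x$V > 0), "\n")
  cat("  ELBO:", utils::tail(x$elbo, 1), "(", length(x$elbo), "iterations,",
      if (x$converged) "converged" else "not converged", ")\n")
  invisible(x)
}

#' Extract credible sets from a fitted sum-of-single-effects model
#'
#' For each active effect, the credible set is the smallest variant set
#' whose cumulative inclusion probability reaches `coverage`. Sets whose
#' purity — the minimum absolute genotype correlation among members —
#' falls below `min_abs_corr` are discarded, as are duplicated sets. The
#' member with the highest PIP is the lead variant; when variant type
#' labels are supplied, each set is classified as `SV-led` (lead is an
#' SV), `contains-SV` (an SV is a member but the lead is an SNV) or
#' `SNV-only`.
#'
#' @param fit a [susie_fit()]
#' @param X the genotype matrix used for fitting (purity computation)
#' @param coverage credible-set mass (default 0.95)
#' @param min_abs_corr purity floor (default 0.25)
#' @param vtypes optional named character vector of variant types
#'   (`"SNV"` vs SV types) keyed by variant id
#' @return list of credible sets, each with `members`, `alpha`, `lead`,
#'   `purity`, `class`, `effect`
#' @export
credible_sets <- function(fit, X, coverage = 0.95, min_abs_corr = 0.25,
                          vtypes = NULL) {
  stopifnot(inherits(fit, "susie_fit"))
  if (is.null(colnames(X))) {
    if (ncol(X) != length(fit$variant_ids) + length(fit$dropped)) {
      stop("X has no column names and its width does not match the fit")
    }
    X <- X[, fit$kept_idx, drop = FALSE]
    colnames(X) <- fit$variant_ids
  } else {
    X <- X[, fit$variant_ids, drop = FALSE]
  }
  sets <- list()
  seen <- character(0)
  for (l in seq_len(nrow(fit$alpha))) {
    if (fit$V[l] <= 0) next
    a <- fit$alpha[l, ]
    ord <- order(a, decreasing = TRUE)
    csum <- cumsum(a[ord])
    size <- which(csum >= coverage)[1]
    if (is.na(size)) size <- length(a)
    members <- fit$variant_ids[ord[seq_len(size)]]
    key <- paste(sort(members), collapse = ",")
    if (key %in% seen) next
    purity <- 1
    if (length(members) > 1) {
      sub <- members
      if (length(sub) > 100) sub <- members[seq_len(100)]
      cm <- suppressWarnings(stats::cor(X[, sub, drop = FALSE]))
      purity <- min(abs(cm[upper.tri(cm)]), na.rm = TRUE)
    }
    if (is.na(purity) || purity < min_abs_corr) next
    seen <- c(seen, key)
    lead <- members[which.max(fit$pip[members])]
    cls <- NA_character_
    if (!is.null(vtypes)) {
      is_sv <- vtypes[members] != "SNV"
      cls <- if (is_sv[match(lead, members)]) "SV-led"
             else if (any(is_sv)) "contains-SV" else "SNV-only"
    }
    sets[[length(sets) + 1L]] <- list(
      members = members,
      alpha = unname(a[ord[seq_len(size)]]),
      lead = lead,
      purity = purity,
      class = cls,
      effect = l
    )
  }
  sets
}

#' Enrichment of SVs among high-PIP fine-mapped variants
#'
#' Pools PIPs over a list of fits and, at each threshold, tests with
#' Fisher's exact test whether SVs are over-represented among variants
#' with `PIP > t` relative to SNVs.
#'
#' @param fits list of [susie_fit()] objects
#' @param vtypes named character vector of variant types keyed by id
#' @param pip_thresholds thresholds in `(0, 1)` (default
#'   `c(0.2, 0.5, 0.8)`)
#' @return data.frame of [fisher_enrichment()] rows, one per threshold
#' @export
sv_pip_enrichment <- function(fits, vtypes,
                              pip_thresholds = c(0.2, 0.5, 0.8)) {
  if (length(fits) == 0) stop("need at least one fit")
  if (any(pip_thresholds <= 0 | pip_thresholds >= 1)) {
    stop("PIP thresholds must lie in (0, 1)")
  }
  pip <- unlist(lapply(fits, `[[`, "pip"))
  ids <- unlist(lapply(fits, `[[`, "variant_ids"))
  is_sv <- vtypes[ids] != "SNV"
  out <- list()
  for (t in pip_thresholds) {
    high <- pip > t
    if (!any(high)) next
    out[[length(out) + 1L]] <- fisher_enrichment(
      is_sv, high, stratum = list(pip_threshold = t))
  }
  if (length(out) == 0) {
    return(data.frame(note = "no variant above any threshold"))
  }
  do.call(rbind, out)
}

#' Summaries of credible sets by class
#'
#' Tabulates credible-set sizes per class and, when a QTL effect table is
#' supplied, the absolute QTL effect size of each set's lead variant by
#' lead class.
#'
#' @param cs_list list of credible-set lists (one per fitted feature),
#'   named by feature id
#' @param qtl_table optional [map_qtls()] output to attach `|beta|` of
#'   lead variants
#' @return data.frame with one row per credible set: feature, class, size,
#'   purity, lead, and `lead_abs_beta` when available
#' @export
credible_set_summary <- function(cs_list, qtl_table = NULL) {
  rows <- list()
  for (f in names(cs_list)) {
    for (cs in cs_list[[f]]) {
      ab <- NA_real_
      if (!is.null(qtl_table)) {
        hit <- qtl_table$feature_id == f & qtl_table$variant_id == cs$lead
        if (any(hit)) ab <- abs(qtl_table$beta[which(hit)[1]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = f, class = cs$class, size = length(cs$members),
        purity = cs$purity, lead = cs$lead, lead_abs_beta = ab,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, rows)
}
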