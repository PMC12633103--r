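#' Simulate SV and SNV genotype call sets
#'
#' Draws per-variant MAFs from the configured spectrum, genotypes each sample
#' as `Binomial(2, MAF)` (Hardy-Weinberg), assigns SV types and
#' mobile-element-peaked lengths, places variants uniformly along a synthetic
#' chromosome, and injects missing genotypes uniformly at random. LD between
#' designated SV/SNV pairs is induced by copy-then-perturb: the SNV's column
#' is a copy of the SV's in which a fraction `1 - sqrt(r2)` of samples is
#' resampled from the marginal genotype distribution, which makes the
#' expected correlation `sqrt(r2)` and the expected r-squared equal to the
#' target.
#'
#' A built-in self-check verifies on every run that realized MAFs track
#' their draws within binomial sampling error and that realized LD hits each
#' target within +/- 0.1 (for `n_samples >= 500`); violations raise a
#' warning and are recorded in the `self_check` attribute.
#'
#' @param config a [sim_config()]
#' @return list with elements `svs` and `snvs` (each a
#'   [variant_callset()]), `maf_draws` (the latent per-variant MAFs) and
#'   attribute `self_check`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  sv_maf <- .draw_mafs(config$maf_spectrum, config$n_svs)
  snv_maf <- .draw_mafs(config$maf_spectrum, config$n_snvs)

  sv_g <- matrix(stats::rbinom(n * config$n_svs, 2, rep(sv_maf, each = n)),
                 nrow = n)
  snv_g <- matrix(stats::rbinom(n * config$n_snvs, 2, rep(snv_maf, each = n)),
                  nrow = n)

  # SV attributes
  types <- sample(names(config$sv_type_probs), config$n_svs, replace = TRUE,
                  prob = config$sv_type_probs)
  comp <- sample(seq_along(config$sv_length_model), config$n_svs,
                 replace = TRUE,
                 prob = vapply(config$sv_length_model, `[[`, numeric(1), "weight"))
  lens <- vapply(seq_len(config$n_svs), function(i) {
    m <- config$sv_length_model[[comp[i]]]
    max(50, round(stats::rlnorm(1, m$meanlog, m$sdlog)))
  }, numeric(1))
  sv_start <- sort(sample.int(config$region_bp - max(lens) - 1, config$n_svs))
  sv_rec <- data.frame(
    id = sprintf("sv%04d", seq_len(config$n_svs)),
    chrom = config$chrom,
    start = sv_start,
    end = sv_start + lens,
    vtype = types,
    length = lens,
    stringsAsFactors = FALSE
  )
  snv_pos <- sort(sample.int(config$region_bp, config$n_snvs))
  snv_rec <- data.frame(
    id = sprintf("snv%05d", seq_len(config$n_snvs)),
    chrom = rep(config$chrom, config$n_snvs),
    start = snv_pos, end = snv_pos,
    vtype = rep("SNV", config$n_snvs), length = rep(1, config$n_snvs),
    stringsAsFactors = FALSE
  )

  # LD targets: rebuild the named SNV column as a perturbed copy of the SV's.
  for (t in config$ld_targets) {
    i_sv <- match(t$sv, sv_rec$id)
    i_snv <- match(t$snv, snv_rec$id)
    if (is.na(i_sv) || is.na(i_snv)) {
      stop("LD target names unknown variant: ", t$sv, " / ", t$snv)
    }
    maf_resample <- if (!is.null(t$snv_maf)) t$snv_maf else sv_maf[i_sv]
    bound <- ld_r2_bound(sv_maf[i_sv], maf_resample)
    if (!is.null(t$snv_maf) && t$r2 > bound + 1e-12) {
      stop(sprintf(
        "infeasible LD target: r2 = %.3f exceeds the bound %.3f implied by MAFs %.3f and %.3f",
        t$r2, bound, sv_maf[i_sv], maf_resample))
    }
    g <- sv_g[, i_sv]
    if (t$r2 < 1) {
      f <- 1 - sqrt(t$r2)
      flip <- stats::runif(n) < f
      g[flip] <- stats::rbinom(sum(flip), 2, maf_resample)
    }
    snv_g[, i_snv] <- g
    snv_maf[i_snv] <- maf_resample
  }

  if (config$missing_rate > 0) {
    sv_g[stats::runif(length(sv_g)) < config$missing_rate] <- NA_integer_
    snv_g[stats::runif(length(snv_g)) < config$missing_rate] <- NA_integer_
  }

  svs <- variant_callset(sv_rec, sv_g, sample_ids)
  snvs <- variant_callset(snv_rec, snv_g, sample_ids)

  check <- .genotype_self_check(svs, snvs, sv_maf, snv_maf,
                                config$ld_targets, n)
  out <- list(svs = svs, snvs = snvs,
              maf_draws = list(sv = sv_maf, snv = snv_maf))
  attr(out, "self_check") <- check
  out
}

.genotype_self_check <- function(svs, snvs, sv_maf, snv_maf, ld_targets, n) {
  aft <- allele_frequencies(svs)
  se <- sqrt(sv_maf * (1 - sv_maf) / (2 * n))
  maf_ok <- abs(aft$af - sv_maf) <= pmax(4 * se, 0.02)
  ld <- lapply(ld_targets, function(t) {
    r2 <- suppressWarnings(genotype_r2(
      svs$genotypes[, t$sv], snvs$genotypes[, t$snv]))
    list(sv = t$sv, snv = t$snv, target = t$r2, realized = r2,
         ok = n < 500 || is.na(r2) || abs(r2 - t$r2) <= 0.1)
  })
  frac_maf_ok <- mean(maf_ok)
  ld_ok <- all(vapply(ld, `[[`, logical(1), "ok"))
  if (frac_maf_ok < 0.99 || !ld_ok) {
    warning(sprintf(
      "generator self-check: %.1f%% of MAFs within tolerance; LD targets ok: %s",
      100 * frac_maf_ok, ld_ok))
  }
  list(maf_within_tolerance = frac_maf_ok, ld = ld)
}
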