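test_that("cis pair enumeration is interval-aware with strict window boundary", {
  anchors <- data.frame(feature_id = "g1", chrom = "chr1",
                        start = 5e6, end = 5e6)
  mk <- function(start, len) {
    variant_callset(make_records(1, start = start, length = len),
                    matrix(rbinom(30, 2, 0.4), 30, 1))
  }
  # 2 Mb SV whose right end reaches into the window
  big <- mk(start = 1e6, len = 2e6 + 1)      # ends at 3,000,001 < 4e6? no
  big2 <- mk(start = 2.5e6, len = 2e6)       # ends at 4.5e6, inside window
  expect_equal(nrow(cis_pairs(anchors, big)), 0)
  expect_equal(nrow(cis_pairs(anchors, big2)), 1)
  # gap of exactly 1 bp beyond the window -> excluded
  at_edge <- mk(start = 6e6, len = 100)      # window ends at 6e6
  expect_equal(nrow(cis_pairs(anchors, at_edge)), 1)
  past_edge <- mk(start = 6e6 + 1, len = 100)
  expect_equal(nrow(cis_pairs(anchors, past_edge)), 0)
  # point SV at the anchor: distance 0
  at_anchor <- mk(start = 5e6 - 10, len = 100)
  cp <- cis_pairs(anchors, at_anchor)
  expect_equal(cp$distance, 0)
  # anchorless features skipped and counted
  anchors2 <- rbind(anchors, data.frame(feature_id = "g2", chrom = NA,
                                        start = NA, end = NA))
  cp2 <- cis_pairs(anchors2, big2)
  expect_equal(attr(cp2, "n_anchorless"), 1)
})

test_that("fit_qtl is exact on noiseless data and calibrated under the null", {
  g <- rep(0:2, each = 20)
  y <- 0.5 * g
  fit <- fit_qtl(y, g)
  expect_equal(unname(fit["beta"]), 0.5, tolerance = 1e-12)
  expect_lt(unname(fit["p"]), 1e-200)
  expect_error(fit_qtl(y, rep(1, 60)), "constant genotype")
  # null calibration at alpha 0.05
  set.seed(11)
  reps <- 2000
  pv <- vapply(seq_len(reps), function(i) {
    unname(fit_qtl(rnorm(80), rbinom(80, 2, 0.3))["p"])
  }, numeric(1))
  rate <- mean(pv < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("fit_qtl recovers a planted effect on the standardized scale", {
  set.seed(12)
  ests <- replicate(200, {
    g <- rbinom(500, 2, 0.2)
    y <- 0.3 * scale(g) + rnorm(500)
    fit_qtl(as.numeric(y), as.numeric(scale(g)))[c("beta", "se")]
  })
  mean_beta <- mean(ests["beta", ])
  se_mean <- sd(ests["beta", ]) / sqrt(200)
  expect_lt(abs(mean_beta - 0.3), 2 * se_mean * 2)
})

test_that("map_qtls agrees with the single-pair fitter (Frisch-Waugh identity)", {
  cfg <- sim_config(n_samples = 120, n_svs = 30, n_snvs = 0,
                    maf_spectrum = list(dist = "point", maf = 0.3),
                    missing_rate = 0, n_genes = 10, n_aptamers = 5,
                    region_bp = 1e7, seed = 13)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(geno, cfg)
  rn <- rank_normalize(log_normalize(ph$expression))
  res <- map_qtls(rn, geno$svs, covariates = ph$covariates, n_pcs = 2,
                  alpha = 1, correction = "none", return_all = TRUE)
  design <- svomics:::.qtl_design(ph$covariates, rn$values, 2)
  expect_gt(nrow(res), 5)
  for (i in sample(nrow(res), 5)) {
    single <- fit_qtl(rn$values[, res$feature_id[i]],
                      geno$svs$genotypes[, res$variant_id[i]],
                      covariates = design)
    expect_equal(res$beta[i], unname(single["beta"]), tolerance = 1e-10)
    expect_equal(res$se[i], unname(single["se"]), tolerance = 1e-10)
    expect_equal(res$p[i], unname(single["p"]), tolerance = 1e-8)
  }
})

test_that("map_qtls finds a strong planted QTL with the right sign and Bonferroni math", {
  cfg <- sim_config(n_samples = 500, n_svs = 40, n_snvs = 0,
                    maf_spectrum = list(dist = "point", maf = 0.3),
                    missing_rate = 0, n_genes = 5, n_aptamers = 60,
                    qtl_effects = data.frame(variant_id = "sv0011",
                                             feature_id = "apt0020", beta = 1),
                    seed = 14)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(geno, cfg)
  rn <- rank_normalize(ph$protein$values)
  om <- omics_matrix(rn[, ], ph$protein$anchors, state = "rank_norm")
  res <- map_qtls(om, geno$svs, covariates = ph$covariates)
  hit <- res[res$feature_id == "apt0020" & res$variant_id == "sv0011", ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$beta, 0)
  # p_adj = min(1, p * n_tests)
  all_res <- map_qtls(om, geno$svs, covariates = ph$covariates,
                      alpha = 1, correction = "bonferroni", return_all = TRUE)
  nt <- attr(all_res, "n_tests")
  expect_equal(all_res$p_adj, pmin(1, all_res$p * nt))
})

test_that("genotype recoding 2-g flips beta sign and preserves p", {
  set.seed(15)
  y <- rnorm(100)
  g <- rbinom(100, 2, 0.4)
  a <- fit_qtl(y, g)
  b <- fit_qtl(y, 2 - g)
  expect_equal(unname(a["beta"]), -unname(b["beta"]))
  expect_equal(unname(a["p"]), unname(b["p"]))
})

test_that("PC optimization unmasks factor-hidden QTLs", {
  effects <- data.frame(variant_id = sprintf("sv%04d", 1:8),
                        feature_id = sprintf("apt%04d", seq(2, 30, by = 4)),
                        beta = 0.5)
  cfg <- sim_config(n_samples = 300, n_svs = 30, n_snvs = 0,
                    maf_spectrum = list(dist = "point", maf = 0.3),
                    missing_rate = 0, n_genes = 5, n_aptamers = 60,
                    n_hidden_factors = 5, factor_sd = 2,
                    qtl_effects = effects, seed = 16)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(geno, cfg)
  om <- omics_matrix(rank_normalize(ph$protein$values)[, ],
                     ph$protein$anchors, state = "rank_norm")
  opt <- optimize_pcs(om, geno$svs, covariates = ph$covariates,
                      pc_grid = c(0, 5, 10))
  expect_gte(opt$best_n_pcs, 5)
  y0 <- opt$yield$n_signif[opt$yield$n_pcs == 0]
  y5 <- opt$yield$n_signif[opt$yield$n_pcs == 5]
  expect_gt(y5, y0)
  # single-point grid returns that point
  expect_equal(optimize_pcs(om, geno$svs, pc_grid = 7)$best_n_pcs, 7)
  expect_error(optimize_pcs(om, geno$svs, pc_grid = integer(0)), "empty")
})

test_that("effect trends detect planted inverse-frequency effects", {
  set.seed(17)
  mafs <- runif(60, 0.02, 0.5)
  tbl <- data.frame(
    feature_id = sprintf("f%02d", 1:60),
    variant_id = sprintf("v%02d", 1:60),
    vtype = "DEL", maf = mafs, sv_length = 500,
    distance = runif(60, 0, 1e6),
    beta = (0.3 / sqrt(2 * mafs * (1 - mafs))) * sample(c(-1, 1), 60, TRUE),
    se = 0.05, p = 1e-8, p_adj = 1e-5, n_used = 500, significant = TRUE)
  tr <- effect_trends(tbl)
  expect_lt(tr$maf_trend["slope"], 0)
  expect_lt(tr$maf_trend["p"], 0.05)
  # identical external table: perfect concordance in every LD bin
  ext <- data.frame(feature_id = tbl$feature_id, variant_id = tbl$variant_id,
                    beta = tbl$beta, r2 = runif(60))
  tr2 <- effect_trends(tbl, external = ext)
  expect_true(all(tr2$ld_concordance$sign_concordance == 1))
  # independent external table: concordance near 0.5 overall
  ext2 <- ext; ext2$beta <- sample(c(-1, 1), 60, TRUE) * abs(ext$beta)
  tr3 <- effect_trends(tbl, external = ext2)
  overall <- sum(tr3$ld_concordance$sign_concordance * tr3$ld_concordance$n) /
    sum(tr3$ld_concordance$n)
  expect_lt(abs(overall - 0.5), 0.25)
  expect_error(effect_trends(tbl[0, ]), "empty")
})
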