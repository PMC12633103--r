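test_that("generator is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_samples = 60, n_svs = 40, n_snvs = 80, seed = 99)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$svs$genotypes, b$svs$genotypes)
  expect_identical(a$snvs$records, b$snvs$records)
  pa <- simulate_phenotypes(a, cfg)
  pb <- simulate_phenotypes(b, cfg)
  expect_identical(pa$expression$values, pb$expression$values)
  expect_identical(pa$covariates, pb$covariates)
})

test_that("point-mass MAF spectrum is realized within binomial sampling error", {
  cfg <- sim_config(n_samples = 800, n_svs = 200, n_snvs = 0,
                    maf_spectrum = list(dist = "point", maf = 0.25),
                    missing_rate = 0, seed = 21)
  geno <- simulate_genotypes(cfg)
  aft <- allele_frequencies(geno$svs)
  se <- sqrt(0.25 * 0.75 / (2 * 800 * 200))  # SE of the grand mean AF
  expect_lt(abs(mean(aft$af) - 0.25), 3 * se)
})

test_that("LD targets are hit: copy at r2=1, independence at r2=0, 0.8 within 0.1", {
  cfg <- sim_config(
    n_samples = 2000, n_svs = 10, n_snvs = 30,
    maf_spectrum = list(dist = "point", maf = 0.3), missing_rate = 0,
    ld_targets = list(
      list(sv = "sv0001", snv = "snv00001", r2 = 1),
      list(sv = "sv0002", snv = "snv00002", r2 = 0),
      list(sv = "sv0003", snv = "snv00003", r2 = 0.8)
    ),
    seed = 31)
  geno <- simulate_genotypes(cfg)
  expect_identical(geno$svs$genotypes[, "sv0001"],
                   geno$snvs$genotypes[, "snv00001"])
  expect_lt(genotype_r2(geno$svs$genotypes[, "sv0002"],
                        geno$snvs$genotypes[, "snv00002"]), 0.01)
  expect_lt(abs(genotype_r2(geno$svs$genotypes[, "sv0003"],
                            geno$snvs$genotypes[, "snv00003"]) - 0.8), 0.1)
})

test_that("infeasible LD targets are rejected with an explanation", {
  cfg <- sim_config(
    n_samples = 100, n_svs = 5, n_snvs = 5,
    maf_spectrum = list(dist = "point", maf = 0.4),
    ld_targets = list(list(sv = "sv0001", snv = "snv00001", r2 = 0.9,
                           snv_maf = 0.05)),
    seed = 1)
  expect_error(simulate_genotypes(cfg), "infeasible LD target")
  expect_error(sim_config(ld_targets = list(list(sv = "a", snv = "b", r2 = 1.2))),
               "r2 must lie")
})

test_that("SV records carry interval, type and mobile-element-peaked lengths", {
  cfg <- sim_config(n_samples = 50, n_svs = 600, n_snvs = 0, seed = 41)
  geno <- simulate_genotypes(cfg)
  r <- geno$svs$records
  expect_true(all(r$length >= 50))
  expect_true(all(r$end - r$start == r$length))
  expect_true(all(r$vtype %in% c("INS", "DEL", "DUP", "INV")))
  # Alu peak visible: a chunk of lengths within 20% of 300 bp
  expect_gt(mean(abs(r$length - 300) < 60), 0.15)
})

test_that("phenotype generator recovers a planted standardized effect by OLS", {
  cfg <- sim_config(
    n_samples = 500, n_svs = 20, n_snvs = 0,
    maf_spectrum = list(dist = "point", maf = 0.3), missing_rate = 0,
    n_genes = 30, n_aptamers = 30,
    qtl_effects = data.frame(variant_id = "sv0005", feature_id = "apt0003",
                             beta = 0.5),
    seed = 51)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(geno, cfg)
  g <- scale(geno$svs$genotypes[, "sv0005"])
  fit <- summary(lm(ph$protein$values[, "apt0003"] ~ g))
  expect_lt(abs(fit$coefficients[2, 1] - 0.5), 2 * fit$coefficients[2, 2])
  expect_identical(ph$truth$qtl_effects$variant_id, "sv0005")
})

test_that("null phenotypes show null-scale genotype correlations", {
  cfg <- sim_config(n_samples = 300, n_svs = 50, n_snvs = 0,
                    maf_spectrum = list(dist = "point", maf = 0.3),
                    missing_rate = 0, n_genes = 100, n_aptamers = 5, seed = 61)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(geno, cfg)
  cors <- abs(cor(geno$svs$genotypes, ph$protein$values))
  # 95th percentile of |r| under the null ~ qnorm(0.975)/sqrt(n)
  expect_lt(quantile(cors, 0.95), 2.5 * qnorm(0.975) / sqrt(300))
})

test_that("noiseless single-effect phenotype is collinear with its genotype", {
  cfg <- sim_config(n_samples = 100, n_svs = 5, n_snvs = 0,
                    maf_spectrum = list(dist = "point", maf = 0.4),
                    missing_rate = 0, n_genes = 5, n_aptamers = 5,
                    noise_sd = 0, n_hidden_factors = 0,
                    qtl_effects = data.frame(variant_id = "sv0002",
                                             feature_id = "apt0001", beta = 1),
                    seed = 71)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(geno, cfg)
  expect_equal(abs(cor(ph$protein$values[, "apt0001"],
                       geno$svs$genotypes[, "sv0002"])), 1, tolerance = 1e-12)
})

test_that("rare-outlier planting hits the configured odds ratio", {
  set.seed(81)
  n <- 2000; p <- 500
  z <- matrix(rnorm(n * p), n, p)
  expo <- matrix(runif(n * p) < 0.02, n, p)
  pl <- plant_rare_outliers(z, expo, odds_ratio = 5, seed = 82)
  fe <- fisher_enrichment(as.vector(expo), as.vector(abs(pl$values) >= 2))
  expect_true(fe$ci_lo < 5 && fe$ci_hi > 5)
  # OR = 1 leaves values untouched
  pl0 <- plant_rare_outliers(z, expo, odds_ratio = 1, seed = 83)
  expect_identical(pl0$values, z)
  # directional planting of a single pair
  z1 <- matrix(rnorm(20), 20, 1)
  e1 <- matrix(FALSE, 20, 1); e1[4, 1] <- TRUE
  pl1 <- plant_rare_outliers(z1, e1, odds_ratio = 1e9, z_shift = 6,
                             direction = "under", seed = 84)
  expect_lt(pl1$values[4, 1], -2)
})

test_that("unreachable outlier planting errors", {
  z <- matrix(rnorm(10), 5, 2)
  expo <- matrix(FALSE, 5, 2)
  expect_error(plant_rare_outliers(z, expo, odds_ratio = 5), "unreachable")
})

test_that("methylation generator builds correlated segments with clip reporting", {
  # zero CpG noise: perfect within-segment correlation
  sim0 <- simulate_methylation(n_samples = 40, n_segments = 10,
                               cpg_noise_sd = 0, seed = 91)
  seg1 <- which(sim0$truth$segment == 1)
  expect_equal(cor(sim0$betas[, seg1[1]], sim0$betas[, seg1[2]]), 1)
  # independent latents: near-zero cross-segment correlation on average
  sim <- simulate_methylation(n_samples = 200, n_segments = 40, seed = 92)
  first_cpg <- match(unique(sim$truth$segment), sim$truth$segment)
  cross <- cor(sim$betas[, first_cpg])
  expect_lt(mean(abs(cross[upper.tri(cross)])), 0.12)
  # clipping reported
  simc <- simulate_methylation(n_samples = 30, n_segments = 5,
                               outliers = data.frame(sample = 1, segment = 1,
                                                     delta = 2),
                               seed = 93)
  expect_gt(simc$n_clipped, 0)
  expect_true(all(simc$betas >= 0 & simc$betas <= 1))
})

test_that("GWAS summary generator: determinism, null calibration, causal top hit", {
  R <- diag(50)
  a <- simulate_gwas_summary(R, n = 5000, seed = 101)
  b <- simulate_gwas_summary(R, n = 5000, seed = 101)
  expect_identical(a, b)
  # null p-values uniform (KS test over pooled draws)
  pv <- unlist(lapply(1:20, function(s)
    simulate_gwas_summary(R, n = 5000, seed = 200 + s)$p))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
  # single strong causal variant tops the locus nearly always
  hits <- vapply(1:100, function(s) {
    lam <- rep(0, 50); lam[17] <- 8
    which.min(simulate_gwas_summary(R, lambda = lam, n = 5000,
                                    seed = 300 + s)$p) == 17
  }, logical(1))
  expect_gte(mean(hits), 0.99)
  # non-PSD rejected
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simulate_gwas_summary(bad, n = 100, seed = 1), "positive semi-definite")
})
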