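test_that("sv_length reproduces known breakpoint arithmetic", {
  recs <- data.frame(
    id = c("hp_del", "nbeal1_del", "tmem106b_ins", "lrrc37a_sva"),
    chrom = c("chr16", "chr2", "chr7", "chr17"),
    start = c(72057133, 203034349, 12242079, 46237502),
    end = c(72058849, 203039584, 12242401, 46238226),
    vtype = c("DEL", "DEL", "INS", "DEL"),
    length = c(1716, 5235, 322, 724)
  )
  expect_equal(sv_length(recs), c(1716, 5235, 322, 724))
})

test_that("sv_length distinguishes SNVs from interval SVs", {
  recs <- make_records(3, vtype = c("DEL", "SNV", "INS"), length = c(200, 1, 300))
  expect_equal(sv_length(recs), c(200, 1, 300))
})

test_that("callset constructor validates the 50 bp SV floor and shapes", {
  expect_error(make_callset(matrix(0L, 2, 3), length = 30), ">= 50 bp")
  expect_error(variant_callset(make_records(2), matrix(0L, 2, 3)), "3 columns")
  expect_error(make_callset(matrix(5L, 2, 3)), "0, 1, 2 or NA")
})

test_that("allele frequencies, MAF and call rate follow hand counts", {
  g <- rbind(c(0L, 0L, 0L), c(1L, 2L, 0L), c(2L, NA, 0L))
  cs <- make_callset(g)
  aft <- allele_frequencies(cs)
  expect_equal(aft$af, c(0.5, 0.5, 0))
  expect_equal(aft$maf, c(0.5, 0.5, 0))
  expect_equal(aft$call_rate, c(1, 2 / 3, 1))
  expect_false(any(aft$all_missing))
  # AF invariant under sample reordering; MAF never exceeds 0.5
  cs2 <- subset_callset(cs, samples = c(3, 1, 2))
  expect_equal(allele_frequencies(cs2)$af, aft$af)
  expect_true(all(aft$maf <= 0.5))
})

test_that("filter_callset applies inclusive missingness and MAF boundaries", {
  set.seed(1)
  g <- matrix(rbinom(100 * 4, 2, 0.3), 100, 4)
  g[1:51, 1] <- NA          # 51% missing -> dropped
  g[, 2] <- rbinom(100, 2, 0.02)
  # force variant 3 to exactly MAF 0.02 (AC 4 of 200)
  g[, 3] <- 0L; g[1:4, 3] <- 1L
  cs <- make_callset(g)
  kept <- filter_callset(cs, max_missing = 0.5, maf_min = 0.02)
  expect_false("v001" %in% kept$records$id)
  expect_true("v003" %in% kept$records$id)   # MAF == 0.02 retained
  # identity filter
  all_kept <- filter_callset(cs, max_missing = 1, maf_min = 0)
  expect_equal(n_variants(all_kept), 4)
})

test_that("VCF round-trip preserves records and genotypes", {
  cfg <- sim_config(n_samples = 40, n_svs = 30, n_snvs = 0, seed = 11)
  geno <- simulate_genotypes(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(geno$svs, path)
  back <- read_variant_vcf(path)
  expect_equal(back$records[, c("id", "chrom", "start", "end", "vtype", "length")],
               geno$svs$records[, c("id", "chrom", "start", "end", "vtype", "length")])
  expect_identical(unname(back$genotypes), unname(geno$svs$genotypes))
  expect_equal(back$sample_ids, geno$svs$sample_ids)
})

test_that("VCF reader honors SVTYPE/END/SVLEN and GT conventions", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr16\t100\tdel1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=1816\tGT\t0/1\t./.",
    "chr7\t500\tins1\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=322\tGT\t1/1\t0/0",
    "chr1\t900\tsnv1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1/1"
  ), path)
  cs <- read_variant_vcf(path)
  expect_equal(cs$records$length, c(1716, 322, 1))
  expect_equal(cs$records$vtype, c("DEL", "INS", "SNV"))
  expect_equal(cs$records$end, c(1816, 822, 900))
  expect_identical(cs$genotypes[, "del1"], c(S1 = 1L, S2 = NA_integer_))
  expect_identical(unname(cs$genotypes[, "snv1"]), c(1L, 2L))
})

test_that("VCF reader skips bad records with a warning and splits multi-allelics", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\tbad1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=50\tGT\t0/1",
    "chr1\t200\tweird\tN\t<CNV>\t.\tPASS\tSVTYPE=CNV;END=400\tGT\t0/1",
    "chr1\t300\tma\tA\tG,T\t.\tPASS\t.\tGT\t1/2"
  ), path)
  expect_warning(cs <- read_variant_vcf(path), "skipped")
  expect_equal(n_variants(cs), 2)
  expect_equal(cs$records$id, c("ma_alt1", "ma_alt2"))
  expect_identical(unname(cs$genotypes[1, ]), c(1L, 1L))
})

test_that("PCA imputation recovers masked low-rank structure and is idempotent", {
  # complete matrix: untouched
  m <- matrix(runif(60, 0, 2), 10, 6)
  expect_identical(impute_genotypes_pca(m, 2)[, ], m)
  # rank-1 completion oracle
  set.seed(5)
  u <- runif(40, 0.2, 1.8); v <- runif(8, 0.1, 1)
  full <- outer(u, v)
  masked <- full; masked[c(3, 25), c(4, 7)] <- NA
  imp <- impute_genotypes_pca(masked, 1, tol = 1e-10, max_iter = 1000)
  expect_lt(max(abs(imp[is.na(masked)] - full[is.na(masked)])), 1e-6)
  # observed cells never altered; imputed in [0, 2]
  expect_identical(imp[!is.na(masked)], full[!is.na(masked)])
  expect_true(all(imp >= 0 & imp <= 2))
})

test_that("imputation beats the column-mean baseline on correlated genotypes", {
  set.seed(7)
  n <- 300
  base <- rbinom(n, 2, 0.3)
  g <- sapply(1:8, function(i) {
    x <- base; fl <- runif(n) < 0.1
    x[fl] <- rbinom(sum(fl), 2, 0.3); x
  })
  masked <- g
  hide <- sample(n, 30)
  masked[hide, 1] <- NA
  imp <- impute_genotypes_pca(masked, 2)
  rmse <- sqrt(mean((imp[hide, 1] - g[hide, 1])^2))
  expect_lt(rmse, sd(g[, 1]))
})

test_that("genotype_r2 matches hand computations and its invariances", {
  g <- c(0, 0, 1, 1, 2, 2)
  expect_equal(genotype_r2(g, g), 1)
  expect_equal(genotype_r2(g, 2 - g), 1)
  expect_equal(genotype_r2(g, c(0, 1, 0, 1, 0, 1)), 0)
  expect_equal(genotype_r2(g, 0.3 + 0.5 * g), 1)  # affine invariance
  expect_warning(r <- genotype_r2(g, rep(1, 6)), "constant")
  expect_true(is.na(r))
  # symmetric; pairwise-complete handling
  h <- c(2, 1, NA, 1, 0, 2)
  expect_equal(genotype_r2(g, h), genotype_r2(h, g))
})

test_that("best_tag_snv returns the max-r2 SNV with distance tie-breaks", {
  set.seed(3)
  n <- 200
  sv_g <- rbinom(n, 2, 0.4)
  snv_g <- cbind(rbinom(n, 2, 0.4), sv_g, rbinom(n, 2, 0.4))
  snvs <- variant_callset(
    make_records(3, vtype = "SNV", start = c(500, 3000, 100000), length = 1),
    snv_g)
  sv <- make_records(1, vtype = "DEL", start = 2000, length = 100)
  hit <- best_tag_snv(sv, sv_g, snvs, window_bp = 1e5)
  expect_equal(hit$snv_id, "v002")
  expect_equal(hit$r2, 1)
  # tie on r2 -> nearer SNV wins
  snvs_tie <- variant_callset(
    make_records(2, vtype = "SNV", start = c(50000, 2500), length = 1),
    cbind(sv_g, sv_g))
  hit2 <- best_tag_snv(sv, sv_g, snvs_tie, window_bp = 1e5)
  expect_equal(hit2$snv_id, "v002")
  # nothing in window
  expect_warning(far <- best_tag_snv(sv, sv_g,
    variant_callset(make_records(1, vtype = "SNV", start = 5e6, length = 1),
                    matrix(rbinom(n, 2, 0.3), n, 1)), window_bp = 1e4),
    "no SNV")
  expect_equal(nrow(far), 0)
})

test_that("independent SNVs show near-zero tagging at large n", {
  set.seed(9)
  n <- 2000
  sv_g <- rbinom(n, 2, 0.3)
  snv_g <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  snvs <- variant_callset(
    make_records(5, vtype = "SNV", start = seq(1000, 5000, by = 1000), length = 1),
    snv_g)
  sv <- make_records(1, vtype = "DEL", start = 2000, length = 100)
  hit <- best_tag_snv(sv, sv_g, snvs, window_bp = 1e5)
  expect_lt(hit$r2, 0.05)
})
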