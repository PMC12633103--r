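# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

make_records <- function(n, chrom = "chr1", vtype = "DEL", start = NULL,
                         length = 100) {
  if (is.null(start)) start <- seq(1000, by = 10000, length.out = n)
  length <- rep_len(length, n)
  vtype <- rep_len(vtype, n)
  data.frame(
    id = sprintf("v%03d", seq_len(n)),
    chrom = chrom, start = start,
    end = ifelse(vtype == "SNV", start, start + length),
    vtype = vtype,
    length = ifelse(vtype == "SNV", 1, length),
    stringsAsFactors = FALSE
  )
}

make_callset <- function(genotypes, ...) {
  genotypes <- as.matrix(genotypes)
  variant_callset(make_records(ncol(genotypes), ...), genotypes)
}

# Adjusted Rand index between two cluster assignments.
rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Brute-force colocalization enumerator: plain loops over per-variant
# causal configurations, no log-sum-exp. Oracle for coloc_abf.
brute_force_coloc <- function(lbf1, lbf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  b1 <- exp(lbf1); b2 <- exp(lbf2)
  h0 <- 1
  h1 <- p1 * sum(b1)
  h2 <- p2 * sum(b2)
  h3 <- 0
  for (i in seq_along(b1)) {
    for (j in seq_along(b2)) {
      if (i != j) h3 <- h3 + p1 * p2 * b1[i] * b2[j]
    }
  }
  h4 <- p12 * sum(b1 * b2)
  pp <- c(h0, h1, h2, h3, h4) / (h0 + h1 + h2 + h3 + h4)
  names(pp) <- paste0("PP.H", 0:4)
  pp
}
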