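#' Construct a variant call set
#'
#' A `variant_callset` bundles a table of variant records with a diploid
#' genotype matrix. Coordinates are 1-based inclusive (VCF `POS` convention);
#' SV intervals are closed `[start, end]`. For insertions the interval spans
#' `start .. start + length`, so `end - start` recovers the inserted length
#' for every variant type.
#'
#' @param records data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `vtype` (one of `INS`, `DEL`, `DUP`, `INV`, `SNV`) and `length` (bp).
#'   An optional `alt_allele` column carries the inserted/alternate sequence.
#' @param genotypes integer matrix, samples x variants, entries in
#'   `{0, 1, 2, NA}` (alternate-allele dosage; `NA` = missing call).
#' @param sample_ids character vector naming the rows of `genotypes`.
#'
#' @return An object of class `variant_callset` with elements `records`,
#'   `genotypes` and `sample_ids`.
#' @export
variant_callset <- function(records, genotypes, sample_ids = rownames(genotypes)) {
  stopifnot(is.data.frame(records), is.matrix(genotypes))
  req <- c("id", "chrom", "start", "end", "vtype", "length")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(genotypes)))
  if (ncol(genotypes) != nrow(records)) {
    stop("genotype matrix has ", ncol(genotypes), " columns but ",
         nrow(records), " variant records")
  }
  if (length(sample_ids) != nrow(genotypes)) {
    stop("sample_ids length does not match genotype rows")
  }
  if (anyDuplicated(records$id)) stop("duplicated variant ids")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA")
  if (any(records$end < records$start)) stop("variant end < start")
  if (any(!nzchar(records$chrom))) stop("empty chromosome name")
  sv <- records$vtype != "SNV"
  if (any(records$length[sv] < 50)) {
    stop("SV records must be >= 50 bp (", sum(records$length[sv] < 50),
         " offending records)")
  }
  if (any(records$length[!sv] != 1)) stop("SNV records must have length 1")
  records$id <- as.character(records$id)
  records$chrom <- as.character(records$chrom)
  records$start <- as.numeric(records$start)
  records$end <- as.numeric(records$end)
  records$length <- as.numeric(records$length)
  rownames(records) <- NULL
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- sample_ids
  colnames(genotypes) <- records$id
  structure(list(records = records, genotypes = genotypes,
                 sample_ids = sample_ids),
            class = "variant_callset")
}

#' @export
print.variant_callset <- function(x, ...) {
  tab <- table(x$records$vtype)
  cat("variant_callset:", nrow(x$records), "variants x",
      length(x$sample_ids), "samples\n")
  cat("  types:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of variants / samples in a call set
#' @param callset a `variant_callset`
#' @return integer count
#' @export
n_variants <- function(callset) nrow(callset$records)

#' @rdname n_variants
#' @export
n_samples <- function(callset) length(callset$sample_ids)

#' Structural-variant length
#'
#' Length in base pairs of each variant record: `end - start` for deletions,
#' duplications and inversions; the stored inserted-sequence length for
#' insertions (whose interval is `start .. start + length`, so the same
#' arithmetic applies); 1 for SNVs.
#'
#' @param records data.frame of variant records, or a `variant_callset`.
#' @return numeric vector of lengths (bp)
#' @export
sv_length <- function(records) {
  if (inherits(records, "variant_callset")) records <- records$records
  ifelse(records$vtype == "SNV", 1, records$end - records$start)
}

#' Allele frequencies, minor allele frequencies and call rates
#'
#' AF is the alternate-allele frequency among non-missing genotypes,
#' `sum(g) / (2 * n_called)`; MAF is `min(AF, 1 - AF)`; call_rate is the
#' fraction of samples with a non-missing genotype. Variants with no called
#' genotype get `NA` AF and are flagged.
#'
#' @param callset a `variant_callset`
#' @return data.frame with columns `id`, `af`, `maf`, `call_rate`, `ac`
#'   (alternate allele count) and `all_missing`.
#' @export
allele_frequencies <- function(callset) {
  g <- callset$genotypes
  called <- colSums(!is.na(g))
  ac <- colSums(g, na.rm = TRUE)
  af <- ifelse(called > 0, ac / (2 * called), NA_real_)
  data.frame(
    id = callset$records$id,
    af = af,
    maf = pmin(af, 1 - af),
    call_rate = called / nrow(g),
    ac = ac,
    all_missing = called == 0,
    row.names = NULL
  )
}

#' Filter a call set on missingness and minor allele frequency
#'
#' Retains variants with missing fraction `<= max_missing` and
#' `MAF >= maf_min` (both boundaries inclusive), preserving variant order.
#'
#' @param callset a `variant_callset`
#' @param max_missing maximum tolerated missing-genotype fraction (default
#'   0.5: variants missing in more than half the cohort are excluded)
#' @param maf_min minimum minor allele frequency (default 0.02, the common-SV
#'   cut used for QTL mapping)
#' @return filtered `variant_callset`
#' @export
filter_callset <- function(callset, max_missing = 0.5, maf_min = 0.02) {
  aft <- allele_frequencies(callset)
  keep <- !aft$all_missing &
    (1 - aft$call_rate) <= max_missing &
    aft$maf >= maf_min
  subset_callset(callset, variants = which(keep))
}

#' Subset a call set by variant and/or sample index
#' @param callset a `variant_callset`
#' @param variants integer or logical index over variants (default: all)
#' @param samples integer or logical index over samples (default: all)
#' @return a `variant_callset`
#' @export
subset_callset <- function(callset, variants = NULL, samples = NULL) {
  if (is.null(variants)) variants <- seq_len(n_variants(callset))
  if (is.null(samples)) samples <- seq_len(n_samples(callset))
  variant_callset(
    records = callset$records[variants, , drop = FALSE],
    genotypes = callset$genotypes[samples, variants, drop = FALSE],
    sample_ids = callset$sample_ids[samples]
  )
}

#' Variant records as a GRanges
#' @param callset a `variant_callset`
#' @return a `GenomicRanges::GRanges` with `id`, `vtype`, `length` metadata
#' @export
callset_granges <- function(callset) {
  r <- callset$records
  GenomicRanges::GRanges(
    seqnames = r$chrom,
    ranges = IRanges::IRanges(start = r$start, end = r$end),
    id = r$id, vtype = r$vtype, length = r$length
  )
}
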