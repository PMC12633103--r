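#' Read SV/SNV calls from a VCF file
#'
#' Reads a VCF (4.2 subset) into a [variant_callset()]. The INFO keys
#' `SVTYPE`, `SVLEN` and `END` are honored: insertions take their length from
#' `|SVLEN|`; deletions, duplications and inversions take `END - POS` when
#' `SVLEN` is absent. Records without an `SVTYPE` whose REF and ALT are single
#' bases are treated as SNVs. Multi-allelic records are split into one
#' biallelic record per alternate allele (genotype = dosage of that allele).
#'
#' Per-sample `GT` values map `./.` (or `.`) to missing, `0/0` to 0, `0/1` to
#' 1 and `1/1` to 2; phased separators are accepted. Records with `END < POS`
#' or an unrecognized `SVTYPE` are skipped; a single warning reports the
#' skip counts.
#'
#' @param path path to a VCF file (plain or bgzipped)
#' @return a `variant_callset`
#' @export
read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcf@gt[, -1, drop = FALSE]
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = nrow(fix))
  sample_ids <- colnames(vcf@gt)[-1]
  gt_field <- sub(":.*$", "", gt_raw)

  info <- fix[, "INFO"]
  svtype <- .info_value(info, "SVTYPE")
  svlen <- suppressWarnings(as.numeric(.info_value(info, "SVLEN")))
  endv <- suppressWarnings(as.numeric(.info_value(info, "END")))
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("var", which(is.na(ids) | ids == "."))

  n_bad_end <- 0L; n_bad_type <- 0L; n_bad_gt <- 0L
  out_rec <- vector("list", nrow(fix))
  out_gt <- vector("list", nrow(fix))

  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    vt <- svtype[i]
    if (is.na(vt)) {
      sym <- grepl("^<.*>$", alts[1])
      if (sym) {
        vt <- gsub("[<>]", "", alts[1])
      } else if (all(nchar(alts) == 1) && nchar(ref[i]) == 1) {
        vt <- "SNV"
      } else if (nchar(ref[i]) > nchar(alts[1])) {
        vt <- "DEL"
      } else {
        vt <- "INS"
      }
    }
    if (!vt %in% c("INS", "DEL", "DUP", "INV", "SNV")) {
      n_bad_type <- n_bad_type + 1L
      next
    }
    if (vt == "SNV") {
      len <- 1; end <- pos[i]
    } else if (vt == "INS") {
      len <- abs(svlen[i])
      if (is.na(len)) len <- nchar(alts[1]) - nchar(ref[i])
      end <- pos[i] + len
    } else {
      if (!is.na(endv[i]) && endv[i] < pos[i]) { n_bad_end <- n_bad_end + 1L; next }
      len <- if (!is.na(endv[i])) endv[i] - pos[i] else abs(svlen[i])
      if (is.na(len)) { n_bad_end <- n_bad_end + 1L; next }
      end <- pos[i] + len
    }
    n_alt <- length(alts)
    per_alt_gt <- matrix(NA_integer_, nrow = length(sample_ids), ncol = n_alt)
    toks <- strsplit(gt_field[i, ], "[/|]")
    for (s in seq_along(toks)) {
      tk <- toks[[s]]
      if (length(tk) == 0 || all(is.na(tk)) || all(tk == ".")) next
      if (any(!tk %in% c(".", as.character(0:n_alt)))) {
        n_bad_gt <- n_bad_gt + 1L
        next
      }
      for (k in seq_len(n_alt)) per_alt_gt[s, k] <- sum(tk == as.character(k))
    }
    recs <- data.frame(
      id = if (n_alt == 1) unname(ids[i]) else paste0(ids[i], "_alt", seq_len(n_alt)),
      chrom = unname(fix[i, "CHROM"]), start = pos[i], end = end,
      vtype = vt, length = len,
      alt_allele = alts, stringsAsFactors = FALSE
    )
    out_rec[[i]] <- recs
    out_gt[[i]] <- per_alt_gt
  }
  if (n_bad_end + n_bad_type + n_bad_gt > 0) {
    warning(sprintf("skipped %d records with END < POS, %d with unknown SVTYPE; %d malformed GT values set to missing",
                    n_bad_end, n_bad_type, n_bad_gt))
  }
  keep <- !vapply(out_rec, is.null, logical(1))
  records <- do.call(rbind, out_rec[keep])
  genotypes <- do.call(cbind, out_gt[keep])
  variant_callset(records, genotypes, sample_ids)
}

.info_value <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
}

#' Write a call set to VCF
#'
#' Emits the minimal VCF 4.2 dialect read by [read_variant_vcf()]: symbolic
#' ALT alleles for SVs, INFO keys `SVTYPE`/`SVLEN`/`END`, and a `GT` FORMAT
#' field. Insertions are written with `END = POS` (VCF convention); their
#' interval is reconstructed from `SVLEN` on read.
#'
#' @param callset a `variant_callset`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_variant_vcf <- function(callset, path) {
  r <- callset$records
  g <- callset$genotypes
  alt <- if ("alt_allele" %in% names(r)) r$alt_allele else rep(NA_character_, nrow(r))
  is_snv <- r$vtype == "SNV"
  alt_out <- ifelse(is_snv, ifelse(is.na(alt), "A", alt), paste0("<", r$vtype, ">"))
  ref_out <- ifelse(is_snv, "N", "N")
  end_out <- ifelse(r$vtype == "INS", r$start, r$end)
  info <- ifelse(is_snv, ".",
                 sprintf("SVTYPE=%s;SVLEN=%d;END=%d", r$vtype,
                         as.integer(ifelse(r$vtype == "DEL", -r$length, r$length)),
                         as.integer(end_out)))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
  gt_str[is.na(g)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", callset$sample_ids), collapse = "\t")
  )
  body <- paste(r$chrom, as.integer(r$start), r$id, ref_out, alt_out, ".", "PASS",
                info, "GT", sep = "\t")
  body <- paste0(body, "\t", apply(gt_str, 2, paste, collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Export variant intervals as BED
#'
#' Converts the internal 1-based closed intervals to BED's 0-based
#' half-open convention.
#'
#' @param callset a `variant_callset`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_variant_bed <- function(callset, path) {
  r <- callset$records
  utils::write.table(
    data.frame(r$chrom, as.integer(r$start - 1), as.integer(r$end), r$id,
               0L, "."),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
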