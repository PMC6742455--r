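#' Read biallelic SNPs from a VCF
#'
#' Parses a VCF (v4.x, plain or gzipped) with vcfR and emits one row per
#' single-base substitution allele. Multi-allelic records are split into one
#' row per alternate allele; each split row carries the same position and
#' reference. Alleles that are not single-base substitutions (INDELs, symbolic
#' or breakend alleles) are dropped and counted.
#'
#' @param path Path to a VCF file.
#' @param keep_samples If `TRUE` and the VCF has a GT FORMAT field, attach a
#'   matrix column `gt` of per-sample alternate-allele doses (0, 1, 2 or `NA`
#'   for missing), one column per sample. For a record split from a
#'   multi-allelic site the dose counts that row's alternate allele only.
#' @return A data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `rsid` (`NA` when "."), and optionally the `gt` matrix column. Attributes
#'   `n_dropped_indel` and `n_dropped_malformed` hold drop counts.
#' @export
read_snps <- function(path, keep_samples = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  ref <- toupper(fix[, "REF"])
  alt_field <- fix[, "ALT"]
  rsid <- fix[, "ID"]
  rsid[!is.na(rsid) & rsid == "."] <- NA_character_

  malformed <- is.na(chrom) | is.na(pos) | is.na(ref) | ref == "" |
    is.na(alt_field) | alt_field == ""
  n_malformed <- sum(malformed)
  if (n_malformed > 0) {
    warning(n_malformed, " malformed VCF record(s) skipped")
  }

  gt_dose <- NULL
  if (keep_samples && !is.null(v@gt) && ncol(v@gt) > 1L) {
    gt_raw <- vcfR::extract.gt(v, element = "GT")
  } else {
    gt_raw <- NULL
    keep_samples <- FALSE
  }

  # split multi-allelic records: one candidate (record, alt-index) per allele
  alts <- strsplit(toupper(alt_field), ",", fixed = TRUE)
  alts[malformed] <- list(character(0))
  n_alt <- lengths(alts)
  rec <- rep.int(seq_along(alts), n_alt)
  alt_idx <- sequence(n_alt)
  alt <- unlist(alts, use.names = FALSE)

  is_snp <- nchar(ref[rec]) == 1L & nchar(alt) == 1L &
    ref[rec] %in% c("A", "C", "G", "T", "N") &
    alt %in% c("A", "C", "G", "T") & alt != ref[rec]
  n_indel <- sum(!is_snp)
  if (n_indel > 0) {
    warning(n_indel, " non-SNP allele(s) (INDEL/symbolic) dropped")
  }
  rec <- rec[is_snp]; alt_idx <- alt_idx[is_snp]; alt <- alt[is_snp]

  out <- data.frame(
    chrom = chrom[rec], pos = pos[rec], ref = ref[rec], alt = alt,
    rsid = rsid[rec], stringsAsFactors = FALSE
  )
  if (keep_samples) {
    out$gt <- gt_allele_dose(gt_raw[rec, , drop = FALSE], alt_idx)
  }
  attr(out, "n_dropped_indel") <- n_indel
  attr(out, "n_dropped_malformed") <- n_malformed
  out
}

#' Convert GT strings to alternate-allele doses
#'
#' Counts how many of the two allele slots in a diploid GT string (`"0/1"`,
#' `"1|1"`, ...) equal a given alternate-allele index. Any missing allele
#' (`"."`) makes the whole call missing: a half-call contributes neither to
#' the allele numerator nor to the denominator.
#'
#' @param gt Character matrix (or vector) of GT strings; `NA` allowed.
#' @param alt_index Alternate-allele index to count (recycled); 1 for the
#'   first ALT allele.
#' @return Integer matrix (or vector) of doses 0/1/2 with `NA` for missing.
#' @export
gt_allele_dose <- function(gt, alt_index = 1L) {
  dm <- dim(gt)
  gtv <- as.character(gt)
  alt_index <- rep_len(alt_index, if (is.null(dm)) length(gtv) else dm[1])
  if (!is.null(dm)) alt_index <- rep.int(alt_index, dm[2])
  parts <- strsplit(gtv, "[/|]")
  dose <- mapply(function(p, k) {
    if (length(p) == 0L || anyNA(p) || any(p == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(p))
    if (anyNA(a)) return(NA_integer_)
    sum(a == k)
  }, parts, as.list(alt_index))
  dose[is.na(gtv)] <- NA_integer_
  dose <- as.integer(dose)
  if (!is.null(dm)) {
    dose <- matrix(dose, nrow = dm[1], ncol = dm[2], dimnames = dimnames(gt))
  }
  dose
}
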