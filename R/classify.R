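#' meSNP class labels
#'
#' A single-base substitution is classified by how it changes CpG
#' dinucleotides in the trinucleotide window centred on the variant. Every
#' CpG affected by the substitution must contain the substituted base, so the
#' 3-bp window captures all of them. Within the window only two dinucleotide
#' "slots" exist — left (flank + centre, a CpG only when the centre is G) and
#' right (centre + flank, a CpG only when the centre is C) — and for a given
#' centre base at most one slot can read CG.
#'
#' * `create`  — no CpG with the reference allele, at least one with the
#'   alternate (the alternate is the methylation-site-creating, MSC, allele)
#' * `destroy` — CpG with the reference, none with the alternate
#' * `displace` — both alleles support a CpG, necessarily in different slots
#' * `none` — neither allele touches a CpG
#' * `unclassifiable` — an `N` (or an undetermined flank) makes the call
#'   ambiguous
#'
#' @return Character vector of the five class labels.
#' @export
mesnp_classes <- function() {
  c("create", "destroy", "displace", "none", "unclassifiable")
}

# class from fully known bases; left/right = NA means the flank does not
# exist (chromosome edge), which can never form a CpG
.class_known <- function(left, ref, alt, right) {
  r <- (!is.na(left) & left == "C" & ref == "G") |
       (!is.na(right) & ref == "C" & right == "G")
  a <- (!is.na(left) & left == "C" & alt == "G") |
       (!is.na(right) & alt == "C" & right == "G")
  out <- rep("none", length(r))
  out[!r & a] <- "create"
  out[r & !a] <- "destroy"
  out[r & a] <- "displace"
  out
}

#' Classify a SNP by its effect on CpG dinucleotides
#'
#' Vectorized over all four arguments. Flanking bases may be `NA` (the flank
#' does not exist: variant at position 1 or at the chromosome end — decidable,
#' that slot simply cannot hold a CpG) or `"N"` (unknown base). An unknown
#' flank yields `unclassifiable` only when the class genuinely depends on it:
#' both resolutions of each `N` are enumerated and the class is returned iff
#' it is invariant.
#'
#' @param left,right Flanking reference bases (`A/C/G/T`, `"N"`, or `NA`).
#' @param ref,alt Reference and alternate alleles at the variant position.
#' @return Character vector of class labels (see [mesnp_classes()]).
#' @examples
#' classify_cpg_variant("C", "A", "G", "T") # create:   CAT -> CGT
#' classify_cpg_variant("T", "C", "T", "G") # destroy:  TCG -> TTG
#' classify_cpg_variant("C", "G", "C", "G") # displace: CGG -> CCG
#' @export
classify_cpg_variant <- function(left, ref, alt, right) {
  n <- max(length(left), length(ref), length(alt), length(right))
  left <- rep_len(as.character(left), n)
  right <- rep_len(as.character(right), n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  stopifnot(all(is.na(ref) | ref != alt))

  bases <- c("A", "C", "G", "T")
  bad_center <- is.na(ref) | is.na(alt) | !(ref %in% bases) | !(alt %in% bases)
  unk_l <- !is.na(left) & !(left %in% bases)   # "N" or other ambiguity code
  unk_r <- !is.na(right) & !(right %in% bases)

  # resolve each unknown flank both ways (CpG-forming vs not) and demand a
  # unanimous class; flanks are shared between the two alleles, so resolving
  # per-base keeps the ref and alt slots consistent
  l_yes <- ifelse(unk_l, "C", left)
  l_no <- ifelse(unk_l, "A", left)
  r_yes <- ifelse(unk_r, "G", right)
  r_no <- ifelse(unk_r, "A", right)
  c11 <- .class_known(l_yes, ref, alt, r_yes)
  c10 <- .class_known(l_yes, ref, alt, r_no)
  c01 <- .class_known(l_no, ref, alt, r_yes)
  c00 <- .class_known(l_no, ref, alt, r_no)

  out <- c00
  out[c11 != c00 | c10 != c00 | c01 != c00] <- "unclassifiable"
  out[bad_center] <- "unclassifiable"
  out
}

#' Scan SNPs against a genome and classify each as a meSNP
#'
#' Retrieves the flanking reference bases for every SNP and applies
#' [classify_cpg_variant()]. Variants at position 1 or at a chromosome end are
#' classified from the one available slot. SNPs on chromosomes absent from
#' the genome are skipped and counted (attribute `n_skipped_chrom`).
#'
#' @param snps SNP data frame from [read_snps()] (columns `chrom`, `pos`,
#'   `ref`, `alt`, ...); assumed reference-consistent (see
#'   [verify_reference_consistency()]).
#' @param genome A `DNAStringSet` from [load_genome()].
#' @return The input rows (minus skipped chromosomes) with added columns
#'   `context` (trinucleotide, `.` for a missing flank), `class`,
#'   `msc_allele` and `msd_allele` (the CpG-creating / CpG-destroying allele,
#'   defined for `create` and `destroy` only).
#' @export
scan_mesnps <- function(snps, genome) {
  known <- snps$chrom %in% names(genome)
  n_skip <- sum(!known)
  if (n_skip > 0) {
    warning(n_skip, " SNP(s) on chromosomes absent from the genome skipped")
  }
  out <- snps[known, , drop = FALSE]
  n <- nrow(out)
  left <- rep(NA_character_, n)
  right <- rep(NA_character_, n)
  for (ch in unique(out$chrom)) {
    i <- which(out$chrom == ch)
    s <- as.character(genome[[ch]])
    len <- nchar(s)
    p <- out$pos[i]
    if (any(p < 1L | p > len)) stop("SNP position out of range on ", ch)
    l <- substring(s, p - 1L, p - 1L)
    r <- substring(s, p + 1L, p + 1L)
    l[p == 1L] <- NA_character_
    r[p == len] <- NA_character_
    left[i] <- l
    right[i] <- r
  }
  out$context <- paste0(ifelse(is.na(left), ".", left), out$ref,
                        ifelse(is.na(right), ".", right))
  out$class <- classify_cpg_variant(left, out$ref, out$alt, right)
  out$msc_allele <- ifelse(out$class == "create", out$alt,
                    ifelse(out$class == "destroy", out$ref, NA_character_))
  out$msd_allele <- ifelse(out$class == "create", out$ref,
                    ifelse(out$class == "destroy", out$alt, NA_character_))
  attr(out, "n_skipped_chrom") <- n_skip
  rownames(out) <- NULL
  out
}

#' Per-chromosome summary of meSNP classes
#'
#' Counts `create`/`destroy`/`displace` per chromosome, with fractions
#' expressed relative to the total number of input SNPs (all chromosomes), so
#' per-class percentages sum to the genome-wide meSNP fraction. `none` and
#' `unclassifiable` records count toward `n_snps` but not toward meSNPs.
#'
#' @param records Output of [scan_mesnps()].
#' @return Data frame with one row per chromosome plus a `Total` row:
#'   `chrom`, `n_snps`, `create`, `destroy`, `displace`, `mesnp_total`, and
#'   `frac_*` columns. Empty input gives a zero-row data frame.
#' @export
summarize_classes <- function(records) {
  cols <- c("chrom", "n_snps", "create", "destroy", "displace", "mesnp_total",
            "frac_create", "frac_destroy", "frac_displace")
  if (nrow(records) == 0L) {
    return(stats::setNames(
      data.frame(character(0), integer(0), integer(0), integer(0),
                 integer(0), integer(0), numeric(0), numeric(0), numeric(0),
                 stringsAsFactors = FALSE), cols))
  }
  chroms <- unique(records$chrom)
  cnt <- function(ch, cl) sum(records$chrom %in% ch & records$class == cl)
  tab <- data.frame(
    chrom = chroms,
    n_snps = vapply(chroms, function(ch) sum(records$chrom == ch), 0L),
    create = vapply(chroms, cnt, 0L, cl = "create"),
    destroy = vapply(chroms, cnt, 0L, cl = "destroy"),
    displace = vapply(chroms, cnt, 0L, cl = "displace"),
    stringsAsFactors = FALSE
  )
  tab <- rbind(tab, data.frame(
    chrom = "Total", n_snps = sum(tab$n_snps), create = sum(tab$create),
    destroy = sum(tab$destroy), displace = sum(tab$displace),
    stringsAsFactors = FALSE
  ))
  total_snps <- nrow(records)
  tab$mesnp_total <- tab$create + tab$destroy + tab$displace
  tab$frac_create <- tab$create / total_snps
  tab$frac_destroy <- tab$destroy / total_snps
  tab$frac_displace <- tab$displace / total_snps
  rownames(tab) <- NULL
  tab
}
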