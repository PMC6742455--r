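#' Load a reference genome from FASTA
#'
#' Reads a (possibly soft-masked) FASTA file into a [Biostrings::DNAStringSet].
#' Sequence names are truncated at the first whitespace, record order is
#' preserved, and soft-masked (lowercase) bases are uppercased: repeat masking
#' carries no information for CpG classification here.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return A `DNAStringSet`, one entry per chromosome/contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), fa)
#' g <- load_genome(fa)
#' genome_base(g, "chr1", 2) # "C"
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) == 0L) stop("empty FASTA file: ", path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) {
    stop("duplicate sequence names in FASTA: ",
         paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
  }
  # DNAString storage is case-insensitive, but be explicit about the contract
  g <- Biostrings::DNAStringSet(toupper(as.character(g)))
  g
}

#' Chromosome lengths of a genome
#' @param genome A `DNAStringSet` as returned by [load_genome()].
#' @return Named integer vector of sequence lengths in bp.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Base at a 1-based genomic position
#'
#' Out-of-range access is an error, never a silent `N`.
#'
#' @param genome A `DNAStringSet`.
#' @param chrom Chromosome name.
#' @param pos 1-based position(s); vectorized.
#' @return Character vector of uppercase bases in `{A,C,G,T,N}`.
#' @export
genome_base <- function(genome, chrom, pos) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (any(pos < 1L | pos > len)) {
    bad <- pos[pos < 1L | pos > len]
    stop("position out of range on ", chrom, " (length ", len, "): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  s <- as.character(genome[[chrom]])
  substring(s, pos, pos)
}

#' Check SNP reference alleles against the genome
#'
#' For each SNP, compares the stated reference allele with the genome base at
#' its position. SNPs on chromosomes absent from the genome are counted
#' separately, not silently dropped.
#'
#' @param snps A SNP data frame (see [read_snps()]): columns `chrom`, `pos`,
#'   `ref` at minimum.
#' @param genome A `DNAStringSet`.
#' @return A list with `n_checked`, `n_mismatch`, `n_unknown_chrom`, and
#'   `mismatches` (data frame with `chrom`, `pos`, `expected`, `found`).
#' @export
verify_reference_consistency <- function(snps, genome) {
  stopifnot(all(c("chrom", "pos", "ref") %in% names(snps)))
  n <- nrow(snps)
  known <- snps$chrom %in% names(genome)
  found <- rep(NA_character_, n)
  for (ch in unique(snps$chrom[known])) {
    i <- which(snps$chrom == ch)
    found[i] <- genome_base(genome, ch, snps$pos[i])
  }
  bad <- known & found != snps$ref
  list(
    n_checked = n,
    n_mismatch = sum(bad),
    n_unknown_chrom = sum(!known),
    mismatches = data.frame(
      chrom = snps$chrom[bad], pos = snps$pos[bad],
      expected = snps$ref[bad], found = found[bad],
      stringsAsFactors = FALSE
    )
  )
}
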