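#' Write a meSNP database table
#'
#' Tab-separated export with the fixed header `Chr, Position, Genome, Ref,
#' Alt, AF, rsID, Consequence, Gene, Functionality, Biotype, meSNP_class`.
#' `Genome` is the trinucleotide context with the variant as the middle base.
#' Annotation fields are taken from same-named lowercase columns when present
#' (`af`, `rsid`, `consequence`, `gene`, `functionality`, `biotype`); any
#' missing value is written as `"."`. The `af` column, when supplied, is the
#' population allele frequency carried over verbatim from the input
#' annotation, not computed here.
#'
#' @param records Classified records from [scan_mesnps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dbmesnp_table <- function(records, path) {
  dot <- function(x) {
    x <- as.character(x)
    ifelse(is.na(x) | x == "", ".", x)
  }
  col <- function(name) {
    if (name %in% names(records)) dot(records[[name]])
    else rep(".", nrow(records))
  }
  out <- data.frame(
    Chr = records$chrom,
    Position = records$pos,
    Genome = records$context,
    Ref = records$ref,
    Alt = records$alt,
    AF = col("af"),
    rsID = col("rsid"),
    Consequence = col("consequence"),
    Gene = col("gene"),
    Functionality = col("functionality"),
    Biotype = col("biotype"),
    meSNP_class = records$class,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a meSNP database table
#'
#' Inverse of [write_dbmesnp_table()]; `"."` fields come back as `NA`.
#'
#' @param path Path to a table written by [write_dbmesnp_table()].
#' @return Data frame with lowercase column names (`chrom`, `pos`, `context`,
#'   `ref`, `alt`, `af`, `rsid`, `consequence`, `gene`, `functionality`,
#'   `biotype`, `class`).
#' @export
read_dbmesnp_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = ".",
                         check.names = FALSE,
                         colClasses = c(Position = "integer"))
  stats::setNames(x, c("chrom", "pos", "context", "ref", "alt", "af", "rsid",
                       "consequence", "gene", "functionality", "biotype",
                       "class"))
}
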