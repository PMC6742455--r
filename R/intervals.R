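#' Read feature intervals from a BED file
#'
#' BED3/BED4 import via rtracklayer. BED is 0-based half-open on disk; the
#' returned `GRanges` is 1-based closed, the only conversion point in the
#' package. An optional 4th column becomes the `name` metadata column.
#'
#' @param path Path to a BED file.
#' @return A `GRanges` in input order (empty for an empty file).
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  f <- strsplit(lines, "\t", fixed = TRUE)
  start <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0) {
    stop("invalid interval (start >= end or non-numeric) at line ", bad[1],
         " of ", path, ": ", lines[bad[1]])
  }
  rtracklayer::import(path, format = "bed")
}

#' Write intervals to a BED file
#'
#' Inverse of [read_intervals()]: 1-based closed `GRanges` out, 0-based
#' half-open BED on disk; a `name` column is written as the 4th field.
#'
#' @param intervals A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  rtracklayer::export(intervals, path, format = "bed")
  invisible(path)
}

#' Annotate SNP records with feature membership
#'
#' Adds `label` to the `features` set of every record whose (1-based) position
#' falls inside any of the intervals. Labels are additive across calls; the
#' `features` column is a list of character vectors, created on first use.
#'
#' @param records A SNP/meSNP data frame with `chrom` and `pos` columns.
#' @param intervals A `GRanges` of features.
#' @param label Membership label to add (single string).
#' @return `records` with an updated `features` list column.
#' @export
annotate_membership <- function(records, intervals, label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (is.null(records$features)) {
    records$features <- I(replicate(nrow(records), character(0), simplify = FALSE))
  }
  if (nrow(records) == 0L || length(intervals) == 0L) return(records)
  hit <- positions_in_intervals(records$chrom, records$pos, intervals)
  records$features[hit] <- lapply(records$features[hit],
                                  function(f) union(f, label))
  records
}

#' Which positions fall inside an interval set
#'
#' @param chrom,pos Parallel vectors of chromosome and 1-based position.
#' @param intervals A `GRanges`.
#' @return Logical vector, `TRUE` where the position is covered.
#' @keywords internal
positions_in_intervals <- function(chrom, pos, intervals) {
  if (length(pos) == 0L || length(intervals) == 0L) {
    return(logical(length(pos)))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(q, intervals, ignore.strand = TRUE)
}

#' Total merged length of an interval set, per chromosome
#'
#' Overlapping intervals are unioned first so shared bases are counted once.
#'
#' @param intervals A `GRanges`.
#' @return Named numeric vector of bp per chromosome.
#' @keywords internal
merged_bp_per_chrom <- function(intervals) {
  m <- GenomicRanges::reduce(intervals, ignore.strand = TRUE)
  if (length(m) == 0L) return(stats::setNames(numeric(0), character(0)))
  tapply(GenomicRanges::width(m),
         as.character(GenomicRanges::seqnames(m)), sum)
}
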