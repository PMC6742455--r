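#' Expected meSNP count inside a feature set
#'
#' Under uniform random placement along a chromosome (ignoring nucleotide
#' composition), the expected number of hits inside features is proportional
#' to the fraction of the chromosome the (merged) features cover.
#'
#' @param n_mesnps Number of meSNPs on the chromosome.
#' @param feature_bp Total merged feature length on the chromosome, in bp.
#' @param chrom_length Chromosome length in bp.
#' @return Real-valued expected count `n_mesnps * feature_bp / chrom_length`.
#' @export
expected_count <- function(n_mesnps, feature_bp, chrom_length) {
  stopifnot(chrom_length > 0, feature_bp >= 0)
  if (feature_bp > chrom_length) {
    stop("feature_bp exceeds chrom_length; merge overlapping features first")
  }
  n_mesnps * feature_bp / chrom_length
}

#' Chi-square test of meSNP enrichment
#'
#' Two-cell Pearson goodness-of-fit against the uniform-placement expectation:
#' `X^2 = (O-E)^2/E + ((T-O)-(T-E))^2/(T-E)` on 1 degree of freedom, with the
#' p-value from the upper tail. Significance is declared at `alpha` (1% by
#' default). No continuity correction by default (intended counts are large);
#' set `correct = TRUE` for Yates' correction.
#'
#' @param observed Observed count of meSNPs inside features.
#' @param expected Expected count from [expected_count()].
#' @param total Total meSNPs on the chromosome.
#' @param alpha Significance level.
#' @param correct Apply Yates' continuity correction.
#' @return List with `observed`, `expected`, `total`, `fold`, `chi_sq`,
#'   `p_value`, `significant`, `testable`. When `expected` is 0 or `>= total`
#'   the result is flagged untestable (`fold` is `NA` when `expected` is 0).
#' @examples
#' chi_square_enrichment(200, 100, 10000) # fold 2, X^2 ~ 101.01
#' @export
chi_square_enrichment <- function(observed, expected, total, alpha = 0.01,
                                  correct = FALSE) {
  stopifnot(observed >= 0, observed <= total)
  testable <- expected > 0 && expected < total
  fold <- if (expected > 0) observed / expected else NA_real_
  if (!testable) {
    return(list(observed = observed, expected = expected, total = total,
                fold = fold, chi_sq = NA_real_, p_value = NA_real_,
                significant = FALSE, testable = FALSE))
  }
  d <- abs(observed - expected)
  if (correct) d <- max(0, d - 0.5)
  chi_sq <- d^2 / expected + d^2 / (total - expected)
  p <- stats::pchisq(chi_sq, df = 1, lower.tail = FALSE)
  list(observed = observed, expected = expected, total = total, fold = fold,
       chi_sq = chi_sq, p_value = p, significant = p < alpha, testable = TRUE)
}

#' Per-chromosome enrichment report
#'
#' For each chromosome carrying at least one meSNP and at least one feature
#' base pair: merges the features, computes the expected count, and runs
#' [chi_square_enrichment()]. Chromosomes without features (or without
#' meSNPs) are omitted from the table. Only records classified `create`,
#' `destroy` or `displace` count as meSNPs.
#'
#' @param records Classified records from [scan_mesnps()].
#' @param features A `GRanges` of features (CGIs, DMRs, ...).
#' @param genome A `DNAStringSet`; supplies chromosome lengths.
#' @param alpha Significance level.
#' @param correct Continuity correction, passed through.
#' @return List with `table` (one row per testable chromosome: `chrom`,
#'   `n_mesnps`, `feature_bp`, `chrom_length`, `observed`, `expected`,
#'   `fold`, `chi_sq`, `p_value`, `significant`) and `average_fold`, the
#'   unweighted mean of per-chromosome folds.
#' @export
enrichment_report <- function(records, features, genome, alpha = 0.01,
                              correct = FALSE) {
  mes <- records[records$class %in% c("create", "destroy", "displace"), ,
                 drop = FALSE]
  feat_bp <- merged_bp_per_chrom(features)
  merged <- GenomicRanges::reduce(features, ignore.strand = TRUE)
  lens <- genome_lengths(genome)
  rows <- list()
  for (ch in intersect(unique(mes$chrom), names(feat_bp))) {
    on_ch <- mes[mes$chrom == ch, , drop = FALSE]
    total <- nrow(on_ch)
    fb <- unname(feat_bp[[ch]])
    if (total == 0L || fb == 0) next
    if (!ch %in% names(lens)) stop("chromosome absent from genome: ", ch)
    obs <- sum(positions_in_intervals(
      on_ch$chrom, on_ch$pos,
      merged[as.character(GenomicRanges::seqnames(merged)) == ch]))
    e <- expected_count(total, fb, lens[[ch]])
    r <- chi_square_enrichment(obs, e, total, alpha = alpha, correct = correct)
    rows[[ch]] <- data.frame(
      chrom = ch, n_mesnps = total, feature_bp = fb,
      chrom_length = lens[[ch]], observed = r$observed, expected = r$expected,
      fold = r$fold, chi_sq = r$chi_sq, p_value = r$p_value,
      significant = r$significant, stringsAsFactors = FALSE
    )
  }
  tab <- if (length(rows) > 0) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame()
  list(table = tab,
       average_fold = if (nrow(tab) > 0) mean(tab$fold, na.rm = TRUE)
                      else NA_real_)
}
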