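#' Construct a sample group
#'
#' A named group of samples with one methylation peak set (a `GRanges`) per
#' sample. Sample order fixes the column order expected in genotype matrices.
#'
#' @param name Group label (e.g. `"HFE"`, `"LFE"`).
#' @param sample_ids Character vector of sample identifiers.
#' @param peaks Named list (or `GRangesList`) of per-sample peak `GRanges`,
#'   aligned with `sample_ids`; may be `NULL` for genotype-only use.
#' @return A list of class `sample_group`.
#' @export
sample_group <- function(name, sample_ids, peaks = NULL) {
  stopifnot(is.character(name), length(name) == 1L, length(sample_ids) >= 1L)
  if (!is.null(peaks)) {
    stopifnot(length(peaks) == length(sample_ids))
    names(peaks) <- sample_ids
  }
  structure(list(name = name, sample_ids = sample_ids, peaks = peaks),
            class = "sample_group")
}

#' Group-specific methylation regions from per-sample peaks
#'
#' A region is specific to one group when, base by base, it is covered by
#' peaks in at least `min_present` of that group's samples and by no peak in
#' any sample of the other group. The emitted region is the intersection of
#' the supporting samples' overlapping peaks (realized as the run of bases
#' with support >= `min_present`); any candidate sharing even one base with an
#' other-group peak is discarded whole, which makes the rule antisymmetric.
#'
#' @param group_a,group_b [sample_group()] objects with peak sets.
#' @param min_present Minimum number of supporting samples (default 3, the
#'   3-of-4 rule).
#' @return A `GRanges` with a `group` metadata column naming the group each
#'   region is specific to.
#' @export
group_specific_peaks <- function(group_a, group_b, min_present = 3L) {
  one_way <- function(g_in, g_out) {
    if (min_present > length(g_in$sample_ids)) {
      stop("min_present (", min_present, ") exceeds group size (",
           length(g_in$sample_ids), ") for group ", g_in$name)
    }
    per_sample <- lapply(g_in$peaks, function(p)
      GenomicRanges::reduce(p, ignore.strand = TRUE))
    cov <- GenomicRanges::coverage(suppressWarnings(
      do.call(c, unname(lapply(per_sample, GenomicRanges::granges)))))
    if (length(cov) == 0L) return(GenomicRanges::GRanges())
    irl <- IRanges::slice(cov, lower = min_present, rangesOnly = TRUE)
    if (sum(lengths(irl)) == 0L) return(GenomicRanges::GRanges())
    cand <- methods::as(irl, "GRanges")
    other <- suppressWarnings(
      do.call(c, unname(lapply(g_out$peaks, GenomicRanges::granges))))
    cand <- cand[!IRanges::overlapsAny(cand, other,
                                             ignore.strand = TRUE)]
    if (length(cand) > 0L) cand$group <- g_in$name
    cand
  }
  res <- suppressWarnings(c(one_way(group_a, group_b),
                            one_way(group_b, group_a)))
  sort(res, ignore.strand = TRUE)
}

#' Number of genotype-vector combinations
#'
#' With `n_states` possible diploid genotype calls per sample (missing,
#' hom-ref, het, hom-alt), `n_states ^ n_samples` distinct genotype vectors
#' exist for a group.
#'
#' @param n_samples Samples per group.
#' @param n_states Genotype states per sample (default 4).
#' @return Count of combinations (e.g. 256 for 4 samples x 4 states).
#' @export
enumerate_genotype_states <- function(n_samples, n_states = 4L) {
  stopifnot(n_samples >= 1L, n_states >= 1L)
  n_states^n_samples
}

#' Genotype vectors with at least k non-missing calls
#'
#' Exact enumeration over all `n_states ^ n_samples` vectors, counting those
#' in which at least `min_called` samples carry a non-missing genotype (one of
#' the `n_states` states is "missing").
#'
#' @param n_samples Samples per group.
#' @param min_called Minimum non-missing calls.
#' @param n_states Genotype states per sample, including missing.
#' @return Count of qualifying vectors (189 for 4 samples, >= 3 called).
#' @export
genotype_states_min_called <- function(n_samples, min_called,
                                       n_states = 4L) {
  stopifnot(n_samples >= 1L, n_states >= 2L, min_called >= 0L)
  grids <- expand.grid(rep(list(seq_len(n_states) - 1L), n_samples))
  # state 0 = missing; the others are called
  sum(rowSums(grids != 0L) >= min_called)
}

#' Per-group alternate-allele frequencies
#'
#' Frequencies are computed over non-missing genotypes only: each called
#' diploid sample contributes two alleles to the denominator and its
#' alternate-allele dose to the numerator. Vectorized over loci when given
#' matrices (loci in rows, samples in columns).
#'
#' @param g1,g2 Integer dose vectors (one locus) or matrices (loci x samples)
#'   with values 0/1/2 and `NA` for missing, for group 1 and group 2.
#' @return Data frame with one row per locus: `af_g1`, `af_g2`,
#'   `n_called_g1`, `n_called_g2`, `delta` (= af_g1 - af_g2), `abs_delta`,
#'   and `callable` (`FALSE` when either group has no called genotype; its
#'   frequencies are `NA`).
#' @examples
#' # hom-ref x3 + missing vs het x3 + missing: |delta| = 3/6 - 0/6 = 0.5
#' group_allele_frequencies(c(0, 0, 0, NA), c(1, 1, 1, NA))
#' @export
group_allele_frequencies <- function(g1, g2) {
  if (is.null(dim(g1))) g1 <- matrix(g1, nrow = 1)
  if (is.null(dim(g2))) g2 <- matrix(g2, nrow = 1)
  stopifnot(nrow(g1) == nrow(g2))
  n1 <- rowSums(!is.na(g1))
  n2 <- rowSums(!is.na(g2))
  af1 <- ifelse(n1 > 0, rowSums(g1, na.rm = TRUE) / (2 * n1), NA_real_)
  af2 <- ifelse(n2 > 0, rowSums(g2, na.rm = TRUE) / (2 * n2), NA_real_)
  data.frame(
    af_g1 = af1, af_g2 = af2, n_called_g1 = n1, n_called_g2 = n2,
    delta = af1 - af2, abs_delta = abs(af1 - af2),
    callable = n1 > 0 & n2 > 0
  )
}

#' Allele-frequency concordance filter
#'
#' A locus passes when both groups have at least `min_called` genotyped
#' samples and the absolute allele-frequency difference reaches
#' `min_abs_delta` (0.5 by default). Vectorized over the rows of `af`.
#'
#' @param af Data frame from [group_allele_frequencies()].
#' @param min_called Minimum called samples per group (default 3).
#' @param min_abs_delta Minimum |AF difference| (default 0.5).
#' @return Data frame with `pass` and `reason` (`""`, `"insufficient_calls"`
#'   or `"insufficient_delta"`; calls are checked first).
#' @export
concordance_filter <- function(af, min_called = 3L, min_abs_delta = 0.5) {
  enough_calls <- af$n_called_g1 >= min_called & af$n_called_g2 >= min_called
  enough_delta <- !is.na(af$abs_delta) & af$abs_delta >= min_abs_delta
  pass <- enough_calls & enough_delta
  reason <- ifelse(pass, "",
            ifelse(!enough_calls, "insufficient_calls", "insufficient_delta"))
  data.frame(pass = pass, reason = reason, stringsAsFactors = FALSE)
}

#' Compatibility of allele frequencies with the methylation phenotype
#'
#' The methylation-site-creating (MSC) allele is the alternate allele for a
#' `create` meSNP and the reference allele for a `destroy` meSNP. A candidate
#' is compatible when the MSC allele is at strictly higher frequency in the
#' hypermethylated group than in the other group (equivalently, the MSD
#' allele is higher in the hypomethylated group). Ties carry no signal and
#' are incompatible. `displace`/`none` classes are indeterminate (`NA`).
#'
#' @param class meSNP class label(s) (see [mesnp_classes()]).
#' @param af Data frame from [group_allele_frequencies()], same length.
#' @param hyper_group `"g1"` or `"g2"`: which group the region is
#'   hypermethylated in (recycled).
#' @return Logical vector: `TRUE` compatible, `FALSE` incompatible, `NA`
#'   indeterminate (non-create/destroy class or uncallable frequencies).
#' @export
methylation_compatibility <- function(class, af, hyper_group) {
  n <- max(length(class), nrow(af))
  class <- rep_len(class, n)
  hyper_group <- rep_len(hyper_group, n)
  stopifnot(all(hyper_group %in% c("g1", "g2")))
  # alternate-allele frequencies -> MSC-allele frequencies
  msc_g1 <- ifelse(class == "create", af$af_g1,
            ifelse(class == "destroy", 1 - af$af_g1, NA_real_))
  msc_g2 <- ifelse(class == "create", af$af_g2,
            ifelse(class == "destroy", 1 - af$af_g2, NA_real_))
  msc_hyper <- ifelse(hyper_group == "g1", msc_g1, msc_g2)
  msc_hypo <- ifelse(hyper_group == "g1", msc_g2, msc_g1)
  out <- msc_hyper > msc_hypo
  out[!af$callable | !class %in% c("create", "destroy")] <- NA
  out
}

#' Annotate candidates with overlapping QTL
#'
#' Fills a `qtl_hits` list column with the labels (`name` metadata column, or
#' `chrom:start-end` when unnamed) of every QTL interval covering each
#' candidate's position, under the same boundary rule as
#' [annotate_membership()].
#'
#' @param candidates Data frame with `chrom` and `pos` columns.
#' @param qtls A `GRanges` of QTL intervals, ideally with a `name` column.
#' @return `candidates` with a `qtl_hits` list column.
#' @export
qtl_overlap <- function(candidates, qtls) {
  labels <- if (!is.null(qtls$name)) as.character(qtls$name)
            else as.character(qtls)
  candidates$qtl_hits <- I(replicate(nrow(candidates), character(0),
                                     simplify = FALSE))
  if (nrow(candidates) == 0L || length(qtls) == 0L) return(candidates)
  q <- GenomicRanges::GRanges(candidates$chrom,
                              IRanges::IRanges(candidates$pos,
                                               candidates$pos))
  ov <- GenomicRanges::findOverlaps(q, qtls, ignore.strand = TRUE)
  hits <- split(labels[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
  for (k in names(hits)) {
    candidates$qtl_hits[[as.integer(k)]] <- unique(hits[[k]])
  }
  candidates
}

#' Candidate epigenetic polymorphisms within group-specific regions
#'
#' End-to-end concordance analysis: intersects classified meSNPs with
#' group-specific hypermethylated regions, computes per-group alternate-allele
#' frequencies from the genotype matrix, applies the concordance filter, and
#' assesses MSC/MSD methylation compatibility for every passing candidate.
#'
#' @param records Classified meSNPs from [scan_mesnps()] carrying a `gt` dose
#'   matrix column (see [read_snps()] with `keep_samples = TRUE`).
#' @param dmrs `GRanges` of group-specific regions with a `group` metadata
#'   column, as from [group_specific_peaks()].
#' @param groups Named character vector mapping sample id -> group name
#'   (exactly two groups).
#' @param hyper_in Which `groups` level is "group 1" for reporting; defaults
#'   to the first group name encountered.
#' @param min_called,min_abs_delta Concordance-filter thresholds.
#' @param tissue Optional tissue label copied to every row.
#' @return Data frame, one row per (meSNP, overlapping region) pair that
#'   passed the filter — columns: `tissue`, `chrom`, `pos`, `rsid`, `ref`,
#'   `alt`, `class`, `dmr` (region as `chrom:start-end`), `hyper_group`,
#'   `af_g1`, `af_g2`, `delta`, `abs_delta`, `status` (`compatible`,
#'   `incompatible` or `indeterminate`). Attribute `n_considered` counts the
#'   overlapping pairs before filtering.
#' @export
concordance_candidates <- function(records, dmrs, groups,
                                   hyper_in = NULL,
                                   min_called = 3L, min_abs_delta = 0.5,
                                   tissue = NA_character_) {
  stopifnot(!is.null(records$gt), !is.null(dmrs$group))
  gnames <- unique(groups)
  if (length(gnames) != 2L) stop("exactly two groups required")
  g1 <- if (is.null(hyper_in)) gnames[1] else hyper_in
  g2 <- setdiff(gnames, g1)
  gt <- records$gt
  s1 <- names(groups)[groups == g1]
  s2 <- names(groups)[groups == g2]
  if (!all(c(s1, s2) %in% colnames(gt))) {
    stop("genotype matrix lacks columns for some samples in `groups`")
  }

  q <- GenomicRanges::GRanges(records$chrom,
                              IRanges::IRanges(records$pos, records$pos))
  ov <- GenomicRanges::findOverlaps(q, dmrs, ignore.strand = TRUE)
  ri <- S4Vectors::queryHits(ov)
  di <- S4Vectors::subjectHits(ov)
  empty <- data.frame(
    tissue = character(0), chrom = character(0), pos = integer(0),
    rsid = character(0), ref = character(0), alt = character(0),
    class = character(0), dmr = character(0), hyper_group = character(0),
    af_g1 = numeric(0), af_g2 = numeric(0), delta = numeric(0),
    abs_delta = numeric(0), status = character(0), stringsAsFactors = FALSE
  )
  if (length(ri) == 0L) {
    attr(empty, "n_considered") <- 0L
    return(empty)
  }

  af <- group_allele_frequencies(gt[ri, s1, drop = FALSE],
                                 gt[ri, s2, drop = FALSE])
  filt <- concordance_filter(af, min_called = min_called,
                             min_abs_delta = min_abs_delta)
  hyper <- ifelse(as.character(dmrs$group[di]) == g1, "g1", "g2")
  compat <- methylation_compatibility(records$class[ri], af, hyper)
  status <- ifelse(is.na(compat), "indeterminate",
                   ifelse(compat, "compatible", "incompatible"))
  out <- data.frame(
    tissue = tissue, chrom = records$chrom[ri], pos = records$pos[ri],
    rsid = if (!is.null(records$rsid)) records$rsid[ri] else NA_character_,
    ref = records$ref[ri], alt = records$alt[ri], class = records$class[ri],
    dmr = paste0(as.character(GenomicRanges::seqnames(dmrs)[di]), ":",
                 GenomicRanges::start(dmrs)[di], "-",
                 GenomicRanges::end(dmrs)[di]),
    hyper_group = as.character(dmrs$group[di]),
    af_g1 = af$af_g1, af_g2 = af$af_g2, delta = af$delta,
    abs_delta = af$abs_delta, status = status, stringsAsFactors = FALSE
  )
  out <- out[filt$pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_considered") <- length(ri)
  out
}

#' Split candidates into a compatible / incompatible report
#'
#' Mirrors the published candidate-table layout: one section for meSNPs whose
#' allele frequencies are compatible with the methylation signal, one for
#' incompatible ones, and an appendix for indeterminate classes (displace).
#'
#' @param candidates Data frame from [concordance_candidates()].
#' @return List of data frames: `compatible`, `incompatible`,
#'   `indeterminate`.
#' @export
candidate_table <- function(candidates) {
  list(
    compatible = candidates[candidates$status == "compatible", ,
                            drop = FALSE],
    incompatible = candidates[candidates$status == "incompatible", ,
                              drop = FALSE],
    indeterminate = candidates[candidates$status == "indeterminate", ,
                               drop = FALSE]
  )
}
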