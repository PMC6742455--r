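#' Specification for a synthetic fixture dataset
#'
#' Describes a fully synthetic dataset shaped like the intended study design:
#' a small multi-chromosome genome with planted CpG islands, SNPs of every
#' meSNP class at known positions, and two phenotype groups of diploid
#' samples (4 per group by default) with per-sample methylation peak sets and
#' planned alternate-allele frequency differences at concordance loci. A
#' single integer seed makes every derived artifact reproducible
#' byte-for-byte.
#'
#' @param seed Integer seed governing all randomness.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param gc_background Background GC fraction; keep well below 0.5 so no
#'   spurious islands arise (a uniform random sequence has an
#'   observed/expected CpG ratio near 1, leaving GC content as the only
#'   binding island criterion).
#' @param islands_per_chrom Planted islands per chromosome.
#' @param island_lengths Lengths (bp) recycled across planted islands.
#' @param island_cpg_density Probability that an island position starts a CG
#'   dinucleotide during construction.
#' @param snp_counts Named counts of planted SNPs per class
#'   (`create`/`destroy`/`displace`/`none`).
#' @param n_per_group Samples per phenotype group.
#' @param group_names Two group labels.
#' @param n_compatible,n_incompatible Planted concordance meSNPs whose allele
#'   frequencies are compatible / incompatible with the methylation signal.
#' @param region_length Length (bp) of each planted group-specific region.
#' @param missing_rate Per-genotype missing probability at non-concordance
#'   loci (concordance loci keep exact planned genotypes).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_chroms = 2L, chrom_length = 50000L,
                         gc_background = 0.30, islands_per_chrom = 2L,
                         island_lengths = c(400L, 600L),
                         island_cpg_density = 0.30,
                         snp_counts = c(create = 10L, destroy = 10L,
                                        displace = 5L, none = 5L),
                         n_per_group = 4L,
                         group_names = c("HFE", "LFE"),
                         n_compatible = 3L, n_incompatible = 2L,
                         region_length = 300L, missing_rate = 0) {
  stopifnot(length(group_names) == 2L, n_per_group >= 1L,
            chrom_length >= 1000L, gc_background > 0, gc_background < 1,
            all(names(snp_counts) %in% mesnp_classes()))
  structure(list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length),
    gc_background = gc_background,
    islands_per_chrom = as.integer(islands_per_chrom),
    island_lengths = as.integer(island_lengths),
    island_cpg_density = island_cpg_density,
    snp_counts = snp_counts, n_per_group = as.integer(n_per_group),
    group_names = group_names, n_compatible = as.integer(n_compatible),
    n_incompatible = as.integer(n_incompatible),
    region_length = as.integer(region_length),
    missing_rate = missing_rate
  ), class = "fixture_spec")
}

# sample a free interval of `len` bp on a chromosome, at least `margin` bp
# away from every interval in `occupied` (data frame chrom/start/end)
.place_interval <- function(chrom, len, chrom_len, occupied, margin = 10L) {
  for (i in seq_len(5000L)) {
    s <- sample.int(chrom_len - len - 2L, 1L) + 1L
    e <- s + len - 1L
    occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
    if (nrow(occ) == 0L ||
        all(e + margin < occ$start | s - margin > occ$end)) {
      return(c(start = s, end = e))
    }
  }
  stop("could not place an interval of length ", len, " on ", chrom,
       "; genome too crowded")
}

# build an island sequence satisfying the relaxed criteria by construction
.island_seq <- function(len, cpg_density) {
  repeat {
    units <- character(0)
    total <- 0L
    while (total < len) {
      if (stats::runif(1) < cpg_density) {
        units <- c(units, "CG"); total <- total + 2L
      } else {
        units <- c(units, sample(c("C", "G", "A", "T"),
                                 1L, prob = c(0.3, 0.3, 0.2, 0.2)))
        total <- total + 1L
      }
    }
    s <- substr(paste(units, collapse = ""), 1L, len)
    st <- window_stats(s)
    if (st$gc_fraction >= 0.5 && st$obs_exp >= 0.6) return(s)
  }
}

#' Generate a synthetic genome with planted CpG islands
#'
#' Background sequence is drawn i.i.d. at `gc_background`; island segments
#' are constructed to satisfy the relaxed island criteria (length, GC,
#' observed/expected) and spliced in at randomly chosen non-overlapping
#' locations.
#'
#' @param spec A [fixture_spec()].
#' @return List with `genome` (a `DNAStringSet`) and `islands` (truth
#'   `GRanges`, 1-based closed).
#' @export
make_genome <- function(spec) {
  set.seed(spec$seed)
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  p <- spec$gc_background
  seqs <- lapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE,
                 prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2)),
          collapse = "")
  })
  names(seqs) <- chroms
  occupied <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  lens <- rep_len(spec$island_lengths,
                  spec$islands_per_chrom * spec$n_chroms)
  truth <- list()
  k <- 0L
  for (ch in chroms) {
    for (j in seq_len(spec$islands_per_chrom)) {
      k <- k + 1L
      len <- lens[k]
      at <- .place_interval(ch, len, spec$chrom_length, occupied,
                            margin = 250L)
      isl <- .island_seq(len, spec$island_cpg_density)
      substr(seqs[[ch]], at["start"], at["end"]) <- isl
      occupied <- rbind(occupied, data.frame(
        chrom = ch, start = at[["start"]], end = at[["end"]],
        stringsAsFactors = FALSE))
      truth[[k]] <- data.frame(chrom = ch, start = at[["start"]],
                               end = at[["end"]], stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  islands <- if (is.null(truth) || nrow(truth) == 0L) GenomicRanges::GRanges()
    else GenomicRanges::GRanges(truth$chrom,
                                IRanges::IRanges(truth$start, truth$end))
  list(genome = Biostrings::DNAStringSet(unlist(seqs)), islands = islands)
}

# trinucleotide templates guaranteeing each class (outer bases cannot change
# the class: every CpG affected by the substitution contains the centre base)
.class_templates <- list(
  create = list(tri = "CAT", ref = "A", alt = "G"),
  destroy = list(tri = "TCG", ref = "C", alt = "T"),
  displace = list(tri = "CGG", ref = "G", alt = "C"),
  none = list(tri = "TAT", ref = "A", alt = "T")
)

#' Plant SNPs of known meSNP class in a synthetic genome
#'
#' For each requested class the genome context is first edited to a template
#' trinucleotide that forces the class, then the SNP is recorded, so the
#' emitted reference is always self-consistent with the truth table. SNPs are
#' kept clear of planted islands and of each other.
#'
#' @param genome_obj List from [make_genome()].
#' @param spec A [fixture_spec()].
#' @return List with `genome` (edited `DNAStringSet`), `islands` (unchanged
#'   truth), and `snps` (data frame `chrom`, `pos`, `ref`, `alt`, `rsid`,
#'   `class_truth`).
#' @export
make_snps <- function(genome_obj, spec) {
  set.seed(spec$seed + 1L)
  seqs <- as.list(as.character(genome_obj$genome))
  chroms <- names(seqs)
  occupied <- as.data.frame(genome_obj$islands)[, c("seqnames", "start", "end")]
  names(occupied) <- c("chrom", "start", "end")
  occupied$chrom <- as.character(occupied$chrom)
  rows <- list()
  n_total <- sum(spec$snp_counts)
  if (n_total > 0 && spec$chrom_length < 50 * n_total / spec$n_chroms) {
    stop("genome too small for the requested number of planted SNPs")
  }
  i <- 0L
  for (cl in names(spec$snp_counts)) {
    tpl <- .class_templates[[cl]]
    if (is.null(tpl)) stop("cannot plant class: ", cl)
    for (j in seq_len(spec$snp_counts[[cl]])) {
      i <- i + 1L
      ch <- sample(chroms, 1L)
      at <- .place_interval(ch, 3L, spec$chrom_length, occupied, margin = 5L)
      substr(seqs[[ch]], at["start"], at["end"]) <- tpl$tri
      occupied <- rbind(occupied, data.frame(
        chrom = ch, start = at[["start"]], end = at[["end"]],
        stringsAsFactors = FALSE))
      rows[[i]] <- data.frame(
        chrom = ch, pos = at[["start"]] + 1L, ref = tpl$ref, alt = tpl$alt,
        rsid = sprintf("sim%04d", i), class_truth = cl,
        stringsAsFactors = FALSE)
    }
  }
  snps <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), rsid = character(0),
               class_truth = character(0), stringsAsFactors = FALSE)
  snps <- snps[order(match(snps$chrom, chroms), snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  list(genome = Biostrings::DNAStringSet(unlist(seqs)),
       islands = genome_obj$islands, snps = snps)
}

# exact dose vector for n diploid samples hitting allele frequency af
# (af * 2n must be an integer); hom-alt first, then one het
.exact_doses <- function(af, n) {
  alleles <- round(af * 2 * n)
  stopifnot(abs(alleles - af * 2 * n) < 1e-9)
  doses <- integer(n)
  k <- 1L
  while (alleles >= 2L && k <= n) { doses[k] <- 2L; alleles <- alleles - 2L; k <- k + 1L }
  if (alleles == 1L) { doses[k] <- 1L; alleles <- 0L }
  doses
}

#' Generate a genotyped cohort with group-specific methylation peaks
#'
#' Extends a planted-SNP fixture with the study's cohort structure: two
#' phenotype groups of diploid samples, per-sample methylation peak sets, and
#' concordance meSNPs planted inside group-specific regions.
#'
#' Planted region types per group-specific truth region: a peak present in
#' exactly `min(3, n)` samples of one group and absent from the other (so the
#' 3-of-4 rule recovers it exactly). Decoy regions — one peak shared by every
#' sample of both groups, one supported by too few samples, and one present
#' in all samples of one group but also one sample of the other — must all be
#' rejected by [group_specific_peaks()].
#'
#' Each truth region hosts one planted `create` or `destroy` meSNP whose
#' exact genotypes realize planned per-group alternate-allele frequencies:
#' compatible candidates put the CpG-forming allele at frequency 1 in the
#' hypermethylated group and 0 in the other; incompatible candidates reverse
#' the pattern. Non-concordance loci receive random genotypes (alt frequency
#' 0.3) thinned by `missing_rate`.
#'
#' @param snps_obj List from [make_snps()].
#' @param spec A [fixture_spec()].
#' @return List with `genome` (edited), `islands`, `snps` (planted + planted
#'   concordance SNPs, with `class_truth` and `status_truth`), `gt` (dose
#'   matrix, loci x samples), `samples`, `groups` (named vector sample ->
#'   group), `group_a`/`group_b` ([sample_group()] objects with peak sets),
#'   `regions_truth` (`GRanges` with `group`), and `candidates_truth`.
#' @export
make_cohort <- function(snps_obj, spec) {
  set.seed(spec$seed + 2L)
  seqs <- as.list(as.character(snps_obj$genome))
  chroms <- names(seqs)
  ga <- spec$group_names[1]
  gb <- spec$group_names[2]
  n <- spec$n_per_group
  samples_a <- paste0(ga, "_", seq_len(n))
  samples_b <- paste0(gb, "_", seq_len(n))
  samples <- c(samples_a, samples_b)
  groups <- stats::setNames(rep(c(ga, gb), each = n), samples)

  occupied <- as.data.frame(snps_obj$islands)[, c("seqnames", "start", "end")]
  names(occupied) <- c("chrom", "start", "end")
  occupied$chrom <- as.character(occupied$chrom)
  if (nrow(snps_obj$snps) > 0) {
    occupied <- rbind(occupied, data.frame(
      chrom = snps_obj$snps$chrom, start = snps_obj$snps$pos - 1L,
      end = snps_obj$snps$pos + 1L, stringsAsFactors = FALSE))
  }

  n_regions <- spec$n_compatible + spec$n_incompatible
  status <- c(rep("compatible", spec$n_compatible),
              rep("incompatible", spec$n_incompatible))
  region_group <- rep(c(ga, gb), length.out = n_regions)
  classes <- rep(c("create", "destroy"), length.out = n_regions)

  regions <- list()
  cand_rows <- list()
  extra_snps <- list()
  gt_cand <- list()
  n_support <- min(3L, n)
  for (r in seq_len(n_regions)) {
    ch <- sample(chroms, 1L)
    at <- .place_interval(ch, spec$region_length, spec$chrom_length,
                          occupied, margin = 50L)
    occupied <- rbind(occupied, data.frame(
      chrom = ch, start = at[["start"]], end = at[["end"]],
      stringsAsFactors = FALSE))
    regions[[r]] <- data.frame(chrom = ch, start = at[["start"]],
                               end = at[["end"]], group = region_group[r],
                               stringsAsFactors = FALSE)
    # plant the concordance meSNP mid-region
    tpl <- .class_templates[[classes[r]]]
    mid <- at[["start"]] + spec$region_length %/% 2L
    substr(seqs[[ch]], mid - 1L, mid + 1L) <- tpl$tri
    extra_snps[[r]] <- data.frame(
      chrom = ch, pos = mid, ref = tpl$ref, alt = tpl$alt,
      rsid = sprintf("simdmr%02d", r), class_truth = classes[r],
      stringsAsFactors = FALSE)
    # planned alternate-allele frequencies: MSC allele fixed in the
    # hypermethylated group for compatible candidates, inverted otherwise
    msc_is_alt <- classes[r] == "create"
    af_hyper_alt <- if (status[r] == "compatible") {
      if (msc_is_alt) 1 else 0
    } else {
      if (msc_is_alt) 0 else 1
    }
    af_other_alt <- 1 - af_hyper_alt
    af_a <- if (region_group[r] == ga) af_hyper_alt else af_other_alt
    af_b <- if (region_group[r] == ga) af_other_alt else af_hyper_alt
    gt_cand[[r]] <- c(.exact_doses(af_a, n), .exact_doses(af_b, n))
    cand_rows[[r]] <- data.frame(
      chrom = ch, pos = mid, class = classes[r], hyper_group = region_group[r],
      af_alt_g1 = af_a, af_alt_g2 = af_b, status_truth = status[r],
      stringsAsFactors = FALSE)
  }
  regions <- do.call(rbind, regions)
  candidates_truth <- do.call(rbind, cand_rows)
  extra_snps <- do.call(rbind, extra_snps)

  # assemble genotype matrix: planted class SNPs get random genotypes
  base_snps <- snps_obj$snps
  n_base <- nrow(base_snps)
  gt <- matrix(NA_integer_, nrow = n_base + n_regions, ncol = 2L * n,
               dimnames = list(NULL, samples))
  if (n_base > 0) {
    g <- matrix(stats::rbinom(n_base * 2L * n, 2L, 0.3),
                nrow = n_base, ncol = 2L * n)
    if (spec$missing_rate > 0) {
      g[stats::runif(length(g)) < spec$missing_rate] <- NA_integer_
    }
    gt[seq_len(n_base), ] <- g
  }
  for (r in seq_len(n_regions)) gt[n_base + r, ] <- gt_cand[[r]]

  base_snps$status_truth <- rep(NA_character_, n_base)
  extra_snps$status_truth <- status
  all_snps <- rbind(base_snps, extra_snps)
  ord <- order(match(all_snps$chrom, chroms), all_snps$pos)
  all_snps <- all_snps[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  rownames(all_snps) <- NULL

  regions_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end),
    group = regions$group)

  # peak sets: supporting samples carry the region verbatim
  peaks <- stats::setNames(
    replicate(2L * n, GenomicRanges::GRanges(), simplify = FALSE), samples)
  add_peak <- function(sids, ch, s, e) {
    for (sid in sids) {
      peaks[[sid]] <<- suppressWarnings(
        c(peaks[[sid]], GenomicRanges::GRanges(ch, IRanges::IRanges(s, e))))
    }
  }
  for (r in seq_len(n_regions)) {
    sup <- if (regions$group[r] == ga) samples_a else samples_b
    add_peak(sup[seq_len(n_support)], regions$chrom[r], regions$start[r],
             regions$end[r])
  }
  # decoys: shared everywhere; under-supported; leaking into the other group
  decoy <- function(len) {
    at <- .place_interval(chroms[1], len, spec$chrom_length, occupied,
                          margin = 50L)
    occupied <<- rbind(occupied, data.frame(
      chrom = chroms[1], start = at[["start"]], end = at[["end"]],
      stringsAsFactors = FALSE))
    at
  }
  d1 <- decoy(spec$region_length)
  add_peak(samples, chroms[1], d1[["start"]], d1[["end"]])
  if (n >= 3L) {
    d2 <- decoy(spec$region_length)
    add_peak(samples_a[seq_len(n_support - 1L)], chroms[1],
             d2[["start"]], d2[["end"]])
  }
  d3 <- decoy(spec$region_length)
  add_peak(c(samples_a, samples_b[1]), chroms[1], d3[["start"]], d3[["end"]])

  list(
    genome = Biostrings::DNAStringSet(unlist(seqs)),
    islands = snps_obj$islands,
    snps = all_snps, gt = gt, samples = samples, groups = groups,
    group_a = sample_group(ga, samples_a, peaks[samples_a]),
    group_b = sample_group(gb, samples_b, peaks[samples_b]),
    regions_truth = sort(regions_gr, ignore.strand = TRUE),
    candidates_truth = candidates_truth
  )
}

#' Generate a complete seeded fixture, optionally writing files
#'
#' Runs [make_genome()], [make_snps()] and [make_cohort()] and, when `outdir`
#' is given, writes `genome.fa`, `snps.vcf` (with GT columns), one
#' `peaks_<sample>.bed` per sample, `groups.tsv`, `islands_truth.bed`,
#' `regions_truth.bed` and `snps_truth.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Optional output directory (created if needed).
#' @return The [make_cohort()] list, with a `paths` element when written.
#' @export
make_fixture <- function(spec = fixture_spec(), outdir = NULL) {
  fx <- make_cohort(make_snps(make_genome(spec), spec), spec)
  fx$spec <- spec
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(outdir, "genome.fa"),
      vcf = file.path(outdir, "snps.vcf"),
      groups = file.path(outdir, "groups.tsv"),
      islands = file.path(outdir, "islands_truth.bed"),
      regions = file.path(outdir, "regions_truth.bed"),
      truth = file.path(outdir, "snps_truth.tsv")
    )
    Biostrings::writeXStringSet(fx$genome, paths$fasta)
    write_snp_vcf(fx$snps, paths$vcf, gt = fx$gt, samples = fx$samples)
    utils::write.table(
      data.frame(sample_id = names(fx$groups), group = unname(fx$groups)),
      paths$groups, sep = "\t", quote = FALSE, row.names = FALSE)
    write_intervals(fx$islands, paths$islands)
    rt <- fx$regions_truth
    rt$name <- rt$group
    write_intervals(rt, paths$regions)
    utils::write.table(fx$snps, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$peaks <- character(0)
    for (sid in fx$samples) {
      p <- file.path(outdir, paste0("peaks_", sid, ".bed"))
      pk <- if (sid %in% fx$group_a$sample_ids) fx$group_a$peaks[[sid]]
            else fx$group_b$peaks[[sid]]
      write_intervals(pk, p)
      paths$peaks <- c(paths$peaks, p)
    }
    fx$paths <- paths
  }
  fx
}

#' Draw diploid genotype doses at planned allele frequencies
#'
#' Samples alternate-allele doses `Binomial(2, af)` independently per sample
#' and locus, then masks genotypes missing at `missing_rate`, so realized
#' group allele frequencies match the planned values in expectation. For
#' exact planned frequencies (used at planted concordance loci) the fixture
#' generator allocates doses deterministically instead.
#'
#' @param af Planned alternate-allele frequency in `[0, 1]`.
#' @param n_samples Samples (columns).
#' @param n_loci Loci (rows).
#' @param missing_rate Per-genotype missing probability.
#' @return Integer dose matrix (`n_loci` x `n_samples`) with `NA` = missing.
#' @export
simulate_genotypes <- function(af, n_samples, n_loci = 1L,
                               missing_rate = 0) {
  stopifnot(af >= 0, af <= 1, missing_rate >= 0, missing_rate < 1)
  g <- matrix(stats::rbinom(n_loci * n_samples, 2L, af),
              nrow = n_loci, ncol = n_samples)
  if (missing_rate > 0) {
    g[stats::runif(length(g)) < missing_rate] <- NA_integer_
  }
  g
}

#' Write SNPs (and optional genotypes) as a minimal VCF
#'
#' Emits a valid VCFv4.2 file with CHROM/POS/ID/REF/ALT columns and, when a
#' dose matrix is supplied, a GT FORMAT field (`0/0`, `0/1`, `1/1`, `./.`).
#' Intended for fixture emission; reading goes through [read_snps()].
#'
#' @param snps Data frame with `chrom`, `pos`, `ref`, `alt`, optional `rsid`.
#' @param path Output path.
#' @param gt Optional integer dose matrix (loci x samples; `NA` = missing).
#' @param samples Sample names (defaults to `colnames(gt)`).
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path, gt = NULL, samples = colnames(gt)) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mesnp-fixture",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  id <- if (!is.null(snps$rsid)) ifelse(is.na(snps$rsid), ".", snps$rsid)
        else rep(".", nrow(snps))
  body <- paste(snps$chrom, snps$pos, id, snps$ref, snps$alt, ".", "PASS",
                ".", sep = "\t")
  if (!is.null(gt)) {
    stopifnot(nrow(gt) == nrow(snps))
    gt_str <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nrow(gt))
    gt_str[is.na(gt)] <- "./."
    cols <- c(cols, "FORMAT", samples)
    body <- paste(body, "GT", apply(gt_str, 1L, paste, collapse = "\t"),
                  sep = "\t")
  }
  writeLines(c(header, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}
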