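gr1 <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))

make_groups <- function(a_peaks, b_peaks) {
  list(
    a = sample_group("A", paste0("a", seq_along(a_peaks)), a_peaks),
    b = sample_group("B", paste0("b", seq_along(b_peaks)), b_peaks)
  )
}

test_that("group-specific peaks follow the 3-of-4 presence/absence rule", {
  empty <- GenomicRanges::GRanges()
  pk <- gr1(101, 300)
  # present in 3/4 of A, absent in B -> emitted as the supported intersection
  g <- make_groups(list(pk, pk, pk, empty), list(empty, empty, empty, empty))
  out <- group_specific_peaks(g$a, g$b, min_present = 3)
  expect_length(out, 1L)
  expect_identical(as.character(out), "chr1:101-300")
  expect_identical(out$group, "A")

  # only 2/4 -> nothing
  g2 <- make_groups(list(pk, pk, empty, empty), list(empty, empty, empty, empty))
  expect_length(group_specific_peaks(g2$a, g2$b, 3), 0L)

  # 4/4 in A but 1/4 in B -> absence rule rejects it
  g3 <- make_groups(list(pk, pk, pk, pk), list(pk, empty, empty, empty))
  expect_length(group_specific_peaks(g3$a, g3$b, 3), 0L)

  # staggered peaks: emitted region is the bp-level intersection
  g4 <- make_groups(list(gr1(101, 250), gr1(150, 300), gr1(120, 280), empty),
                    list(empty, empty, empty, empty))
  out4 <- group_specific_peaks(g4$a, g4$b, 3)
  expect_identical(as.character(out4), "chr1:150-250")

  expect_error(group_specific_peaks(g$a, g$b, min_present = 5),
               "exceeds group size")
})

test_that("group-specific peaks are antisymmetric and monotone in min_present", {
  set.seed(61)
  for (rep in 1:10) {
    mk <- function() {
      n <- sample(0:3, 1)
      if (n == 0) return(GenomicRanges::GRanges())
      s <- sample.int(2000, n)
      gr1(s, s + sample.int(300, n))
    }
    g <- make_groups(replicate(4, mk()), replicate(4, mk()))
    r2 <- group_specific_peaks(g$a, g$b, 2)
    r3 <- group_specific_peaks(g$a, g$b, 3)
    r4 <- group_specific_peaks(g$a, g$b, 4)
    # no region claimed by both groups
    a_regs <- r2[r2$group == "A"]
    b_regs <- r2[r2$group == "B"]
    expect_false(any(IRanges::overlapsAny(a_regs, b_regs)))
    # raising the support threshold never adds covered bases
    width_of <- function(x) sum(GenomicRanges::width(x))
    expect_lte(width_of(r3), width_of(r2))
    expect_lte(width_of(r4), width_of(r3))
  }
})

test_that("genotype-state enumeration is exact", {
  expect_identical(enumerate_genotype_states(4, 4), 256)
  expect_identical(enumerate_genotype_states(1, 4), 4)
  # exact enumeration: 3^4 fully called + 4 * 3^3 with one missing
  expect_identical(genotype_states_min_called(4, 3), 189L)
  expect_identical(genotype_states_min_called(4, 3) -
                     genotype_states_min_called(4, 4), 108L)
  expect_identical(genotype_states_min_called(4, 0), 256L)
})

test_that("group allele frequencies use called genotypes only", {
  # hom_ref x3 + missing vs het x3 + missing
  af1 <- group_allele_frequencies(c(0, 0, 0, NA), c(1, 1, 1, NA))
  expect_equal(af1$af_g1, 0)
  expect_equal(af1$af_g2, 3 / 6)
  expect_equal(af1$abs_delta, 0.5)
  expect_identical(af1$n_called_g1, 3)

  # hom_alt, het, hom_alt, hom_alt vs hom_ref x3, het
  af2 <- group_allele_frequencies(c(2, 1, 2, 2), c(0, 0, 0, 1))
  expect_equal(af2$delta, 7 / 8 - 1 / 8)

  expect_equal(group_allele_frequencies(c(0, 1, 2), c(0, 1, 2))$delta, 0)

  # all-missing group flagged uncallable
  af3 <- group_allele_frequencies(c(NA, NA), c(1, 1))
  expect_false(af3$callable)
  expect_true(is.na(af3$af_g1))

  # invariant to sample order within a group
  set.seed(71)
  g1 <- sample(c(0:2, NA), 8, TRUE)
  g2 <- sample(c(0:2, NA), 8, TRUE)
  a <- group_allele_frequencies(g1, g2)
  b <- group_allele_frequencies(sample(g1), sample(g2))
  expect_equal(a$delta, b$delta)

  # swapping groups negates delta, preserves abs_delta
  sw <- group_allele_frequencies(g2, g1)
  expect_equal(sw$delta, -a$delta)
  expect_equal(sw$abs_delta, a$abs_delta)
})

test_that("concordance filter applies call and delta thresholds", {
  af <- group_allele_frequencies(
    rbind(c(0, 0, 0, NA), c(0.49 * 0, 0, 0, 0), c(2, 2, NA, NA)),
    rbind(c(1, 1, 1, NA), c(1, 1, 1, 0.02 * 0), c(0, 0, 0, 0)))
  af$abs_delta[2] <- 0.49 # boundary probe just below threshold
  out <- concordance_filter(af)
  expect_true(out$pass[1])
  expect_identical(out$reason[1], "")
  expect_false(out$pass[2])
  expect_identical(out$reason[2], "insufficient_delta")
  expect_false(out$pass[3]) # abs_delta 1.0 but only 2 called in g1
  expect_identical(out$reason[3], "insufficient_calls")
})

test_that("methylation compatibility follows the MSC/MSD allele rule", {
  af <- group_allele_frequencies(rbind(c(2, 2, 2, 1), c(1, 1, 0, 0),
                                       c(0, 0, 0, 0), c(1, 1, 1, 1)),
                                 rbind(c(0, 0, 1, 0), c(0, 0, 0, 0),
                                       c(2, 2, 1, 2), c(1, 1, 1, 1)))
  # create: MSC = alt at 0.875 in hyper g1 vs 0.125 -> compatible
  expect_true(methylation_compatibility("create", af[1, ], "g1"))
  # create with the alt allele frequent in the hypomethylated group
  expect_false(methylation_compatibility("create", af[2, ], "g2"))
  # destroy: MSC = ref, ref frequency higher in hyper group -> compatible
  expect_true(methylation_compatibility("destroy", af[3, ], "g1"))
  # ties carry no signal
  expect_false(methylation_compatibility("create", af[4, ], "g1"))
  # displace is indeterminate
  expect_true(is.na(methylation_compatibility("displace", af[1, ], "g1")))
  # swapping group labels together with hyper_group preserves the verdict
  af_sw <- group_allele_frequencies(rbind(c(0, 0, 1, 0)),
                                    rbind(c(2, 2, 2, 1)))
  expect_true(methylation_compatibility("create", af_sw, "g2"))
})

test_that("QTL overlap fills hit labels under the half-open boundary rule", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tFE_QTL1", "chr1\t150\t400\tFE_QTL2"), bed)
  qtls <- read_intervals(bed)
  cand <- data.frame(chrom = "chr1", pos = c(101L, 180L, 100L, 500L),
                     stringsAsFactors = FALSE)
  cand <- qtl_overlap(cand, qtls)
  expect_identical(cand$qtl_hits[[1]], "FE_QTL1")
  expect_identical(sort(cand$qtl_hits[[2]]), c("FE_QTL1", "FE_QTL2"))
  expect_length(cand$qtl_hits[[3]], 0L) # pos 100 = offset 99, outside
  expect_length(cand$qtl_hits[[4]], 0L)
})

test_that("candidate table routes planted fixture candidates to sections", {
  fx <- make_fixture(fixture_spec(seed = 13, n_compatible = 4L,
                                  n_incompatible = 3L))
  rec <- scan_mesnps(fx$snps, fx$genome)
  rec$gt <- fx$gt
  regions <- group_specific_peaks(fx$group_a, fx$group_b, 3)
  expect_identical(as.character(regions), as.character(fx$regions_truth))
  expect_identical(regions$group, fx$regions_truth$group)

  cand <- concordance_candidates(rec, regions, fx$groups,
                                 hyper_in = fx$spec$group_names[1])
  tab <- candidate_table(cand)
  expect_identical(nrow(tab$compatible), 4L)
  expect_identical(nrow(tab$incompatible), 3L)
  expect_identical(nrow(tab$indeterminate), 0L)
  truth <- fx$candidates_truth
  got <- cand[match(truth$pos, cand$pos), ]
  expect_identical(got$status, truth$status_truth)
  expect_equal(got$af_g1, truth$af_alt_g1)
  expect_equal(got$af_g2, truth$af_alt_g2)
})
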