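test_that("FASTA loading uppercases, preserves order, and bounds-checks", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgt", ">chr2", "NNCG"), fa)
  g <- load_genome(fa)
  expect_identical(names(g), c("chr1", "chr2"))
  expect_identical(genome_base(g, "chr1", 2), "C")
  expect_identical(genome_base(g, "chr2", 1:2), c("N", "N"))
  expect_error(genome_base(g, "chr1", 5), "out of range")
  expect_error(genome_base(g, "chr3", 1), "unknown chromosome")
  expect_identical(unname(genome_lengths(g)), c(4L, 4L))

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr1", "ACGT"), dup)
  expect_error(load_genome(dup), "duplicate")
})

test_that("coordinate law: 1-based accessor matches 0-based string offset", {
  fa <- tempfile(fileext = ".fa")
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  writeLines(c(">c1", s), fa)
  g <- load_genome(fa)
  pos <- sample.int(200, 50)
  raw <- strsplit(s, "")[[1]]
  expect_identical(genome_base(g, "c1", pos), raw[(pos - 1) + 1])
})

test_that("VCF reading splits multi-allelics and drops INDELs with counts", {
  f <- write_tmp_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t10\trs1\tC\tT\t.\tPASS\t.",
    "chr1\t20\t.\tC\tT,G\t.\tPASS\t.",
    "chr1\t30\t.\tCA\tC\t.\tPASS\t.",
    "chr1\t40\t.\tG\tGTT,A\t.\tPASS\t."
  ))
  snps <- suppressWarnings(read_snps(f))
  expect_identical(nrow(snps), 4L)
  expect_identical(snps$rsid, c("rs1", NA, NA, NA))
  expect_identical(snps$alt, c("T", "T", "G", "A"))
  expect_identical(snps$pos, c(10L, 20L, 20L, 40L))
  expect_identical(attr(snps, "n_dropped_indel"), 2L)
  # conservation: emitted rows == single-base substitution alleles in input
  expect_identical(nrow(snps), 1L + 2L + 0L + 1L)
})

test_that("VCF genotypes become per-allele doses with missing handling", {
  f <- write_tmp_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t10\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t1|1\t./.",
    "chr1\t20\t.\tA\tC,G\t.\tPASS\t.\tGT\t1/2\t2/2\t0/0"
  ))
  snps <- read_snps(f, keep_samples = TRUE)
  expect_identical(colnames(snps$gt), c("s1", "s2", "s3"))
  expect_identical(unname(snps$gt[1, ]), c(1L, 2L, NA))
  # multi-allelic row 2 split per allele: doses count that allele only
  expect_identical(unname(snps$gt[2, ]), c(1L, 0L, 0L)) # alt C
  expect_identical(unname(snps$gt[3, ]), c(1L, 2L, 0L)) # alt G
})

test_that("gt_allele_dose treats half-calls as missing", {
  expect_identical(gt_allele_dose(c("0/0", "0/1", "1/1", "./.", ".", NA)),
                   c(0L, 1L, 2L, NA, NA, NA))
  expect_identical(gt_allele_dose("./1"), NA_integer_)
  expect_identical(gt_allele_dose("0/2", alt_index = 2L), 1L)
})

test_that("reference consistency check lists mismatches and unknown chroms", {
  g <- tiny_genome(chr1 = "AACGA")
  snps <- data.frame(chrom = c("chr1", "chr1", "chrZ"),
                     pos = c(3L, 4L, 1L),
                     ref = c("C", "T", "A"), stringsAsFactors = FALSE)
  rep <- verify_reference_consistency(snps, g)
  expect_identical(rep$n_checked, 3L)
  expect_identical(rep$n_mismatch, 1L)
  expect_identical(rep$n_unknown_chrom, 1L)
  expect_identical(rep$mismatches$pos, 4L)
  expect_identical(rep$mismatches$expected, "T")
  expect_identical(rep$mismatches$found, "G")

  empty <- verify_reference_consistency(snps[0, ], g)
  expect_identical(empty$n_checked, 0L)
  expect_identical(empty$n_mismatch, 0L)
})

test_that("BED round trip preserves coordinates and labels", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t300\tCGI", "chr2\t0\t50\tDMR1"), bed)
  gr <- read_intervals(bed)
  # 0-based half-open on disk -> 1-based closed in memory
  expect_identical(GenomicRanges::start(gr), c(101L, 1L))
  expect_identical(GenomicRanges::end(gr), c(300L, 50L))
  expect_identical(gr$name, c("CGI", "DMR1"))

  out <- tempfile(fileext = ".bed")
  write_intervals(gr, out)
  gr2 <- read_intervals(out)
  expect_identical(as.character(gr2), as.character(gr))
  expect_identical(gr2$name, gr$name)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t300\t100"), bad)
  expect_error(read_intervals(bad), "line 2")

  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_length(read_intervals(empty), 0L)
})

test_that("dbmeSNP export has the fixed header and dots for missing fields", {
  g <- tiny_genome(chr1 = "TACGT")
  snps <- data.frame(chrom = "chr1", pos = 3L, ref = "C", alt = "T",
                     rsid = NA_character_, stringsAsFactors = FALSE)
  rec <- scan_mesnps(snps, g)
  f <- tempfile(fileext = ".tsv")
  write_dbmesnp_table(rec, f)
  lines <- readLines(f)
  expect_identical(
    lines[1],
    paste("Chr", "Position", "Genome", "Ref", "Alt", "AF", "rsID",
          "Consequence", "Gene", "Functionality", "Biotype", "meSNP_class",
          sep = "\t"))
  expect_identical(lines[2],
                   "chr1\t3\tACG\tC\tT\t.\t.\t.\t.\t.\t.\tdestroy")
  back <- read_dbmesnp_table(f)
  expect_identical(back$context, "ACG")
  expect_true(is.na(back$rsid))

  write_dbmesnp_table(rec[0, ], f)
  expect_length(readLines(f), 1L) # header only
})

test_that("fixture VCF emission round-trips through the VCF reader", {
  fx <- make_fixture(fixture_spec(seed = 3))
  d <- tempfile()
  fx <- make_fixture(fixture_spec(seed = 3), outdir = d)
  snps <- read_snps(fx$paths$vcf, keep_samples = TRUE)
  expect_identical(snps$pos, fx$snps$pos)
  expect_identical(snps$ref, fx$snps$ref)
  expect_identical(snps$alt, fx$snps$alt)
  expect_identical(unname(snps$gt), unname(fx$gt))
  g <- load_genome(fx$paths$fasta)
  expect_identical(verify_reference_consistency(snps, g)$n_mismatch, 0L)
})
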