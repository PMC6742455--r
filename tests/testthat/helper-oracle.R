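# Independent full-sequence oracle for the meSNP classifier: compare the set
# of CpG start positions in the reference sequence with the set in the
# mutated sequence. Works on N-free sequences.

cpg_starts <- function(s) {
  m <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

oracle_class <- function(s, pos, alt) {
  mut <- s
  substr(mut, pos, pos) <- alt
  r <- cpg_starts(s)
  a <- cpg_starts(mut)
  lost <- setdiff(r, a)
  gained <- setdiff(a, r)
  if (length(lost) == 0 && length(gained) == 0) "none"
  else if (length(lost) == 0) "create"
  else if (length(gained) == 0) "destroy"
  else if (length(lost) == 1 && length(gained) == 1) "displace"
  else stop("oracle: impossible CpG set change for a single substitution")
}

random_case <- function(len = 30L) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  pos <- sample.int(len, 1L)
  ref <- substr(s, pos, pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  list(seq = s, pos = pos, ref = ref, alt = alt)
}

# batch of random classification cases, with the window bases the package
# classifier sees (NA at sequence edges)
random_cases <- function(n, len = 30L) {
  cases <- replicate(n, random_case(len), simplify = FALSE)
  df <- data.frame(
    seq = vapply(cases, `[[`, "", "seq"),
    pos = vapply(cases, `[[`, 0L, "pos"),
    ref = vapply(cases, `[[`, "", "ref"),
    alt = vapply(cases, `[[`, "", "alt"),
    stringsAsFactors = FALSE
  )
  df$left <- ifelse(df$pos > 1L, substr(df$seq, df$pos - 1L, df$pos - 1L),
                    NA_character_)
  df$right <- ifelse(df$pos < len, substr(df$seq, df$pos + 1L, df$pos + 1L),
                     NA_character_)
  df
}

comp_base <- function(b) {
  out <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
  out[is.na(b)] <- NA_character_
  unname(out)
}

# small in-memory genome + matching SNP table for io/scan tests
tiny_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

write_tmp_vcf <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    lines
  ), f)
  f
}
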