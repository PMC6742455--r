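#' CpG-island criteria
#'
#' Relaxed islands must be at least 200 bp long, strict islands at least
#' 500 bp; both require GC content of at least 50% and an observed/expected
#' CpG ratio of at least 0.60. The two presets differ only in minimum length.
#'
#' @param mode `"relaxed"` or `"strict"`.
#' @param min_length,min_gc,min_obs_exp Override individual thresholds.
#' @return List with `min_length`, `min_gc`, `min_obs_exp`.
#' @export
cgi_criteria <- function(mode = c("relaxed", "strict"),
                         min_length = NULL, min_gc = 0.50,
                         min_obs_exp = 0.60) {
  mode <- match.arg(mode)
  if (is.null(min_length)) min_length <- if (mode == "relaxed") 200L else 500L
  list(min_length = as.integer(min_length), min_gc = min_gc,
       min_obs_exp = min_obs_exp)
}

#' Composition statistics of a sequence segment
#'
#' The observed/expected CpG ratio uses the classical form
#' `n_CpG * L / (n_C * n_G)`, defined as 0 when the segment contains no C or
#' no G. Non-ACGT bases count as neither C nor G. CG occurrences cannot
#' self-overlap, so a plain scan counts them all.
#'
#' @param segment A single sequence string (or `DNAString`).
#' @return List with `length`, `gc_fraction`, `n_cpg`, `obs_exp`.
#' @examples
#' window_stats(strrep("CG", 100)) # gc 1.0, obs/exp 2.0
#' @export
window_stats <- function(segment) {
  s <- toupper(as.character(segment))
  stopifnot(length(s) == 1L, nchar(s) >= 1L)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  len <- length(x)
  n_c <- sum(x == "C")
  n_g <- sum(x == "G")
  n_cpg <- if (len < 2L) 0L else sum(x[-len] == "C" & x[-1L] == "G")
  list(
    length = len,
    gc_fraction = (n_c + n_g) / len,
    n_cpg = n_cpg,
    obs_exp = if (n_c == 0L || n_g == 0L) 0 else n_cpg * len / (n_c * n_g)
  )
}

#' Detect CpG islands by sliding-window scan
#'
#' Slides a fixed 200-bp window one base at a time along each chromosome,
#' marks windows meeting the GC and observed/expected thresholds, unions
#' overlapping qualifying windows, filters the merged runs by `min_length`,
#' and finally re-checks every merged interval against all criteria
#' (intervals failing the re-check are dropped), so every emitted island
#' satisfies the criteria on recomputation. Deterministic; for reproducing a
#' published annotation, load the published intervals with [read_intervals()]
#' instead.
#'
#' @param genome A `DNAStringSet` from [load_genome()].
#' @param criteria List from [cgi_criteria()].
#' @param window Scan window size in bp (default 200, the relaxed minimum
#'   island length).
#' @return A `GRanges` of islands (1-based closed coordinates).
#' @export
detect_cgi <- function(genome, criteria = cgi_criteria("relaxed"),
                       window = 200L) {
  out <- list()
  for (ch in names(genome)) {
    s <- as.character(genome[[ch]])
    len <- nchar(s)
    if (len < window) next
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    is_c <- x == "C"
    is_g <- x == "G"
    cum_gc <- cumsum(is_c + is_g)
    cum_c <- cumsum(is_c)
    cum_g <- cumsum(is_g)
    # CpG start positions; a window [s, s+w-1] contains the CpGs starting in
    # [s, s+w-2]
    is_cpg <- c(is_c[-len] & is_g[-1L], FALSE)
    cum_cpg <- cumsum(is_cpg)
    starts <- seq_len(len - window + 1L)
    ends <- starts + window - 1L
    rsum <- function(cum, a, b) cum[b] - ifelse(a > 1L, cum[a - 1L], 0)
    gc <- rsum(cum_gc, starts, ends) / window
    n_c <- rsum(cum_c, starts, ends)
    n_g <- rsum(cum_g, starts, ends)
    n_cpg <- rsum(cum_cpg, starts, ends - 1L)
    obs_exp <- ifelse(n_c == 0 | n_g == 0, 0, n_cpg * window / (n_c * n_g))
    ok <- gc >= criteria$min_gc & obs_exp >= criteria$min_obs_exp
    if (!any(ok)) next
    merged <- IRanges::reduce(IRanges::IRanges(starts[ok], ends[ok]))
    merged <- merged[IRanges::width(merged) >= criteria$min_length]
    if (length(merged) == 0L) next
    keep <- vapply(seq_along(merged), function(i) {
      st <- window_stats(substring(s, IRanges::start(merged)[i],
                                   IRanges::end(merged)[i]))
      st$gc_fraction >= criteria$min_gc && st$obs_exp >= criteria$min_obs_exp
    }, logical(1))
    merged <- merged[keep]
    if (length(merged) > 0L) {
      out[[ch]] <- GenomicRanges::GRanges(ch, merged)
    }
  }
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  res <- suppressWarnings(do.call(c, unname(out)))
  names(res) <- NULL
  res
}
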