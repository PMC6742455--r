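#' Default sequence-ontology term to category mapping
#'
#' Bins the standard VEP consequence terms into a small set of genomic
#' categories (splice site, coding, UTRs, non-coding RNA, intron, proximal
#' promoter, downstream, TF binding site, regulatory, intergenic, ...).
#' `rank` follows the conventional most-severe-first consequence ordering and
#' breaks ties when a variant carries several terms. Supply your own data
#' frame with the same columns to change the binning.
#'
#' @return Data frame with columns `term`, `category`, `rank` (1 = most
#'   severe).
#' @export
so_category_map <- function() {
  m <- matrix(c(
    "transcript_ablation",                "coding",            "1",
    "splice_acceptor_variant",            "splice_site",       "2",
    "splice_donor_variant",               "splice_site",       "3",
    "stop_gained",                        "coding",            "4",
    "frameshift_variant",                 "coding",            "5",
    "stop_lost",                          "coding",            "6",
    "start_lost",                         "coding",            "7",
    "transcript_amplification",           "coding",            "8",
    "inframe_insertion",                  "coding",            "9",
    "inframe_deletion",                   "coding",            "10",
    "missense_variant",                   "coding",            "11",
    "protein_altering_variant",           "coding",            "12",
    "splice_region_variant",              "splice_site",       "13",
    "incomplete_terminal_codon_variant",  "coding",            "14",
    "start_retained_variant",             "coding",            "15",
    "stop_retained_variant",              "coding",            "16",
    "synonymous_variant",                 "coding",            "17",
    "coding_sequence_variant",            "coding",            "18",
    "mature_miRNA_variant",               "non_coding_RNA",    "19",
    "5_prime_UTR_variant",                "utr5",              "20",
    "3_prime_UTR_variant",                "utr3",              "21",
    "non_coding_transcript_exon_variant", "non_coding_RNA",    "22",
    "intron_variant",                     "intron",            "23",
    "NMD_transcript_variant",             "non_coding_RNA",    "24",
    "non_coding_transcript_variant",      "non_coding_RNA",    "25",
    "upstream_gene_variant",              "proximal_promoter", "26",
    "downstream_gene_variant",            "downstream",        "27",
    "TFBS_ablation",                      "tf_binding_site",   "28",
    "TFBS_amplification",                 "tf_binding_site",   "29",
    "TF_binding_site_variant",            "tf_binding_site",   "30",
    "regulatory_region_ablation",         "regulatory",        "31",
    "regulatory_region_amplification",    "regulatory",        "32",
    "feature_elongation",                 "other_feature",     "33",
    "regulatory_region_variant",          "regulatory",        "34",
    "feature_truncation",                 "other_feature",     "35",
    "intergenic_variant",                 "intergenic",        "36"
  ), ncol = 3, byrow = TRUE)
  data.frame(term = m[, 1], category = m[, 2], rank = as.integer(m[, 3]),
             stringsAsFactors = FALSE)
}

#' Bin consequence terms into one category
#'
#' When a variant carries multiple consequence terms, the category of the
#' most severe (lowest rank) term wins. Terms absent from the mapping fall
#' into `"other"` with a warning; an empty term list is `"unannotated"`.
#'
#' @param so_terms Character vector of SO consequence terms for one variant
#'   (a single comma/ampersand-separated string is split first).
#' @param mapping Data frame as from [so_category_map()].
#' @return Single category label.
#' @export
categorize_consequence <- function(so_terms, mapping = so_category_map()) {
  stopifnot(all(c("term", "category", "rank") %in% names(mapping)))
  if (length(so_terms) == 1L && !is.na(so_terms)) {
    so_terms <- strsplit(so_terms, "[,&]")[[1]]
  }
  so_terms <- so_terms[!is.na(so_terms) & nzchar(so_terms)]
  if (length(so_terms) == 0L) return("unannotated")
  i <- match(so_terms, mapping$term)
  if (anyNA(i)) {
    warning("unknown consequence term(s): ",
            paste(so_terms[is.na(i)], collapse = ", "))
    if (all(is.na(i))) return("other")
  }
  mapping$category[i[which.min(mapping$rank[i])]]
}
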