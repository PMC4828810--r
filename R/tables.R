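# Bundled reference tables: published results of a male/female garden
# asparagus (A. officinalis) two-library sRNA + degradome study, transcribed
# as plain text. They serve as arithmetic validation inputs (recomputing
# fold-change ratios from printed TPM pairs, deriving structural counts from
# the novel-miRNA table) — not as data the pipeline depends on.

#' Published differential-expression reference table
#'
#' Per-miRNA female/male TPM pairs with the printed ratio and log2 fold
#' change. The printed values carry the source's own rounding conventions
#' (TPM 2 d.p., ratio 3 d.p., log2 4 d.p.); a few rows are internally
#' inconsistent at that precision, which the validation checks account for.
#'
#' @return data.frame: mirna, sequence, length, family, tpm_F, tpm_M,
#'   ratio, log2_fc.
#' @export
reference_de_table <- function() {
  read.delim(system.file("extdata", "reference_de_table.tsv",
                         package = "mirpipe"),
             stringsAsFactors = FALSE)
}

#' Published novel-miRNA reference table
#'
#' One row per precursor locus (multi-locus miRNAs repeat the mature row);
#' `is_star` flags the one miRNA* entry, which does not count toward the
#' novel-miRNA total.
#'
#' @return data.frame: mirna, sequence, length, gc_pct, tpm_F, tpm_M, mfe,
#'   mfei, unigene, start, end, strand, is_star.
#' @export
reference_novel_table <- function() {
  read.delim(system.file("extdata", "reference_novel_table.tsv",
                         package = "mirpipe"),
             stringsAsFactors = FALSE)
}

#' Published read-accounting reference table
#'
#' Library statistics of the two sRNA libraries (raw through final clean and
#' unique reads).
#'
#' @return data.frame: category, F, M.
#' @export
reference_accounting <- function() {
  read.delim(system.file("extdata", "reference_accounting.tsv",
                         package = "mirpipe"),
             stringsAsFactors = FALSE)
}

#' Derived summaries of the novel-miRNA reference table
#'
#' Recomputes, from the table alone: the number of distinct novel miRNAs
#' (stars excluded), the number generated from the most prolific unigene,
#' the number with more than one precursor locus, and the fraction of 21-nt
#' matures.
#'
#' @param tab table from [reference_novel_table()] (default).
#' @return list: n_novel, top_unigene, n_top_unigene, n_multi_locus,
#'   pct_21nt.
#' @export
novel_table_summary <- function(tab = reference_novel_table()) {
  main <- tab[tab$is_star == 0, ]
  per_mirna <- unique(main[, c("mirna", "length")])
  loci_per <- table(main$mirna)
  per_unigene <- table(unique(main[, c("mirna", "unigene")])$unigene)
  top <- names(per_unigene)[which.max(per_unigene)]
  list(n_novel = nrow(per_mirna),
       top_unigene = top,
       n_top_unigene = as.integer(max(per_unigene)),
       n_multi_locus = sum(loci_per > 1L),
       pct_21nt = 100 * mean(per_mirna$length == 21L))
}
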