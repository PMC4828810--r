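# Degradome (PARE) analysis: mapping of 20-21 nt degradome reads,
# miRNA-target complementarity scoring, cleavage detection opposite miRNA
# nucleotide 10, category 0-4 classification and t-plot tables.

#' Build per-transcript degradome 5'-end profiles
#'
#' Each perfect sense-strand occurrence of a read increments the count at
#' the read's 5'-end position; multi-mapping reads increment every matched
#' position. Antisense matches are ignored (mRNA decay is sense-strand).
#'
#' @param reads character vector of degradome reads (only 20-21 nt reads are
#'   used; others are dropped).
#' @param transcriptome named character vector of DNA transcripts.
#' @return named list of integer count vectors (one per transcript, length =
#'   transcript length), with attribute `total` = total mapped read count.
#' @export
map_degradome <- function(reads, transcriptome) {
  reads <- toupper(reads[nchar(reads) %in% 20:21])
  profiles <- lapply(transcriptome, function(tx) integer(nchar(tx)))
  total <- 0L
  if (length(reads) > 0L) {
    tab <- table(reads)
    for (r in names(tab)) {
      cnt <- as.integer(tab[[r]])
      for (id in names(transcriptome)) {
        hits <- gregexpr(r, transcriptome[[id]], fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) next
        for (p in as.integer(hits)) {
          profiles[[id]][p] <- profiles[[id]][p] + cnt
          total <- total + cnt
        }
      }
    }
  }
  attr(profiles, "total") <- total
  profiles
}

#' Score miRNA-target complementarity along a transcript
#'
#' Slides the reverse-complement frame of the miRNA along the transcript and
#' scores each ungapped window with the plant-target convention: match 0,
#' G:U wobble 0.5, mismatch 1.0, penalties doubled at miRNA positions 2-13
#' (the 5' core). Windows with total penalty <= `max_score` are reported.
#'
#' @param mirna mature miRNA (RNA or DNA, 20-24 nt).
#' @param transcript DNA string (or single named element).
#' @param max_score penalty cutoff (default 7).
#' @return data.frame (start, end, score, pairing) with 1-based transcript
#'   coordinates; `pairing` strings run 5'->3' along the miRNA
#'   (`|` match, `o` wobble, `x` mismatch).
#' @export
target_align <- function(mirna, transcript, max_score = 7) {
  mir <- strsplit(dna_to_rna(mirna), "", fixed = TRUE)[[1L]]
  L <- length(mir)
  if (L < 20L || L > 24L) stop("miRNA length must be 20-24 nt")
  tx <- strsplit(dna_to_rna(toupper(transcript[[1L]])), "", fixed = TRUE)[[1L]]
  n <- length(tx)
  if (n < L) {
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0), pairing = character(0),
                      stringsAsFactors = FALSE))
  }
  nw <- n - L + 1L
  # penalty of miRNA position j against target base at site start + L - j
  pen <- matrix(0, nrow = nw, ncol = L)
  sym <- matrix("x", nrow = nw, ncol = L)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (j in seq_len(L)) {
    tb <- tx[(seq_len(nw) - 1L) + (L - j + 1L)]
    match_ <- tb == comp[[mir[j]]]
    wobble <- (mir[j] == "G" & tb == "U") | (mir[j] == "U" & tb == "G")
    p <- ifelse(match_, 0, ifelse(wobble, 0.5, 1.0))
    if (j >= 2L && j <= 13L) p <- p * 2
    pen[, j] <- p
    sym[, j] <- ifelse(match_, "|", ifelse(wobble, "o", "x"))
  }
  score <- rowSums(pen)
  keep <- which(score <= max_score)
  data.frame(start = keep, end = keep + L - 1L, score = score[keep],
             pairing = apply(sym[keep, , drop = FALSE], 1, paste0,
                             collapse = ""),
             stringsAsFactors = FALSE)
}

#' Detect a cleavage signature for a target alignment
#'
#' A hit requires degradome 5' ends at the transcript position paired with
#' miRNA nucleotide 10 (`start + L - 10`); `offset_window` can widen the
#' admitted miRNA positions (e.g. `c(9, 10, 11)`), in which case the
#' best-covered admitted position is used (ties resolved in the given
#' order).
#'
#' @param alignment one-row data.frame from [target_align()].
#' @param profile integer count vector for the transcript.
#' @param offset_window admitted miRNA positions (default 10).
#' @return list (`cleavage_pos`, `reads`) or `NULL` when no admitted
#'   position has coverage.
#' @export
detect_cleavage <- function(alignment, profile, offset_window = 10L) {
  L <- alignment$end - alignment$start + 1L
  pos <- alignment$start + L - as.integer(offset_window)
  pos <- pos[pos >= 1L & pos <= length(profile)]
  if (length(pos) == 0L) return(NULL)
  cnt <- profile[pos]
  if (all(cnt == 0L)) return(NULL)
  best <- pos[which.max(cnt)]
  list(cleavage_pos = best, reads = profile[best])
}

#' Classify a degradome hit into categories 0-4
#'
#' With `c` the count at the cleavage site, `M` the maximum position count on
#' the transcript and `m` the median over occupied positions (count > 0):
#' category 4 iff `c == 1`; else 0 iff `c == M` attained at exactly one
#' position; else 1 iff `c == M` (shared maximum); else 2 iff `c > m`;
#' else 3.
#'
#' @param count_at_site reads at the cleavage position (>= 1).
#' @param profile integer count vector for the transcript.
#' @return integer category in 0..4.
#' @export
categorize <- function(count_at_site, profile) {
  if (count_at_site < 1L) stop("cleavage site must have coverage")
  if (count_at_site == 1L) return(4L)
  occ <- profile[profile > 0L]
  M <- max(occ)
  if (count_at_site == M) {
    if (sum(profile == M) == 1L) return(0L)
    return(1L)
  }
  if (count_at_site > stats::median(occ)) return(2L)
  3L
}

#' Per-position t-plot table
#'
#' @param profile integer count vector for one transcript.
#' @param hits data.frame of hits on this transcript (with `cleavage_pos`),
#'   or `NULL`.
#' @return data.frame (position, count, is_cleavage_site) over occupied
#'   positions; counts sum to the profile total.
#' @export
tplot_table <- function(profile, hits = NULL) {
  pos <- which(profile > 0L)
  data.frame(position = pos, count = profile[pos],
             is_cleavage_site = pos %in% (hits$cleavage_pos %||% integer(0)))
}

#' Identify miRNA cleavage targets from a degradome profile set
#'
#' For every miRNA x profiled transcript pair: complementarity scoring
#' ([target_align()]), cleavage detection at the position opposite miRNA
#' nucleotide 10 ([detect_cleavage()]) and category classification
#' ([categorize()]).
#'
#' @param mirnas named character vector of mature miRNAs (RNA or DNA).
#' @param transcriptome named character vector of DNA transcripts.
#' @param profiles list from [map_degradome()].
#' @param max_score complementarity penalty cutoff (default 7).
#' @param offset_window admitted cleavage positions, see [detect_cleavage()].
#' @return data.frame: mirna, transcript, site_start, site_end, score,
#'   pairing, cleavage_pos, reads, category.
#' @export
degradome_targets <- function(mirnas, transcriptome, profiles, max_score = 7,
                              offset_window = 10L) {
  rows <- list()
  for (mid in names(mirnas)) {
    for (tid in names(profiles)) {
      prof <- profiles[[tid]]
      if (sum(prof) == 0L) next
      al <- target_align(mirnas[[mid]], transcriptome[[tid]], max_score)
      for (k in seq_len(nrow(al))) {
        hit <- detect_cleavage(al[k, ], prof, offset_window)
        if (is.null(hit)) next
        rows[[length(rows) + 1L]] <-
          data.frame(mirna = mid, transcript = tid,
                     site_start = al$start[k], site_end = al$end[k],
                     score = al$score[k], pairing = al$pairing[k],
                     cleavage_pos = hit$cleavage_pos, reads = hit$reads,
                     category = categorize(hit$reads, prof),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(mirna = character(0), transcript = character(0),
                      site_start = integer(0), site_end = integer(0),
                      score = numeric(0), pairing = character(0),
                      cleavage_pos = integer(0), reads = integer(0),
                      category = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
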