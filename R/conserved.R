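# Assignment of unique sRNA tags to known mature miRNAs, family grouping and
# positional nucleotide-bias statistics.

#' Assign unique sRNAs to known mature miRNAs
#'
#' Ungapped, end-to-end comparison against reference matures of the same
#' length (no indels, no length slack): a read is assigned to the reference
#' with the fewest mismatches, at most `max_mismatch`; ties go to the
#' lexicographically smallest reference id. Callers should pre-filter reads
#' with [filter_candidates()] (TPM >= 5 in at least one library, 20-24 nt).
#'
#' @param unique_reads data.frame from [collapse_reads()] (already gated).
#' @param mature_db named character vector of mature miRNAs (miRBase-style;
#'   RNA or DNA alphabet).
#' @param max_mismatch maximum mismatches (default 2).
#' @return data.frame of assignments: sequence, ref_id, family, mismatches
#'   (one row per assigned read; unassigned reads are simply absent and flow
#'   to novel-miRNA discovery).
#' @export
match_known <- function(unique_reads, mature_db, max_mismatch = 2L) {
  if (length(mature_db) == 0L) stop("mature_db is empty")
  db <- rna_to_dna(mature_db)
  db_len <- nchar(db)
  reads <- unique_reads$sequence
  rows <- lapply(reads, function(r) {
    idx <- which(db_len == nchar(r))
    if (length(idx) == 0L) return(NULL)
    rc <- strsplit(r, "", fixed = TRUE)[[1L]]
    mm <- vapply(idx, function(i) {
      sum(strsplit(db[[i]], "", fixed = TRUE)[[1L]] != rc)
    }, integer(1))
    best <- min(mm)
    if (best > max_mismatch) return(NULL)
    cand <- sort(names(db)[idx[mm == best]])
    data.frame(sequence = r, ref_id = cand[1L],
               family = family_name(cand[1L]), mismatches = best,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sequence = character(0), ref_id = character(0),
                      family = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Parse the miRNA family from a reference id
#'
#' `aof-miR166d-1` -> `miR166`: the `miR` + digits token, letters and
#' suffixes stripped.
#'
#' @param ids character vector of miRNA ids.
#' @return family names (`NA` when no `miR<digits>` token is present).
#' @export
family_name <- function(ids) {
  m <- regmatches(ids, regexpr("miR[0-9]+", ids))
  out <- rep(NA_character_, length(ids))
  out[regexpr("miR[0-9]+", ids) > 0] <- m
  out
}

#' Family membership summary
#'
#' @param assignments data.frame from [match_known()].
#' @return data.frame (family, members) sorted by member count descending;
#'   member counts sum to the number of distinct assigned reads.
#' @export
family_summary <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(data.frame(family = character(0), members = integer(0)))
  }
  a <- assignments[!duplicated(assignments$sequence), ]
  tab <- sort(table(a$family), decreasing = TRUE)
  data.frame(family = names(tab), members = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Positional nucleotide frequencies
#'
#' Frequencies of A/C/G/U at each position over a set of miRNA sequences
#' (e.g. to show the 5'-uridine bias of plant miRNAs). At each position the
#' frequencies are computed over the sequences long enough to cover it, so
#' every column sums to 1.
#'
#' @param sequences character vector (RNA or DNA; reported as RNA).
#' @return 4 x max-length matrix, rows A/C/G/U, columns positions.
#' @export
nucleotide_bias <- function(sequences) {
  if (length(sequences) == 0L) stop("no sequences")
  seqs <- dna_to_rna(sequences)
  maxlen <- max(nchar(seqs))
  mat <- matrix(0, nrow = 4, ncol = maxlen,
                dimnames = list(c("A", "C", "G", "U"), seq_len(maxlen)))
  for (p in seq_len(maxlen)) {
    b <- substr(seqs[nchar(seqs) >= p], p, p)
    tab <- table(factor(b, levels = c("A", "C", "G", "U")))
    mat[, p] <- as.numeric(tab) / length(b)
  }
  mat
}
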