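# Novel miRNA discovery: perfect transcript mapping of candidate sRNAs,
# +/-200 nt precursor window extraction, folding, and the stem-loop /
# duplex / star / MFE / MFEI annotation criteria.

#' Default novel-miRNA evaluation thresholds
#'
#' MFE cutoff -18 kcal/mol; advisory MFEI window 0.7-1.5 (recorded but not
#' gating by default, since MFEI calibration depends on the folding energy
#' model); duplex criteria in the Dicer-product annotation convention: at
#' most 4 unpaired mature bases, no asymmetric bulge over 2 nt, a star with
#' a 2-nt 3' overhang.
#'
#' @param mfe_max maximum (most positive) precursor MFE, kcal/mol.
#' @param mfei_min,mfei_max advisory MFEI window.
#' @param mfei_required should the MFEI window gate acceptance?
#' @param max_unpaired_mature duplex mismatch bound on the mature.
#' @param max_bulge_asym maximum asymmetric bulge (nt) in the duplex.
#' @param flank precursor window flank on each side (nt).
#' @param tpm_min,len_range candidate inclusion gate.
#' @return named list of thresholds.
#' @export
novel_thresholds <- function(mfe_max = -18, mfei_min = 0.7, mfei_max = 1.5,
                             mfei_required = FALSE, max_unpaired_mature = 4L,
                             max_bulge_asym = 2L, flank = 200L, tpm_min = 5,
                             len_range = c(20L, 24L)) {
  list(mfe_max = mfe_max, mfei_min = mfei_min, mfei_max = mfei_max,
       mfei_required = mfei_required,
       max_unpaired_mature = max_unpaired_mature,
       max_bulge_asym = max_bulge_asym, flank = flank,
       tpm_min = tpm_min, len_range = len_range)
}

#' Map a read perfectly to a transcriptome, both strands
#'
#' Every exact occurrence is reported: `+` hits as substring matches, `-`
#' hits as occurrences of the reverse complement, with coordinates always on
#' the `+` axis, 1-based inclusive.
#'
#' @param sread DNA read (20-24 nt for miRNA candidates).
#' @param transcriptome named character vector of DNA transcripts.
#' @return data.frame (unigene, start, end, strand); zero rows when unmapped.
#' @export
map_perfect <- function(sread, transcriptome) {
  sread <- toupper(sread)
  L <- nchar(sread)
  rc <- revcomp(sread)
  rows <- list()
  for (id in names(transcriptome)) {
    tx <- transcriptome[[id]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") sread else rc
      hits <- gregexpr(pat, tx, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      rows[[length(rows) + 1L]] <-
        data.frame(unigene = id, start = as.integer(hits),
                   end = as.integer(hits) + L - 1L, strand = strand,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(unigene = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Extract a precursor window around a mapped locus
#'
#' The window is `[max(1, start - flank), min(L, end + flank)]` on the `+`
#' axis; for `-` loci the returned sequence is the reverse complement of the
#' window, so the mature is always a literal substring of the returned
#' sequence.
#'
#' @param locus one-row data.frame (unigene, start, end, strand).
#' @param transcriptome named character vector.
#' @param flank flank size in nt (default 200).
#' @return list: `sequence` (DNA, oriented with the mature sense),
#'   `window_start`, `window_end` (on the `+` axis), `mature_offset` (1-based
#'   within `sequence`), `mature_length`, `strand`, `unigene`.
#' @export
extract_precursor <- function(locus, transcriptome, flank = 200L) {
  tx <- transcriptome[[locus$unigene]]
  if (is.null(tx)) stop("unknown unigene: ", locus$unigene)
  ws <- max(1L, locus$start - flank)
  we <- min(nchar(tx), locus$end + flank)
  s <- substr(tx, ws, we)
  if (locus$strand == "-") {
    s <- revcomp(s)
    off <- we - locus$end + 1L
  } else {
    off <- locus$start - ws + 1L
  }
  list(sequence = s, window_start = ws, window_end = we,
       mature_offset = off, mature_length = locus$end - locus$start + 1L,
       strand = locus$strand, unigene = locus$unigene)
}

#' Locate the miRNA* partner of a mature in a folded precursor
#'
#' The star is the opposite-arm segment pairing with the mature, shifted to
#' give the duplex a 2-nt 3' overhang on each strand. Absent when fewer than
#' (mature length - 4) mature bases are paired, or when the mature pairs
#' into both arms.
#'
#' @param fold a `fold_result` for the precursor.
#' @param mature_offset 1-based mature start within the precursor.
#' @param mature_length mature length.
#' @return list (`start`, `end`, `sequence` in RNA) or `NULL` when absent.
#' @export
find_star <- function(fold, mature_offset, mature_length) {
  pt <- pair_table(fold$structure)
  n <- length(pt)
  m1 <- mature_offset
  m2 <- mature_offset + mature_length - 1L
  if (m2 > n) return(NULL)
  idx <- m1:m2
  paired <- idx[pt[idx] != 0L]
  if (length(paired) < mature_length - 4L) return(NULL)
  partners <- pt[paired]
  if (!(all(partners > m2) || all(partners < m1))) return(NULL)
  i_min <- min(paired)
  i_max <- max(paired)
  # same projection serves both arms: partner coords decrease along the mature
  a <- pt[i_max] - ((m2 - 2L) - i_max)
  b <- pt[i_min] + (i_min - m1) + 2L
  lo <- max(1L, min(a, b))
  hi <- min(n, max(a, b))
  if (lo > hi) return(NULL)
  if (lo <= m2 && hi >= m1) return(NULL)   # star may not overlap the mature
  list(start = lo, end = hi,
       sequence = dna_to_rna(substr(fold$sequence, lo, hi)))
}

# Duplex geometry checks along the mature: unpaired-base count and the
# largest asymmetric bulge between consecutive paired positions.
#' @keywords internal
duplex_stats <- function(pt, m1, m2) {
  idx <- m1:m2
  paired <- idx[pt[idx] != 0L]
  n_unpaired <- length(idx) - length(paired)
  max_asym <- 0L
  if (length(paired) >= 2L) {
    for (k in seq_len(length(paired) - 1L)) {
      i <- paired[k]; j <- paired[k + 1L]
      gap_m <- j - i - 1L
      gap_s <- abs(pt[i] - pt[j]) - 1L
      max_asym <- max(max_asym, abs(gap_m - gap_s))
    }
  }
  list(n_unpaired = n_unpaired, max_asym = max_asym)
}

#' Evaluate a precursor window against the novel-miRNA criteria
#'
#' Folds the window, requires (a) the mature to lie entirely within one arm
#' of a single stem-loop (no base in the terminal loop), then trims the
#' window to that stem-loop, refolds, and on the trimmed precursor checks
#' (b) the mature/star duplex (at most `max_unpaired_mature` unpaired mature
#' bases, no asymmetric bulge over `max_bulge_asym` nt), (c) presence of a
#' star with a 2-nt 3' overhang on the opposite arm, (d) MFE at or below
#' `mfe_max`, and (e) the advisory MFEI window. Reported coordinates are the
#' trimmed precursor on the unigene `+` axis.
#'
#' @param sread the candidate read (DNA).
#' @param window precursor window from [extract_precursor()].
#' @param thresholds list from [novel_thresholds()].
#' @param params folding energy parameters.
#' @return one-row data.frame: locus and precursor columns (unigene, start,
#'   end, strand, arm, precursor, structure, mfe, gc, mfei, mature_offset,
#'   star), per-criterion verdicts (`ok_hairpin`, `ok_arm`, `ok_duplex`,
#'   `ok_star`, `ok_mfe`, `ok_mfei`), overall `pass`, and `reason` for early
#'   failures.
#' @export
evaluate_candidate <- function(sread, window, thresholds = novel_thresholds(),
                               params = rna_energy_params()) {
  sread <- toupper(rna_to_dna(sread))
  L <- nchar(sread)
  # anchor the mature by its sequence: trust the supplied offset only when it
  # actually spells the read, otherwise locate the read in the window (this
  # is what makes re-evaluation of reported precursor coordinates work)
  m_off <- window$mature_offset
  if (is.null(m_off) ||
      substr(window$sequence, m_off, m_off + L - 1L) != sread) {
    m_off <- as.integer(regexpr(sread, window$sequence, fixed = TRUE))
  }
  window$mature_offset <- m_off
  window$mature_length <- L
  fail <- function(reason, f = NULL) {
    data.frame(unigene = window$unigene, start = window$window_start,
               end = window$window_end, strand = window$strand,
               arm = NA_character_, precursor = NA_character_,
               structure = NA_character_, mfe = if (is.null(f)) NA_real_ else f$mfe,
               gc = NA_real_, mfei = NA_real_, mature_offset = NA_integer_,
               star = NA_character_, ok_hairpin = FALSE, ok_arm = FALSE,
               ok_duplex = FALSE, ok_star = FALSE, ok_mfe = FALSE,
               ok_mfei = FALSE, pass = FALSE, reason = reason,
               stringsAsFactors = FALSE)
  }
  if (m_off < 1L) return(fail("mature_not_in_window"))
  if (nchar(window$sequence) < 2L * L + params$min_hairpin) {
    return(fail("window_too_short"))
  }
  f <- fold(window$sequence, params)
  hp <- find_hairpins(f)
  m1 <- window$mature_offset
  m2 <- m1 + L - 1L
  in_arm <- which((hp$stem5_start <= m1 & m2 <= hp$stem5_end) |
                    (hp$stem3_start <= m1 & m2 <= hp$stem3_end))
  if (nrow(hp) == 0L) return(fail("no_hairpin", f))
  if (length(in_arm) == 0L) {
    out <- fail("mature_not_in_one_arm", f)
    out$ok_hairpin <- TRUE
    return(out)
  }
  h <- hp[in_arm[1L], ]

  # trim to the minimal hairpin-containing subsequence and refold, iterating
  # to a fixed point so that re-evaluating the reported coordinates
  # reproduces the identical precursor and verdicts
  ts <- h$stem5_start
  te <- h$stem3_end
  for (iter in 1:5) {
    prec <- substr(window$sequence, ts, te)
    f2 <- fold(prec, params)
    m1t <- m1 - ts + 1L
    m2t <- m1t + L - 1L
    hp2 <- find_hairpins(f2)
    in_arm2 <- which((hp2$stem5_start <= m1t & m2t <= hp2$stem5_end) |
                       (hp2$stem3_start <= m1t & m2t <= hp2$stem3_end))
    if (length(in_arm2) == 0L) break
    h2 <- hp2[in_arm2[1L], ]
    if (h2$stem5_start == 1L && h2$stem3_end == nchar(prec)) break
    ts <- ts + h2$stem5_start - 1L
    te <- ts + (h2$stem3_end - h2$stem5_start)
  }
  ok_hairpin <- nrow(hp2) > 0L
  ok_arm <- length(in_arm2) > 0L
  arm <- NA_character_
  if (ok_arm) {
    h2 <- hp2[in_arm2[1L], ]
    arm <- if (m2t <= h2$stem5_end) "5p" else "3p"
  }
  pt2 <- pair_table(f2$structure)
  ds <- duplex_stats(pt2, m1t, m2t)
  ok_duplex <- ds$n_unpaired <= thresholds$max_unpaired_mature &&
    ds$max_asym <= thresholds$max_bulge_asym
  star <- find_star(f2, m1t, L)
  ok_star <- !is.null(star)
  gc <- gc_fraction(prec)
  mfei_val <- if (gc > 0 && f2$mfe <= 0) mfei(f2$mfe, nchar(prec), gc) else NA_real_
  ok_mfe <- f2$mfe <= thresholds$mfe_max
  ok_mfei <- !is.na(mfei_val) && mfei_val >= thresholds$mfei_min &&
    mfei_val <= thresholds$mfei_max
  pass <- ok_hairpin && ok_arm && ok_duplex && ok_star && ok_mfe &&
    (!thresholds$mfei_required || ok_mfei)

  # trimmed precursor back on the unigene '+' axis
  if (window$strand == "+") {
    ps <- window$window_start + ts - 1L
    pe <- window$window_start + te - 1L
  } else {
    ps <- window$window_end - te + 1L
    pe <- window$window_end - ts + 1L
  }
  data.frame(unigene = window$unigene, start = ps, end = pe,
             strand = window$strand, arm = arm,
             precursor = dna_to_rna(prec), structure = f2$structure,
             mfe = f2$mfe, gc = gc, mfei = mfei_val, mature_offset = m1t,
             star = if (ok_star) star$sequence else NA_character_,
             ok_hairpin = ok_hairpin, ok_arm = ok_arm, ok_duplex = ok_duplex,
             ok_star = ok_star, ok_mfe = ok_mfe, ok_mfei = ok_mfei,
             pass = pass, reason = NA_character_, stringsAsFactors = FALSE)
}

# Merge same-mature loci on one unigene/strand whose precursor windows
# overlap by >= 50% (duplicate windows from near-identical mappings); the
# lowest-MFE representative is kept.
#' @keywords internal
merge_overlapping_loci <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  keep <- rep(TRUE, nrow(cand))
  key <- paste(cand$sequence, cand$unigene, cand$strand)
  for (g in unique(key)) {
    idx <- which(key == g & keep)
    if (length(idx) <= 1L) next
    idx <- idx[order(cand$mfe[idx])]
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      for (b in idx[-seq_len(a)]) {
        if (!keep[b]) next
        ov <- min(cand$end[idx[a]], cand$end[b]) -
          max(cand$start[idx[a]], cand$start[b]) + 1L
        w <- min(cand$end[idx[a]] - cand$start[idx[a]],
                 cand$end[b] - cand$start[b]) + 1L
        if (ov >= 0.5 * w) keep[b] <- FALSE
      }
    }
  }
  cand[keep, , drop = FALSE]
}

#' Discover novel miRNA candidates
#'
#' Applies the inclusion gate ([filter_candidates()]), removes reads already
#' assigned to known miRNAs, maps the rest perfectly to the transcriptome
#' (both strands), extracts +/-`flank` nt windows, and evaluates each locus
#' with [evaluate_candidate()].
#'
#' @param unique_reads data.frame from [collapse_reads()].
#' @param transcriptome named character vector of DNA transcripts.
#' @param exclude character vector of read sequences to skip (typically the
#'   conserved assignments).
#' @param thresholds list from [novel_thresholds()].
#' @param params folding energy parameters.
#' @return data.frame of evaluated loci (all candidates, with `pass`
#'   verdicts), one row per read x locus, plus a `sequence` column.
#' @export
scan_novel_loci <- function(unique_reads, transcriptome, exclude = character(0),
                            thresholds = novel_thresholds(),
                            params = rna_energy_params()) {
  gated <- filter_candidates(unique_reads, thresholds$tpm_min,
                             thresholds$len_range)
  gated <- gated[!gated$sequence %in% exclude, , drop = FALSE]
  rows <- list()
  for (r in gated$sequence) {
    loci <- map_perfect(r, transcriptome)
    for (k in seq_len(nrow(loci))) {
      w <- extract_precursor(loci[k, ], transcriptome, thresholds$flank)
      ev <- evaluate_candidate(r, w, thresholds, params)
      ev$sequence <- r
      rows[[length(rows) + 1L]] <- ev
    }
  }
  if (length(rows) == 0L) {
    return(cbind(data.frame(unigene = character(0), start = integer(0),
                            end = integer(0), strand = character(0),
                            arm = character(0), precursor = character(0),
                            structure = character(0), mfe = numeric(0),
                            gc = numeric(0), mfei = numeric(0),
                            mature_offset = integer(0), star = character(0),
                            ok_hairpin = logical(0), ok_arm = logical(0),
                            ok_duplex = logical(0), ok_star = logical(0),
                            ok_mfe = logical(0), ok_mfei = logical(0),
                            pass = logical(0), reason = character(0),
                            stringsAsFactors = FALSE),
                 sequence = character(0)))
  }
  merge_overlapping_loci(do.call(rbind, rows))
}

#' Assemble the novel miRNA set from passing candidate loci
#'
#' One novel miRNA per distinct mature sequence, aggregating all passing
#' loci (several precursors per mature and several miRNAs per unigene are
#' allowed). Ids are assigned in lexicographic order of the mature sequence.
#'
#' @param candidates data.frame from [scan_novel_loci()].
#' @param unique_reads data.frame from [collapse_reads()] (count/TPM source).
#' @param id_prefix prefix for assigned ids (default `"novel-miRn"`).
#' @return list with `mirnas` (id, sequence in RNA, length, counts, TPM,
#'   n_loci), `loci` (per-locus table with ids), and `summary` (length
#'   histogram and per-unigene miRNA counts).
#' @export
assemble_novel_set <- function(candidates, unique_reads,
                               id_prefix = "novel-miRn") {
  pass <- candidates[candidates$pass, , drop = FALSE]
  if (nrow(pass) == 0L) {
    return(list(mirnas = data.frame(id = character(0), sequence = character(0),
                                    length = integer(0), n_loci = integer(0),
                                    stringsAsFactors = FALSE),
                loci = pass,
                summary = list(length_histogram = table(integer(0)),
                               unigene_mirnas = integer(0))))
  }
  mats <- sort(unique(pass$sequence))
  ids <- sprintf("%s%02d", id_prefix, seq_along(mats))
  names(ids) <- mats
  pass$id <- ids[pass$sequence]
  pass <- pass[order(pass$id, pass$unigene, pass$start), , drop = FALSE]
  count_cols <- grep("^(count|tpm)_", names(unique_reads), value = TRUE)
  info <- unique_reads[match(mats, unique_reads$sequence), count_cols,
                       drop = FALSE]
  mirnas <- cbind(data.frame(id = ids, sequence = dna_to_rna(mats),
                             length = nchar(mats), stringsAsFactors = FALSE),
                  info,
                  n_loci = as.integer(table(pass$id)[ids]))
  rownames(mirnas) <- NULL
  list(mirnas = mirnas, loci = pass,
       summary = list(length_histogram = table(mirnas$length),
                      unigene_mirnas = sort(table(pass$unigene),
                                            decreasing = TRUE)))
}
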