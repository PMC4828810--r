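# Ground-truth synthetic data: transcriptomes with planted stem-loop
# precursors, two sRNA libraries (shared and library-biased miRNA abundances,
# ncRNA contaminants, a 3' adapter), and degradome reads marking
# miRNA-guided cleavage positions. Everything downstream of sequencing is
# testable against the returned truth table without any external download.
#
# Reads are generated in the DNA alphabet (sequencers emit DNA); mature
# miRNAs are reported in the RNA alphabet, as miRBase prints them. All
# randomness flows through one explicit seed per generator call.

#' Generate a random unigene set
#'
#' @param n_unigenes number of transcripts (>= 1).
#' @param length_range integer range of transcript lengths, within
#'   `[300, 5000]` nt.
#' @param gc_fraction target GC content of the pool (0-1, exclusive).
#' @param seed integer seed; identical seeds give identical output.
#' @return named character vector of DNA sequences, ids `UN00001`, ...
#' @export
generate_transcriptome <- function(n_unigenes, length_range = c(300, 2000),
                                   gc_fraction = 0.45, seed = 1L) {
  if (n_unigenes < 1L) stop("n_unigenes must be >= 1")
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 300 || length_range[2] > 5000) {
    stop("length_range must be an increasing interval within [300, 5000]")
  }
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0,1)")
  set.seed(seed)
  pool <- seq(length_range[1], length_range[2])
  lens <- pool[sample.int(length(pool), n_unigenes, replace = TRUE)]
  seqs <- vapply(lens, random_dna, character(1), gc = gc_fraction)
  names(seqs) <- sprintf("UN%05d", seq_len(n_unigenes))
  seqs
}

# Substitute k bases of `arm` (within positions `lo..hi`) so they no longer
# pair with their partner on the opposite strand; used to roughen the
# mature/star duplex.
#' @keywords internal
inject_mismatches <- function(arm, partner_arm, lo, hi, k) {
  if (k <= 0L) return(arm)
  a <- strsplit(arm, "", fixed = TRUE)[[1L]]
  p <- strsplit(partner_arm, "", fixed = TRUE)[[1L]]
  n <- length(a)
  for (j in sample(lo:hi, k)) {
    partner <- dna_to_rna(p[n - j + 1L])   # flush helix: j pairs n-j+1
    bad <- c("A", "C", "G", "T")[!vapply(c("A", "C", "G", "U"),
              can_pair_rna, logical(1), b = partner)]
    a[j] <- sample(bad, 1L)
  }
  paste0(a, collapse = "")
}

#' Plant a stem-loop miRNA precursor into a unigene
#'
#' Overwrites a window of the unigene with a constructed precursor shaped
#' like a canonical plant pre-miRNA: a lower stem, the mature/star duplex,
#' an upper stem, and an 8-12 nt unpairable loop. The 3' arm is the reverse
#' complement of the 5' arm with `stem_mismatches` non-pairing substitutions
#' injected opposite the mature interior (always on the star side, so the
#' mature still maps perfectly to the transcript). The mature sits strictly
#' inside one arm, and its star — the opposite-arm segment whose duplex with
#' the mature has 2-nt 3' overhangs — is recoverable from the fold. On the
#' `-` strand the reverse complement of the precursor is inserted, emulating
#' antisense-transcript miRNA loci.
#'
#' @param unigene single named character (DNA transcript).
#' @param mature mature miRNA, RNA or DNA, 20-24 nt.
#' @param arm `"5p"` or `"3p"`: which precursor arm carries the mature.
#' @param strand `"+"` or `"-"`.
#' @param position 1-based start of the inserted precursor on the `+` axis.
#' @param stem_mismatches number of mismatched mature bases in the duplex.
#' @param seed integer seed.
#' @return list with `unigene` (modified, same name) and `truth`, a one-row
#'   data.frame: `unigene`, `start`, `end`, `strand`, `arm` giving the exact
#'   1-based inclusive mature locus on the `+` axis, plus `precursor_start`,
#'   `precursor_end`.
#' @export
plant_precursor <- function(unigene, mature, arm = c("5p", "3p"),
                            strand = c("+", "-"), position,
                            stem_mismatches = 0L, seed = 1L) {
  arm <- match.arg(arm)
  strand <- match.arg(strand)
  mature_dna <- rna_to_dna(mature)
  L <- nchar(mature_dna)
  if (L < 20L || L > 24L) stop("mature length must be 20-24 nt")
  set.seed(seed)
  loop <- paste0(sample(c("A", "C"), sample(8:12, 1L), replace = TRUE),
                 collapse = "")
  lower <- random_dna(sample(8:12, 1L), gc = 0.5)   # lower stem, 5' side
  upper <- random_dna(sample(5:8, 1L), gc = 0.5)    # upper stem, 5' side
  core <- if (arm == "5p") mature_dna else revcomp(mature_dna)
  arm5 <- paste0(lower, core, upper)
  arm3 <- revcomp(arm5)
  core_start <- nchar(lower) + 1L
  core_end <- nchar(lower) + L
  if (arm == "5p") {
    # mismatches go into the 3' arm, opposite the mature interior
    n5 <- nchar(arm5)
    arm3 <- inject_mismatches(arm3, arm5, n5 - core_end + 3L,
                              n5 - core_start - 1L, stem_mismatches)
  } else {
    # mature lives on the 3' arm; roughen the 5' arm core (the star source)
    arm5 <- inject_mismatches(arm5, arm3, core_start + 1L, core_end - 3L,
                              stem_mismatches)
  }
  prec <- paste0(arm5, loop, arm3)
  plen <- nchar(prec)
  ulen <- nchar(unigene)
  if (position < 1L || position + plen - 1L > ulen) {
    stop("precursor window does not fit in the unigene at this position")
  }
  m1 <- if (arm == "5p") core_start else
    nchar(arm5) + nchar(loop) + (nchar(arm5) - core_end) + 1L
  if (strand == "-") {
    prec <- revcomp(prec)
    m1 <- plen - (m1 + L - 1L) + 1L
  }
  mod <- paste0(substr(unigene, 1L, position - 1L), prec,
                substr(unigene, position + plen, ulen))
  names(mod) <- names(unigene)
  truth <- data.frame(unigene = names(unigene) %||% NA_character_,
                      start = position + m1 - 1L,
                      end = position + m1 + L - 2L,
                      strand = strand, arm = arm,
                      precursor_start = position,
                      precursor_end = position + plen - 1L,
                      stringsAsFactors = FALSE)
  list(unigene = mod, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant a perfectly complementary miRNA target site
#'
#' Inserts the reverse complement of the mature miRNA into the transcript, so
#' the expected cleavage position (opposite miRNA nucleotide 10) is
#' `position + length(miRNA) - 10` on the transcript.
#'
#' @param unigene single named character (DNA transcript).
#' @param mature mature miRNA (RNA or DNA).
#' @param position 1-based insertion start.
#' @return list with `unigene` (modified) and `cleavage_pos`.
#' @export
plant_target_site <- function(unigene, mature, position) {
  site <- revcomp(rna_to_dna(mature))
  L <- nchar(site)
  if (position < 1L || position + L - 1L > nchar(unigene)) {
    stop("target site does not fit in the unigene at this position")
  }
  mod <- paste0(substr(unigene, 1L, position - 1L), site,
                substr(unigene, position + L, nchar(unigene)))
  names(mod) <- names(unigene)
  list(unigene = mod, cleavage_pos = position + L - 10L)
}

#' Generate a small structured-ncRNA contaminant set
#'
#' Stands in for an Rfam-style rRNA/tRNA/snRNA/snoRNA collection: random
#' sequences whose substrings are planted as contaminants by
#' [simulate_srna_libraries()].
#'
#' @param n number of records.
#' @param length_range length range in nt.
#' @param gc_fraction GC content.
#' @param seed integer seed.
#' @return named character vector (`ncRNA01`, ...).
#' @export
generate_ncrna_set <- function(n = 10L, length_range = c(70, 160),
                               gc_fraction = 0.5, seed = 1L) {
  set.seed(seed)
  pool <- seq(length_range[1], length_range[2])
  lens <- pool[sample.int(length(pool), n, replace = TRUE)]
  seqs <- vapply(lens, random_dna, character(1), gc = gc_fraction)
  names(seqs) <- sprintf("ncRNA%02d", seq_len(n))
  seqs
}

#' @keywords internal
validate_truth <- function(truth, transcriptome = NULL) {
  m <- truth$mirnas
  stopifnot(all(m$start >= 1L), all(m$end >= m$start),
            all(m$count_F >= 0L), all(m$count_M >= 0L),
            all(m$count_F + m$count_M > 0L))
  if (!is.null(transcriptome)) {
    stopifnot(all(m$end <= nchar(transcriptome[m$unigene])))
    if (nrow(truth$cleavage) > 0L) {
      stopifnot(all(truth$cleavage$position >= 1L),
                all(truth$cleavage$position <=
                      nchar(transcriptome[truth$cleavage$unigene])))
    }
  }
  invisible(TRUE)
}

#' Simulate a complete two-library study with known ground truth
#'
#' Builds a transcriptome, plants `n_mirnas` precursors (a mix of arms and
#' strands; `n_multi_locus` matures get a second precursor locus on another
#' unigene), assigns per-library expected counts with `n_de` differentially
#' expressed miRNAs (one of them male-specific when `n_de >= 2`), and plants
#' `n_targets` perfectly complementary cleavage sites for the first matures.
#'
#' Default abundances emulate a deeply down-scaled two-library experiment:
#' baseline expected counts of 8-40 reads per library per miRNA, 8-fold
#' planted differential expression, 5% ncRNA contamination.
#'
#' @param n_unigenes,n_mirnas,n_de,n_multi_locus,n_targets scenario sizes.
#' @param seed integer seed driving every random choice.
#' @return list with `transcriptome`, `ncrna`, `adapter`, and `truth` (list
#'   of `mirnas` and `cleavage` data.frames; class `mirpipe_truth`).
#' @export
simulate_study <- function(n_unigenes = 30L, n_mirnas = 10L, n_de = 2L,
                           n_multi_locus = 1L, n_targets = 3L, seed = 1L) {
  set.seed(seed)
  tx <- generate_transcriptome(n_unigenes, c(600, 1500), 0.45,
                               seed = seed + 101L)
  ncrna <- generate_ncrna_set(8L, seed = seed + 202L)
  adapter <- "TGGAATTCTCGGGTGCCAAGG"   # common sRNA 3' adapter sequence
  set.seed(seed)

  matures <- character(n_mirnas)
  for (i in seq_len(n_mirnas)) {
    len <- sample(20:24, 1L, prob = c(0.2, 0.4, 0.2, 0.1, 0.1))
    matures[i] <- paste0(c("T", sample(c("A", "C", "G", "T"), len - 1L,
                                       replace = TRUE)), collapse = "")
  }
  matures <- unique(matures)
  n_mirnas <- length(matures)

  arms <- sample(c("5p", "3p"), n_mirnas, replace = TRUE)
  strands <- sample(c("+", "-"), n_mirnas, replace = TRUE, prob = c(0.8, 0.2))
  host <- sample(names(tx), n_mirnas, replace = FALSE)
  rows <- vector("list", n_mirnas)
  for (i in seq_len(n_mirnas)) {
    u <- tx[host[i]]
    pos <- sample(150:(nchar(u) - 150L), 1L)
    # always >= 1 stem mismatch: a perfect-revcomp star arm would let the
    # mature itself map onto the star region of its own precursor
    pp <- plant_precursor(u, matures[i], arms[i], strands[i], pos,
                          stem_mismatches = sample(1:2, 1L),
                          seed = seed + 1000L + i)
    tx[host[i]] <- pp$unigene
    rows[[i]] <- pp$truth
  }
  truth_m <- do.call(rbind, rows)
  truth_m$mirna_id <- sprintf("mir%02d", seq_len(n_mirnas))
  truth_m$mature_rna <- dna_to_rna(matures)

  # second locus for the first n_multi_locus matures, on a fresh unigene
  extra <- list()
  if (n_multi_locus > 0L) {
    free <- setdiff(names(tx), host)
    for (i in seq_len(min(n_multi_locus, length(free)))) {
      u <- tx[free[i]]
      pos <- sample(150:(nchar(u) - 150L), 1L)
      pp <- plant_precursor(u, matures[i], "3p", "+", pos,
                            stem_mismatches = 1L, seed = seed + 2000L + i)
      tx[free[i]] <- pp$unigene
      e <- pp$truth
      e$mirna_id <- truth_m$mirna_id[i]
      e$mature_rna <- truth_m$mature_rna[i]
      extra[[i]] <- e
    }
  }
  loci <- rbind(truth_m, do.call(rbind, extra))

  # Baseline: equal expected counts in both libraries; planted DE miRNAs
  # keep the baseline in their up-library and drop 8-fold in the other, so
  # the two library totals stay roughly balanced.
  base <- sample(8:40, n_mirnas, replace = TRUE)
  count_F <- base
  count_M <- base
  de <- rep("ns", n_mirnas)
  if (n_de > 0L) {
    de_idx <- seq_len(min(n_de, n_mirnas))
    # planted DE miRNAs are moderately abundant, so the planted 8-fold
    # effect is statistically detectable at the simulated library depth
    base[de_idx] <- sample(25:40, length(de_idx), replace = TRUE)
    count_F[de_idx] <- base[de_idx]
    count_M[de_idx] <- base[de_idx]
    for (k in de_idx) {
      if (k %% 2L == 1L) {
        count_M[k] <- max(1L, round(base[k] / 8))
        de[k] <- "up_female"
      } else {
        # k == 2 is the male-specific case (absent from the female library)
        count_F[k] <- if (k == 2L) 0L else max(1L, round(base[k] / 8))
        de[k] <- "up_male"
      }
    }
  }
  truth_m$count_F <- count_F
  truth_m$count_M <- count_M
  truth_m$de <- de

  cleav <- data.frame(mirna_id = character(0), unigene = character(0),
                      position = integer(0), stringsAsFactors = FALSE)
  if (n_targets > 0L) {
    tgt_host <- setdiff(names(tx), c(host, loci$unigene))
    n_targets <- min(n_targets, n_mirnas, length(tgt_host))
    for (i in seq_len(n_targets)) {
      u <- tx[tgt_host[i]]
      pos <- sample(100:(nchar(u) - 100L), 1L)
      ps <- plant_target_site(u, matures[i], pos)
      tx[tgt_host[i]] <- ps$unigene
      cleav <- rbind(cleav, data.frame(mirna_id = truth_m$mirna_id[i],
                                       unigene = tgt_host[i],
                                       position = ps$cleavage_pos,
                                       stringsAsFactors = FALSE))
    }
  }

  truth <- structure(list(mirnas = truth_m, loci = loci, cleavage = cleav),
                     class = "mirpipe_truth")
  validate_truth(truth, tx)
  list(transcriptome = tx, ncrna = ncrna, adapter = adapter, truth = truth)
}

#' Simulate raw reads of the two sRNA libraries
#'
#' Each planted miRNA appears exactly `count_F` / `count_M` times as
#' insert+adapter reads in the respective library. Contaminants are exact
#' substrings of the ncRNA set; half of the noise reads are decoys sampled
#' from transcript positions (so they map perfectly downstream) and half are
#' random sequence.
#'
#' @param truth a `mirpipe_truth` object (see [simulate_study()]).
#' @param adapter 3' adapter, length >= 10.
#' @param ncrna named character vector of contaminant source sequences.
#' @param transcriptome named character vector (decoy source).
#' @param contaminant_fraction target contaminant fraction of each library,
#'   in `[0, 1)`.
#' @param noise_reads number of noise reads per library.
#' @param read_length raw read length before trimming.
#' @param seed integer seed.
#' @return list of two character vectors of raw DNA reads, named `F` and `M`.
#' @export
simulate_srna_libraries <- function(truth, adapter, ncrna = NULL,
                                    transcriptome = NULL,
                                    contaminant_fraction = 0.05,
                                    noise_reads = 0L, read_length = 40L,
                                    seed = 1L) {
  if (nchar(adapter) < 10L) stop("adapter length must be >= 10")
  if (contaminant_fraction >= 1 || contaminant_fraction < 0) {
    stop("contaminant_fraction must be in [0, 1)")
  }
  set.seed(seed)
  m <- truth$mirnas
  mk_read <- function(insert) substr(paste0(insert, adapter), 1L, read_length)
  out <- list()
  for (lib in c("F", "M")) {
    counts <- if (lib == "F") m$count_F else m$count_M
    planted <- rep(mk_read(rna_to_dna(m$mature_rna)), counts)
    noise <- character(0)
    if (noise_reads > 0L) {
      n_decoy <- floor(noise_reads / 2)
      if (!is.null(transcriptome) && n_decoy > 0L) {
        # decoys are background transcript fragments; keep them off the
        # planted precursor windows so they stay non-miRNA by construction
        loci <- truth$loci %||% truth$mirnas
        dec <- character(0)
        while (length(dec) < n_decoy) {
          id <- sample(names(transcriptome), 1L)
          len <- sample(20:24, 1L)
          L <- nchar(transcriptome[[id]])
          p <- sample.int(L - len + 1L, 1L)
          on_prec <- any(loci$unigene == id &
                           p <= loci$precursor_end &
                           p + len - 1L >= loci$precursor_start)
          if (!on_prec) {
            dec <- c(dec, substr(transcriptome[[id]], p, p + len - 1L))
          }
        }
        noise <- mk_read(dec)
      }
      n_rand <- noise_reads - length(noise)
      if (n_rand > 0L) {
        rnd <- vapply(sample(16:28, n_rand, replace = TRUE), random_dna,
                      character(1))
        noise <- c(noise, mk_read(rnd))
      }
    }
    n_cont <- if (is.null(ncrna)) 0L else
      round(contaminant_fraction / (1 - contaminant_fraction) *
              (length(planted) + length(noise)))
    cont <- character(0)
    if (n_cont > 0L) {
      src <- sample(names(ncrna), n_cont, replace = TRUE)
      lens <- sample(18:30, n_cont, replace = TRUE)
      cont <- vapply(seq_len(n_cont), function(i) {
        L <- nchar(ncrna[[src[i]]])
        p <- sample.int(L - lens[i] + 1L, 1L)
        substr(ncrna[[src[i]]], p, p + lens[i] - 1L)
      }, character(1))
      cont <- mk_read(cont)
    }
    reads <- c(planted, cont, noise)
    names(reads) <- sprintf("%s_read%06d", lib, seq_along(reads))
    out[[lib]] <- reads
  }
  out
}

#' Simulate degradome (PARE) reads
#'
#' For each entry of the truth cleavage table, emits `reads_per_site` reads
#' whose 5' end is exactly the cleavage position; background reads start at
#' uniformly random transcript positions. Sites too close to the transcript
#' end for a full read are skipped with a warning.
#'
#' @param truth a `mirpipe_truth` object.
#' @param transcriptome named character vector of DNA transcripts.
#' @param reads_per_site signal depth per planted site (>= 1).
#' @param background_reads number of uniform background reads.
#' @param read_length degradome read length (20 or 21 nt).
#' @param seed integer seed.
#' @return character vector of DNA reads.
#' @export
simulate_degradome <- function(truth, transcriptome, reads_per_site = 10L,
                               background_reads = 0L, read_length = 20L,
                               seed = 1L) {
  if (reads_per_site < 1L) stop("reads_per_site must be >= 1")
  if (!read_length %in% 20:21) stop("read_length must be 20 or 21")
  set.seed(seed)
  reads <- character(0)
  cl <- truth$cleavage
  for (i in seq_len(nrow(cl))) {
    tx <- transcriptome[[cl$unigene[i]]]
    p <- cl$position[i]
    if (p + read_length - 1L > nchar(tx)) {
      warning(sprintf("cleavage site %s:%d too close to transcript end; skipped",
                      cl$unigene[i], p))
      next
    }
    reads <- c(reads, rep(substr(tx, p, p + read_length - 1L), reads_per_site))
  }
  if (background_reads > 0L) {
    ids <- sample(names(transcriptome), background_reads, replace = TRUE)
    bg <- vapply(ids, function(id) {
      L <- nchar(transcriptome[[id]])
      p <- sample.int(L - read_length + 1L, 1L)
      substr(transcriptome[[id]], p, p + read_length - 1L)
    }, character(1), USE.NAMES = FALSE)
    reads <- c(reads, bg)
  }
  if (length(reads) > 0L) names(reads) <- sprintf("dg%06d", seq_along(reads))
  reads
}

#' Write a truth table as TSV
#'
#' Columns: mirna_id, sequence, unigene, start, end, strand, arm, count_F,
#' count_M, de_direction (one row per planted mature locus).
#'
#' @param truth a `mirpipe_truth` object.
#' @param path output TSV.
#' @export
write_truth_tsv <- function(truth, path) {
  m <- truth$mirnas
  write_tsv(data.frame(mirna_id = m$mirna_id, sequence = m$mature_rna,
                       unigene = m$unigene, start = m$start, end = m$end,
                       strand = m$strand, arm = m$arm,
                       count_F = m$count_F, count_M = m$count_M,
                       de_direction = m$de, stringsAsFactors = FALSE), path)
}
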