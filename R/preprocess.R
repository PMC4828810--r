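# Raw reads -> collapsed unique sRNA tags with per-library counts and TPM.
#
# Stage order follows standard sRNA-seq accounting: adapter trimming, then
# quality/length cleanup ("clean reads"), then ncRNA contaminant removal
# ("final clean reads"), then collapsing to unique tags. TPM denominators are
# each library's final clean read total.

#' Trim the 3' sequencing adapter from raw reads
#'
#' Returns the read prefix preceding the left-most adapter occurrence. An
#' occurrence is a full adapter match or a suffix overlap at the read end of
#' at least `min_overlap` bases, with at most `max_mismatch` mismatches.
#' Reads without any occurrence are rejected (`NA`), unless
#' `keep_untrimmed = TRUE` (for input that is already partially trimmed).
#'
#' @param reads character vector of raw DNA reads.
#' @param adapter adapter sequence (length >= `min_overlap`).
#' @param min_overlap minimum adapter bases that must be seen (default 6).
#' @param max_mismatch mismatches tolerated in the match (default 1).
#' @param keep_untrimmed keep reads with no adapter occurrence as-is.
#' @return character vector of inserts; `NA` marks rejected reads.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L, max_mismatch = 1L,
                         keep_untrimmed = FALSE) {
  if (nchar(adapter) < min_overlap) stop("adapter shorter than min_overlap")
  out <- .trim_adapter_cpp(as.character(reads), toupper(adapter),
                           as.integer(min_overlap), as.integer(max_mismatch))
  if (keep_untrimmed) out[is.na(out)] <- as.character(reads)[is.na(out)]
  names(out) <- names(reads)
  out
}

#' Keep reads within a length window
#'
#' @param reads character vector.
#' @param min_len,max_len inclusive bounds in nt (defaults 15 and 45).
#' @return the retained reads, order preserved.
#' @export
filter_length <- function(reads, min_len = 15L, max_len = 45L) {
  reads[!is.na(reads) & nchar(reads) >= min_len & nchar(reads) <= max_len]
}

#' Drop low-quality reads
#'
#' Reads containing `N` are always dropped; when Phred+33 quality strings are
#' supplied (FASTQ input), reads with mean Phred below `min_mean_phred` are
#' dropped too. FASTA input (no qualities) only gets the `N` rule.
#'
#' @param reads character vector of reads.
#' @param quals matching quality strings or `NULL`.
#' @param min_mean_phred mean-quality cutoff (default 20).
#' @return retained reads.
#' @export
filter_quality <- function(reads, quals = NULL, min_mean_phred = 20) {
  keep <- !grepl("N", reads, fixed = TRUE)
  if (!is.null(quals)) {
    mean_q <- vapply(quals, function(q) {
      if (nchar(q) == 0L) return(0)
      mean(utf8ToInt(q) - 33L)
    }, 0.0, USE.NAMES = FALSE)
    keep <- keep & mean_q >= min_mean_phred
  }
  reads[keep]
}

#' Remove ncRNA contaminants
#'
#' A read is removed iff it is an exact substring of any record in the ncRNA
#' set or of its reverse complement.
#'
#' @param reads character vector of DNA reads.
#' @param ncrna_set named character vector (Rfam-style rRNA/tRNA/snRNA/snoRNA
#'   sequences); must be non-empty.
#' @return list with `retained` (reads kept, order preserved) and
#'   `removed_count`.
#' @export
filter_ncrna <- function(reads, ncrna_set) {
  if (length(ncrna_set) == 0L) stop("ncRNA set is empty")
  subject <- paste(c(toupper(ncrna_set), revcomp(ncrna_set)), collapse = "#")
  uniq <- unique(reads)
  hit <- vapply(uniq, function(r) grepl(r, subject, fixed = TRUE),
                logical(1), USE.NAMES = TRUE)
  keep <- !hit[reads]
  list(retained = reads[keep], removed_count = sum(!keep))
}

#' Run the full per-library cleanup
#'
#' @param reads raw reads (character vector) for one library.
#' @param quals optional FASTQ quality strings.
#' @param adapter 3' adapter, or `NULL` for pre-trimmed input.
#' @param ncrna_set contaminant set, or `NULL` to skip that stage.
#' @param min_len,max_len retained length window.
#' @param min_overlap,max_mismatch,keep_untrimmed see [trim_adapter()].
#' @return list with `clean` (final clean reads) and `accounting` (one-row
#'   data.frame: raw_reads, after_trim, clean_reads, after_ncrna,
#'   unique_reads).
#' @export
preprocess_library <- function(reads, quals = NULL, adapter = NULL,
                               ncrna_set = NULL, min_len = 15L, max_len = 45L,
                               min_overlap = 6L, max_mismatch = 1L,
                               keep_untrimmed = FALSE) {
  raw_n <- length(reads)
  if (!is.null(adapter)) {
    trimmed <- trim_adapter(reads, adapter, min_overlap, max_mismatch,
                            keep_untrimmed)
    if (!is.null(quals)) quals <- quals[!is.na(trimmed)]
    trimmed <- trimmed[!is.na(trimmed)]
    if (!is.null(quals)) {
      quals <- substr(quals, 1L, nchar(trimmed))
    }
  } else {
    trimmed <- reads
  }
  after_trim <- length(trimmed)
  clean <- filter_quality(trimmed, quals)
  clean <- filter_length(clean, min_len, max_len)
  clean_n <- length(clean)
  if (!is.null(ncrna_set)) {
    fr <- filter_ncrna(clean, ncrna_set)
    clean <- fr$retained
  }
  list(clean = toupper(unname(clean)),
       accounting = data.frame(raw_reads = raw_n, after_trim = after_trim,
                               clean_reads = clean_n,
                               after_ncrna = length(clean),
                               unique_reads = length(unique(clean))))
}

#' Collapse clean reads into unique sRNA tags
#'
#' One record per distinct sequence with per-library raw counts and TPM
#' (count / library final-clean total x 1e6).
#'
#' @param libraries named list of character vectors of final clean reads
#'   (names are the library labels, e.g. `F` and `M`).
#' @return list with `unique_reads` (data.frame: sequence, `count_<lib>`,
#'   `tpm_<lib>` per library) and `totals` (named final clean totals).
#' @export
collapse_reads <- function(libraries) {
  labs <- names(libraries)
  if (is.null(labs) || any(labs == "")) stop("libraries must be named")
  all_seq <- sort(unique(unlist(libraries, use.names = FALSE)))
  out <- data.frame(sequence = all_seq, stringsAsFactors = FALSE)
  totals <- vapply(libraries, length, integer(1))
  for (lab in labs) {
    tab <- table(libraries[[lab]])
    cnt <- as.integer(tab[all_seq])
    cnt[is.na(cnt)] <- 0L
    out[[paste0("count_", lab)]] <- cnt
    out[[paste0("tpm_", lab)]] <-
      if (totals[lab] > 0L) cnt / totals[lab] * 1e6 else 0
  }
  list(unique_reads = out, totals = totals)
}

#' Preprocess two (or more) raw sRNA libraries
#'
#' Applies [preprocess_library()] per library and collapses the result.
#'
#' @param libraries named list; each element either a character vector of
#'   reads or a list with `seq` and `qual` (as from [read_seqs()]).
#' @param adapter,ncrna_set,... forwarded to [preprocess_library()].
#' @return list with `unique_reads`, `totals`, `accounting` (one row per
#'   library, library label in column `library`).
#' @export
preprocess_libraries <- function(libraries, adapter = NULL, ncrna_set = NULL,
                                 ...) {
  cleaned <- list()
  acc <- list()
  for (lab in names(libraries)) {
    x <- libraries[[lab]]
    if (is.list(x)) {
      r <- preprocess_library(x$seq, x$qual, adapter, ncrna_set, ...)
    } else {
      r <- preprocess_library(x, NULL, adapter, ncrna_set, ...)
    }
    cleaned[[lab]] <- r$clean
    acc[[lab]] <- cbind(data.frame(library = lab, stringsAsFactors = FALSE),
                        r$accounting)
  }
  cl <- collapse_reads(cleaned)
  list(unique_reads = cl$unique_reads, totals = cl$totals,
       accounting = do.call(rbind, acc))
}

#' Length distribution of unique sRNAs
#'
#' @param unique_reads data.frame from [collapse_reads()].
#' @return long data.frame (library, length, n_unique, fraction); fractions
#'   sum to 1 within each library.
#' @export
length_distribution <- function(unique_reads) {
  if (nrow(unique_reads) == 0L) stop("no unique reads")
  labs <- sub("^count_", "", grep("^count_", names(unique_reads),
                                  value = TRUE))
  lens <- nchar(unique_reads$sequence)
  rows <- lapply(labs, function(lab) {
    present <- unique_reads[[paste0("count_", lab)]] > 0L
    tab <- table(factor(lens[present], levels = sort(unique(lens))))
    data.frame(library = lab, length = as.integer(names(tab)),
               n_unique = as.integer(tab),
               fraction = as.integer(tab) / sum(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gate unique reads for miRNA identification
#'
#' Keeps tags with TPM >= `tpm_min` in at least one library and length
#' within `len_range` (defaults: TPM >= 5, 20-24 nt).
#'
#' @param unique_reads data.frame from [collapse_reads()].
#' @param tpm_min minimum TPM in at least one library.
#' @param len_range inclusive length window.
#' @return the retained rows.
#' @export
filter_candidates <- function(unique_reads, tpm_min = 5, len_range = c(20L, 24L)) {
  tpm_cols <- grep("^tpm_", names(unique_reads), value = TRUE)
  tpm_ok <- Reduce(`|`, lapply(tpm_cols, function(cn) unique_reads[[cn]] >= tpm_min))
  len <- nchar(unique_reads$sequence)
  unique_reads[tpm_ok & len >= len_range[1] & len <= len_range[2], ,
               drop = FALSE]
}
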