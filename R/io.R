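# Plain-text sequence IO, delegated to Biostrings.

#' Read sRNA sequences from FASTA or FASTQ
#'
#' The format is taken from the file extension (`.fq`/`.fastq` => FASTQ,
#' anything else FASTA). FASTQ qualities (Sanger Phred+33) are returned so the
#' preprocess stage can apply its quality filter; FASTA input has no
#' qualities and skips that filter.
#'
#' @param path input file.
#' @return list with `seq` (named character vector, DNA) and `qual`
#'   (character vector of quality strings, or `NULL` for FASTA).
#' @export
read_seqs <- function(path) {
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  if (fastq) {
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    qual <- as.character(Biostrings::quality(x))
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    qual <- NULL
  }
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  list(seq = seqs, qual = qual)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (names become headers; unnamed input is
#'   numbered `seq1`, `seq2`, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(rna_to_dna(seqs)), path)
  invisible(path)
}

#' @keywords internal
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
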