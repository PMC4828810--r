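# Sequence alphabet helpers. Reads are handled in DNA alphabet (T); mature
# miRNAs are reported in RNA alphabet (U), as in miRBase.

COMP_DNA <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Convert between DNA and RNA alphabets
#'
#' @param x character vector of sequences.
#' @return character vector with T<->U swapped, uppercased.
#' @export
dna_to_rna <- function(x) chartr("tT", "uU", toupper(chartr("u", "t", x)))

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("uU", "tT", toupper(x))

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    chars <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1L]])
    paste0(COMP_DNA[chars], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @keywords internal
check_alphabet <- function(x, alphabet, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste0(alphabet, collapse = "")), toupper(x))
  if (any(bad)) {
    stop(sprintf("invalid %s alphabet (expected only %s): %s",
                 what, paste(alphabet, collapse = ","),
                 substr(x[bad][1L], 1L, 40L)), call. = FALSE)
  }
  invisible(TRUE)
}

#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Can two RNA bases pair (Watson-Crick + G:U wobble)?
#' @keywords internal
can_pair_rna <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}
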