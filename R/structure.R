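# Secondary-structure prediction and the MFE/MFEI statistics used to judge
# candidate miRNA precursors.

#' Fold an RNA sequence into its minimum-free-energy structure
#'
#' Computes the optimal nested secondary structure under the package's
#' nearest-neighbor energy model (see [rna_energy_params()]) by dynamic
#' programming. Only canonical pairs (Watson-Crick and G:U) are formed, the
#' minimum hairpin loop is 3 nt and interior loops are bounded at
#' `params$max_interior` unpaired bases. The result is deterministic; among
#' co-optimal structures a pairing-rich, leftmost-pairing representative is
#' returned. Typical inputs are precursor windows of 30-500 nt, but any
#' sequence of at least 5 nt is accepted.
#'
#' @param sequence RNA (or DNA; T is read as U) string.
#' @param params energy parameter list from [rna_energy_params()].
#' @return an object of class `fold_result`: list with `sequence` (RNA),
#'   `structure` (dot-bracket) and `mfe` (kcal/mol, <= 0).
#' @examples
#' fold("GGGGGAAAACCCCC")
#' @export
fold <- function(sequence, params = rna_energy_params()) {
  sequence <- dna_to_rna(sequence)
  check_alphabet(sequence, c("A", "C", "G", "U"), "RNA")
  if (nchar(sequence) < 5L) stop("sequence too short to fold (< 5 nt)")
  res <- .fold_dp(sequence, params$stack, params$hairpin, params$bulge,
                  params$internal, params$asym_coef, params$asym_max,
                  params$ml_init, params$ml_branch, params$ml_unpaired,
                  params$min_hairpin, params$max_interior)
  out <- list(sequence = sequence, structure = res$structure,
              mfe = min(res$mfe, 0))
  class(out) <- "fold_result"
  out
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, sprintf(" (%.1f kcal/mol)\n", x$mfe),
      sep = "")
  invisible(x)
}

#' Extract maximal stem-loops from a folded structure
#'
#' A stem-loop is seeded at each hairpin-closing pair (a pair with no pairs
#' nested inside) and extended outward through enclosing pairs as long as the
#' enclosing pair has that stem as its only branch (bulges and internal loops
#' are absorbed). Multibranch junctions terminate the extension, so a
#' multi-loop structure yields one span per branch ending in a terminal loop.
#'
#' @param fold a `fold_result` (or any list with `structure`).
#' @return data.frame with columns `stem5_start`, `stem5_end`, `loop_start`,
#'   `loop_end`, `stem3_start`, `stem3_end` (1-based, inclusive) and `pairs`
#'   (number of base pairs in the stem).
#' @export
find_hairpins <- function(fold) {
  pt <- pair_table(fold$structure)
  n <- length(pt)
  if (n == 0L || all(pt == 0L)) {
    return(data.frame(stem5_start = integer(0), stem5_end = integer(0),
                      loop_start = integer(0), loop_end = integer(0),
                      stem3_start = integer(0), stem3_end = integer(0),
                      pairs = integer(0)))
  }
  # parent of each pair and number of direct pair-children
  left_idx <- which(pt > seq_len(n))            # left ends of pairs
  parent <- setNames(rep(NA_integer_, length(left_idx)), left_idx)
  nchild <- setNames(rep(0L, length(left_idx)), left_idx)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (pt[i] > i) {
      key <- as.character(i)
      if (length(stack) > 0L) {
        par <- as.character(stack[length(stack)])
        parent[key] <- stack[length(stack)]
        nchild[par] <- nchild[par] + 1L
      }
      stack <- c(stack, i)
    } else if (pt[i] != 0L && pt[i] < i) {
      stack <- stack[-length(stack)]
    }
  }
  hairpin_left <- left_idx[vapply(as.character(left_idx),
                                  function(k) nchild[k] == 0L, logical(1))]
  rows <- lapply(hairpin_left, function(h) {
    a <- h
    while (!is.na(parent[as.character(a)]) &&
           nchild[as.character(parent[as.character(a)])] == 1L) {
      a <- parent[as.character(a)]
    }
    inner_i <- h
    inner_j <- pt[h]
    outer_i <- a
    outer_j <- pt[a]
    npairs <- sum(left_idx >= outer_i & left_idx <= inner_i)
    data.frame(stem5_start = outer_i, stem5_end = inner_i,
               loop_start = inner_i + 1L, loop_end = inner_j - 1L,
               stem3_start = inner_j, stem3_end = outer_j,
               pairs = npairs)
  })
  out <- do.call(rbind, rows)
  out[order(out$stem5_start), , drop = FALSE]
}

#' GC fraction of a sequence
#'
#' @param sequence DNA or RNA string.
#' @return fraction of G+C bases, in `[0, 1]`.
#' @examples
#' gc_fraction("AGCGGGGUGUUCUGAUCCAUA")  # 0.524 for a 21-nt mature miRNA
#' @export
gc_fraction <- function(sequence) {
  if (nchar(sequence) == 0L) stop("empty sequence")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Minimal folding free energy index (MFEI)
#'
#' MFEI = (|MFE| / length * 100) / (GC * 100): the adjusted MFE per 100 nt
#' divided by the GC percentage. miRNA precursors typically score higher
#' (around 0.7-1.5 on mfold-type energies) than tRNA/rRNA/mRNA, which makes
#' MFEI a useful precursor filter. Computed on the precursor's own GC
#' fraction.
#'
#' @param mfe minimum free energy in kcal/mol (<= 0).
#' @param length sequence length in nt (> 0).
#' @param gc GC fraction in `(0, 1]`.
#' @return non-negative real.
#' @examples
#' mfei(-60, 200, 0.5)  # 0.6
#' @export
mfei <- function(mfe, length, gc) {
  if (length <= 0) stop("length must be positive")
  if (is.na(gc) || gc <= 0 || gc > 1) stop("gc must be in (0, 1]")
  if (mfe > 0) stop("mfe must be <= 0")
  (abs(mfe) / length * 100) / (gc * 100)
}
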