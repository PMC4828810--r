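# Nearest-neighbor RNA folding energy model.
#
# One parameter table drives both the dynamic-programming folder (src/fold.cpp)
# and the R structure evaluator below, so the two routes score any structure
# identically. Values are Turner-like stacking/loop energies in kcal/mol at
# 37 C; absolute energies are model-dependent, which is why MFE thresholds
# elsewhere in the package are configuration values rather than constants.

PAIR_LEVELS <- c("CG", "GC", "AU", "UA", "GU", "UG")

#' Folding energy parameter set
#'
#' Returns the nearest-neighbor parameter table used by [fold()] and
#' [eval_structure_energy()]: stacking energies for the six canonical pairs
#' (Watson-Crick plus G:U wobble), hairpin/bulge/internal-loop initiation
#' penalties with logarithmic extrapolation, an internal-loop asymmetry
#' penalty, and affine multibranch-loop costs. Only canonical pairs are
#' allowed; the minimum hairpin loop is 3 nt.
#'
#' @param max_loop precompute loop penalties up to this size (nt).
#' @return a list with components `pairs`, `stack` (6x6 matrix, kcal/mol),
#'   `hairpin`, `bulge`, `internal` (penalty vectors indexed by loop size),
#'   `asym_coef`, `asym_max`, `ml_init`, `ml_branch`, `ml_unpaired`,
#'   `min_hairpin`, `max_interior`.
#' @export
rna_energy_params <- function(max_loop = 800L) {
  stack <- matrix(c(
    # inner:  CG    GC    AU    UA    GU    UG      outer:
            -3.3, -3.4, -2.1, -2.1, -1.4, -2.1,   # CG
            -2.4, -3.3, -2.2, -2.3, -1.5, -2.5,   # GC
            -2.1, -2.2, -0.9, -1.3, -0.6, -1.4,   # AU
            -2.1, -2.4, -1.1, -0.9, -1.0, -1.3,   # UA
            -2.1, -2.5, -1.4, -1.3, -0.5,  1.3,   # GU
            -1.4, -1.5, -0.6, -1.0, -0.3, -0.5),  # UG
    nrow = 6, byrow = TRUE, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))

  sizes <- seq_len(max_loop)
  hairpin <- rep(Inf, max_loop)
  h0 <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)      # sizes 3..9
  hairpin[3:9] <- h0
  hairpin[sizes > 9] <- round(6.4 + 1.08 * log(sizes[sizes > 9] / 9), 1)

  bulge <- rep(Inf, max_loop)
  b0 <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)           # sizes 1..6
  bulge[1:6] <- b0
  bulge[sizes > 6] <- round(4.4 + 1.08 * log(sizes[sizes > 6] / 6), 1)

  internal <- rep(Inf, max_loop)
  i0 <- c(1.5, 1.6, 1.7, 1.8, 2.0)                # sizes 2..6
  internal[2:6] <- i0
  internal[sizes > 6] <- round(2.0 + 1.08 * log(sizes[sizes > 6] / 6), 1)

  list(pairs = PAIR_LEVELS, stack = stack,
       hairpin = hairpin, bulge = bulge, internal = internal,
       asym_coef = 0.5, asym_max = 3.0,
       ml_init = 3.4, ml_branch = 0.4, ml_unpaired = 0.0,
       min_hairpin = 3L, max_interior = 30L)
}

#' @keywords internal
pair_index <- function(a, b) match(paste0(a, b), PAIR_LEVELS)

#' Parse dot-bracket notation into a pair table
#'
#' @param structure dot-bracket string (`(`, `)`, `.`).
#' @return integer vector `pt` with `pt[i]` the 1-based partner of position
#'   `i`, or 0 if unpaired.
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("(", ")", "."))) stop("invalid dot-bracket string")
  n <- length(chars)
  pt <- integer(n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      open <- c(open, i)
    } else if (chars[i] == ")") {
      if (length(open) == 0L) stop("unbalanced dot-bracket string")
      j <- open[length(open)]
      open <- open[-length(open)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(open) > 0L) stop("unbalanced dot-bracket string")
  pt
}

#' Score a secondary structure under the package energy model
#'
#' Decomposes a nested structure into its loops (hairpin, stack, bulge,
#' internal, multibranch, exterior) and sums their free-energy contributions
#' from [rna_energy_params()]. This loop-decomposition route is independent of
#' the dynamic-programming recursions in [fold()] and is used to cross-check
#' them.
#'
#' @param sequence RNA string (A/C/G/U).
#' @param structure dot-bracket string of the same length.
#' @param params energy parameter list, see [rna_energy_params()].
#' @return free energy in kcal/mol (`Inf` for structures the model forbids,
#'   e.g. a hairpin loop shorter than 3 nt).
#' @export
eval_structure_energy <- function(sequence, structure,
                                  params = rna_energy_params()) {
  sequence <- dna_to_rna(sequence)
  check_alphabet(sequence, c("A", "C", "G", "U"), "RNA")
  if (nchar(sequence) != nchar(structure)) {
    stop("sequence and structure lengths differ")
  }
  s <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  pt <- pair_table(structure)
  n <- length(pt)
  # integer tenths of kcal/mol so both scoring routes agree exactly
  st10 <- round(params$stack * 10)
  h10 <- round(params$hairpin * 10)
  b10 <- round(params$bulge * 10)
  i10 <- round(params$internal * 10)
  e <- 0
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j <= i) next
    pij <- pair_index(s[i], s[j])
    if (is.na(pij)) stop(sprintf("non-canonical pair %s-%s at %d,%d",
                                 s[i], s[j], i, j))
    # collect direct children of (i, j)
    children <- list()
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (pt[k] > k) {
        children[[length(children) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    nc <- length(children)
    if (nc == 0L) {
      size <- j - i - 1L
      if (size < params$min_hairpin) return(Inf)
      e <- e + h10[size]
    } else if (nc == 1L) {
      k <- children[[1L]][1L]; l <- children[[1L]][2L]
      pkl <- pair_index(s[k], s[l])
      n1 <- k - i - 1L; n2 <- j - l - 1L
      if (n1 == 0L && n2 == 0L) {
        e <- e + st10[pij, pkl]
      } else if (n1 == 0L || n2 == 0L) {
        nb <- n1 + n2
        e <- e + b10[nb]
        if (nb == 1L) e <- e + st10[pij, pkl]   # single-nt bulge keeps stack
      } else {
        e <- e + i10[n1 + n2] +
          round(min(params$asym_max, params$asym_coef * abs(n1 - n2)) * 10)
      }
    } else {
      e <- e + round(params$ml_init * 10) +
        round(params$ml_branch * 10) * (nc + 1L) +
        round(params$ml_unpaired * 10) * unpaired
    }
  }
  if (!is.finite(e)) return(Inf)
  e / 10
}
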