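# Independent oracles used to cross-check the package implementations.

# Exhaustive enumeration of all nested secondary structures (canonical pairs
# only, minimum hairpin loop 3). Returns dot-bracket strings; intended for
# sequences up to ~20 nt.
enumerate_structures <- function(seq) {
  s <- strsplit(dna_to_rna(seq), "", fixed = TRUE)[[1L]]
  n <- length(s)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return("")
    key <- paste0(i, "_", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- paste0(".", rec(i + 1L, j))
    k <- i + 4L
    while (k <= j) {
      if (paste0(s[i], s[k]) %in% c("AU", "UA", "CG", "GC", "GU", "UG")) {
        inner <- rec(i + 1L, k - 1L)
        right <- rec(k + 1L, j)
        out <- c(out, as.vector(outer(paste0("(", inner, ")"), right,
                                      paste0)))
      }
      k <- k + 1L
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# Brute-force MFE: minimum of eval_structure_energy over all enumerated
# structures (0 for the open chain).
brute_force_mfe <- function(seq, params = rna_energy_params()) {
  es <- vapply(enumerate_structures(seq), eval_structure_energy, 0.0,
               sequence = seq, params = params, USE.NAMES = FALSE)
  min(c(0, es[is.finite(es)]))
}

# Two-sided Fisher p by explicit hypergeometric enumeration over all tables
# with the observed margins; tables at most as probable as the observed one
# (within the customary 1e-7 relative slack for floating-point ties) are
# summed.
fisher_oracle <- function(a, ta, b, tb) {
  c1 <- a + b
  lo <- max(0L, c1 - tb)
  hi <- min(c1, ta)
  x <- lo:hi
  d <- stats::dhyper(x, ta, tb, c1)
  sum(d[d <= d[x == a] * (1 + 1e-7)])
}

# Degradome category classifier written from the rule text, independent of
# categorize(): loops instead of vectorised max/median calls.
categorize_oracle <- function(count_at_site, profile) {
  if (count_at_site == 1L) return(4L)
  occ <- c()
  for (v in profile) if (v > 0L) occ <- c(occ, v)
  M <- occ[1L]
  for (v in occ) if (v > M) M <- v
  n_at_max <- 0L
  for (v in profile) if (v == M) n_at_max <- n_at_max + 1L
  if (count_at_site == M && n_at_max == 1L) return(0L)
  if (count_at_site == M) return(1L)
  srt <- sort(occ)
  m <- if (length(srt) %% 2L == 1L) {
    srt[(length(srt) + 1L) / 2L]
  } else {
    (srt[length(srt) / 2L] + srt[length(srt) / 2L + 1L]) / 2
  }
  if (count_at_site > m) return(2L)
  3L
}

# Random RNA sequence (uniform bases).
random_rna <- function(n) {
  paste0(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Random DNA sequence at a target GC content.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
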