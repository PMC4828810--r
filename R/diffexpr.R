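# Two-library count-based differential expression: TPM normalisation, fold
# changes, Fisher's exact / chi-square tests, BH adjustment and DE calls,
# plus the 2^-ddCt qRT-PCR calculator.

#' Transcripts-per-million normalisation
#'
#' @param count non-negative read count(s).
#' @param library_total the library's final clean read total (> 0).
#' @return `count / library_total * 1e6`.
#' @export
tpm <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be > 0")
  if (any(count < 0)) stop("counts must be >= 0")
  count / library_total * 1e6
}

#' Fold change between two TPM values
#'
#' Ratio is `tpm_a / tpm_b`: 0 when `tpm_a` is 0 and `Inf` when `tpm_b` is 0
#' (either case sets the library-specific flag); log2 is defined only when
#' both are positive.
#'
#' @param tpm_a,tpm_b TPM values (not both 0).
#' @return data.frame (ratio, log2_fc, library_specific), vectorised.
#' @export
fold_change <- function(tpm_a, tpm_b) {
  if (any(tpm_a < 0 | tpm_b < 0)) stop("TPM must be >= 0")
  if (any(tpm_a == 0 & tpm_b == 0)) stop("both TPM values are zero")
  ratio <- ifelse(tpm_b == 0, Inf, tpm_a / tpm_b)
  log2_fc <- ifelse(tpm_a > 0 & tpm_b > 0, log2(tpm_a / tpm_b), NA_real_)
  data.frame(ratio = ratio, log2_fc = log2_fc,
             library_specific = tpm_a == 0 | tpm_b == 0)
}

#' Two-sided Fisher's exact test on a 2x2 count table
#'
#' Tests the table `[[count_a, total_a - count_a], [count_b, total_b -
#' count_b]]`; the two-sided p sums hypergeometric probabilities of tables
#' at most as probable as the observed one.
#'
#' @param count_a,total_a,count_b,total_b non-negative integers,
#'   `count <= total` (vectorised).
#' @return p-value(s).
#' @export
fisher_test_counts <- function(count_a, total_a, count_b, total_b) {
  if (any(c(count_a, total_a, count_b, total_b) < 0)) {
    stop("negative inputs")
  }
  if (any(count_a > total_a | count_b > total_b)) stop("count > total")
  mapply(function(ca, ta, cb, tb) {
    p <- stats::fisher.test(matrix(c(ca, ta - ca, cb, tb - cb), nrow = 2,
                                   byrow = TRUE))$p.value
    min(1, max(0, p))   # guard the tiny floating overshoot above 1
  }, count_a, total_a, count_b, total_b)
}

#' Chi-square test on the same 2x2 table
#'
#' 1-df chi-square, no continuity correction by default.
#'
#' @inheritParams fisher_test_counts
#' @param correct apply the Yates continuity correction.
#' @return p-value(s).
#' @export
chisq_test_counts <- function(count_a, total_a, count_b, total_b,
                              correct = FALSE) {
  mapply(function(ca, ta, cb, tb) {
    m <- matrix(c(ca, ta - ca, cb, tb - cb), nrow = 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      stop("zero margin in 2x2 table")
    }
    suppressWarnings(stats::chisq.test(m, correct = correct)$p.value)
  }, count_a, total_a, count_b, total_b)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up by default (Bonferroni available); output
#' order matches input.
#'
#' @param p p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return adjusted p-values.
#' @export
adjust_p <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Build the differential-expression table for two libraries
#'
#' TPM, fold change (library a over library b), the chosen test's raw p,
#' adjusted p, and the DE call: `up_a` when ratio >= `fc_threshold`, `up_b`
#' when ratio <= 1/`fc_threshold`, each requiring adjusted p < `alpha`;
#' library-specific entries (one TPM zero) are callable on p alone.
#'
#' @param ids miRNA identifiers.
#' @param count_a,count_b per-miRNA read counts.
#' @param total_a,total_b library final clean totals.
#' @param fc_threshold fold-change cutoff (default 2).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param test `"fisher"` (default) or `"chisq"`.
#' @param p_adjust_method see [adjust_p()].
#' @param labels two library labels used in the `de_call` values and column
#'   names (default `c("F", "M")`).
#' @return data.frame: id, count/tpm per library, ratio, log2_fc,
#'   library_specific, p_raw, p_adj, de_call.
#' @export
de_table <- function(ids, count_a, count_b, total_a, total_b,
                     fc_threshold = 2, alpha = 0.05,
                     test = c("fisher", "chisq"),
                     p_adjust_method = "BH", labels = c("F", "M")) {
  test <- match.arg(test)
  tpm_a <- tpm(count_a, total_a)
  tpm_b <- tpm(count_b, total_b)
  fc <- fold_change(tpm_a, tpm_b)
  p_raw <- if (test == "fisher") {
    fisher_test_counts(count_a, total_a, count_b, total_b)
  } else {
    chisq_test_counts(count_a, total_a, count_b, total_b)
  }
  p_adj <- adjust_p(p_raw, p_adjust_method)
  up_a <- fc$ratio >= fc_threshold & p_adj < alpha
  up_b <- fc$ratio <= 1 / fc_threshold & p_adj < alpha
  de_call <- ifelse(up_a, paste0("up_", labels[1]),
                    ifelse(up_b, paste0("up_", labels[2]), "ns"))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  out[[paste0("count_", labels[1])]] <- count_a
  out[[paste0("count_", labels[2])]] <- count_b
  out[[paste0("tpm_", labels[1])]] <- tpm_a
  out[[paste0("tpm_", labels[2])]] <- tpm_b
  out$ratio <- fc$ratio
  out$log2_fc <- fc$log2_fc
  out$library_specific <- fc$library_specific
  out$p_raw <- p_raw
  out$p_adj <- p_adj
  out$de_call <- de_call
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-[(Ct_target,cond - Ct_ref,cond) - (Ct_target,base - Ct_ref,base)]`.
#'
#' @param ct_target_cond,ct_ref_cond Ct of target and reference gene in the
#'   condition of interest.
#' @param ct_target_base,ct_ref_base Ct pair in the baseline condition.
#' @return relative expression (1 when ddCt = 0).
#' @examples
#' ddct(20, 15, 22, 15)  # ddCt = -2 -> 4
#' @export
ddct <- function(ct_target_cond, ct_ref_cond, ct_target_base, ct_ref_base) {
  stopifnot(is.finite(ct_target_cond), is.finite(ct_ref_cond),
            is.finite(ct_target_base), is.finite(ct_ref_base))
  2^-((ct_target_cond - ct_ref_cond) - (ct_target_base - ct_ref_base))
}

# Table formatting conventions used in report files: TPM 2 d.p., ratio
# 3 d.p., log2 4 d.p.
#' @keywords internal
format_tpm <- function(x) sprintf("%.2f", x)
#' @keywords internal
format_ratio <- function(x) ifelse(is.infinite(x), "Inf", sprintf("%.3f", x))
#' @keywords internal
format_log2 <- function(x) ifelse(is.na(x), "", sprintf("%.4f", x))
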