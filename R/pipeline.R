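# Orchestration of the full analysis: preprocess -> conserved assignment ->
# novel discovery -> differential expression -> degradome targets, with
# Table-style TSV reports. All stages are deterministic given the inputs, so
# re-running a configuration reproduces the report files byte for byte.

#' Assemble a pipeline configuration
#'
#' In-memory variant: every input is an R object (reads, sequences). Use
#' [run_pipeline_files()] for file-path inputs.
#'
#' @param libraries named list of two raw read vectors (or `list(seq, qual)`
#'   pairs), e.g. `list(F = ..., M = ...)`.
#' @param transcriptome named character vector of unigene DNA sequences.
#' @param mature_db named character vector of known mature miRNAs (or `NULL`
#'   to skip conserved assignment).
#' @param ncrna_db contaminant set (or `NULL` to skip that filter).
#' @param degradome degradome reads (or `NULL` to skip the degradome stage).
#' @param adapter 3' adapter (or `NULL` for pre-trimmed reads).
#' @param thresholds novel-miRNA thresholds, see [novel_thresholds()].
#' @param fc_threshold,alpha,test,p_adjust_method DE-stage settings.
#' @param max_mismatch conserved-assignment mismatch bound.
#' @param degradome_max_score,cleavage_window degradome-stage settings.
#' @param seed integer seed recorded with the run.
#' @param outdir report directory (or `NULL` for no files).
#' @return list of class `mirpipe_config`.
#' @export
pipeline_config <- function(libraries, transcriptome, mature_db = NULL,
                            ncrna_db = NULL, degradome = NULL, adapter = NULL,
                            thresholds = novel_thresholds(),
                            fc_threshold = 2, alpha = 0.05, test = "fisher",
                            p_adjust_method = "BH", max_mismatch = 2L,
                            degradome_max_score = 7, cleavage_window = 10L,
                            seed = 1L, outdir = NULL) {
  cfg <- list(libraries = libraries, transcriptome = transcriptome,
              mature_db = mature_db, ncrna_db = ncrna_db,
              degradome = degradome, adapter = adapter,
              thresholds = thresholds, fc_threshold = fc_threshold,
              alpha = alpha, test = test, p_adjust_method = p_adjust_method,
              max_mismatch = max_mismatch,
              degradome_max_score = degradome_max_score,
              cleavage_window = cleavage_window, seed = seed, outdir = outdir)
  class(cfg) <- "mirpipe_config"
  cfg
}

#' Run the full pipeline from file paths
#'
#' Thin wrapper that reads FASTA/FASTQ inputs and calls [run_pipeline()].
#' Missing paths fail fast with the offending path.
#'
#' @param library_paths named character vector of two sRNA read files.
#' @param transcriptome_path,mature_db_path,ncrna_path,degradome_path input
#'   FASTA/FASTQ paths (the last three optional, `NULL` to skip).
#' @param ... further arguments to [pipeline_config()].
#' @return a `mirpipe_result`.
#' @export
run_pipeline_files <- function(library_paths, transcriptome_path,
                               mature_db_path = NULL, ncrna_path = NULL,
                               degradome_path = NULL, ...) {
  need <- c(library_paths, transcriptome_path, mature_db_path, ncrna_path,
            degradome_path)
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L) stop("missing input file: ", missing[1L])
  libs <- lapply(library_paths, read_seqs)
  cfg <- pipeline_config(
    libraries = libs,
    transcriptome = read_seqs(transcriptome_path)$seq,
    mature_db = if (!is.null(mature_db_path)) read_seqs(mature_db_path)$seq,
    ncrna_db = if (!is.null(ncrna_path)) read_seqs(ncrna_path)$seq,
    degradome = if (!is.null(degradome_path)) read_seqs(degradome_path)$seq,
    ...)
  run_pipeline(cfg)
}

#' Run the full analysis pipeline
#'
#' Stages in order: preprocessing/collapsing, conserved miRNA assignment,
#' novel miRNA discovery, differential expression over all called miRNAs,
#' and (when degradome reads are present) degradome target identification
#' for the called miRNAs. When `outdir` is set, Table-style TSV reports and
#' a per-stage run log are written.
#'
#' @param config a `mirpipe_config`.
#' @return object of class `mirpipe_result`: list with `accounting`,
#'   `unique_reads`, `totals`, `conserved`, `families`, `novel`, `de`,
#'   `degradome_hits`, `tplots`, `config`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mirpipe_config"))
  labs <- names(config$libraries)
  if (length(labs) != 2L) stop("exactly two libraries are required")
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }

  pp <- preprocess_libraries(config$libraries, adapter = config$adapter,
                             ncrna_set = config$ncrna_db)
  for (k in seq_len(nrow(pp$accounting))) {
    a <- pp$accounting[k, ]
    say("preprocess [%s]: raw %d -> trimmed %d -> clean %d -> final %d (unique %d)",
        a$library, a$raw_reads, a$after_trim, a$clean_reads, a$after_ncrna,
        a$unique_reads)
  }

  gated <- filter_candidates(pp$unique_reads, config$thresholds$tpm_min,
                             config$thresholds$len_range)
  say("candidate gate (TPM >= %g, %d-%d nt): %d of %d unique reads",
      config$thresholds$tpm_min, config$thresholds$len_range[1],
      config$thresholds$len_range[2], nrow(gated), nrow(pp$unique_reads))

  conserved <- if (!is.null(config$mature_db)) {
    match_known(gated, config$mature_db, config$max_mismatch)
  } else {
    match_known(gated[0, , drop = FALSE], c(dummy = "A"), 0L)
  }
  say("conserved: %d reads assigned to %d families", nrow(conserved),
      nrow(family_summary(conserved)))

  cand <- scan_novel_loci(pp$unique_reads, config$transcriptome,
                          exclude = conserved$sequence,
                          thresholds = config$thresholds)
  novel <- assemble_novel_set(cand, pp$unique_reads)
  say("novel: %d candidate loci, %d passing, %d novel miRNAs",
      nrow(cand), sum(cand$pass), nrow(novel$mirnas))

  # DE over all called miRNAs (conserved + novel)
  ids <- character(0)
  seqs <- character(0)
  if (nrow(conserved) > 0L) {
    ids <- conserved$ref_id
    seqs <- conserved$sequence
  }
  if (nrow(novel$mirnas) > 0L) {
    ids <- c(ids, novel$mirnas$id)
    seqs <- c(seqs, rna_to_dna(novel$mirnas$sequence))
  }
  de <- NULL
  if (length(ids) > 0L) {
    m <- match(seqs, pp$unique_reads$sequence)
    cA <- pp$unique_reads[[paste0("count_", labs[1])]][m]
    cB <- pp$unique_reads[[paste0("count_", labs[2])]][m]
    de <- de_table(ids, cA, cB, pp$totals[[labs[1]]], pp$totals[[labs[2]]],
                   fc_threshold = config$fc_threshold, alpha = config$alpha,
                   test = config$test,
                   p_adjust_method = config$p_adjust_method, labels = labs)
    de$sequence <- dna_to_rna(seqs)
    say("differential expression: %d tested, %d up-%s, %d up-%s",
        nrow(de), sum(de$de_call == paste0("up_", labs[1])), labs[1],
        sum(de$de_call == paste0("up_", labs[2])), labs[2])
  }

  hits <- NULL
  tplots <- NULL
  if (!is.null(config$degradome) && length(ids) > 0L) {
    profiles <- map_degradome(config$degradome, config$transcriptome)
    mirnas <- setNames(dna_to_rna(seqs), ids)
    mirnas <- mirnas[!duplicated(names(mirnas))]
    hits <- degradome_targets(mirnas, config$transcriptome, profiles,
                              config$degradome_max_score,
                              config$cleavage_window)
    tplots <- lapply(unique(hits$transcript), function(tid) {
      tplot_table(profiles[[tid]], hits[hits$transcript == tid, ])
    })
    names(tplots) <- unique(hits$transcript)
    say("degradome: %d mapped reads, %d target hits on %d transcripts",
        attr(profiles, "total"), nrow(hits), length(tplots))
  }

  res <- structure(list(accounting = pp$accounting,
                        unique_reads = pp$unique_reads, totals = pp$totals,
                        conserved = conserved,
                        families = family_summary(conserved),
                        novel = novel, de = de, degradome_hits = hits,
                        tplots = tplots, config = config, log = log),
                   class = "mirpipe_result")
  if (!is.null(config$outdir)) render_reports(res, config$outdir)
  res
}

#' Write Table-style TSV reports for a pipeline result
#'
#' Files: `accounting.tsv`, `unique_reads.tsv`, `conserved.tsv`,
#' `novel_mirnas.tsv` + `novel_loci.tsv`, `de_table.tsv` (TPM 2 d.p., ratio
#' 3 d.p., log2 4 d.p.; log2 blank for library-specific entries),
#' `degradome_hits.tsv`, per-transcript `tplot_<id>.tsv`, `summary.txt` and
#' `run.log`.
#'
#' @param res a `mirpipe_result`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
render_reports <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  labs <- names(res$config$libraries)
  write_tsv(res$accounting, p("accounting.tsv"))
  ur <- res$unique_reads
  for (cn in grep("^tpm_", names(ur), value = TRUE)) ur[[cn]] <- format_tpm(ur[[cn]])
  write_tsv(ur, p("unique_reads.tsv"))
  write_tsv(res$conserved, p("conserved.tsv"))
  nm <- res$novel$mirnas
  if (nrow(nm) > 0L) {
    for (cn in grep("^tpm_", names(nm), value = TRUE)) nm[[cn]] <- format_tpm(nm[[cn]])
  }
  write_tsv(nm, p("novel_mirnas.tsv"))
  loci <- res$novel$loci
  if (nrow(loci) > 0L) {
    loci$mfe <- sprintf("%.2f", loci$mfe)
    loci$gc <- sprintf("%.1f", 100 * loci$gc)
    loci$mfei <- sprintf("%.2f", loci$mfei)
  }
  write_tsv(loci, p("novel_loci.tsv"))
  if (!is.null(res$de)) {
    de <- res$de
    for (cn in grep("^tpm_", names(de), value = TRUE)) de[[cn]] <- format_tpm(de[[cn]])
    de$ratio <- format_ratio(de$ratio)
    de$log2_fc <- format_log2(de$log2_fc)
    write_tsv(de, p("de_table.tsv"))
  }
  if (!is.null(res$degradome_hits)) {
    write_tsv(res$degradome_hits, p("degradome_hits.tsv"))
    for (tid in names(res$tplots)) {
      write_tsv(res$tplots[[tid]], p(sprintf("tplot_%s.tsv", tid)))
    }
  }
  summary_lines <- c(
    sprintf("final clean reads: %s", paste(sprintf("%s=%d", labs,
            res$totals[labs]), collapse = " ")),
    sprintf("unique reads: %d", nrow(res$unique_reads)),
    sprintf("conserved miRNAs: %d (families: %d)", nrow(res$conserved),
            nrow(res$families)),
    sprintf("novel miRNAs: %d", nrow(res$novel$mirnas)),
    if (!is.null(res$de)) sprintf("DE: %d up_%s, %d up_%s",
        sum(res$de$de_call == paste0("up_", labs[1])), labs[1],
        sum(res$de$de_call == paste0("up_", labs[2])), labs[2]),
    if (!is.null(res$degradome_hits))
      sprintf("degradome hits: %d", nrow(res$degradome_hits)))
  writeLines(summary_lines, p("summary.txt"))
  writeLines(res$log, p("run.log"))
  invisible(outdir)
}

#' @export
print.mirpipe_result <- function(x, ...) {
  cat("mirpipe pipeline result\n")
  cat(sprintf("  libraries: %s (final clean %s)\n",
              paste(names(x$totals), collapse = "/"),
              paste(x$totals, collapse = "/")))
  cat(sprintf("  unique sRNAs: %d\n", nrow(x$unique_reads)))
  cat(sprintf("  conserved assignments: %d\n", nrow(x$conserved)))
  cat(sprintf("  novel miRNAs: %d\n", nrow(x$novel$mirnas)))
  if (!is.null(x$de)) {
    cat(sprintf("  DE calls: %d of %d\n", sum(x$de$de_call != "ns"),
                nrow(x$de)))
  }
  if (!is.null(x$degradome_hits)) {
    cat(sprintf("  degradome hits: %d\n", nrow(x$degradome_hits)))
  }
  invisible(x)
}

#' @export
summary.mirpipe_result <- function(object, ...) {
  print(object)
  cat("\nper-library accounting:\n")
  print(object$accounting, row.names = FALSE)
  if (nrow(object$families) > 0L) {
    cat("\nconserved families:\n")
    print(head(object$families, 10), row.names = FALSE)
  }
  invisible(object)
}
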