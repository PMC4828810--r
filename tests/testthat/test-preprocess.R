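test_that("adapter trimming returns the insert before the left-most hit", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "TGACAGAAGAGAGAGAGCACT"      # 21 nt
  expect_equal(unname(trim_adapter(paste0(insert, adapter), adapter)), insert)
  # suffix overlap at the read end
  expect_equal(unname(trim_adapter(paste0(insert, substr(adapter, 1, 8)),
                                   adapter)), insert)
  # one mismatch tolerated, two not
  mut <- paste0("A", substr(adapter, 2, nchar(adapter)))
  expect_equal(unname(trim_adapter(paste0(insert, mut), adapter)), insert)
  mut2 <- paste0("AA", substr(adapter, 3, nchar(adapter)))
  expect_true(is.na(trim_adapter(paste0(insert, mut2), adapter)))
  # no occurrence: rejected in raw mode, kept in pre-trimmed mode
  expect_true(is.na(trim_adapter(insert, adapter)))
  expect_equal(unname(trim_adapter(insert, adapter, keep_untrimmed = TRUE)),
               insert)
  # a 12-nt insert is returned here and removed later by the length filter
  short <- substr(insert, 1, 12)
  out <- trim_adapter(paste0(short, adapter), adapter)
  expect_equal(unname(out), short)
  expect_equal(length(filter_length(out)), 0L)
  expect_error(trim_adapter("ACGT", "ACG", min_overlap = 6), "min_overlap")
})

test_that("length filter keeps the 15-45 nt window, preserving order", {
  reads <- c(strrep("A", 14), strrep("C", 15), strrep("G", 45),
             strrep("T", 46), strrep("A", 21))
  kept <- filter_length(reads)
  expect_equal(kept, c(strrep("C", 15), strrep("G", 45), strrep("A", 21)))
  expect_equal(length(filter_length(character(0))), 0L)
})

test_that("quality filter drops N-containing and low-quality reads", {
  reads <- c("ACGTACGTACGTACGTACGT", "ACGTNCGTACGTACGTACGT")
  expect_equal(filter_quality(reads), reads[1])
  quals <- c(strrep("I", 20), strrep("#", 20))   # Phred 40 vs Phred 2
  expect_equal(filter_quality(rep(reads[1], 2), quals), reads[1])
})

test_that("ncRNA filtering removes exactly the planted contaminants", {
  ncrna <- generate_ncrna_set(5, seed = 2)
  interior <- substr(ncrna[[1]], 20, 40)      # interior 21-mer
  rc <- revcomp(substr(ncrna[[2]], 10, 31))   # reverse-complement fragment
  free <- "TTTTTTTTTTGGGGGGGGGGA"
  fr <- filter_ncrna(c(interior, free, rc), ncrna)
  expect_equal(fr$retained, free)
  expect_equal(fr$removed_count, 2L)
  expect_error(filter_ncrna("ACGT", character(0)), "empty")

  # generator truth: removed count equals the planted contaminant count
  sc <- build_scenario(seed = 31, noise_reads = 0)
  for (lib in c("F", "M")) {
    counts <- sum(if (lib == "F") sc$truth$mirnas$count_F else
      sc$truth$mirnas$count_M)
    n_cont <- round(0.05 / 0.95 * counts)
    ins <- trim_adapter(sc$libraries[[lib]], sc$adapter)
    ins <- filter_length(ins)
    fr <- filter_ncrna(ins, sc$ncrna)
    expect_equal(fr$removed_count, n_cont)
  }
})

test_that("collapsing conserves counts and normalises TPM to one million", {
  libs <- list(F = c(rep("ACGTACGTACGTACGTACGT", 3), "TTTTGGGGCCCCAAAATTTT"),
               M = c(rep("ACGTACGTACGTACGTACGT", 2)))
  cl <- collapse_reads(libs)
  u <- cl$unique_reads
  expect_equal(nrow(u), 2L)
  row <- u[u$sequence == "ACGTACGTACGTACGTACGT", ]
  expect_equal(row$count_F, 3L)
  expect_equal(row$count_M, 2L)
  expect_equal(sum(u$count_F), length(libs$F))
  expect_equal(sum(u$count_M), length(libs$M))
  expect_equal(sum(u$tpm_F), 1e6, tolerance = 1e-6)
  expect_equal(sum(u$tpm_M), 1e6, tolerance = 1e-6)

  # 1000 reads drawn from 10 templates collapse to exactly 10 tags
  set.seed(9)
  templates <- vapply(rep(21, 10), random_rna, "")
  templates <- rna_to_dna(templates)
  draws <- sample(templates, 1000, replace = TRUE)
  cl2 <- collapse_reads(list(F = draws, M = character(0)))
  expect_equal(nrow(cl2$unique_reads), 10L)
  expect_equal(sort(cl2$unique_reads$count_F),
               sort(as.integer(table(draws))))
})

test_that("accounting is monotone and collapse conserves library totals", {
  sc <- build_scenario(seed = 37, noise_reads = 30)
  pp <- preprocess_libraries(sc$libraries, adapter = sc$adapter,
                             ncrna_set = sc$ncrna)
  a <- pp$accounting
  expect_true(all(a$raw_reads >= a$after_trim))
  expect_true(all(a$after_trim >= a$clean_reads))
  expect_true(all(a$clean_reads >= a$after_ncrna))
  expect_true(all(a$after_ncrna >= a$unique_reads))
  for (lab in c("F", "M")) {
    expect_equal(sum(pp$unique_reads[[paste0("count_", lab)]]),
                 a$after_ncrna[a$library == lab])
    expect_equal(unname(pp$totals[lab]),
                 a$after_ncrna[a$library == lab])
  }
})

test_that("preprocessing already-clean input changes nothing", {
  clean <- c("TGACAGAAGAGAGAGAGCACT", "TTTTGGGGCCCCAAAATTTTT")
  r <- preprocess_library(clean, adapter = NULL, ncrna_set = NULL)
  expect_equal(r$clean, clean)
  expect_equal(r$accounting$raw_reads, r$accounting$after_ncrna)
})

test_that("length distribution reports per-library fractions summing to 1", {
  libs <- list(F = c(rep(strrep("A", 24), 3), rep(strrep("C", 21), 2),
                     strrep("G", 20)),
               M = rep(strrep("A", 24), 2))
  # distinct sequences per length so unique-read counting is visible
  libs$F <- c(libs$F, substr(strrep("ACGT", 6), 1, 24))
  cl <- collapse_reads(libs)
  ld <- length_distribution(cl$unique_reads)
  for (lab in c("F", "M")) {
    expect_equal(sum(ld$fraction[ld$library == lab]), 1)
  }
  f24 <- ld$fraction[ld$library == "F" & ld$length == 24]
  f21 <- ld$fraction[ld$library == "F" & ld$length == 21]
  expect_gt(f24, f21)   # 24-nt class leads, then 21-nt
  expect_error(length_distribution(cl$unique_reads[0, ]), "no unique reads")
})

test_that("candidate gate applies the TPM and length rules", {
  u <- data.frame(sequence = c(strrep("A", 21), strrep("C", 21),
                               strrep("G", 19)),
                  count_F = c(10L, 1L, 10L), count_M = c(0L, 0L, 0L),
                  tpm_F = c(100, 2, 100), tpm_M = c(0, 0, 0))
  g <- filter_candidates(u, tpm_min = 5, len_range = c(20, 24))
  expect_equal(g$sequence, strrep("A", 21))
})
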