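test_that("perfect mapping finds every occurrence on both strands", {
  tx <- c(UN1 = paste0(random_dna(100), "TGACAGAAGAGAGAGAGCACT",
                       random_dna(100)),
          UN2 = paste0(random_dna(50),
                       revcomp("TGACAGAAGAGAGAGAGCACT"), random_dna(50)))
  set.seed(47)
  read <- "TGACAGAAGAGAGAGAGCACT"
  loci <- map_perfect(read, tx)
  expect_equal(nrow(loci), 2L)
  plus <- loci[loci$unigene == "UN1", ]
  expect_equal(plus$start, 101L)
  expect_equal(plus$end, 121L)
  expect_equal(plus$strand, "+")
  minus <- loci[loci$unigene == "UN2", ]
  expect_equal(minus$strand, "-")
  expect_equal(revcomp(substr(tx["UN2"], minus$start, minus$end)), read)
  # absent read maps nowhere
  expect_equal(nrow(map_perfect(strrep("ACGT", 5), c(A = strrep("T", 400)))),
               0L)
})

test_that("precursor windows use +/-200 nt with boundary clipping", {
  tx <- c(UN1 = random_dna(1000))
  set.seed(53)
  w <- extract_precursor(data.frame(unigene = "UN1", start = 250, end = 270,
                                    strand = "+"), tx, 200)
  expect_equal(w$window_start, 50L)
  expect_equal(w$window_end, 470L)
  expect_equal(nchar(w$sequence), 421L)
  expect_equal(w$mature_offset, 201L)
  expect_equal(substr(w$sequence, w$mature_offset, w$mature_offset + 20),
               substr(tx[["UN1"]], 250, 270))

  clipped <- extract_precursor(data.frame(unigene = "UN1", start = 5,
                                          end = 25, strand = "+"), tx, 200)
  expect_equal(clipped$window_start, 1L)
  expect_equal(clipped$window_end, 225L)

  minus <- extract_precursor(data.frame(unigene = "UN1", start = 250,
                                        end = 270, strand = "-"), tx, 200)
  mat <- revcomp(substr(tx[["UN1"]], 250, 270))
  expect_equal(substr(minus$sequence, minus$mature_offset,
                      minus$mature_offset + 20), mat)
})

test_that("evaluation criteria gate candidates as specified", {
  u <- generate_transcriptome(1, c(900, 900), 0.45, seed = 61)
  mat <- paste0("T", random_dna(20, 0.5))
  pp <- plant_precursor(u, mat, "5p", "+", 400, stem_mismatches = 1,
                        seed = 61)
  tx <- setNames(pp$unigene, "UN00001")
  loci <- map_perfect(mat, tx)
  w <- extract_precursor(loci[1, ], tx, 200)
  ev <- evaluate_candidate(mat, w)
  expect_true(ev$pass)
  expect_true(all(unlist(ev[c("ok_hairpin", "ok_arm", "ok_duplex",
                              "ok_star", "ok_mfe")])))
  expect_equal(ev$arm, "5p")

  # an unreachable MFE threshold fails criterion (d) and the overall verdict
  strict <- novel_thresholds(mfe_max = -500)
  ev2 <- evaluate_candidate(mat, w, strict)
  expect_false(ev2$ok_mfe)
  expect_false(ev2$pass)

  # a mature straddling the terminal loop fails the arm criterion
  arm <- "GGCGGCGGCGGCGGCGGCGG"
  hair <- paste0(arm, "AACAACAACA", revcomp(arm))
  straddle <- list(sequence = hair, window_start = 1L,
                   window_end = nchar(hair), mature_offset = 11L,
                   mature_length = 20L, strand = "+", unigene = "X")
  ev3 <- evaluate_candidate(substr(hair, 11, 30), straddle)
  expect_false(ev3$ok_arm)
  expect_false(ev3$pass)

  # windows too short to hold a duplex fail with a reason
  tiny <- list(sequence = substr(hair, 1, 30), window_start = 1L,
               window_end = 30L, mature_offset = 1L, mature_length = 20L,
               strand = "+", unigene = "X")
  ev4 <- evaluate_candidate(arm, tiny)
  expect_false(ev4$pass)
  expect_equal(ev4$reason, "window_too_short")
})

test_that("star recovery matches the planted duplex geometry", {
  u <- generate_transcriptome(1, c(900, 900), 0.45, seed = 67)
  mat <- paste0("T", random_dna(20, 0.5))
  for (arm in c("5p", "3p")) {
    pp <- plant_precursor(u, mat, arm, "+", 400, stem_mismatches = 0,
                          seed = 71)
    tx <- setNames(pp$unigene, "UN00001")
    loci <- map_perfect(mat, tx)
    w <- extract_precursor(loci[1, ], tx, 200)
    f <- fold(w$sequence)
    star <- find_star(f, w$mature_offset, w$mature_length)
    expect_false(is.null(star))
    # star pairs the mature: its reverse complement matches the mature core
    star_rc <- revcomp(rna_to_dna(star$sequence))
    expect_true(grepl(substr(mat, 3, 18), star_rc, fixed = TRUE))
    # the star must not overlap the mature
    expect_true(star$end < w$mature_offset ||
                  star$start > w$mature_offset + w$mature_length - 1L)
  }
  # a mature with 5+ unpaired bases has no admissible star
  open5 <- fold(paste0("GGGGGGGGGGGGGGGGGGGG", "AAACAAACAAAC",
                       "CCCCCCCCCCCCCCC"))
  expect_null(find_star(open5, 16L, 20L))
})

test_that("novel assembly aggregates loci per distinct mature", {
  sc <- build_scenario(seed = 73, n_multi_locus = 2, n_targets = 0,
                       noise_reads = 0)
  pp <- preprocess_libraries(sc$libraries, adapter = sc$adapter,
                             ncrna_set = sc$ncrna)
  cand <- scan_novel_loci(pp$unique_reads, sc$transcriptome)
  novel <- assemble_novel_set(cand, pp$unique_reads)
  truth <- sc$truth
  planted <- rna_to_dna(truth$mirnas$mature_rna)
  called <- rna_to_dna(novel$mirnas$sequence)
  expect_setequal(called, planted)
  # ids follow the lexicographic order of the mature sequence
  expect_equal(novel$mirnas$id,
               sprintf("novel-miRn%02d", seq_len(nrow(novel$mirnas))))
  expect_equal(novel$mirnas$sequence, sort(novel$mirnas$sequence))
  # multi-locus truth: the planted two-precursor matures carry 2 loci
  multi <- truth$loci$mirna_id[duplicated(truth$loci$mirna_id)]
  for (id in multi) {
    seq_rna <- truth$mirnas$mature_rna[truth$mirnas$mirna_id == id]
    expect_equal(novel$mirnas$n_loci[novel$mirnas$sequence == seq_rna], 2L)
  }
  # locus table and summary are consistent
  expect_equal(sum(novel$mirnas$n_loci), nrow(novel$loci))
  expect_equal(assemble_novel_set(cand[0, ], pp$unique_reads)$mirnas$id,
               character(0))
})

test_that("coordinate round-trip reproduces identical verdicts", {
  sc <- build_scenario(seed = 79, n_targets = 0)
  pp <- preprocess_libraries(sc$libraries, adapter = sc$adapter,
                             ncrna_set = sc$ncrna)
  cand <- scan_novel_loci(pp$unique_reads, sc$transcriptome)
  pass <- cand[cand$pass, ]
  for (k in seq_len(min(4, nrow(pass)))) {
    row <- pass[k, ]
    redo <- evaluate_candidate(
      row$sequence,
      extract_precursor(row[, c("unigene", "start", "end", "strand")],
                        sc$transcriptome, 0L))
    expect_true(redo$pass, info = row$sequence)
    expect_equal(redo$start, row$start)
    expect_equal(redo$end, row$end)
  }
})

test_that("minus-strand calls mirror plus-strand calls on the rev-complement", {
  u <- generate_transcriptome(1, c(900, 900), 0.45, seed = 83)
  mat <- paste0("T", random_dna(20, 0.5))
  pp <- plant_precursor(u, mat, "5p", "-", 400, stem_mismatches = 1,
                        seed = 83)
  tx_minus <- setNames(pp$unigene, "UN00001")
  tx_plus <- setNames(revcomp(pp$unigene), "UN00001")
  l_minus <- map_perfect(mat, tx_minus)
  l_plus <- map_perfect(mat, tx_plus)
  expect_equal(l_minus$strand, "-")
  expect_equal(l_plus$strand, "+")
  L <- unname(nchar(pp$unigene))
  expect_equal(l_plus$start, L - l_minus$end + 1L)
  ev_minus <- evaluate_candidate(mat, extract_precursor(l_minus[1, ],
                                                        tx_minus, 200))
  ev_plus <- evaluate_candidate(mat, extract_precursor(l_plus[1, ],
                                                       tx_plus, 200))
  expect_equal(ev_minus$pass, ev_plus$pass)
  expect_equal(ev_minus$mfe, ev_plus$mfe)
  expect_equal(ev_minus$start, L - ev_plus$end + 1L)
  expect_equal(ev_minus$end, L - ev_plus$start + 1L)
})

test_that("conserved-assigned sequences never enter the novel set", {
  sc <- build_scenario(seed = 89, n_targets = 0)
  pp <- preprocess_libraries(sc$libraries, adapter = sc$adapter,
                             ncrna_set = sc$ncrna)
  # declare the first two planted matures as known miRNAs
  db <- setNames(sc$truth$mirnas$mature_rna[1:2],
                 c("aof-miR901", "aof-miR902"))
  gated <- filter_candidates(pp$unique_reads)
  conserved <- match_known(gated, db)
  expect_equal(sort(unique(conserved$sequence)),
               sort(rna_to_dna(sc$truth$mirnas$mature_rna[1:2])))
  cand <- scan_novel_loci(pp$unique_reads, sc$transcriptome,
                          exclude = conserved$sequence)
  novel <- assemble_novel_set(cand, pp$unique_reads)
  expect_false(any(novel$mirnas$sequence %in% db))
})
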