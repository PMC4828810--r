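test_that("degradome mapping counts 5' ends, including multi-mappers", {
  set.seed(107)
  core <- random_dna(20)
  tx <- c(T1 = paste0(random_dna(99), core, random_dna(60)),
          T2 = paste0(random_dna(39), core, random_dna(120)))
  profiles <- map_degradome(core, tx)
  expect_equal(profiles$T1[100], 1L)
  expect_equal(profiles$T2[40], 1L)
  expect_equal(attr(profiles, "total"), 2L)
  p10 <- map_degradome(rep(core, 10), tx)
  expect_equal(p10$T1[100], 10L)
  expect_equal(sum(p10$T1), 10L)
  # off-length reads are ignored
  expect_equal(attr(map_degradome(substr(core, 1, 19), tx), "total"), 0L)
  # generator truth: per-position counts equal the planted depth
  sc <- build_scenario(seed = 109, reads_per_site = 7, background_reads = 0)
  pr <- map_degradome(sc$degradome, sc$transcriptome)
  cl <- sc$truth$cleavage
  for (i in seq_len(nrow(cl))) {
    expect_equal(pr[[cl$unigene[i]]][cl$position[i]], 7L)
  }
  expect_equal(attr(pr, "total"), 7L * nrow(cl))
})

test_that("target scoring follows the weighted match/wobble/mismatch scheme", {
  mir <- "UGACAGAAGAGAGAGAGCACA"     # 21 nt
  site <- revcomp(rna_to_dna(mir))
  tx <- paste0(strrep("T", 50), site, strrep("T", 50))
  al <- target_align(mir, tx, max_score = 7)
  hit <- al[al$start == 51, ]
  expect_equal(hit$score, 0)
  expect_equal(hit$pairing, strrep("|", 21))

  # one G:U outside the 2-13 core scores 0.5; inside the core it doubles.
  # Within the site, miRNA position j faces site position L - j + 1.
  mir_chars <- strsplit(mir, "")[[1]]
  stopifnot(mir_chars[17] == "G")    # outside-core wobble: G faces T
  site17 <- site
  substr(site17, 21 - 17 + 1, 21 - 17 + 1) <- "T"
  al17 <- target_align(mir, paste0(strrep("T", 50), site17, strrep("T", 50)))
  expect_equal(al17[al17$start == 51, "score"], 0.5)
  stopifnot(mir_chars[5] == "A")     # in-core mismatch doubles to 2
  site5 <- site
  substr(site5, 21 - 5 + 1, 21 - 5 + 1) <- "C"
  al5 <- target_align(mir, paste0(strrep("T", 50), site5, strrep("T", 50)))
  expect_equal(al5[al5$start == 51, "score"], 2.0)
  stopifnot(mir_chars[6] == "G")     # in-core wobble doubles to 1
  site6 <- site
  substr(site6, 21 - 6 + 1, 21 - 6 + 1) <- "T"
  al6 <- target_align(mir, paste0(strrep("T", 50), site6, strrep("T", 50)))
  expect_equal(al6[al6$start == 51, "score"], 1.0)
})

test_that("window scores equal a per-window brute-force recomputation", {
  set.seed(113)
  mir <- dna_to_rna(random_dna(21))
  tx <- random_dna(300)
  al <- target_align(mir, tx, max_score = Inf)
  mirc <- strsplit(mir, "")[[1]]
  txc <- strsplit(dna_to_rna(tx), "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  brute <- vapply(seq_len(300 - 21 + 1), function(s) {
    total <- 0
    for (j in 1:21) {
      tb <- txc[s + 21 - j]
      pen <- if (tb == comp[[mirc[j]]]) 0
        else if ((mirc[j] == "G" && tb == "U") ||
                 (mirc[j] == "U" && tb == "G")) 0.5
        else 1
      if (j >= 2 && j <= 13) pen <- pen * 2
      total <- total + pen
    }
    total
  }, 0.0)
  expect_equal(al$score, unname(brute))
  expect_equal(min(al$score), min(brute))
})

test_that("cleavage detection anchors at miRNA nucleotide 10", {
  sc <- build_scenario(seed = 127, reads_per_site = 9, background_reads = 0)
  pr <- map_degradome(sc$degradome, sc$transcriptome)
  cl <- sc$truth$cleavage
  truth_m <- sc$truth$mirnas
  for (i in seq_len(nrow(cl))) {
    mir <- truth_m$mature_rna[truth_m$mirna_id == cl$mirna_id[i]]
    al <- target_align(mir, sc$transcriptome[[cl$unigene[i]]])
    best <- al[which.min(al$score), ]
    hit <- detect_cleavage(best, pr[[cl$unigene[i]]])
    expect_false(is.null(hit))
    expect_equal(hit$cleavage_pos, cl$position[i])
    expect_equal(hit$reads, 9L)
  }
  # reads opposite miRNA nucleotide 14 are not a cleavage signature
  prof <- integer(200)
  al1 <- data.frame(start = 100L, end = 120L)
  prof[100 + 21 - 14] <- 5L
  expect_null(detect_cleavage(al1, prof))
  expect_null(detect_cleavage(al1, integer(200)))
  # a widened window admits position 9-11
  prof2 <- integer(200)
  prof2[100 + 21 - 11] <- 5L
  expect_null(detect_cleavage(al1, prof2))
  expect_equal(detect_cleavage(al1, prof2, c(9, 10, 11))$cleavage_pos,
               100L + 21L - 11L)
})

test_that("category rules cover the published tier definitions", {
  # a single position with a single read: category 4
  prof <- integer(300); prof[100] <- 1L
  expect_equal(categorize(1L, prof), 4L)
  # unique maximum at the site: category 0
  prof0 <- integer(300); prof0[100] <- 10L; prof0[200] <- 2L; prof0[250] <- 2L
  expect_equal(categorize(10L, prof0), 0L)
  # shared maximum: category 1
  prof1 <- integer(300); prof1[100] <- 5L; prof1[200] <- 5L; prof1[250] <- 2L
  expect_equal(categorize(5L, prof1), 1L)
  # above the occupied-position median: category 2
  prof2 <- integer(300)
  prof2[c(100, 150, 200, 210, 220)] <- c(4L, 9L, 2L, 1L, 1L)
  expect_equal(categorize(4L, prof2), 2L)
  # at/below the median: category 3
  expect_equal(categorize(2L, prof2), 3L)
  expect_error(categorize(0L, prof2), "coverage")
})

test_that("classification agrees with the brute-force oracle", {
  set.seed(131)
  for (rep in 1:150) {
    n <- sample(30:80, 1)
    prof <- integer(n)
    occ <- sample(n, sample(3:12, 1))
    prof[occ] <- pmax(1L, rpois(length(occ), sample(1:6, 1)))
    site <- sample(occ, 1)
    expect_equal(categorize(prof[site], prof),
                 categorize_oracle(prof[site], prof))
  }
})

test_that("categories are stable under integer scaling except the c=1 tier", {
  set.seed(137)
  for (rep in 1:40) {
    n <- 60
    prof <- integer(n)
    occ <- sample(n, 6)
    prof[occ] <- pmax(1L, rpois(6, 4))
    site <- sample(occ, 1)
    before <- categorize(prof[site], prof)
    after <- categorize(3L * prof[site], 3L * prof)
    if (prof[site] > 1L) {
      expect_equal(after, before)
    } else {
      expect_equal(before, 4L)
      expect_true(after %in% 0:3)
    }
  }
})

test_that("t-plot tables conserve the mapped total and flag hit rows", {
  prof <- integer(300)
  prof[c(100, 150, 200)] <- c(10L, 3L, 1L)
  tp <- tplot_table(prof, data.frame(cleavage_pos = 100L))
  expect_equal(sum(tp$count), sum(prof))
  expect_equal(sum(tp$is_cleavage_site), 1L)
  expect_equal(tp$position[tp$is_cleavage_site], 100L)
  expect_equal(nrow(tplot_table(integer(300))), 0L)
})

test_that("planted cleavage targets are recovered with strong categories", {
  sc <- build_scenario(seed = 139, reads_per_site = 10, background_reads = 40)
  pr <- map_degradome(sc$degradome, sc$transcriptome)
  truth_m <- sc$truth$mirnas
  mirnas <- setNames(truth_m$mature_rna, truth_m$mirna_id)
  hits <- degradome_targets(mirnas, sc$transcriptome, pr)
  cl <- sc$truth$cleavage
  for (i in seq_len(nrow(cl))) {
    h <- hits[hits$mirna == cl$mirna_id[i] &
                hits$transcript == cl$unigene[i] &
                hits$cleavage_pos == cl$position[i], ]
    expect_equal(nrow(h), 1L)
    expect_lte(h$category, 2L)
  }
})
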