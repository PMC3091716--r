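# Motif parsing, scoring, calibration and block scanning.

write_transfac_fixture <- function(path) {
  writeLines(c(
    "AC  M00001", "XX", "NA  TST1", "XX",
    "P0      A      C      G      T",
    "01     90      4      3      3",
    "02      3     91      3      3",
    "03      3      3     91      3",
    "04      3      3      3     91",
    "05     91      3      3      3",
    "06      3     91      3      3",
    "07      3      3     91      3",
    "08      3      3      3     91",
    "XX", "//",
    "AC  M00002", "XX", "NA  TST2", "XX",
    "P0      A      C      G      T",
    "01     25     25     25     25",
    "02     25     25     25     25",
    "03     25     25     25     25",
    "04     25     25     25     25",
    "05     25     25     25     25",
    "XX", "//"), path)
}

test_that("TRANSFAC and MEME dialects parse into equivalent matrices", {
  f <- tempfile()
  write_transfac_fixture(f)
  lib <- read_motifs(f, "transfac")
  expect_length(lib, 2)
  expect_equal(lib[["M00001"]]$width, 8)
  expect_equal(lib[["M00001"]]$name, "TST1")
  expect_equal(unname(colSums(lib[["M00001"]]$counts)), rep(100, 8))
  expect_equal(motif_consensus(lib[["M00001"]]), "ACGTACGT")
  unlink(f)

  m <- tempfile()
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF MX01 TFX",
               "letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0",
               " 0.85 0.05 0.05 0.05", " 0.05 0.85 0.05 0.05",
               " 0.05 0.05 0.85 0.05", " 0.05 0.05 0.05 0.85",
               " 0.85 0.05 0.05 0.05", " 0.05 0.85 0.05 0.05"), m)
  meme <- read_motifs(m, "meme")
  expect_equal(meme[["MX01"]]$width, 6)
  # probabilities scaled to counts by nsites
  expect_equal(unname(meme[["MX01"]]$counts[1, 1]), 0.85 * 20)
  expect_equal(motif_consensus(meme[["MX01"]]), "ACGTAC")
  unlink(m)
})

test_that("malformed matrices are rejected with the motif named", {
  f <- tempfile()
  writeLines(c("AC  MBAD", "XX", "P0      A      C      G      T",
               "01     10     10     10     10",
               "02     10     10     10     10",
               "03      0      0      0      0",
               "04     10     10     10     10",
               "05     10     10     10     10", "XX", "//"), f)
  expect_error(read_motifs(f, "transfac"), "MBAD.*all-zero")
  unlink(f)
  expect_error(crmminer:::.new_motif("MR", "MR",
                                     matrix(1, 4, 8)[, 1:4]), "width")
})

test_that("a motif library round-trips through the TRANSFAC writer", {
  lib <- make_motif_library(5, seed = 8)
  f <- tempfile()
  write_motifs_transfac(lib, f)
  back <- read_motifs(f, "transfac")
  expect_equal(names(back), names(lib))
  for (id in names(lib))
    expect_equal(back[[id]]$counts, lib[[id]]$counts)
  unlink(f)
})

test_that("site scoring maximises at the consensus, respects strand
          symmetry, and treats uniform motifs as flat", {
  m <- toy_motif()
  cons <- motif_consensus(m)
  set.seed(2)
  for (i in 1:20)
    expect_lte(score_site(m, random_dna(8)), score_site(m, cons))
  s <- random_dna(8)
  expect_equal(score_site(m, s, "+"), score_site(m, revcomp_chr(s), "-"))
  # uniform motif scores every sequence identically
  u <- crmminer:::.new_motif("MU", "MU", matrix(25, 4, 6))
  expect_equal(score_site(u, "ACGTAC"), score_site(u, "TTTTTT"))
  # N is unscorable
  expect_equal(score_site(m, "ACGTACGN"), -Inf)
})

test_that("calibration hits the target background rate and is monotone
          in p", {
  # heterogeneous counts give an effectively continuous score
  # distribution, so the empirical quantile is tight
  set.seed(510)
  m <- crmminer:::.new_motif("MC", "MC",
                             matrix(round(runif(36, 1, 100), 1), 4, 9))
  bg <- random_background(400, 1000, seed = 100)
  c1 <- calibrate_cutoff(m, bg, p = 1e-3)
  c2 <- calibrate_cutoff(m, bg, p = 1e-4)
  expect_gte(c2, c1)           # smaller p never lowers the cutoff
  expect_equal(calibrate_cutoff(m, bg, p = 1), -Inf)
  # fresh background: empirical per-position hit rate within a binomial
  # band around the target
  fresh <- random_background(400, 1000, seed = 101)
  sc <- unlist(lapply(fresh, function(s)
    c(scan_sequence(m, s, "+"), scan_sequence(m, s, "-"))))
  rate <- mean(sc > c1)
  expect_gt(rate, 0.5e-3)
  expect_lt(rate, 2e-3)
})

test_that("a more informative motif sits further above the background mean
          than a weak one", {
  strong <- toy_motif("MS", dom = 94)
  weak <- crmminer:::.new_motif("MW", "MW", {
    cm <- matrix(20, 4, 8)
    cm[1, ] <- 40
    cm
  })
  bg <- random_background(100, 500, seed = 7)
  gap <- function(m) {
    sc <- unlist(lapply(bg, function(s) scan_sequence(m, s)))
    calibrate_cutoff(m, bg, 1e-3) - mean(sc)
  }
  expect_gt(gap(strong), gap(weak))
})

test_that("scan_blocks reports exactly the planted site, restricted to
          conserved segments, and matches a naive rescan", {
  m <- toy_motif()
  m$cutoff <- 8
  lib <- structure(list(M900 = m), class = "crm_motif_library")
  set.seed(55)
  seq <- paste0(random_dna(60), motif_consensus(m), random_dna(60))
  genome <- c(chr1 = seq)
  blocks <- data.frame(block_id = "b1", chrom = "chr1", start = 0,
                       end = 128)
  blocks$conserved <- list(cbind(start = 40L, end = 100L))
  hits <- scan_blocks(blocks, lib, genome)
  expect_true(all(hits$start >= 40 & hits$end <= 100))
  expect_true(any(hits$start == 60 & hits$strand == "+"))
  # naive rescan oracle inside the conserved interval
  naive <- 0L
  for (i in 40:(100 - 8)) {
    win <- substr(seq, i + 1, i + 8)
    if (score_site(m, win) > m$cutoff) naive <- naive + 1L
    if (score_site(m, win, "-") > m$cutoff) naive <- naive + 1L
  }
  expect_equal(nrow(hits), naive)
  # segments shorter than the motif width yield nothing
  blocks2 <- blocks
  blocks2$conserved <- list(cbind(start = 40L, end = 45L))
  expect_equal(nrow(scan_blocks(blocks2, lib, genome)), 0)
})

test_that("block scanning agrees with the Biostrings scoring oracle", {
  m <- toy_motif()
  set.seed(77)
  s <- random_dna(200)
  ours <- scan_sequence(m, s)
  oracle <- Biostrings::PWMscoreStartingAt(
    m$log_odds, Biostrings::DNAString(s), 1:(200 - 7))
  expect_equal(unname(ours), unname(oracle), tolerance = 1e-9)
})
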