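# Discontiguous similarity, conservation scores, cutoff and blocks.

seg_row <- function(hs, he, os, oe, score)
  data.frame(h_start = hs, h_end = he, o_start = os, o_end = oe,
             score = score)

test_that("a single segment inside the window is its own similarity", {
  segs <- seg_row(100, 140, 3000, 3040, 40)
  res <- discontiguous_similarity(segs, 0, 1000)
  expect_equal(res$score, 40)
  expect_true(res$o_window[1] <= 3000 && res$o_window[2] >= 3040)
})

test_that("ortholog co-location constrains which segments can be summed", {
  # three segments in R; ortholog parts span 1.8 kb; only the first two
  # fit one 1-kb ortholog window
  segs <- rbind(seg_row(10, 60, 1000, 1050, 30),
                seg_row(200, 260, 1700, 1760, 20),
                seg_row(500, 550, 2750, 2800, 25))
  res <- discontiguous_similarity(segs, 0, 1000)
  expect_equal(res$score, 50)
  expect_equal(res$score, brute_similarity(segs, 0, 1000))
})

test_that("empty window scores zero and similarity is monotone in added
          segments", {
  expect_equal(discontiguous_similarity(seg_row(1, 2, 1, 2, 5)[0, ],
                                        0, 1000)$score, 0)
  set.seed(20)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    segs <- seg_row(sort(sample(0:900, n)), 0, sample(0:2000, n), 0,
                    round(runif(n, 5, 50), 1))
    segs$h_end <- segs$h_start + sample(10:60, n, TRUE)
    segs$o_end <- segs$o_start + sample(10:60, n, TRUE)
    segs <- segs[segs$h_end <= 1000, , drop = FALSE]
    if (nrow(segs) < 2) next
    s_all <- discontiguous_similarity(segs, 0, 1000)$score
    s_less <- discontiguous_similarity(segs[-1, , drop = FALSE], 0, 1000)$score
    expect_gte(s_all, s_less)
  }
})

test_that("similarity equals a brute-force window scan on random instances", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(1:50, 1)
    hs <- sort(sample(0:950, n))
    segs <- data.frame(h_start = hs,
                       h_end = pmin(1000, hs + sample(10:80, n, TRUE)),
                       o_start = sample(0:3000, n, TRUE), o_end = 0,
                       score = round(runif(n, 1, 100), 2))
    segs$o_end <- segs$o_start + sample(10:1200, n, TRUE)
    expect_equal(discontiguous_similarity(segs, 0, 1000)$score,
                 brute_similarity(segs, 0, 1000))
  }
})

test_that("contiguous and discontiguous conservation of the same total
          conserved length score identically", {
  # one 300-bp segment vs three 100-bp segments spread over the kilobase,
  # co-locatable in the ortholog: same C
  contig <- seg_row(0, 300, 0, 300, 300)
  spread <- rbind(seg_row(0, 100, 0, 100, 100),
                  seg_row(400, 500, 300, 400, 100),
                  seg_row(850, 950, 600, 700, 100))
  s1 <- conservation_score(list(mouse = contig), 0, 1000)
  s2 <- conservation_score(list(mouse = spread), 0, 1000)
  expect_equal(s1, s2)
  expect_equal(s1, 300)
})

test_that("conservation averages the species and falls back to a single
          ortholog", {
  m <- seg_row(0, 100, 0, 100, 100)
  r <- seg_row(0, 60, 0, 60, 60)
  expect_equal(conservation_score(list(mouse = m, rat = r), 0, 1000), 80)
  expect_equal(conservation_score(list(mouse = m), 0, 1000), 100)
  expect_equal(conservation_score(list(mouse = m[0, ], rat = r[0, ]),
                                  0, 1000), 0)
  # a species that aligned nothing still contributes a zero to the mean
  expect_equal(conservation_score(list(mouse = m, rat = r[0, ]), 0, 1000), 50)
  expect_error(conservation_score(list(), 0, 1000), "ortholog")
})

test_that("the pooled cutoff is the smallest score exceeded by at most 5%
          of windows", {
  expect_equal(compute_cutoff(1:100), 95)
  expect_equal(compute_cutoff(rep(7, 50)), 7)
  expect_error(compute_cutoff(1:19), "at least 20")
  # quantile parameter is honoured
  expect_equal(compute_cutoff(1:100, quantile = 0.9), 90)
})

test_that("blocks merge overlapping passing windows and trim the 3' end to
          the last conserved base", {
  wins <- data.frame(region = 1L, start = c(0, 500), end = c(1000, 1500),
                     truncated = FALSE, C = c(50, 40))
  segs <- data.frame(h_start = c(0, 480, 1300), h_end = c(40, 520, 1320),
                     region = 1L)
  b <- find_blocks(wins, segs, cutoff = 10)
  expect_equal(nrow(b), 1)
  expect_equal(b$start, 0)
  expect_equal(b$end, 1320)
  expect_equal(b$C_max, 50)
  # isolated window whose only segment is (0,40) trims to (0,40)
  w2 <- data.frame(region = 1L, start = 0, end = 1000, truncated = FALSE,
                   C = 99)
  s2 <- data.frame(h_start = 0, h_end = 40, region = 1L)
  b2 <- find_blocks(w2, s2, cutoff = 1)
  expect_equal(c(b2$start, b2$end), c(0, 40))
  # nothing passes
  expect_equal(nrow(find_blocks(w2, s2, cutoff = 1000)), 0)
})

test_that("blocks are disjoint and each ends inside a conserved segment", {
  set.seed(9)
  n <- 40
  starts <- sort(sample(0:8000, n))
  segs <- data.frame(h_start = starts, h_end = starts + sample(20:200, n, TRUE),
                     region = 1L)
  wins <- data.frame(region = 1L, start = segs$h_start,
                     end = pmin(segs$h_start + 1000, 9000),
                     truncated = FALSE, C = runif(n, 0, 100))
  b <- find_blocks(wins, segs, cutoff = 30)
  if (nrow(b) > 1)
    expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  for (i in seq_len(nrow(b)))
    expect_true(any(segs$h_start < b$end[i] &
                      pmin(segs$h_end, b$end[i]) == b$end[i]))
})

test_that("windows are anchored at segment starts and truncated at region
          ends", {
  segs <- list(mouse = data.frame(
    h_start = c(100, 700), h_end = c(160, 760), o_start = c(0, 500),
    o_end = c(60, 560), score = c(60, 60), region = 1L))
  regions <- data.frame(start = 0, end = 1200, region = 1L)
  w <- conservation_windows(segs, regions)
  expect_equal(w$start, c(100, 700))
  expect_equal(w$end, c(1100, 1200))
  expect_equal(w$truncated, c(FALSE, TRUE))
  expect_equal(w$C, c(120, 60))
})
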