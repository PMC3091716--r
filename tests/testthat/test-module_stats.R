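# Target genes, gene-set overlap, CE-pair enrichment and preference tests.

test_that("hypergeometric overlap matches exhaustive enumeration and the
          published composite-element example", {
  expect_equal(hypergeom_overlap(100, 10, 10, 0), 1)
  expect_equal(hypergeom_overlap(10, 4, 3, 2),
               enum_hyper_upper(10, 4, 3, 2))
  for (N in c(8, 10, 12)) {
    set.seed(N)
    M <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
    for (m in 0:min(M, n))
      expect_equal(hypergeom_overlap(N, M, n, m),
                   enum_hyper_upper(N, M, n, m), tolerance = 1e-12)
  }
  p <- hypergeom_overlap(135981, 2515, 21635, 528)
  expect_equal(signif(p, 3), 7.17e-12)
})

test_that("BH adjustment reproduces the hand-applied step-up and is
          monotone", {
  expect_equal(adjust_fdr(0.031), 0.031)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  set.seed(12)
  p <- runif(50)
  q1 <- adjust_fdr(p)
  p2 <- p; p2[7] <- min(1, p[7] + 0.2)
  q2 <- adjust_fdr(p2)
  expect_true(all(q2 >= q1 - 1e-12))
})

test_that("CE-pair enrichment counts the pair universe from the motif
          library size", {
  expect_equal(ce_pair_enrichment(character(0), character(0), 522)$N, 135981)
  expect_equal(ce_pair_enrichment(character(0), character(0), 2)$N, 1)
  res <- ce_pair_enrichment(c("A;B", "C;D"), c("E;F", "G;H"), 10)
  expect_equal(res$m, 0)
  expect_equal(res$p, 1)
  res2 <- ce_pair_enrichment(c("A;B", "C;D"), c("A;B"), 10)
  expect_equal(res2$m, 1)
  expect_lt(res2$p, 1)
})

test_that("module motif pairs enumerate unordered pairs across modules", {
  mods <- data.frame(module_id = 1:2)
  mods$items <- list(c("M1", "M2", "M3"), c("M2", "M4"))
  expect_setequal(module_motif_pairs(mods),
                  c("M1;M2", "M1;M3", "M2;M3", "M2;M4"))
})

test_that("order preference applies the fair-coin binomial tails", {
  expect_equal(binom_pref_pvalue(1, 1), 0.5)
  expect_equal(binom_pref_pvalue(10, 9), 11 / 1024)
  expect_equal(binom_pref_pvalue(10, 5), pbinom(5, 10, 0.5))
  expect_equal(binom_pref_pvalue(8, 8), 1 / 256)
  expect_equal(binom_pref_pvalue(6, 3), pbinom(3, 6, 0.5))
})

test_that("each directional tail of the order test is conservative under a
          fair coin", {
  # the test picks its tail from the data, so each direction must hold
  # its nominal level on its own
  set.seed(14)
  n <- 50
  m <- rbinom(10000, n, 0.5)
  p <- vapply(m, function(mm) binom_pref_pvalue(n, mm), numeric(1))
  rej_upper <- mean(p < 0.05 & m > n / 2)
  rej_lower <- mean(p < 0.05 & m <= n / 2)
  expect_lte(rej_upper, 0.05)
  expect_lte(rej_lower, 0.05)
})

test_that("order, strand and distance preferences read the 5'-most site of
          each motif per CRM", {
  # two CRMs: A before B in both, same strand in both, gap 30 bp
  tfbs <- data.frame(
    block_id = rep(c("c1", "c2"), each = 3),
    motif_id = c("A", "A", "B", "A", "B", "B"),
    chrom = "x",
    start = c(10, 500, 50, 20, 60, 700),
    end = c(18, 508, 60, 28, 70, 710),
    strand = c("+", "-", "+", "+", "+", "-"),
    score = c(5, 9, 5, 5, 5, 9))
  op <- order_preference(tfbs, c("A", "B"))
  expect_equal(op$n, 2)
  expect_equal(op$m, 2)            # 5'-most A (10, 20) precedes B (50, 60)
  expect_equal(op$p, 0.25)
  sp <- strand_preference(tfbs, c("A", "B"))
  expect_equal(sp$m, 2)            # both chosen sites on '+'
  dp <- distance_preference(tfbs, c("A", "B"))
  expect_equal(dp$distances, c(32, 32))
  expect_equal(sum(dp$counts), 2)  # count conservation
})

test_that("distance preference finds a planted bin and respects the worked
          Poisson tail", {
  # rate 2 with one bin of count 10
  res <- distance_preference_from_distances(c(rep(25, 10), 75, 125, 175,
                                              225, 275, 325, 375, 425,
                                              475, 490))
  expect_equal(res$counts[1], 10)
  expect_equal(res$rate, 2)
  expect_equal(res$p[1], ppois(9, 2, lower.tail = FALSE))
  expect_equal(res$p[1], 4.65e-5, tolerance = 1e-3)
  expect_equal(res$preferred_range, c(0, 50))
  # uniform counts: no significant bin
  resu <- distance_preference_from_distances(25 + 50 * 0:9)
  expect_false(any(resu$significant))
  # all distances in one far bin: that bin is the preferred range
  res1 <- distance_preference_from_distances(c(rep(460, 10)))
  expect_equal(res1$preferred_range, c(450, 500))
  expect_true(res1$degenerate)
})

test_that("location preference tests labels against the pooled background", {
  bg <- c(rep("upstream", 30), rep("downstream", 30), rep("intron", 40))
  res <- location_preference(rep("intron", 20), bg)
  i <- which(res$label == "intron")
  expect_equal(res$p[i], 0.4^20)
  expect_true(res$prefers[i])
  expect_false(any(res$prefers[-i]))
  # matching the background exactly: nothing preferred
  res2 <- location_preference(bg, bg)
  expect_false(any(res2$prefers))
  # a single CRM can never be significant against background > alpha
  res3 <- location_preference("intron", bg, alpha = 0.05)
  expect_false(any(res3$prefers))
})

test_that("gene-set overlap combines the hypergeometric test with BH across
          module-set pairs", {
  sets <- list(s1 = sprintf("g%02d", 1:10), s2 = sprintf("g%02d", 41:60))
  targets <- list(mod1 = sprintf("g%02d", 1:8),
                  mod2 = sprintf("g%02d", 21:30))
  uni <- sprintf("g%02d", 1:60)
  res <- gene_set_overlap(targets, sets, uni)
  expect_equal(nrow(res), 4)
  r11 <- res[res$module_id == "mod1" & res$gene_set_id == "s1", ]
  expect_equal(r11$m, 8)
  expect_equal(r11$p, hypergeom_overlap(60, 10, 8, 8))
  expect_equal(res$q, adjust_fdr(res$p))
})

test_that("CRMs are assigned to the nearest gene with declared tie-breaks
          and location labels", {
  genes <- data.frame(
    id = c("gA", "gB"), chrom = "c1", strand = c("+", "-"),
    tx_start = c(2000, 6000), tx_end = c(3000, 7000),
    cds_start = c(2000, 6000), cds_end = c(3000, 7000),
    stringsAsFactors = FALSE)
  genes$exons <- list(cbind(start = 2000L, end = 3000L),
                      cbind(start = 6000L, end = 7000L))
  genes <- crmminer:::.new_genes(genes)
  terr <- noncoding_territories(genes, chrom_sizes = c(c1 = 9000L))
  crms <- data.frame(chrom = "c1",
                     start = c(1000, 3200, 4450, 7250),
                     end = c(1100, 3300, 4550, 7350))
  res <- suppressMessages(assign_target_genes(crms, genes, terr))
  expect_equal(res$gene_id[1], "gA")
  expect_equal(res$location[1], "upstream")
  expect_equal(res$gene_id[2], "gA")
  expect_equal(res$location[2], "downstream")
  # equidistant between the two genes: tie toward the 5'-most gene
  expect_equal(res$gene_id[3], "gA")
  expect_true(res$tie[3])
  # 300 bp upstream of the '-' strand gene's TSS (tx_end)
  expect_equal(res$gene_id[4], "gB")
  expect_equal(res$location[4], "upstream")
  expect_equal(res$dist_tss[4], 300)
})
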