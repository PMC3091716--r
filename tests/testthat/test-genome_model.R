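# Annotation parsing, ortholog tables and non-coding territories.

bed12_fixture <- function(path) {
  writeLines(c(
    # 3-exon coding gene: exons (100,200) (300,400) (500,650), CDS 150-600
    "chr1\t100\t650\tg1\t0\t+\t150\t600\t0\t3\t100,100,150,\t0,200,400,",
    # non-coding gene: thickStart == thickEnd
    "chr1\t700\t800\tg2\t0\t-\t700\t700\t0\t1\t100,\t0,",
    # single-exon coding gene on the minus strand
    "chr1\t900\t1200\tg3\t0\t-\t950\t1150\t0\t1\t300,\t0,"), path)
}

test_that("BED12 parses with empty-CDS genes excluded and intron structure
          derived from inter-exon gaps", {
  f <- tempfile(fileext = ".bed")
  bed12_fixture(f)
  expect_warning(genes <- read_genes(f, "bed12"), "non-coding")
  expect_equal(genes$id, c("g1", "g3"))
  g1 <- genes[genes$id == "g1", ]
  expect_equal(c(g1$tx_start, g1$tx_end), c(100, 650))
  expect_equal(c(g1$cds_start, g1$cds_end), c(150, 600))
  introns <- gene_introns(g1)
  expect_equal(unname(introns[, "start"]), c(200, 400))
  expect_equal(unname(introns[, "end"]), c(300, 500))
  unlink(f)
})

test_that("genes round-trip through BED12 write and re-parse", {
  f <- tempfile(fileext = ".bed")
  bed12_fixture(f)
  genes <- suppressWarnings(read_genes(f, "bed12"))
  f2 <- tempfile(fileext = ".bed")
  write_bed12(genes, f2)
  back <- read_genes(f2, "bed12")
  expect_equal(back$tx_start, genes$tx_start)
  expect_equal(back$tx_end, genes$tx_end)
  expect_equal(back$cds_start, genes$cds_start)
  expect_equal(back$cds_end, genes$cds_end)
  expect_equal(back$exons, genes$exons)
  unlink(c(f, f2))
})

test_that("GFF3 1-based closed coordinates convert to the internal 0-based
          half-open convention", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=geneA;Name=geneA",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=tA;Parent=geneA",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=tA",
    "chr1\tsrc\tCDS\t121\t180\t.\t+\t0\tParent=tA"), f)
  genes <- read_genes(f, "gff3")
  expect_equal(genes$tx_start, 100)
  expect_equal(genes$tx_end, 200)
  expect_equal(genes$cds_start, 120)
  expect_equal(genes$cds_end, 180)
  unlink(f)
})

test_that("ortholog tables drop rodent-less rows with a count and reject
          unknown ids", {
  mkgenes <- function(ids) {
    df <- data.frame(id = ids, chrom = "c", strand = "+",
                     tx_start = seq(0, by = 1000,
                                    length.out = length(ids)),
                     tx_end = seq(500, by = 1000,
                                  length.out = length(ids)),
                     stringsAsFactors = FALSE)
    df$cds_start <- df$tx_start; df$cds_end <- df$tx_end
    df$exons <- lapply(seq_along(ids), function(i)
      cbind(start = df$tx_start[i], end = df$tx_end[i]))
    crmminer:::.new_genes(df)
  }
  hum <- mkgenes(c("h1", "h2", "h3", "h4", "h5"))
  mou <- mkgenes(c("m1", "m2", "m3"))
  rat <- mkgenes(c("r1", "r2"))
  f <- tempfile(fileext = ".tsv")
  writeLines(c("human_gene\tmouse_gene\trat_gene",
               "h1\tm1\tr1", "h2\tm2\t", "h3\t\tr2", "h4\t\t",
               "h5\tm3\t"), f)
  expect_message(
    groups <- load_ortholog_groups(f, hum, list(mouse = mou, rat = rat)),
    "1 row")
  expect_length(groups, 4)
  expect_equal(names(groups[[1]]$rodents), c("mouse", "rat"))
  expect_equal(unname(groups[[2]]$rodents), "m2")
  writeLines(c("human_gene\tmouse_gene", "h1\tnope"), f)
  expect_error(load_ortholog_groups(f, hum, list(mouse = mou)), "unknown")
  unlink(f)
})

test_that("territories span neighbour coding boundaries, include introns,
          and never overlap any CDS", {
  df <- data.frame(
    id = c("left", "mid", "right"), chrom = "c1", strand = "+",
    tx_start = c(0, 2000, 4000), tx_end = c(500, 3000, 4500),
    stringsAsFactors = FALSE)
  df$cds_start <- c(0, 2000, 4000); df$cds_end <- c(500, 3000, 4500)
  df$exons <- list(cbind(start = 0L, end = 500L),
                   cbind(start = c(2000L, 2400L, 2800L),
                         end = c(2200L, 2600L, 3000L)),
                   cbind(start = 4000L, end = 4500L))
  genes <- crmminer:::.new_genes(df)
  terr <- noncoding_territory("mid", genes)
  expect_equal(terr$label, c("upstream", "intron", "intron", "downstream"))
  expect_equal(terr$start, c(500, 2200, 2600, 3000))
  expect_equal(terr$end, c(2000, 2400, 2800, 4000))
  # exact length bookkeeping: span minus exonic length
  expect_equal(sum(terr$end - terr$start),
               (4000 - 500) - sum(vapply(seq_len(3), function(i) {
                 e <- genes$exons[[2]]
                 e[i, "end"] - e[i, "start"]
               }, numeric(1))))
  # no region overlaps any coding exon interval
  coding <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    e <- genes$exons[[i]]
    cbind(pmax(e[, "start"], genes$cds_start[i]),
          pmin(e[, "end"], genes$cds_end[i]))
  }))
  coding <- coding[coding[, 2] > coding[, 1], , drop = FALSE]
  for (i in seq_len(nrow(terr)))
    expect_false(any(terr$start[i] < coding[, 2] &
                       terr$end[i] > coding[, 1]))
})

test_that("a gene alone on a contig takes the whole contig and an
          intronless gene has no intron regions", {
  df <- data.frame(id = "solo", chrom = "c9", strand = "+",
                   tx_start = 2000, tx_end = 3000, cds_start = 2000,
                   cds_end = 3000, stringsAsFactors = FALSE)
  df$exons <- list(cbind(start = 2000L, end = 3000L))
  genes <- crmminer:::.new_genes(df)
  terr <- noncoding_territory("solo", genes, chrom_sizes = c(c9 = 10000L))
  expect_equal(terr$start, c(0, 3000))
  expect_equal(terr$end, c(2000, 10000))
  expect_false("intron" %in% terr$label)
})

test_that("an overlapping neighbour truncates the flank to empty rather
          than a negative interval", {
  df <- data.frame(id = c("a", "b"), chrom = "c1", strand = "+",
                   tx_start = c(1000, 1500), tx_end = c(3000, 3500),
                   cds_start = c(1000, 1500), cds_end = c(3000, 3500),
                   stringsAsFactors = FALSE)
  df$exons <- list(cbind(start = 1000L, end = 3000L),
                   cbind(start = 1500L, end = 3500L))
  genes <- crmminer:::.new_genes(df)
  terr <- noncoding_territory("a", genes, chrom_sizes = c(c1 = 5000L))
  expect_true(all(terr$end > terr$start))
  expect_false("downstream" %in% terr$label)
})

test_that("strand determines which flank is upstream", {
  df <- data.frame(id = "neg", chrom = "c1", strand = "-",
                   tx_start = 2000, tx_end = 3000, cds_start = 2000,
                   cds_end = 3000, stringsAsFactors = FALSE)
  df$exons <- list(cbind(start = 2000L, end = 3000L))
  genes <- crmminer:::.new_genes(df)
  terr <- noncoding_territory("neg", genes, chrom_sizes = c(c1 = 5000L))
  expect_equal(terr$label[terr$start == 3000], "upstream")
  expect_equal(terr$label[terr$start == 0], "downstream")
})

test_that("territory sequences and BED export agree with coordinates", {
  genome <- c(c1 = paste(rep(c("A", "C", "G", "T"), 25), collapse = ""))
  terr <- data.frame(gene_id = "g", chrom = "c1", start = c(0, 8),
                     end = c(4, 12), label = c("upstream", "downstream"))
  seqs <- territory_sequences(terr, genome)
  expect_equal(seqs, c("ACGT", "ACGT"))
  f <- tempfile(fileext = ".bed")
  write_territory_bed(terr, f)
  lines <- readLines(f)
  expect_match(lines[1], "^c1\t0\t4\tg\\|upstream")
  unlink(f)
})
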