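## Gene annotations, ortholog groups, and non-coding territories.
##
## Internal coordinates are 0-based half-open throughout (BED native; GFF3
## 1-based closed coordinates are converted on read). The non-coding
## territory of a gene runs from the nearest coding-sequence boundary of
## the 5' adjacent gene to the gene's translational start (upstream), from
## the gene's stop codon to the nearest coding boundary of the 3' adjacent
## gene (downstream), plus the gene's own introns; boundaries are defined
## by codons, so UTRs fall inside the territory.

.new_genes <- function(df) {
  bad <- df$tx_start >= df$tx_end
  if (any(bad)) stop("gene ", df$id[which(bad)[1]], ": tx_start >= tx_end")
  bad <- !is.na(df$cds_start) &
    (df$cds_start < df$tx_start | df$cds_end > df$tx_end)
  if (any(bad))
    stop("gene ", df$id[which(bad)[1]], ": CDS outside transcript")
  df <- df[order(df$chrom, df$tx_start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("crm_genes", "data.frame")
  df
}

#' Read gene annotations
#'
#' Parses BED12 or GFF3 into the internal gene table. Genes with an empty
#' coding span (BED12 `thickStart == thickEnd`, or no CDS features in GFF3)
#' are flagged non-coding and excluded with a warning, as are genes for
#' which only one transcript is kept (the longest CDS per gene id).
#'
#' @param path Annotation file.
#' @param format `"bed12"` or `"gff3"` (default guessed from the
#'   extension).
#' @return A `crm_genes` data.frame: `id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`, `cds_start`, `cds_end` (0-based half-open) and a list-column
#'   `exons` of 2-column matrices, sorted by (chrom, start).
#' @export
read_genes <- function(path, format = c("auto", "bed12", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else "bed12"
  }
  if (format == "bed12") .read_bed12(path) else .read_gff3(path)
}

.read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$blocks)) stop("not a BED12 file (no block structure): ", path)
  n <- length(gr)
  cds_start <- GenomicRanges::start(gr$thick) - 1L
  cds_end <- GenomicRanges::end(gr$thick)
  empty_cds <- GenomicRanges::width(gr$thick) == 0
  exons <- lapply(seq_len(n), function(i) {
    bl <- gr$blocks[[i]]
    off <- GenomicRanges::start(gr)[i] - 1L
    cbind(start = off + IRanges::start(bl) - 1L, end = off + IRanges::end(bl))
  })
  df <- data.frame(id = as.character(gr$name),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   tx_start = GenomicRanges::start(gr) - 1L,
                   tx_end = GenomicRanges::end(gr),
                   cds_start = ifelse(empty_cds, NA_integer_, cds_start),
                   cds_end = ifelse(empty_cds, NA_integer_, cds_end),
                   stringsAsFactors = FALSE)
  df$exons <- exons
  if (any(empty_cds)) {
    warning(sum(empty_cds), " gene(s) with empty CDS excluded (non-coding)")
    df <- df[!empty_cds, , drop = FALSE]
  }
  .new_genes(df)
}

.read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  parent_of <- function(x) vapply(x$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "")
  tx <- gr[typ %in% c("mRNA", "transcript")]
  tx_parent <- parent_of(tx)
  sub <- gr[typ %in% c("exon", "CDS")]
  sub_parent <- parent_of(sub)
  rows <- list()
  for (i in seq_along(genes)) {
    gid <- as.character(genes$ID[i])
    gname <- if (!is.null(genes$Name) && !is.na(genes$Name[i]))
      as.character(genes$Name[i]) else gid
    tids <- as.character(tx$ID[tx_parent == gid])
    if (!length(tids)) tids <- gid   # features attached to the gene directly
    best <- NULL; best_len <- -1
    for (tid in tids) {
      ft <- sub[sub_parent == tid]
      cds <- ft[as.character(ft$type) == "CDS"]
      len <- sum(GenomicRanges::width(cds))
      if (len > best_len) { best <- ft; best_len <- len }
    }
    cds <- best[as.character(best$type) == "CDS"]
    ex <- best[as.character(best$type) == "exon"]
    if (!length(ex)) ex <- cds
    rows[[i]] <- data.frame(
      id = gname, chrom = as.character(GenomicRanges::seqnames(genes)[i]),
      strand = as.character(GenomicRanges::strand(genes)[i]),
      tx_start = GenomicRanges::start(genes)[i] - 1L,
      tx_end = GenomicRanges::end(genes)[i],
      cds_start = if (length(cds)) min(GenomicRanges::start(cds)) - 1L
                  else NA_integer_,
      cds_end = if (length(cds)) max(GenomicRanges::end(cds))
                else NA_integer_,
      stringsAsFactors = FALSE)
    ex <- GenomicRanges::reduce(ex)
    rows[[i]]$exons <- list(cbind(start = GenomicRanges::start(ex) - 1L,
                                  end = GenomicRanges::end(ex)))
  }
  df <- do.call(rbind, rows)
  no_cds <- is.na(df$cds_start)
  if (any(no_cds)) {
    warning(sum(no_cds), " gene(s) without CDS excluded (non-coding)")
    df <- df[!no_cds, , drop = FALSE]
  }
  .new_genes(df)
}

#' Introns of a gene
#' @param gene One row of a `crm_genes` data.frame.
#' @return 2-column matrix of intron intervals (0-based half-open),
#'   possibly empty.
#' @export
gene_introns <- function(gene) {
  ex <- gene$exons[[1]]
  ex <- ex[order(ex[, "start"]), , drop = FALSE]
  if (nrow(ex) < 2)
    return(cbind(start = integer(0), end = integer(0)))
  cbind(start = ex[-nrow(ex), "end"], end = ex[-1, "start"])
}

#' Write genes as BED12
#' @param genes A `crm_genes` data.frame.
#' @param path Output file.
#' @export
write_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    ex <- ex[order(ex[, "start"]), , drop = FALSE]
    paste(g$chrom, g$tx_start, g$tx_end, g$id, 0, g$strand,
          g$cds_start, g$cds_end, "0", nrow(ex),
          paste0(paste(ex[, "end"] - ex[, "start"], collapse = ","), ","),
          paste0(paste(ex[, "start"] - g$tx_start, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog group table
#'
#' TSV with columns `human_gene` and optional `mouse_gene`, `rat_gene`.
#' Rows lacking any rodent gene are dropped (with a message reporting the
#' count); gene ids absent from the supplied annotations are an error.
#'
#' @param path TSV file.
#' @param human `crm_genes` table for human.
#' @param rodents Named list of `crm_genes` tables, e.g.
#'   `list(mouse = ..., rat = ...)`.
#' @return A list of ortholog groups, each
#'   `list(human = id, rodents = c(mouse = id, rat = id))` (species absent
#'   from a row are dropped from `rodents`).
#' @export
load_ortholog_groups <- function(path, human, rodents) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"human_gene" %in% names(tab)) stop("missing column human_gene")
  rodent_cols <- intersect(paste0(names(rodents), "_gene"), names(tab))
  if (!length(rodent_cols)) stop("no rodent gene column found")
  groups <- list(); dropped <- 0L
  for (i in seq_len(nrow(tab))) {
    rg <- c()
    for (col in rodent_cols) {
      v <- tab[[col]][i]
      if (!is.na(v) && nzchar(v)) rg[sub("_gene$", "", col)] <- v
    }
    if (!length(rg)) { dropped <- dropped + 1L; next }
    hid <- tab$human_gene[i]
    if (!hid %in% human$id) stop("unknown human gene id: ", hid)
    for (sp in names(rg)) {
      if (!rg[sp] %in% rodents[[sp]]$id)
        stop("unknown ", sp, " gene id: ", rg[sp])
    }
    groups[[length(groups) + 1]] <- list(human = hid, rodents = rg)
  }
  if (dropped)
    message(dropped, " row(s) without any rodent ortholog dropped")
  groups
}

#' Non-coding territory of a gene
#'
#' Upstream: from the nearest coding boundary of the 5' neighbour (or the
#' contig start) to the gene's translational start. Downstream: from the
#' stop codon to the nearest coding boundary of the 3' neighbour (or the
#' contig end). Introns: the gene's introns within its coding span.
#' Neighbours are the nearest annotated coding genes on either side on the
#' same chromosome, any strand; a neighbour overlapping the gene's coding
#' span truncates the flank to empty. Labels follow the gene's orientation.
#'
#' @param gene_id Id of the focal gene.
#' @param genes `crm_genes` table containing it (and its neighbours).
#' @param chrom_sizes Named integer vector of chromosome lengths (used for
#'   contig ends); optional, defaults to unbounded on the right.
#' @return Data.frame of regions: `gene_id`, `chrom`, `start`, `end`,
#'   `label` (upstream / downstream / intron), disjoint and sorted.
#' @export
noncoding_territory <- function(gene_id, genes, chrom_sizes = NULL) {
  g <- genes[genes$id == gene_id, , drop = FALSE]
  if (nrow(g) != 1) stop("gene id not found (or duplicated): ", gene_id)
  others <- genes[genes$chrom == g$chrom & genes$id != gene_id, , drop = FALSE]
  left_bound <- suppressWarnings(
    max(0L, others$cds_end[others$cds_end <= g$cds_start]))
  right_lim <- if (!is.null(chrom_sizes) && g$chrom %in% names(chrom_sizes))
    chrom_sizes[[g$chrom]] else .Machine$integer.max
  cand <- others$cds_start[others$cds_start >= g$cds_end]
  right_bound <- if (length(cand)) min(cand) else right_lim
  # neighbours overlapping the coding span truncate the flank to empty
  if (any(others$cds_start < g$cds_start & others$cds_end > g$cds_start))
    left_bound <- g$cds_start
  if (any(others$cds_start < g$cds_end & others$cds_end > g$cds_end))
    right_bound <- g$cds_end
  left <- c(start = left_bound, end = g$cds_start)
  right <- c(start = g$cds_end, end = right_bound)
  up <- if (g$strand == "+") left else right
  dn <- if (g$strand == "+") right else left
  introns <- gene_introns(g)
  introns <- introns[introns[, "start"] >= g$cds_start &
                       introns[, "end"] <= g$cds_end, , drop = FALSE]
  regions <- data.frame(
    gene_id = gene_id, chrom = g$chrom,
    start = c(up["start"], dn["start"], introns[, "start"]),
    end = c(up["end"], dn["end"], introns[, "end"]),
    label = c("upstream", "downstream", rep("intron", nrow(introns))),
    stringsAsFactors = FALSE)
  regions <- regions[regions$end > regions$start, , drop = FALSE]
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

#' Non-coding territories for all genes
#'
#' @param genes `crm_genes` table.
#' @param chrom_sizes Named chromosome lengths.
#' @return One territory data.frame (see [noncoding_territory()]) with all
#'   genes stacked.
#' @export
noncoding_territories <- function(genes, chrom_sizes = NULL) {
  do.call(rbind, lapply(genes$id, noncoding_territory, genes = genes,
                        chrom_sizes = chrom_sizes))
}

#' Fetch the sequence of each territory region
#'
#' @param territory Territory data.frame.
#' @param genome Named `DNAStringSet` or character vector.
#' @return Character vector of region sequences (forward strand).
#' @export
territory_sequences <- function(territory, genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  vapply(seq_len(nrow(territory)), function(i) {
    substr(genome[[territory$chrom[i]]], territory$start[i] + 1L,
           territory$end[i])
  }, "")
}

#' Export territory regions as BED6 (label in the name field)
#' @param territory Territory data.frame.
#' @param path Output file.
#' @export
write_territory_bed <- function(territory, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t+", territory$chrom,
                   territory$start, territory$end, territory$gene_id,
                   territory$label)
  writeLines(lines, path)
  invisible(path)
}
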