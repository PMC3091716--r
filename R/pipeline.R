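## End-to-end pipeline over a dataset: territories -> conserved segments ->
## blocks -> TFBS candidates -> transactions -> motif modules.

#' Align the non-coding territories of every ortholog group
#'
#' For each group and each rodent species, aligns every human territory
#' region against every ortholog territory region and reports conserved
#' segments in genomic (contig) coordinates.
#'
#' @param dataset A `crm_dataset` (or a list with compatible `genomes`,
#'   `genes`, `orthologs` elements).
#' @param params [align_params()].
#' @return A list per group: `gene_id`, `chrom`, `regions` (human
#'   territory), and `segments` (named list per species; each data.frame
#'   carries `region` and `o_region` ids).
#' @export
align_dataset <- function(dataset, params = align_params()) {
  terr <- lapply(names(dataset$genomes), function(sp) {
    sizes <- setNames(nchar(dataset$genomes[[sp]]),
                      names(dataset$genomes[[sp]]))
    noncoding_territories(dataset$genes[[sp]], chrom_sizes = sizes)
  })
  names(terr) <- names(dataset$genomes)
  lapply(dataset$orthologs, function(grp) {
    ht <- terr$human[terr$human$gene_id == grp$human, , drop = FALSE]
    ht$region <- seq_len(nrow(ht))
    hseqs <- territory_sequences(ht, dataset$genomes$human)
    segs <- list()
    for (sp in names(grp$rodents)) {
      ot <- terr[[sp]][terr[[sp]]$gene_id == grp$rodents[[sp]], ,
                       drop = FALSE]
      ot$region <- seq_len(nrow(ot))
      oseqs <- territory_sequences(ot, dataset$genomes[[sp]])
      rows <- list()
      for (i in seq_len(nrow(ht))) for (j in seq_len(nrow(ot))) {
        s <- align_regions(hseqs[i], oseqs[j], params)
        if (!nrow(s)) next
        s$h_start <- s$h_start + ht$start[i]
        s$h_end <- s$h_end + ht$start[i]
        s$o_start <- s$o_start + ot$start[j]
        s$o_end <- s$o_end + ot$start[j]
        s$region <- ht$region[i]
        s$o_region <- ot$region[j]
        rows[[length(rows) + 1]] <- s
      }
      segs[[sp]] <- if (length(rows)) {
        pooled <- do.call(rbind, rows)
        # segments from different ortholog regions may collide on the
        # human side; keep the best per human interval
        resolve_overlaps(pooled)
      } else data.frame(h_start = integer(0), h_end = integer(0),
                        o_start = integer(0), o_end = integer(0),
                        strand = character(0), score = numeric(0),
                        identity = numeric(0), n_match = integer(0),
                        n_mismatch = integer(0), n_gap_open = integer(0),
                        n_gap_ext = integer(0), region = integer(0),
                        o_region = integer(0))
    }
    list(gene_id = grp$human, chrom = ht$chrom[1], regions = ht,
         segments = segs)
  })
}

#' Select conserved blocks across all groups
#'
#' Scores candidate windows in every group, pools the conservation scores
#' to set the genome-wide cutoff (at most `1 - cutoff_quantile` of windows
#' exceed it), and merges/trims the passing windows into blocks.
#'
#' @param aligned Output of [align_dataset()].
#' @param window Window length (bp).
#' @param cutoff_quantile Pooled retention quantile (default 0.95).
#' @return List with `blocks` (data.frame: `block_id`, `group`, `gene_id`,
#'   `chrom`, `start`, `end`, `C_max`, `n_windows`, list-column
#'   `conserved`), `windows` (pooled, with `group`), and `cutoff`.
#' @export
find_conserved_blocks <- function(aligned, window = 1000L,
                                  cutoff_quantile = 0.95) {
  winlist <- lapply(seq_along(aligned), function(g) {
    w <- conservation_windows(aligned[[g]]$segments, aligned[[g]]$regions,
                              window)
    if (nrow(w)) w$group <- g
    w
  })
  wins <- do.call(rbind, winlist[vapply(winlist, nrow, 0L) > 0])
  if (is.null(wins) || !nrow(wins)) stop("no conserved segments anywhere")
  cutoff <- compute_cutoff(wins$C, cutoff_quantile)
  blocks <- list()
  for (g in seq_along(aligned)) {
    w <- winlist[[g]]
    if (!nrow(w)) next
    segs <- do.call(rbind, lapply(aligned[[g]]$segments, function(s)
      s[, c("h_start", "h_end", "region"), drop = FALSE]))
    b <- find_blocks(w, segs, cutoff)
    if (!nrow(b)) next
    b$group <- g
    b$gene_id <- aligned[[g]]$gene_id
    b$chrom <- aligned[[g]]$chrom
    blocks[[length(blocks) + 1]] <- b
  }
  if (!length(blocks)) {
    bl <- data.frame(block_id = character(0), group = integer(0),
                     gene_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     C_max = numeric(0), n_windows = integer(0))
    bl$conserved <- list()
    return(list(blocks = bl, windows = wins, cutoff = cutoff))
  }
  bl <- do.call(rbind, blocks)
  bl <- bl[order(bl$group, bl$start), , drop = FALSE]
  bl$block_id <- sprintf("b%05d", seq_len(nrow(bl)))
  rownames(bl) <- NULL
  cols <- c("block_id", "group", "gene_id", "chrom", "start", "end",
            "C_max", "n_windows", "conserved")
  list(blocks = bl[, cols], windows = wins, cutoff = cutoff)
}

#' Run the full discovery pipeline on a dataset
#'
#' Alignment, block selection, motif-cutoff calibration (unless a
#' calibrated library is supplied), TFBS scanning, FP-tree mining and
#' module calling.
#'
#' @param dataset A `crm_dataset`.
#' @param motifs Optional calibrated `crm_motif_library`; defaults to the
#'   dataset's library calibrated on `background_regions` random 1 kb
#'   sequences.
#' @param params [align_params()].
#' @param window,cutoff_quantile Block selection parameters.
#' @param motif_p Per-position background hit probability for cutoffs.
#' @param background_regions Number of random background regions for
#'   calibration.
#' @param min_support,alpha Mining parameters.
#' @param max_size Largest itemset size mined.
#' @return List with `aligned`, `blocks`, `windows`, `cutoff`, `motifs`,
#'   `tfbs`, `transactions`, `frequent`, `modules`.
#' @export
run_pipeline <- function(dataset, motifs = NULL, params = align_params(),
                         window = 1000L, cutoff_quantile = 0.95,
                         motif_p = 1e-4, background_regions = 10000L,
                         min_support = 100L, alpha = 0.05, max_size = Inf) {
  aligned <- align_dataset(dataset, params)
  bl <- find_conserved_blocks(aligned, window, cutoff_quantile)
  if (is.null(motifs)) {
    bg <- random_background(background_regions, 1000L, dataset$config$gc,
                            seed = dataset$config$seed + 7777L)
    motifs <- calibrate_cutoffs(dataset$motifs, bg, motif_p)
  }
  genome <- dataset$genomes$human
  tfbs <- scan_blocks(bl$blocks, motifs, genome)
  trans <- build_transactions(bl$blocks$block_id, tfbs)
  freq <- mine_frequent(trans, min_support = min_support,
                        max_size = max_size)
  mods <- call_modules(freq, trans, alpha = alpha)
  list(aligned = aligned, blocks = bl$blocks, windows = bl$windows,
       cutoff = bl$cutoff, motifs = motifs, tfbs = tfbs,
       transactions = trans, frequent = freq, modules = mods)
}
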