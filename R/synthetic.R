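## Seeded synthetic data: orthologous gene groups whose non-coding
## territories contain planted conserved islands carrying motif sites,
## plus background conserved elements and neutral spacer.
##
## The generator emulates the data regime the block-selection step is built
## for: most of a territory is neutral sequence with no usable homology
## between human and rodent (neutral mammalian DNA is largely unalignable),
## scattered short conserved elements (the fate of ancient repeats and
## miscellaneous constrained elements) provide a large population of
## weakly conserved candidate windows, and a minority of ~1 kb islands are
## strongly conserved and carry the planted TFBSs. The genome-wide 5%
## conservation cutoff then separates islands from the background
## population, as it does on real genomes.

.BASES4 <- c("A", "C", "G", "T")

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.random_dna_codes <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample.int(4L, n, replace = TRUE, prob = p) - 1L
}

.codes_to_string <- function(v) paste(.BASES4[v + 1L], collapse = "")
# light-weight reverse complement for short generator strings
.rc_chr <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
.string_to_codes <- function(s) {
  match(strsplit(toupper(s), "")[[1]], .BASES4) - 1L
}

#' Random background sequences
#'
#' I.i.d. sequences used as the calibration background for motif cutoffs.
#'
#' @param n Number of regions.
#' @param len Region length in bp (default 1000).
#' @param gc GC fraction.
#' @param seed Optional seed (local to this call).
#' @return Character vector of sequences.
#' @export
random_background <- function(n, len = 1000L, gc = 0.5, seed = NULL) {
  gen <- function() vapply(seq_len(n), function(i)
    .codes_to_string(.random_dna_codes(len, gc)), "")
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Simulation configuration
#'
#' Defaults define the standard study conditions: 1000 ortholog groups
#' (human + mouse + rat), 3 kb territories containing one 850 bp strongly
#' conserved island (5% substitution) and 24 short background conserved
#' elements (25 bp, 10% substitution) in neutral spacer, a 12-motif
#' library, and one planted 3-motif module inserted into the islands of
#' 120 groups, with every motif's overall planted site frequency held at
#' 0.15 of the groups.
#'
#' @param seed Master seed.
#' @param n_groups Number of ortholog groups.
#' @param territory_length Non-coding territory length (bp).
#' @param island_length Length of the conserved island (bp).
#' @param island_sub_rate Substitution rate inside islands.
#' @param decoy_count,decoy_length,decoy_sub_rate Background conserved
#'   elements per territory.
#' @param spacer_mode `"independent"` (neutral spacer drawn independently
#'   per species, emulating unalignable neutral DNA) or `"diverged"`
#'   (spacer evolved from the ancestor at `sub_rate` with indels).
#' @param sub_rate,indel_rate Spacer divergence for `"diverged"` mode.
#' @param gc Background GC fraction.
#' @param rodents Rodent species to generate.
#' @param n_motifs,motif_width,motif_dominant Motif library: count, width
#'   range, and per-column dominant-base probability range (information
#'   content control).
#' @param planted_module Character vector of member motif ids, or `NULL`
#'   for a null run (no planted module).
#' @param module_n_blocks Number of groups receiving the full module.
#' @param site_freq Target per-motif planted site frequency across groups.
#' @param spacing `"random"` site placement within the island, or
#'   `"fixed_gap"` for a fixed edge-to-edge gap between consecutive module
#'   sites.
#' @param gap Gap in bp for `spacing = "fixed_gap"`.
#' @param order `"random"` or `"fixed"` (module sites in the order given).
#' @param strand `"random"` or `"same"` (all module sites on +).
#' @param motif_seed Optional separate seed for the motif library
#'   (defaults to `seed + 101`), so several datasets can share one
#'   library.
#' @return A list of class `crm_sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_groups = 1000L,
                              territory_length = 3000L,
                              island_length = 850L, island_sub_rate = 0.05,
                              decoy_count = 24L, decoy_length = 25L,
                              decoy_sub_rate = 0.10,
                              spacer_mode = c("independent", "diverged"),
                              sub_rate = 0.4, indel_rate = 0.02, gc = 0.5,
                              rodents = c("mouse", "rat"), n_motifs = 12L,
                              motif_width = c(8L, 10L),
                              motif_dominant = c(0.97, 0.99),
                              planted_module = c("M001", "M002", "M003"),
                              module_n_blocks = 120L, site_freq = 0.15,
                              spacing = c("random", "fixed_gap"), gap = 30L,
                              order = c("random", "fixed"),
                              strand = c("random", "same"),
                              motif_seed = NULL) {
  stopifnot(island_sub_rate >= 0, island_sub_rate <= 1, sub_rate >= 0,
            sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            site_freq >= 0, site_freq <= 1)
  structure(list(seed = as.integer(seed), n_groups = as.integer(n_groups),
                 territory_length = as.integer(territory_length),
                 island_length = as.integer(island_length),
                 island_sub_rate = island_sub_rate,
                 decoy_count = as.integer(decoy_count),
                 decoy_length = as.integer(decoy_length),
                 decoy_sub_rate = decoy_sub_rate,
                 spacer_mode = match.arg(spacer_mode),
                 sub_rate = sub_rate, indel_rate = indel_rate, gc = gc,
                 rodents = rodents, n_motifs = as.integer(n_motifs),
                 motif_width = as.integer(motif_width),
                 motif_dominant = motif_dominant,
                 planted_module = planted_module,
                 module_n_blocks = as.integer(module_n_blocks),
                 site_freq = site_freq, spacing = match.arg(spacing),
                 gap = as.integer(gap), order = match.arg(order),
                 strand = match.arg(strand),
                 motif_seed = if (is.null(motif_seed)) NULL
                              else as.integer(motif_seed)),
            class = "crm_sim_config")
}

# smallest Hamming distance between two consensus strings over all
# offsets (overlap >= min_overlap) and both strands of the second
.consensus_distance <- function(a, b, min_overlap = 7L) {
  best <- Inf
  for (x in c(b, .rc_chr(b))) {
    for (off in seq(-(nchar(x) - min_overlap),
                    nchar(a) - min_overlap)) {
      s1 <- substr(a, max(1L, 1L + off), min(nchar(a), nchar(x) + off))
      s2 <- substr(x, max(1L, 1L - off), min(nchar(x), nchar(a) - off))
      n <- min(nchar(s1), nchar(s2))
      if (n < min_overlap) next
      d <- sum(strsplit(substr(s1, 1, n), "")[[1]] !=
                 strsplit(substr(s2, 1, n), "")[[1]])
      best <- min(best, d)
    }
  }
  best
}

#' Generate a random motif library
#'
#' Count matrices with one dominant base per column; the dominant-base
#' probability range controls the information content (near 1: consensus-
#' dominated columns; near 0.25: near-uniform columns). Motifs whose
#' consensus lies within Hamming distance 2 of an already accepted one
#' (any offset with at least 7 bp overlap, either strand) are redrawn, so
#' the library is non-redundant — the regime the independence null of the
#' module significance test describes, and what a curated library looks
#' like. Deterministic under the seed.
#'
#' @param n_motifs Number of motifs.
#' @param width_range Integer range of motif widths.
#' @param dominant_range Range of the per-column dominant-base probability.
#' @param nsites Counts per column.
#' @param seed Seed (local to this call).
#' @param min_distance Smallest allowed consensus distance between motifs.
#' @return A `crm_motif_library`.
#' @export
make_motif_library <- function(n_motifs = 12L, width_range = c(8L, 10L),
                               dominant_range = c(0.97, 0.99),
                               nsites = 100L, seed = 1L,
                               min_distance = 3L) {
  .with_seed(seed, {
    draw <- function(i) {
      w <- sample(seq(width_range[1], width_range[2]), 1)
      counts <- matrix(0, 4, w, dimnames = list(.BASES4, NULL))
      for (j in seq_len(w)) {
        dom <- sample.int(4L, 1)
        p <- runif(1, dominant_range[1], dominant_range[2])
        nd <- round(nsites * p)
        rest <- nsites - nd
        others <- setdiff(1:4, dom)
        split <- rep(rest %/% 3, 3)
        extra <- rest %% 3
        if (extra) split[seq_len(extra)] <- split[seq_len(extra)] + 1L
        split <- pmax(split, 1L)   # no all-zero rows in a column
        counts[dom, j] <- nsites - sum(split)
        counts[others, j] <- split
      }
      .new_motif(sprintf("M%03d", i), sprintf("TF%02d", i), counts)
    }
    motifs <- list()
    accepted <- character(0)
    for (i in seq_len(n_motifs)) {
      for (try in 1:100) {
        m <- draw(i)
        cons <- motif_consensus(m)
        ok <- all(vapply(accepted, .consensus_distance, numeric(1),
                         a = cons) >= min_distance)
        if (ok) break
      }
      if (!ok) stop("could not draw ", n_motifs, " sufficiently distinct ",
                    "motifs; relax min_distance or widen widths")
      motifs[[i]] <- m
      accepted <- c(accepted, cons)
    }
    names(motifs) <- vapply(motifs, `[[`, "", "id")
    structure(motifs, class = "crm_motif_library")
  })
}

#' Sample a site sequence from a motif's count matrix
#' @param motif A `crm_motif`.
#' @return Character string of length `width`.
#' @export
sample_site <- function(motif) {
  probs <- sweep(motif$counts, 2, colSums(motif$counts), "/")
  paste(vapply(seq_len(motif$width), function(j)
    sample(.BASES4, 1, prob = probs[, j]), ""), collapse = "")
}
#' Evolve an ortholog copy of an ancestor sequence
#'
#' Conserved intervals are copied with a reduced substitution rate and no
#' indels; the remaining (spacer) positions substitute at `sub_rate` and
#' acquire indels at `indel_rate` per bp with geometric lengths (mean 3
#' bp). Substitutions always change the base. Returns the pair plus a
#' coordinate map from ancestor to ortholog positions.
#'
#' @param ancestor DNA string.
#' @param sub_rate Spacer substitution rate.
#' @param indel_rate Per-bp indel initiation rate in spacer.
#' @param conserved_intervals 2-column matrix (`start`, `end`, 0-based
#'   half-open) of conserved intervals, or `NULL`.
#' @param conserved_sub_rate Substitution rate inside conserved intervals.
#' @param seed Optional seed (local to this call).
#' @return List with `human` (the ancestor), `ortholog`, and `map`
#'   (integer vector: `map[i + 1]` is the ortholog coordinate aligned to
#'   ancestor position `i`, for `i` in `0..n`).
#' @export
evolve_pair <- function(ancestor, sub_rate = 0.4, indel_rate = 0.02,
                        conserved_intervals = NULL,
                        conserved_sub_rate = 0.05, seed = NULL) {
  run <- function() {
    v <- .string_to_codes(ancestor)
    n <- length(v)
    cons <- logical(n)
    if (!is.null(conserved_intervals) && nrow(conserved_intervals)) {
      for (k in seq_len(nrow(conserved_intervals)))
        cons[(conserved_intervals[k, 1] + 1L):conserved_intervals[k, 2]] <- TRUE
    }
    rate <- ifelse(cons, conserved_sub_rate, sub_rate)
    hit <- runif(n) < rate
    v2 <- v
    if (any(hit))
      v2[hit] <- (v[hit] + sample.int(3L, sum(hit), replace = TRUE)) %% 4L
    deleted <- logical(n)
    ins_after <- character(n)
    if (indel_rate > 0) {
      ev <- which(runif(n) < indel_rate & !cons)
      for (p in ev) {
        len <- 1L + rgeom(1, 1 / 3)
        if (runif(1) < 0.5) {                      # deletion
          q <- p
          while (q <= n && q < p + len && !cons[q]) { deleted[q] <- TRUE; q <- q + 1L }
        } else {                                   # insertion after p
          ins_after[p] <- paste0(ins_after[p],
                                 .codes_to_string(.random_dna_codes(len)))
        }
      }
    }
    chars <- .BASES4[v2 + 1L]
    chars[deleted] <- ""
    chars <- paste0(chars, ins_after)
    out_len <- nchar(chars)
    map <- cumsum(c(0L, out_len))
    list(human = toupper(ancestor), ortholog = paste(chars, collapse = ""),
         map = map)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

# sample k non-overlapping intervals of length len inside [lo, hi),
# avoiding the intervals in `avoid` (2-col matrix); returns starts
.place_intervals <- function(k, len, lo, hi, avoid = NULL, margin = 5L,
                             max_tries = 2000L) {
  starts <- integer(0)
  taken <- avoid
  tries <- 0L
  while (length(starts) < k && tries < max_tries) {
    tries <- tries + 1L
    s <- sample(seq(lo, hi - len), 1)
    iv <- c(s - margin, s + len + margin)
    clash <- FALSE
    if (!is.null(taken) && nrow(taken))
      clash <- any(taken[, 1] < iv[2] & taken[, 2] > iv[1])
    if (clash) next
    starts <- c(starts, s)
    taken <- rbind(taken, c(s, s + len))
  }
  sort(starts)
}

#' Generate a complete synthetic dataset
#'
#' Produces genomes (one contig per ortholog group and species, each a
#' non-coding territory followed by a single-exon gene), gene tables,
#' ortholog groups, the motif library, and the ground truth of planted
#' islands and TFBSs. Fully deterministic under the configuration seed.
#'
#' @param config A [simulation_config()].
#' @return List of class `crm_dataset` with elements `genomes` (named
#'   character vectors per species), `genes` (`crm_genes` per species),
#'   `orthologs`, `motifs`, `truth`, and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  .with_seed(config$seed, .simulate_dataset_impl(config))
}

.simulate_dataset_impl <- function(config) {
  motifs <- make_motif_library(config$n_motifs, config$motif_width,
                               config$motif_dominant,
                               seed = if (!is.null(config$motif_seed))
                                 config$motif_seed else config$seed + 101L)
  ids <- names(motifs)
  members <- config$planted_module
  if (!is.null(members) && !all(members %in% ids))
    stop("planted module motifs must exist in the generated library")
  L <- config$territory_length
  gene_len <- 300L
  n <- config$n_groups
  planted_groups <- if (is.null(members)) integer(0)
                    else sort(sample.int(n, config$module_n_blocks))
  # per-motif individual insertion rate keeping the overall site frequency
  ind_rate <- setNames(rep(config$site_freq, length(ids)), ids)
  if (!is.null(members)) {
    extra <- config$site_freq * n - config$module_n_blocks
    ind_rate[members] <- max(0, extra) / (n - config$module_n_blocks)
  }
  species <- c("human", config$rodents)
  genomes <- setNames(vector("list", length(species)), species)
  for (sp in species) genomes[[sp]] <- character(n)
  truth_sites <- list()
  island_starts <- integer(n)
  # per-motif sampling tables, hoisted out of the group loop
  # planted TFBSs are the canonical (consensus) site of each matrix: they
  # model functional high-affinity sites, which for matrices this
  # informative are essentially consensus-identical
  cons_m <- lapply(motifs, motif_consensus)
  draw_site <- function(mo) cons_m[[mo]]
  for (g in seq_len(n)) {
    anc <- .random_dna_codes(L, config$gc)
    island_start <- sample(seq(200L, L - 1000L), 1)
    island <- c(island_start, island_start + config$island_length)
    # keep background elements clear of the island: downstream so x-drop
    # extension cannot chain them into an over-long segment, and far
    # enough upstream that no window anchored at a background element can
    # contain the whole island (which would double-count island-level
    # conservation in the pooled cutoff population)
    capture <- 1000L - config$island_length
    avoid <- rbind(island + c(-(capture + 10L), 60L))
    dstarts <- .place_intervals(config$decoy_count, config$decoy_length,
                                0L, L, avoid = avoid)
    decoys <- cbind(dstarts, dstarts + config$decoy_length)
    # choose the motifs with a site in this group's island
    planted_here <- if (g %in% planted_groups) members else character(0)
    indiv <- ids[runif(length(ids)) < ind_rate[ids]]
    indiv <- setdiff(indiv, planted_here)
    widths_m <- vapply(motifs, `[[`, 0L, "width")
    place_lo <- island[1] + 5L; place_hi <- island[2] - 5L
    taken <- NULL
    sg_motif <- character(0); sg_start <- integer(0)
    sg_strand <- character(0); sg_mod <- logical(0)
    place_one <- function(mo, s) {
      w <- widths_m[[mo]]
      std <- if (config$strand == "same") "+"
             else sample(c("+", "-"), 1)
      site <- draw_site(mo)
      if (std == "-") site <- .rc_chr(site)
      anc[(s + 1L):(s + w)] <<- .string_to_codes(site)
      taken <<- rbind(taken, c(s, s + w))
      sg_motif <<- c(sg_motif, mo); sg_start <<- c(sg_start, s)
      sg_strand <<- c(sg_strand, std)
      sg_mod <<- c(sg_mod, mo %in% planted_here)
      invisible()
    }
    if (length(planted_here)) {
      ord <- if (config$order == "fixed") planted_here
             else sample(planted_here)
      if (config$spacing == "fixed_gap") {
        total <- sum(widths_m[ord]) + config$gap * (length(ord) - 1L)
        s0 <- sample(seq(place_lo, place_hi - total), 1)
        s <- s0
        for (mo in ord) {
          place_one(mo, s)
          s <- s + widths_m[[mo]] + config$gap
        }
      } else {
        for (mo in ord) {
          st <- .place_intervals(1L, widths_m[[mo]], place_lo, place_hi,
                                 avoid = taken)
          if (length(st)) place_one(mo, st)
        }
      }
    }
    for (mo in indiv) {
      st <- .place_intervals(1L, widths_m[[mo]], place_lo, place_hi,
                             avoid = taken)
      if (length(st)) place_one(mo, st)
    }
    conserved <- rbind(island, decoys)
    genomes$human[g] <- .codes_to_string(anc)
    for (sp in config$rodents) {
      if (config$spacer_mode == "independent") {
        orth <- .random_dna_codes(L, config$gc)
        for (k in seq_len(nrow(conserved))) {
          idx <- (conserved[k, 1] + 1L):conserved[k, 2]
          rate <- if (k == 1) config$island_sub_rate else config$decoy_sub_rate
          seg <- anc[idx]
          hit <- runif(length(seg)) < rate
          seg[hit] <- (seg[hit] + sample.int(3L, sum(hit), TRUE)) %% 4L
          orth[idx] <- seg
        }
        genomes[[sp]][g] <- .codes_to_string(orth)
      } else {
        ev <- evolve_pair(.codes_to_string(anc), config$sub_rate,
                          config$indel_rate, conserved,
                          config$island_sub_rate)
        genomes[[sp]][g] <- ev$ortholog
      }
    }
    island_starts[g] <- island[1]
    if (length(sg_motif))
      truth_sites[[length(truth_sites) + 1]] <- data.frame(
        group = g, motif = sg_motif, start = sg_start,
        end = sg_start + unname(widths_m[sg_motif]), strand = sg_strand,
        in_module = sg_mod, stringsAsFactors = FALSE)
    # append the gene after the territory
    for (sp in species) {
      glen <- nchar(genomes[[sp]][g])
      genomes[[sp]][g] <- paste0(genomes[[sp]][g],
                                 .codes_to_string(.random_dna_codes(gene_len,
                                                                    config$gc)))
    }
  }
  contig <- sprintf("g%04d", seq_len(n))
  prefix <- c(human = "hg", mouse = "mm", rat = "rn")
  genes <- list()
  for (sp in species) {
    names(genomes[[sp]]) <- contig
    tlen <- nchar(genomes[[sp]]) - gene_len
    df <- data.frame(id = paste0(prefix[[sp]], sprintf("%04d", seq_len(n))),
                     chrom = contig, strand = "+",
                     tx_start = tlen, tx_end = tlen + gene_len,
                     cds_start = tlen, cds_end = tlen + gene_len,
                     stringsAsFactors = FALSE)
    df$exons <- lapply(seq_len(n), function(i)
      cbind(start = df$tx_start[i], end = df$tx_end[i]))
    genes[[sp]] <- .new_genes(df)
  }
  orthologs <- lapply(seq_len(n), function(g) {
    list(human = genes$human$id[g],
         rodents = setNames(vapply(config$rodents, function(sp)
           genes[[sp]]$id[g], ""), config$rodents))
  })
  truth <- list(
    module = members,
    planted_groups = planted_groups,
    islands = data.frame(group = seq_len(n), start = island_starts,
                         end = island_starts + config$island_length),
    sites = if (length(truth_sites)) do.call(rbind, truth_sites)
            else data.frame(group = integer(0), motif = character(0),
                            start = integer(0), end = integer(0),
                            strand = character(0), in_module = logical(0)))
  structure(list(genomes = genomes, genes = genes, orthologs = orthologs,
                 motifs = motifs, truth = truth, config = config),
            class = "crm_dataset")
}

#' Write a dataset to disk
#'
#' Emits per-species FASTA and BED12, the ortholog TSV, the motif library
#' in TRANSFAC format, and the ground truth as JSON.
#'
#' @param dataset A `crm_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(dataset$genomes)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(dataset$genomes[[sp]]),
      file.path(dir, paste0(sp, ".fa")))
    write_bed12(dataset$genes[[sp]], file.path(dir, paste0(sp, ".bed")))
  }
  ortho <- data.frame(
    human_gene = vapply(dataset$orthologs, `[[`, "", "human"))
  for (sp in setdiff(names(dataset$genomes), "human")) {
    ortho[[paste0(sp, "_gene")]] <- vapply(dataset$orthologs, function(o)
      if (sp %in% names(o$rodents)) o$rodents[[sp]] else "", "")
  }
  write.table(ortho, file.path(dir, "orthologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_motifs_transfac(dataset$motifs, file.path(dir, "motifs.transfac"))
  truth <- dataset$truth
  jsonlite::write_json(
    list(module = truth$module, planted_groups = truth$planted_groups,
         islands = truth$islands, sites = truth$sites),
    file.path(dir, "ground_truth.json"))
  invisible(dir)
}
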