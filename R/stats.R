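## Downstream statistics for predicted modules and CRMs: target genes,
## gene-set overlap, composite-element enrichment, and order / distance /
## strand / location preferences of motif pairs.

#' Upper-tail hypergeometric overlap p-value
#'
#' `P(X >= m)` for X hypergeometric: `m` successes drawn when `n` of `N`
#' genes are targets and `M` of `N` belong to the gene set. Computed via
#' the stable log-space tail of [stats::phyper()].
#'
#' @param N Genes in the universe.
#' @param M Genes in the set.
#' @param n Target genes of the module.
#' @param m Overlap.
#' @return p-value in (0, 1].
#' @export
hypergeom_overlap <- function(N, M, n, m) {
  if (m < 0 || M > N || n > N || m > min(M, n))
    stop("need 0 <= m <= min(M, n) <= N")
  if (m == 0) return(1)
  exp(phyper(m - 1, M, N - M, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Numeric vector of p-values.
#' @param method Adjustment method (default `"BH"`).
#' @return Adjusted q-values.
#' @export
adjust_fdr <- function(p, method = "BH") {
  p.adjust(p, method = method)
}

#' Fair-coin binomial tail for order / strand preferences
#'
#' Upper tail `P(X >= m)` when `m > n/2`, lower tail `P(X <= m)` otherwise,
#' for `X ~ Binomial(n, 1/2)`.
#' @param n Informative CRMs.
#' @param m CRMs showing the tested configuration.
#' @return p-value in (0, 1].
#' @export
binom_pref_pvalue <- function(n, m) {
  if (n < 1 || m < 0 || m > n) stop("need 0 <= m <= n, n >= 1")
  if (m > n / 2) pbinom(m - 1, n, 0.5, lower.tail = FALSE)
  else pbinom(m, n, 0.5)
}

#' Assign each CRM to its nearest gene
#'
#' The target gene of a CRM is the gene whose coding span is closest to the
#' CRM interval on the same chromosome (distance 0 when they overlap; ties
#' broken toward the 5'-most gene, i.e. smallest coding start, and logged).
#' The location label (upstream / downstream / intron) is taken from the
#' territory region containing the CRM midpoint, and the signed distance
#' from the midpoint to the gene's transcription start site is reported
#' (positive when the CRM lies upstream of the TSS in the gene's reading
#' direction).
#'
#' @param crms Data.frame with `chrom`, `start`, `end` (one row per CRM).
#' @param genes A `crm_genes` data.frame (see [read_genes()]).
#' @param territories Territory data.frame from [noncoding_territories()]
#'   (columns `gene_id`, `chrom`, `start`, `end`, `label`); used for the
#'   location label.
#' @return `crms` with `gene_id`, `location`, `dist_tss` and `tie` columns.
#' @export
assign_target_genes <- function(crms, genes, territories = NULL) {
  n <- nrow(crms)
  gene_id <- character(n); location <- character(n)
  dist_tss <- rep(NA_real_, n); tie <- logical(n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == crms$chrom[i], , drop = FALSE]
    if (!nrow(g)) { gene_id[i] <- NA_character_; location[i] <- NA_character_; next }
    d <- pmax(0, pmax(g$cds_start - crms$end[i], crms$start[i] - g$cds_end))
    best <- which(d == min(d))
    if (length(best) > 1) {
      tie[i] <- TRUE
      best <- best[order(g$cds_start[best], g$id[best])][1]
      message("CRM ", i, ": target-gene tie broken toward ", g$id[best])
    }
    gene_id[i] <- g$id[best]
    mid <- (crms$start[i] + crms$end[i]) / 2
    tss <- if (g$strand[best] == "+") g$tx_start[best] else g$tx_end[best]
    dist_tss[i] <- if (g$strand[best] == "+") tss - mid else mid - tss
    loc <- NA_character_
    if (!is.null(territories)) {
      tr <- territories[territories$gene_id == gene_id[i] &
                          territories$chrom == crms$chrom[i] &
                          territories$start <= mid & mid < territories$end, ,
                        drop = FALSE]
      if (nrow(tr)) loc <- tr$label[1]
    }
    if (is.na(loc)) {
      loc <- if (mid >= g$cds_start[best] && mid < g$cds_end[best]) "intron"
      else if ((mid < g$cds_start[best]) == (g$strand[best] == "+")) "upstream"
      else "downstream"
    }
    location[i] <- loc
  }
  crms$gene_id <- gene_id
  crms$location <- location
  crms$dist_tss <- dist_tss
  crms$tie <- tie
  crms
}

#' Gene-set overlap of module target genes
#'
#' Hypergeometric upper-tail p-value of the overlap between each module's
#' target genes and each gene set, with BH adjustment across all
#' module-set tests.
#'
#' @param module_targets Named list: target gene ids per module.
#' @param gene_sets Named list of gene-id vectors (e.g. from
#'   [read_gene_sets()]).
#' @param universe Character vector of all gene ids in the annotation.
#' @return Data.frame with `module_id`, `gene_set_id`, `N`, `M`, `n`, `m`,
#'   `p`, `q`.
#' @export
gene_set_overlap <- function(module_targets, gene_sets, universe) {
  N <- length(unique(universe))
  rows <- list()
  for (mod in names(module_targets)) {
    tg <- intersect(unique(module_targets[[mod]]), universe)
    for (gs in names(gene_sets)) {
      set <- intersect(unique(gene_sets[[gs]]), universe)
      m <- length(intersect(tg, set))
      rows[[length(rows) + 1]] <- data.frame(
        module_id = mod, gene_set_id = gs, N = N, M = length(set),
        n = length(tg), m = m,
        p = hypergeom_overlap(N, length(set), length(tg), m))
    }
  }
  if (!length(rows))
    return(data.frame(module_id = character(0), gene_set_id = character(0),
                      N = integer(0), M = integer(0), n = integer(0),
                      m = integer(0), p = numeric(0), q = numeric(0)))
  out <- do.call(rbind, rows)
  out$q <- adjust_fdr(out$p)
  out
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then gene ids, tab
#'   separated).
#' @return Named list of gene-id vectors.
#' @export
read_gene_sets <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path, warn = FALSE), "\t")
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[[`, "", 1))
}

#' Composite-element pair enrichment
#'
#' Tests whether the unordered motif pairs occurring in predicted modules
#' are enriched for experimentally verified composite-element (CE) pairs,
#' against the universe of all pairs formable from the motif library.
#'
#' @param predicted_pairs Character vector of predicted pairs, each
#'   `"idA;idB"` with the two ids sorted (see [module_motif_pairs()]).
#' @param ce_pairs Character vector of CE pairs in the same encoding.
#' @param motif_count Number of motifs in the library.
#' @return List with `N` (possible pairs), `M`, `n`, `m` and `p`.
#' @export
ce_pair_enrichment <- function(predicted_pairs, ce_pairs, motif_count) {
  N <- motif_count * (motif_count - 1) / 2
  predicted_pairs <- unique(predicted_pairs)
  ce_pairs <- unique(ce_pairs)
  m <- length(intersect(predicted_pairs, ce_pairs))
  list(N = N, M = length(ce_pairs), n = length(predicted_pairs), m = m,
       p = hypergeom_overlap(N, length(ce_pairs), length(predicted_pairs), m))
}

#' All unordered motif pairs occurring in emitted modules
#'
#' @param modules Output of [call_modules()].
#' @return Character vector of `"idA;idB"` keys (ids sorted within a pair).
#' @export
module_motif_pairs <- function(modules) {
  pairs <- unlist(lapply(modules$items, function(it) {
    if (length(it) < 2) return(character(0))
    apply(combn(sort(it), 2), 2, paste, collapse = ";")
  }))
  sort(unique(pairs))
}

# 5'-most site of each motif of the pair in each CRM; ties by highest
# score. Returns per-CRM coordinates or drops uninformative CRMs.
.pair_sites <- function(tfbs, pair) {
  hits <- tfbs[tfbs$motif_id %in% pair, , drop = FALSE]
  out <- list()
  for (b in unique(hits$block_id)) {
    hb <- hits[hits$block_id == b, , drop = FALSE]
    picks <- lapply(pair, function(mo) {
      hm <- hb[hb$motif_id == mo, , drop = FALSE]
      if (!nrow(hm)) return(NULL)
      hm[order(hm$start, -hm$score), , drop = FALSE][1, ]
    })
    if (any(vapply(picks, is.null, TRUE))) next
    out[[length(out) + 1]] <- data.frame(
      block_id = b,
      a_start = picks[[1]]$start, a_end = picks[[1]]$end,
      a_strand = picks[[1]]$strand,
      b_start = picks[[2]]$start, b_end = picks[[2]]$end,
      b_strand = picks[[2]]$strand)
  }
  if (!length(out))
    return(data.frame(block_id = character(0), a_start = integer(0),
                      a_end = integer(0), a_strand = character(0),
                      b_start = integer(0), b_end = integer(0),
                      b_strand = character(0)))
  do.call(rbind, out)
}

#' Order preference of a motif pair
#'
#' Among the CRMs containing sites of both motifs (5'-most site per motif,
#' ties by score; CRMs where both start at the same position are
#' uninformative), `m` counts those where the first motif's site is 5' of
#' the second's; the p-value is the fair-coin binomial tail.
#'
#' @param tfbs TFBS candidates of the module's CRMs.
#' @param pair Character vector of two motif ids `(A, B)`.
#' @return List with `n`, `m`, `fraction` (dominant-order fraction `m/n`)
#'   and `p`; `NULL` when no CRM is informative.
#' @export
order_preference <- function(tfbs, pair) {
  st <- .pair_sites(tfbs, pair)
  st <- st[st$a_start != st$b_start, , drop = FALSE]
  n <- nrow(st)
  if (!n) return(NULL)
  m <- sum(st$a_start < st$b_start)
  list(pair = paste(pair, collapse = ";"), n = n, m = m, fraction = m / n,
       p = binom_pref_pvalue(n, m))
}

#' Strand preference of a motif pair
#'
#' `m` counts the informative CRMs whose two sites fall on the same strand;
#' same fair-coin binomial tail as [order_preference()].
#'
#' @inheritParams order_preference
#' @return List with `n`, `m`, `p`; `NULL` when uninformative.
#' @export
strand_preference <- function(tfbs, pair) {
  st <- .pair_sites(tfbs, pair)
  n <- nrow(st)
  if (!n) return(NULL)
  m <- sum(st$a_strand == st$b_strand)
  list(pair = paste(pair, collapse = ";"), n = n, m = m,
       p = binom_pref_pvalue(n, m))
}

#' Distance preference of a motif pair
#'
#' Edge-to-edge gaps between the two chosen sites per CRM (0 when the sites
#' overlap) are binned at `bin_width` bp from 0 to the largest observed
#' distance. The Poisson rate is the mean count per bin over that span;
#' each bin's upper-tail p-value is corrected (Bonferroni over bins by
#' default) and the preferred range is the maximal run of adjacent
#' significant bins.
#'
#' @inheritParams order_preference
#' @param bin_width Bin width in bp (default 50).
#' @param alpha Significance level after correction (default 0.05).
#' @param correction `"bonferroni"` or `"BH"`.
#' @return List with `distances`, `counts`, `rate`, `p` (per bin),
#'   `significant` (logical per bin), `preferred_range` (bp, or `NULL`),
#'   `degenerate` (TRUE when fewer than 2 occupied bins).
#' @export
distance_preference <- function(tfbs, pair, bin_width = 50L, alpha = 0.05,
                                correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  st <- .pair_sites(tfbs, pair)
  if (!nrow(st)) return(NULL)
  gap <- pmax(0, pmax(st$a_start, st$b_start) - pmin(st$a_end, st$b_end))
  distance_preference_from_distances(gap, bin_width, alpha, correction)
}

#' Distance preference from raw distances
#'
#' Workhorse behind [distance_preference()], also used for CRM-to-TSS
#' distances of a module.
#'
#' @param distances Non-negative distances in bp.
#' @param bin_width,alpha,correction As in [distance_preference()].
#' @return See [distance_preference()].
#' @export
distance_preference_from_distances <- function(distances, bin_width = 50L,
                                               alpha = 0.05,
                                               correction = "bonferroni") {
  bin <- distances %/% bin_width
  n_bins <- max(bin) + 1L
  counts <- tabulate(bin + 1L, nbins = n_bins)
  rate <- mean(counts)
  p <- ppois(counts - 1, rate, lower.tail = FALSE)
  padj <- if (correction == "bonferroni") pmin(1, p * n_bins)
          else adjust_fdr(p)
  sig <- padj < alpha
  pref <- NULL
  if (any(sig)) {
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    pref <- c((starts[best] - 1L) * bin_width, ends[best] * bin_width)
  }
  list(distances = distances, counts = counts, rate = rate, p = p,
       p_adjusted = padj, significant = sig, preferred_range = pref,
       degenerate = sum(counts > 0) < 2)
}

#' Location preference of a module's CRMs
#'
#' For each label (upstream / downstream / intron), the module's CRM count
#' with that label is tested against the background label proportion pooled
#' over all CRMs (binomial upper tail, Bonferroni over the three labels).
#'
#' @param labels Character vector: location labels of the module's CRMs.
#' @param background Character vector: labels of all CRMs (the pool).
#' @param alpha Significance level (default 0.05).
#' @return Data.frame with one row per label: `label`, `count`, `n`,
#'   `background_prop`, `p`, `p_corrected`, `prefers`.
#' @export
location_preference <- function(labels, background, alpha = 0.05) {
  labs <- c("upstream", "downstream", "intron")
  n <- length(labels)
  bg <- vapply(labs, function(l) mean(background == l), numeric(1))
  cnt <- vapply(labs, function(l) sum(labels == l), numeric(1))
  p <- vapply(seq_along(labs), function(i) {
    if (cnt[i] == 0) return(1)
    pbinom(cnt[i] - 1, n, bg[i], lower.tail = FALSE)
  }, numeric(1))
  p_corr <- pmin(1, p * length(labs))
  data.frame(label = labs, count = cnt, n = n, background_prop = bg,
             p = p, p_corrected = p_corr, prefers = p_corr < alpha,
             row.names = NULL)
}
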