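## Frequent motif-combination mining and module significance.
##
## Each conserved block is a transaction whose items are the motifs with at
## least one TFBS candidate in the block (presence/absence). An FP-tree
## enumerates every motif combination of size >= 2 supported by at least
## `min_support` blocks; the expected number of blocks carrying all motifs
## of a combination under independence is lambda = B * prod(b_i / B), and
## the combination's p-value is the upper Poisson tail at its observed
## support. Combinations significant after Bonferroni correction over the
## evaluated (frequent) combinations are the motif modules; their
## supporting blocks are the CRMs.

#' Build block transactions from TFBS candidates
#'
#' One transaction per block (blocks without any hit keep an empty itemset
#' and still count in the block universe B); items are the distinct motif
#' ids hit in the block.
#'
#' @param block_ids Character vector of all block ids (the universe).
#' @param tfbs TFBS candidate data.frame from [scan_blocks()].
#' @return An object of class `crm_transactions`: a named list of character
#'   vectors.
#' @export
build_transactions <- function(block_ids, tfbs) {
  block_ids <- as.character(block_ids)
  items <- split(as.character(tfbs$motif_id), as.character(tfbs$block_id))
  out <- lapply(setNames(block_ids, block_ids), function(b) {
    sort(unique(items[[b]]))
  })
  out[vapply(out, is.null, TRUE)] <- list(character(0))
  structure(out, class = "crm_transactions")
}

# ---- FP-tree -------------------------------------------------------------

# Build an FP-tree from integer-coded transactions (items already ordered
# by decreasing global frequency; each transaction sorted by that order).
# Nodes are parallel vectors; children are looked up via a hashed
# "parent.item" key; the header table links every node of an item.
.fp_build <- function(itemlists, weights, n_items) {
  env <- new.env(parent = emptyenv())
  env$item <- integer(1); env$count <- numeric(1); env$parent <- integer(1)
  env$item[1] <- 0L; env$count[1] <- 0; env$parent[1] <- 0L   # root = 1
  env$n <- 1L
  children <- new.env(parent = emptyenv())
  header <- vector("list", n_items)
  for (t in seq_along(itemlists)) {
    tr <- itemlists[[t]]; w <- weights[t]
    node <- 1L
    for (it in tr) {
      key <- paste0(node, ".", it)
      child <- children[[key]]
      if (is.null(child)) {
        env$n <- env$n + 1L
        child <- env$n
        env$item[child] <- it
        env$count[child] <- 0
        env$parent[child] <- node
        children[[key]] <- child
        header[[it]] <- c(header[[it]], child)
      }
      env$count[child] <- env$count[child] + w
      node <- child
    }
  }
  list(env = env, header = header)
}

# Recursive FP-growth over conditional pattern bases.
.fp_mine <- function(itemlists, weights, counts, min_support, max_size,
                     suffix, emit) {
  keep <- which(counts >= min_support)
  if (!length(keep)) return(invisible())
  # order surviving items by decreasing count (ties: smaller original rank)
  ord <- keep[order(-counts[keep], keep)]
  rank <- integer(length(counts)); rank[ord] <- seq_along(ord)
  proj <- lapply(itemlists, function(tr) {
    tr <- tr[counts[tr] >= min_support]
    tr[order(rank[tr])]
  })
  tree <- .fp_build(proj, weights, length(counts))
  env <- tree$env; header <- tree$header
  # least frequent first
  for (it in rev(ord)) {
    nodes <- header[[it]]
    sup <- sum(env$count[nodes])
    if (sup < min_support) next
    newset <- c(it, suffix)
    emit(newset, sup)
    if (length(newset) >= max_size) next
    # conditional pattern base: prefix path of every node carrying `it`
    base <- vector("list", length(nodes))
    bw <- numeric(length(nodes))
    ccounts <- numeric(length(counts))
    for (k in seq_along(nodes)) {
      p <- env$parent[nodes[k]]
      path <- integer(0)
      while (p != 1L) { path <- c(env$item[p], path); p <- env$parent[p] }
      base[[k]] <- path
      bw[k] <- env$count[nodes[k]]
      if (length(path)) ccounts[path] <- ccounts[path] + bw[k]
    }
    if (any(ccounts >= min_support))
      .fp_mine(base, bw, ccounts, min_support, max_size, newset, emit)
  }
  invisible()
}

#' Mine frequent motif combinations with an FP-tree
#'
#' Enumerates all itemsets of size >= 2 contained in at least `min_support`
#' transactions, via FP-tree construction and conditional pattern-base
#' recursion. Output is deterministic: sorted by itemset size, then
#' lexicographically on the semicolon-joined sorted motif ids.
#'
#' @param transactions A `crm_transactions` object (or plain list of
#'   character vectors).
#' @param min_support Minimum number of supporting blocks (default 100).
#' @param max_size Largest itemset size to enumerate (default unlimited).
#' @param max_itemsets Abort when more than this many itemsets are emitted,
#'   with instructions to raise `min_support`.
#' @return Data.frame with `key` (semicolon-joined sorted motif ids),
#'   `size`, `support`, and a list-column `items`.
#' @export
mine_frequent <- function(transactions, min_support = 100L, max_size = Inf,
                          max_itemsets = 1e6) {
  if (min_support < 1) stop("min_support must be at least 1")
  items_all <- sort(unique(unlist(transactions, use.names = FALSE)))
  res_items <- list(); res_sup <- numeric(0)
  if (length(items_all)) {
    code <- setNames(seq_along(items_all), items_all)
    ilists <- lapply(transactions, function(tr) unname(code[tr]))
    counts <- numeric(length(items_all))
    tab <- table(unlist(ilists, use.names = FALSE))
    counts[as.integer(names(tab))] <- as.numeric(tab)
    nout <- 0L
    emit <- function(set, sup) {
      if (length(set) < 2) return(invisible())
      nout <<- nout + 1L
      if (nout > max_itemsets)
        stop("more than ", max_itemsets, " frequent itemsets; ",
             "raise min_support (or max_itemsets)")
      res_items[[nout]] <<- sort(items_all[set])
      res_sup[nout] <<- sup
    }
    .fp_mine(ilists, rep(1, length(ilists)), counts, min_support, max_size,
             integer(0), emit)
  }
  keys <- vapply(res_items, paste, "", collapse = ";")
  sizes <- lengths(res_items)
  ord <- order(sizes, keys)
  out <- data.frame(key = keys[ord], size = sizes[ord],
                    support = res_sup[ord], stringsAsFactors = FALSE)
  out$items <- res_items[ord]
  out
}

#' Poisson clump p-value of a motif combination
#'
#' Under the independence null the number of blocks containing all motifs
#' of the combination is approximated as Poisson with rate
#' `lambda = B * prod(b_i / B)`, where `b_i` is the number of blocks
#' containing motif i; the p-value is the upper tail at the observed
#' support `k`. Blocks are disjoint by construction, so clumping of
#' overlapping windows is already absorbed upstream.
#'
#' @param k Observed support (blocks containing all motifs).
#' @param b Integer vector: per-motif block counts.
#' @param B Total number of blocks.
#' @return p-value in (0, 1].
#' @export
clump_pvalue <- function(k, b, B) {
  if (B < 1 || any(b < 0) || any(b > B)) stop("invalid block counts")
  if (k == 0) return(1)
  lambda <- B * prod(b / B)
  max(ppois(k - 1, lambda, lower.tail = FALSE), .Machine$double.xmin)
}

#' Call significant motif modules
#'
#' Computes the clump p-value of every frequent combination, applies a
#' Bonferroni correction over the evaluated combinations, and emits those
#' with corrected p below `alpha` as motif modules, with their supporting
#' blocks as CRMs.
#'
#' @param frequent Output of [mine_frequent()].
#' @param transactions The `crm_transactions` the itemsets were mined from.
#' @param alpha Significance level on the corrected p-value (default 0.05).
#' @return Data.frame with `module_id`, `key`, `size`, `support`, `p_raw`,
#'   `p_corrected`, list-columns `items` and `crm_block_ids`.
#' @export
call_modules <- function(frequent, transactions, alpha = 0.05) {
  B <- length(transactions)
  empty <- data.frame(module_id = integer(0), key = character(0),
                      size = integer(0), support = numeric(0),
                      p_raw = numeric(0), p_corrected = numeric(0))
  empty$items <- list(); empty$crm_block_ids <- list()
  if (!nrow(frequent)) return(empty)
  item_counts <- table(unlist(lapply(transactions, unique),
                              use.names = FALSE))
  n_tests <- nrow(frequent)
  p_raw <- vapply(seq_len(n_tests), function(i) {
    b <- as.numeric(item_counts[frequent$items[[i]]])
    clump_pvalue(frequent$support[i], b, B)
  }, numeric(1))
  p_corr <- pmin(1, p_raw * n_tests)
  sel <- which(p_corr < alpha)
  if (!length(sel)) return(empty)
  crms <- lapply(sel, function(i) {
    it <- frequent$items[[i]]
    names(transactions)[vapply(transactions,
                               function(tr) all(it %in% tr), TRUE)]
  })
  out <- data.frame(module_id = seq_along(sel), key = frequent$key[sel],
                    size = frequent$size[sel],
                    support = frequent$support[sel],
                    p_raw = p_raw[sel], p_corrected = p_corr[sel],
                    stringsAsFactors = FALSE)
  out$items <- frequent$items[sel]
  out$crm_block_ids <- crms
  out
}

#' Export motif modules as TSV
#' @param modules Output of [call_modules()].
#' @param path Output file.
#' @export
write_modules <- function(modules, path) {
  df <- modules[, c("module_id", "key", "support", "p_raw", "p_corrected")]
  names(df)[2] <- "motif_ids"
  df$p_raw <- format(df$p_raw, digits = 4, scientific = TRUE)
  df$p_corrected <- format(df$p_corrected, digits = 4, scientific = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
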