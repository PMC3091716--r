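# Shared fixtures, all built in code.

random_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  if (is.null(seed)) return(gen())
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  gen()
}

mutate_dna <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  i <- which(runif(length(v)) < rate)
  v[i] <- vapply(v[i], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(v, collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# brute-force 6-mer seed oracle
brute_seeds <- function(h, o, k = 6) {
  hs <- substring(h, 1:(nchar(h) - k + 1), k:nchar(h))
  os <- substring(o, 1:(nchar(o) - k + 1), k:nchar(o))
  out <- NULL
  for (i in seq_along(hs)) {
    j <- which(os == hs[i])
    if (length(j)) out <- rbind(out, cbind(i - 1L, j - 1L))
  }
  out
}

# a deterministic small TRANSFAC-style motif: strong consensus
toy_motif <- function(id = "M900", consensus = "ACGTACGT", dom = 94) {
  w <- nchar(consensus)
  counts <- matrix(2, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  for (j in seq_len(w)) counts[idx[j], j] <- dom
  crmminer:::.new_motif(id, id, counts)
}

# exhaustive hypergeometric upper tail by enumerating all draws (tiny N)
enum_hyper_upper <- function(N, M, n, m) {
  draws <- combn(N, n)
  hits <- colSums(draws <= M)   # first M elements are "in the set"
  mean(hits >= m)
}

# brute-force Apriori oracle for frequent itemsets of size >= 2
# (enumeration capped at the largest transaction; a size with no frequent
# set ends the search by anti-monotonicity)
apriori_oracle <- function(transactions, min_support) {
  items <- sort(unique(unlist(transactions)))
  kmax <- max(c(2, lengths(transactions)))
  out <- list()
  for (k in 2:min(kmax, length(items))) {
    any_freq <- FALSE
    for (s in combn(items, k, simplify = FALSE)) {
      sup <- sum(vapply(transactions, function(tr) all(s %in% tr), TRUE))
      if (sup >= min_support) {
        out[[paste(s, collapse = ";")]] <- sup
        any_freq <- TRUE
      }
    }
    if (!any_freq) break
  }
  out
}

# brute-force best 1-kb ortholog window similarity
brute_similarity <- function(segs, r_start, r_end, window = 1000) {
  inside <- segs[segs$h_start >= r_start & segs$h_end <= r_end &
                   (segs$o_end - segs$o_start) <= window, , drop = FALSE]
  if (!nrow(inside)) return(0)
  cand <- sort(unique(c(inside$o_start, inside$o_end - window)))
  best <- 0
  for (w in cand) {
    s <- sum(inside$score[inside$o_start >= w & inside$o_end <= w + window])
    best <- max(best, s)
  }
  best
}
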