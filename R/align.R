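## Seed-and-extend local alignment of orthologous non-coding sequences.
## Short exact words shared by the two sequences are extended into gapped
## local alignments with an x-drop rule; the retained alignments are the
## "conserved segments" that all downstream conservation scoring uses.

#' Alignment parameters
#'
#' Scoring and retention parameters for the seed-and-extend aligner. Scores
#' are in match/mismatch units: a gap run of length L costs
#' `gap_open + L * gap_ext`. The defaults (match +1, mismatch -1, gap open
#' -3, gap extend -0.5, x-drop 10, minimum retained score 12, i.e. at least
#' two chained clean words) give short exact words extended into conserved
#' segments while leaving unrelated sequence essentially unaligned.
#'
#' @param word_len Seed word length in bp (exact match; minimum 4).
#' @param degeneracy Allowed mismatches inside a seed word. Only 0
#'   (exact seeds) is supported.
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap opening cost (> 0, subtracted).
#' @param gap_ext Per-column gap extension cost (> 0, subtracted).
#' @param xdrop Extension stops when the running score drops this far below
#'   the running maximum.
#' @param min_score Minimum score for a segment pair to be retained.
#' @return A list of class `crm_align_params`.
#' @export
align_params <- function(word_len = 6L, degeneracy = 0L, match = 1,
                         mismatch = -1, gap_open = 3, gap_ext = 0.5,
                         xdrop = 10, min_score = 12) {
  if (word_len < 4) stop("word_len must be at least 4")
  if (degeneracy != 0) stop("only degeneracy = 0 (exact seeds) is supported")
  if (match <= 0 || mismatch >= 0) stop("need match > 0 and mismatch < 0")
  structure(list(word_len = as.integer(word_len), degeneracy = 0L,
                 match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, xdrop = xdrop, min_score = min_score),
            class = "crm_align_params")
}

.as_seq <- function(x) {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet"))
    x <- as.character(x)
  if (!is.character(x) || length(x) != 1)
    stop("expected a single DNA sequence")
  toupper(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Find exact seed words shared by two sequences
#'
#' Lists every position pair at which the two sequences share an identical
#' `word_len`-mer, on both strands of the ortholog. Words containing N never
#' seed. Ortholog positions are reported on its forward strand.
#'
#' @param seq_h,seq_o Human and ortholog DNA sequences (character or
#'   `DNAString`).
#' @param word_len Seed word length (bp); minimum 4.
#' @param degeneracy Must be 0 (exact match).
#' @return A data.frame with columns `h_pos`, `o_pos` (0-based starts) and
#'   `strand`.
#' @export
find_seeds <- function(seq_h, seq_o, word_len = 6L, degeneracy = 0L) {
  if (word_len < 4) stop("word_len must be at least 4")
  if (degeneracy != 0) stop("only degeneracy = 0 (exact seeds) is supported")
  h <- .as_seq(seq_h); o <- .as_seq(seq_o)
  fwd <- cpp_find_seeds(h, o, as.integer(word_len))
  fwd$strand <- rep("+", nrow(fwd))
  rc <- cpp_find_seeds(h, .revcomp(o), as.integer(word_len))
  if (nrow(rc)) {
    rc$o_pos <- nchar(o) - rc$o_pos - as.integer(word_len)
    rc$strand <- "-"
  } else rc$strand <- character(0)
  out <- rbind(fwd, rc)
  out[order(out$h_pos, out$o_pos, out$strand), , drop = FALSE]
}

.segment_df <- function(lst, strand, o_len) {
  df <- as.data.frame(lst)
  if (strand == "-") {
    os <- o_len - df$o_end
    oe <- o_len - df$o_start
    df$o_start <- os
    df$o_end <- oe
  }
  df$strand <- strand
  ncols <- df$n_match + df$n_mismatch + df$n_gap_ext
  df$identity <- ifelse(ncols > 0, df$n_match / ncols, 0)
  df[, c("h_start", "h_end", "o_start", "o_end", "strand", "score",
         "identity", "n_match", "n_mismatch", "n_gap_open", "n_gap_ext")]
}

#' Extend a single seed into a conserved segment pair
#'
#' Gapped extension of one seed in both directions until the score drops
#' `xdrop` below the running maximum. Returns `NULL` when the best extension
#' scores below the retention threshold.
#'
#' @param seq_h,seq_o Sequences as in [find_seeds()].
#' @param h_pos,o_pos 0-based seed start positions; `o_pos` is on the
#'   forward strand of the ortholog.
#' @param strand `"+"` or `"-"`: strand of the ortholog the seed matched on.
#' @param params An [align_params()] object.
#' @return A one-row segment data.frame, or `NULL`.
#' @export
extend_seed <- function(seq_h, seq_o, h_pos, o_pos, strand = "+",
                        params = align_params()) {
  h <- .as_seq(seq_h); o <- .as_seq(seq_o)
  o_len <- nchar(o)
  oo <- if (strand == "-") .revcomp(o) else o
  op <- if (strand == "-") o_len - o_pos - params$word_len else o_pos
  res <- cpp_extend_seed(h, oo, as.integer(h_pos), as.integer(op),
                         params$word_len, params$match, params$mismatch,
                         params$gap_open, params$gap_ext, params$xdrop,
                         params$min_score)
  if (!length(res)) return(NULL)
  .segment_df(res, strand, o_len)
}

#' Align two non-coding sequences into conserved segment pairs
#'
#' Finds all exact seed words on both strands, extends each into a gapped
#' local alignment, deduplicates seeds falling inside already-retained
#' segments, and resolves overlaps on the human sequence greedily by score
#' (ties: smaller human start, then forward strand). The result is a set of
#' mutually non-overlapping (on the human sequence) conserved segment pairs.
#'
#' @inheritParams find_seeds
#' @param params An [align_params()] object.
#' @return A data.frame of segments with 0-based half-open coordinates
#'   `h_start`, `h_end`, `o_start`, `o_end` (forward strand of each input),
#'   `strand`, `score`, `identity` and the alignment column counts
#'   `n_match`, `n_mismatch`, `n_gap_open`, `n_gap_ext`.
#' @export
align_regions <- function(seq_h, seq_o, params = align_params()) {
  h <- .as_seq(seq_h); o <- .as_seq(seq_o)
  m <- cpp_align_pair(h, o, params$word_len, params$match, params$mismatch,
                      params$gap_open, params$gap_ext, params$xdrop,
                      params$min_score)
  ncols <- m[, 7] + m[, 8] + m[, 10]
  data.frame(h_start = as.integer(m[, 1]), h_end = as.integer(m[, 2]),
             o_start = as.integer(m[, 3]), o_end = as.integer(m[, 4]),
             strand = c("+", "-")[m[, 5] + 1], score = m[, 6],
             identity = ifelse(ncols > 0, m[, 7] / ncols, 0),
             n_match = as.integer(m[, 7]), n_mismatch = as.integer(m[, 8]),
             n_gap_open = as.integer(m[, 9]),
             n_gap_ext = as.integer(m[, 10]),
             stringsAsFactors = FALSE)
}

#' Resolve overlapping segments on the human sequence
#'
#' Greedy selection by decreasing score (ties: smaller `h_start`, `"+"`
#' strand first); a segment overlapping an already kept one on the human
#' coordinates is dropped.
#'
#' @param segs A segment data.frame as returned by [align_regions()].
#' @return The non-overlapping subset, sorted by `h_start`.
#' @export
resolve_overlaps <- function(segs) {
  if (!nrow(segs)) return(segs)
  ord <- order(-segs$score, segs$h_start, segs$strand)
  segs <- segs[ord, , drop = FALSE]
  kept_s <- integer(0); kept_e <- integer(0); keep <- logical(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    if (!any(segs$h_start[i] < kept_e & segs$h_end[i] > kept_s)) {
      keep[i] <- TRUE
      kept_s <- c(kept_s, segs$h_start[i])
      kept_e <- c(kept_e, segs$h_end[i])
    }
  }
  out <- segs[keep, , drop = FALSE]
  out <- out[order(out$h_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-score a segment from its stored alignment column counts
#'
#' Self-consistency check: the reported score of a segment equals
#' `match * n_match + mismatch * n_mismatch - gap_open * n_gap_open -
#' gap_ext * n_gap_ext`.
#'
#' @param segs Segment data.frame.
#' @param params The [align_params()] used to produce it.
#' @return Numeric vector of recomputed scores.
#' @export
rescore_segments <- function(segs, params = align_params()) {
  params$match * segs$n_match + params$mismatch * segs$n_mismatch -
    params$gap_open * segs$n_gap_open - params$gap_ext * segs$n_gap_ext
}

#' Export segments as TSV
#'
#' @param segs Segment data.frame (optionally with `chrom` and `species`
#'   columns added by the caller).
#' @param path Output file.
#' @export
write_segments <- function(segs, path) {
  write.table(segs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segments from TSV (e.g. from an external aligner run)
#'
#' @param path TSV written by [write_segments()] or an external tool using
#'   the same columns.
#' @return Segment data.frame.
#' @export
read_segments <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
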