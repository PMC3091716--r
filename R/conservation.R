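## Discontiguous sequence similarity and conserved-block selection.
##
## The similarity S(R, R') of a 1 kb human window R and an ortholog window
## R' is the sum of scores of the conserved segments whose two sides lie
## entirely inside R and R'; divergent spacer between segments contributes
## nothing, so a region conserved in scattered pieces scores the same as one
## conserved in a single run of the same total length. The conservation of R
## is the mean of the best S over all ortholog windows, across the available
## rodent species. Windows above the pooled 95% cutoff are merged and
## trimmed into blocks, the CRM candidates.

#' Best discontiguous similarity of a human window against all ortholog
#' windows
#'
#' Maximises, over every possible 1 kb ortholog window start, the sum of
#' scores of segments whose human side lies inside `[r_start, r_end)` and
#' whose ortholog side lies inside the ortholog window. The sweep is over
#' segment endpoints; no re-alignment is done.
#'
#' @param segments Segment data.frame for one species (columns `h_start`,
#'   `h_end`, `o_start`, `o_end`, `score`; optionally `o_region` when the
#'   ortholog territory has several regions whose coordinates are
#'   independent).
#' @param r_start,r_end Human window, 0-based half-open.
#' @param window Ortholog window length in bp (default 1000).
#' @return A list with `score` (0 when no segment fits) and `o_window`
#'   (`c(start, end)` of a best ortholog window, or `NULL`).
#' @export
discontiguous_similarity <- function(segments, r_start, r_end, window = 1000L) {
  inside <- segments$h_start >= r_start & segments$h_end <= r_end
  segs <- segments[inside, , drop = FALSE]
  # ortholog side must fit in a single window
  segs <- segs[segs$o_end - segs$o_start <= window, , drop = FALSE]
  if (!nrow(segs)) return(list(score = 0, o_window = NULL))
  oreg <- if ("o_region" %in% names(segs)) segs$o_region else rep(1L, nrow(segs))
  best <- 0; best_w <- NULL
  for (rg in unique(oreg)) {
    ss <- segs[oreg == rg, , drop = FALSE]
    # a window start w admits a segment iff o_end - window <= w <= o_start
    lo <- ss$o_end - window
    hi <- ss$o_start
    ev_pos <- c(lo, hi + 1L)
    ev_val <- c(ss$score, -ss$score)
    ord <- order(ev_pos, ev_val)   # removes before adds at equal position
    run <- cumsum(ev_val[ord])
    i <- which.max(run)
    if (run[i] > best) {
      best <- run[i]
      best_w <- c(ev_pos[ord][i], ev_pos[ord][i] + window)
    }
  }
  if (is.null(best_w)) list(score = 0, o_window = NULL)
  else list(score = best, o_window = best_w)
}

#' Conservation score of a human window
#'
#' The mean of the best discontiguous similarity scores over the species
#' with an ortholog in the group; with a single rodent ortholog the
#' conservation equals that species' similarity. A species whose ortholog
#' aligned nothing contributes 0 and is still averaged.
#'
#' @param segments_by_species Named list of segment data.frames, one per
#'   rodent species present in the ortholog group (possibly empty
#'   data.frames).
#' @param r_start,r_end Human window.
#' @param window Ortholog window length (bp).
#' @return Numeric conservation score (>= 0).
#' @export
conservation_score <- function(segments_by_species, r_start, r_end,
                               window = 1000L) {
  if (!length(segments_by_species)) stop("at least one rodent ortholog needed")
  s <- vapply(segments_by_species, function(segs) {
    discontiguous_similarity(segs, r_start, r_end, window)$score
  }, numeric(1))
  mean(s)
}

#' Score candidate windows anchored at conserved segment starts
#'
#' Every candidate window starts at the human start of a conserved segment
#' (of any species) and runs 1 kb, truncated (and flagged) at the end of the
#' territory region containing it.
#'
#' @param segments_by_species Named list of segment data.frames with human
#'   coordinates in the territory's genomic frame; each needs a `region`
#'   column when the territory has several regions.
#' @param regions Data.frame of the human territory regions (`start`,
#'   `end`, and `region` id); windows never cross a region boundary.
#' @param window Window length (bp).
#' @return Data.frame of windows: `region`, `start`, `end`, `truncated`,
#'   per-species scores `S_<species>` and conservation `C`.
#' @export
conservation_windows <- function(segments_by_species, regions,
                                 window = 1000L) {
  species <- names(segments_by_species)
  out <- list()
  for (k in seq_len(nrow(regions))) {
    rs <- regions$start[k]; re <- regions$end[k]
    rg <- if ("region" %in% names(regions)) regions$region[k] else k
    in_reg <- lapply(segments_by_species, function(segs) {
      if ("region" %in% names(segs)) segs <- segs[segs$region == rg, , drop = FALSE]
      segs[segs$h_start >= rs & segs$h_end <= re, , drop = FALSE]
    })
    anchors <- sort(unique(unlist(lapply(in_reg, function(s) s$h_start))))
    if (!length(anchors)) next
    ws <- anchors
    we <- pmin(ws + window, re)
    smat <- vapply(in_reg, function(segs) {
      if (!nrow(segs)) return(numeric(length(ws)))
      # the ortholog side may span several regions with independent
      # coordinates: take the best single-region window
      oreg <- if ("o_region" %in% names(segs)) segs$o_region
              else rep(1L, nrow(segs))
      best <- numeric(length(ws))
      for (rg in unique(oreg)) {
        sel <- oreg == rg
        s <- cpp_window_scores(as.integer(ws), as.integer(we),
                               as.integer(segs$h_start[sel]),
                               as.integer(segs$h_end[sel]),
                               as.integer(segs$o_start[sel]),
                               as.integer(segs$o_end[sel]),
                               as.numeric(segs$score[sel]),
                               as.integer(window))
        best <- pmax(best, s)
      }
      best
    }, numeric(length(ws)))
    smat <- matrix(smat, nrow = length(ws),
                   dimnames = list(NULL, paste0("S_", species)))
    df <- data.frame(region = rg, start = ws, end = we,
                     truncated = (we - ws) < window)
    df <- cbind(df, as.data.frame(smat))
    df$C <- rowMeans(smat)
    out[[length(out) + 1]] <- df
  }
  if (!length(out)) {
    df <- data.frame(region = integer(0), start = integer(0),
                     end = integer(0), truncated = logical(0))
    for (sp in species) df[[paste0("S_", sp)]] <- numeric(0)
    df$C <- numeric(0)
    return(df)
  }
  do.call(rbind, out)
}

#' Genome-wide conservation score cutoff
#'
#' The smallest score `c` such that at most `1 - quantile` of the windows
#' have a conservation score strictly larger than `c` (empirical, no
#' interpolation). Windows are pooled across all ortholog groups before
#' calling this.
#'
#' @param C Numeric vector of window conservation scores (>= 20 values).
#' @param quantile Retention quantile (default 0.95: at most 5% of windows
#'   exceed the cutoff).
#' @return The cutoff score.
#' @export
compute_cutoff <- function(C, quantile = 0.95) {
  if (length(C) < 20) stop("need at least 20 scored windows to set a cutoff")
  vals <- sort(unique(C))
  frac_gt <- vapply(vals, function(v) mean(C > v), numeric(1))
  vals[which(frac_gt <= (1 - quantile) + 1e-12)[1]]
}

#' Merge passing windows into conserved blocks
#'
#' Windows with conservation strictly above the cutoff are merged by
#' interval union (within a region); each merged interval is then trimmed on
#' its 3' end back to the last base covered by a conserved segment, so every
#' block ends inside a segment. Blocks are disjoint and sorted.
#'
#' @param windows Window data.frame from [conservation_windows()].
#' @param segments Segment data.frame pooled over species (human
#'   coordinates; `region` column honoured if present).
#' @param cutoff Conservation cutoff from [compute_cutoff()].
#' @return Data.frame of blocks: `region`, `start`, `end`, `C_max`,
#'   `n_windows`, plus a list-column `conserved` holding a 2-column matrix
#'   of the merged conserved sub-intervals inside each block.
#' @export
find_blocks <- function(windows, segments, cutoff) {
  pass <- windows[windows$C > cutoff, , drop = FALSE]
  empty <- data.frame(region = integer(0), start = integer(0),
                      end = integer(0), C_max = numeric(0),
                      n_windows = integer(0))
  empty$conserved <- list()
  if (!nrow(pass)) return(empty)
  out <- list()
  for (rg in unique(pass$region)) {
    pw <- pass[pass$region == rg, , drop = FALSE]
    segs <- segments
    if ("region" %in% names(segs)) segs <- segs[segs$region == rg, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(pw$start + 1L, pw$end))
    ms <- IRanges::start(ir) - 1L
    me <- IRanges::end(ir)
    for (i in seq_along(ms)) {
      ov <- segs$h_start < me[i] & segs$h_end > ms[i]
      if (!any(ov)) next   # cannot happen for anchored windows; be safe
      new_end <- max(pmin(segs$h_end[ov], me[i]))
      cons <- IRanges::reduce(IRanges::IRanges(
        pmax(segs$h_start[ov], ms[i]) + 1L,
        pmin(segs$h_end[ov], new_end)))
      wins_in <- pw$start >= ms[i] & pw$start < me[i]
      row <- data.frame(region = rg, start = ms[i], end = new_end,
                        C_max = max(pw$C[wins_in]),
                        n_windows = sum(wins_in))
      row$conserved <- list(cbind(start = IRanges::start(cons) - 1L,
                                  end = IRanges::end(cons)))
      out[[length(out) + 1]] <- row
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$region, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
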