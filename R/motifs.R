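## Motif matrices, cutoff calibration and TFBS scanning.
##
## Matrices are stored as 4 x width count matrices (rows A,C,G,T). Scores
## are natural-log odds against a uniform background with a pseudocount of
## 0.01 of the column total. The score cutoff of a motif is calibrated so
## that hits occur on random non-coding background with a per-position
## probability below 1e-4, pooling both strands.

.BASES <- c("A", "C", "G", "T")

#' Log-odds matrix from a count matrix
#'
#' @param counts 4 x width count matrix, rows A,C,G,T.
#' @param pseudocount Fraction of each column total added as pseudocount,
#'   spread according to the background (default 0.01).
#' @param background Base composition (default uniform).
#' @return 4 x width matrix of natural-log odds.
#' @export
motif_log_odds <- function(counts, pseudocount = 0.01,
                           background = rep(0.25, 4)) {
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("motif has an all-zero column")
  pc <- pseudocount * tot
  freq <- (counts + outer(background, pc)) / rep(tot + pc, each = 4)
  log(freq / background)
}

.new_motif <- function(id, name, counts, pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("motif ", id, ": count matrix must have 4 rows")
  if (ncol(counts) < 5) stop("motif ", id, ": width must be at least 5")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("motif ", id, ": malformed counts")
  if (any(colSums(counts) <= 0))
    stop("motif ", id, ": all-zero column in count matrix")
  rownames(counts) <- .BASES
  lo <- motif_log_odds(counts, pseudocount)
  structure(list(id = id, name = name, counts = counts,
                 width = ncol(counts), log_odds = lo, cutoff = NA_real_,
                 log_base = "e", pseudocount = pseudocount),
            class = "crm_motif")
}

#' @export
print.crm_motif <- function(x, ...) {
  cat(sprintf("<motif %s (%s), width %d, cutoff %s>\n", x$id, x$name,
              x$width, ifelse(is.na(x$cutoff), "uncalibrated",
                              format(x$cutoff, digits = 4))))
  invisible(x)
}

#' Consensus sequence of a motif (most frequent base per column)
#' @param motif A `crm_motif`.
#' @return Character consensus string.
#' @export
motif_consensus <- function(motif) {
  paste(.BASES[apply(motif$counts, 2, which.max)], collapse = "")
}

#' Read a motif library
#'
#' Supports the TRANSFAC flat-file dialect (blocks with `AC`/`ID`/`NA`
#' fields, a `P0` header line and numbered count rows, terminated by `//`)
#' and the MEME minimal format (probability matrices scaled to counts by
#' `nsites`, default 20).
#'
#' @param path Motif file.
#' @param format `"transfac"`, `"meme"`, or `"auto"` (sniff the header).
#' @param pseudocount Passed to [motif_log_odds()].
#' @return A list of `crm_motif` objects (class `crm_motif_library`),
#'   named by motif id.
#' @export
read_motifs <- function(path, format = c("auto", "transfac", "meme"),
                        pseudocount = 0.01) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^MEME version", lines))) "meme" else "transfac"
  }
  motifs <- if (format == "transfac") .parse_transfac(lines, pseudocount)
            else .parse_meme(lines, pseudocount)
  if (!length(motifs)) stop("no motifs found in ", path)
  names(motifs) <- vapply(motifs, `[[`, "", "id")
  structure(motifs, class = "crm_motif_library")
}

.parse_transfac <- function(lines, pseudocount) {
  motifs <- list()
  id <- NULL; nm <- ""; rows <- list(); order <- .BASES
  flush <- function() {
    if (is.null(id)) return(invisible())
    if (!length(rows)) stop("motif ", id, ": no count rows")
    w <- unique(vapply(rows, length, 0L))
    if (length(w) != 1) stop("motif ", id, ": ragged count matrix")
    counts <- do.call(cbind, rows)      # 4 x width after transpose below
    counts <- matrix(unlist(rows), nrow = 4,
                     dimnames = list(order, NULL))
    motifs[[length(motifs) + 1]] <<- .new_motif(id, nm, counts, pseudocount)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || ln == "XX") next
    tag <- sub("^([A-Z0-9]+).*$", "\\1", ln)
    if (tag == "AC") {
      id <- trimws(sub("^AC", "", ln)); nm <- id; rows <- list()
    } else if (tag == "ID") {
      if (nm == id) nm <- trimws(sub("^ID", "", ln))
    } else if (tag == "NA") {
      nm <- trimws(sub("^NA", "", ln))
    } else if (tag == "P0" || tag == "PO") {
      flds <- strsplit(ln, "[[:space:]]+")[[1]][-1]
      if (!all(.BASES %in% toupper(flds[1:4])))
        stop("line ", i, ": P0 header must name A C G T")
      order <- toupper(flds[1:4])
    } else if (grepl("^[0-9]+[[:space:]]", ln)) {
      flds <- strsplit(ln, "[[:space:]]+")[[1]]
      v <- suppressWarnings(as.numeric(flds[2:5]))
      if (any(is.na(v)))
        stop("line ", i, ": malformed count row for motif ", id)
      names(v) <- order
      rows[[length(rows) + 1]] <- v[.BASES]
    } else if (ln == "//") {
      flush(); id <- NULL; rows <- list(); order <- .BASES
    }
  }
  flush()
  motifs
}

.parse_meme <- function(lines, pseudocount) {
  motifs <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^MOTIF", ln)) {
      flds <- strsplit(ln, "[[:space:]]+")[[1]]
      id <- flds[2]
      nm <- if (length(flds) >= 3) flds[3] else id
      # find the letter-probability header
      j <- i + 1
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", trimws(lines[j]))) j <- j + 1
      if (j > length(lines)) stop("motif ", id, ": no probability matrix")
      hdr <- trimws(lines[j])
      w <- as.integer(sub(".*w=[[:space:]]*([0-9]+).*", "\\1", hdr))
      nsites <- if (grepl("nsites=", hdr))
        as.numeric(sub(".*nsites=[[:space:]]*([0-9.]+).*", "\\1", hdr)) else 20
      rows <- matrix(NA_real_, nrow = 4, ncol = w)
      for (k in seq_len(w)) {
        v <- suppressWarnings(as.numeric(
          strsplit(trimws(lines[j + k]), "[[:space:]]+")[[1]]))
        if (length(v) != 4 || any(is.na(v)))
          stop("motif ", id, ": ragged probability matrix at row ", k)
        rows[, k] <- v
      }
      motifs[[length(motifs) + 1]] <-
        .new_motif(id, nm, rows * nsites, pseudocount)
      i <- j + w + 1
    } else i <- i + 1
  }
  motifs
}

#' Write a motif library in TRANSFAC flat-file format
#' @param motifs A `crm_motif_library`.
#' @param path Output file.
#' @export
write_motifs_transfac <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(c(sprintf("AC  %s", m$id), "XX", sprintf("NA  %s", m$name),
                 "XX", "P0      A      C      G      T"), con)
    for (j in seq_len(m$width)) {
      writeLines(sprintf("%02d  %5g  %5g  %5g  %5g", j, m$counts[1, j],
                         m$counts[2, j], m$counts[3, j], m$counts[4, j]), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Score one site against a motif
#'
#' Sum of per-position log-odds; on the minus strand the reverse complement
#' of the site is scored. A site containing N is unscorable (-Inf).
#'
#' @param motif A `crm_motif`.
#' @param seq DNA string of length equal to the motif width.
#' @param strand `"+"` or `"-"`.
#' @return Numeric score.
#' @export
score_site <- function(motif, seq, strand = "+") {
  s <- .as_seq(seq)
  if (nchar(s) != motif$width)
    stop("site length must equal the motif width (", motif$width, ")")
  if (strand == "-") s <- .revcomp(s)
  cpp_pwm_scan(s, motif$log_odds)[1]
}

#' Score every window of a sequence on one strand
#'
#' @param motif A `crm_motif`.
#' @param seq DNA sequence.
#' @param strand Strand to score; minus-strand scores are reported at the
#'   forward-strand start coordinate of the window.
#' @return Numeric vector of length `nchar(seq) - width + 1`.
#' @export
scan_sequence <- function(motif, seq, strand = "+") {
  s <- .as_seq(seq)
  if (strand == "+") return(cpp_pwm_scan(s, motif$log_odds))
  rev(cpp_pwm_scan(.revcomp(s), motif$log_odds))
}

#' Calibrate a motif score cutoff on background sequence
#'
#' Pools the scores of every motif-width window on both strands of the
#' background sequences and returns the empirical `1 - p` quantile (no
#' interpolation), so that a random position scores strictly above the
#' cutoff with probability below `p`.
#'
#' @param motif A `crm_motif`.
#' @param background Character vector or `DNAStringSet` of background
#'   sequences (e.g. random 1 kb non-coding regions).
#' @param p Target per-position hit probability (default 1e-4).
#' @return The cutoff score (`-Inf` when `p = 1`, so everything is a hit).
#' @export
calibrate_cutoff <- function(motif, background, p = 1e-4) {
  if (inherits(background, "DNAStringSet")) background <- as.character(background)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(background)))
  scores <- c(cpp_pwm_scan_pool(background, motif$log_odds),
              cpp_pwm_scan_pool(rc, motif$log_odds))
  if (!length(scores)) stop("background contains no scorable window")
  idx <- ceiling((1 - p) * length(scores))
  if (idx < 1) return(-Inf)
  sort(scores, partial = idx)[idx]
}

#' Calibrate all motifs of a library
#'
#' @param motifs A `crm_motif_library`.
#' @param background As in [calibrate_cutoff()].
#' @param p Per-position hit probability.
#' @return The library with `$cutoff` set on every motif; the calibration
#'   table (motif_id, width, cutoff) is attached as attribute
#'   `"calibration"`.
#' @export
calibrate_cutoffs <- function(motifs, background, p = 1e-4) {
  if (inherits(background, "DNAStringSet")) background <- as.character(background)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(background)))
  for (i in seq_along(motifs)) {
    scores <- c(cpp_pwm_scan_pool(background, motifs[[i]]$log_odds),
                cpp_pwm_scan_pool(rc, motifs[[i]]$log_odds))
    idx <- ceiling((1 - p) * length(scores))
    motifs[[i]]$cutoff <- if (idx < 1) -Inf else sort(scores, partial = idx)[idx]
  }
  attr(motifs, "calibration") <- data.frame(
    motif_id = vapply(motifs, `[[`, "", "id"),
    width = vapply(motifs, `[[`, 0L, "width"),
    cutoff = vapply(motifs, `[[`, 0, "cutoff"),
    row.names = NULL)
  motifs
}

#' Scan the conserved segments of blocks for TFBS candidates
#'
#' Every motif-width window lying entirely inside a conserved sub-interval
#' of a block is scored on both strands; windows scoring strictly above the
#' motif's calibrated cutoff are reported. Overlapping hits of the same
#' motif are all kept.
#'
#' @param blocks Block data.frame from [find_blocks()], with `block_id` and
#'   `chrom` columns added by the pipeline (or `region` used as chrom).
#' @param motifs A calibrated `crm_motif_library`.
#' @param genome Named `DNAStringSet` (or named character vector) holding
#'   the sequences the block coordinates refer to.
#' @return Data.frame of TFBS candidates: `block_id`, `motif_id`, `chrom`,
#'   `start`, `end`, `strand`, `score`.
#' @export
scan_blocks <- function(blocks, motifs, genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  cutoffs <- vapply(motifs, `[[`, 0, "cutoff")
  if (any(is.na(cutoffs)))
    stop("motif cutoffs must be calibrated before scanning")
  lo_list <- lapply(motifs, `[[`, "log_odds")
  widths <- vapply(motifs, `[[`, 0L, "width")
  ids <- vapply(motifs, `[[`, "", "id")
  out <- list()
  for (b in seq_len(nrow(blocks))) {
    bid <- if ("block_id" %in% names(blocks)) blocks$block_id[b] else b
    chrom <- if ("chrom" %in% names(blocks)) blocks$chrom[b]
             else as.character(blocks$region[b])
    cons <- blocks$conserved[[b]]
    if (is.null(cons) || !nrow(cons)) next
    for (k in seq_len(nrow(cons))) {
      cs <- cons[k, "start"]; ce <- cons[k, "end"]
      seg <- substr(genome[[chrom]], cs + 1L, ce)
      hits <- cpp_scan_hits(seg, lo_list, cutoffs)
      if (!nrow(hits)) next
      mi <- hits[, 1]
      out[[length(out) + 1]] <- data.frame(
        block_id = bid, motif_id = ids[mi], chrom = chrom,
        start = cs + as.integer(hits[, 2]),
        end = cs + as.integer(hits[, 2]) + widths[mi],
        strand = c("+", "-")[hits[, 3] + 1], score = hits[, 4],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(block_id = character(0), motif_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$block_id, res$chrom, res$start, res$motif_id,
                   res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
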