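# RSY-rich segment scanning.
#
# Arginine/serine-rich (often tyrosine-containing) cargo segments act as
# TrnSR-recognized signals. Candidate segments are found by sliding
# windows of 15-30 residues and three composition criteria:
#   RSY_comp      = (#R + #S + #Y) / length            > 0.3
#   dipepRSY_comp = #{RS, SR, SY, YS} / (length - 1)   > 0.2
#   dipepSY_comp  = #{SY, YS} / (length - 1)           > 0
# Dipeptides are counted at every overlapping adjacent pair. All
# inequalities are strict; coordinates are 1-based inclusive.

RSY_DIPEP <- c("RS", "SR", "SY", "YS")
SY_DIPEP <- c("SY", "YS")

#' Composition of one sliding window
#'
#' @param seq protein sequence (single string, case-insensitive; `X`
#'   counts as non-RSY).
#' @param start 1-based start position.
#' @param length window length, 15-30.
#' @return one-row data.frame: `start`, `end`, `length`, `rsy_comp`,
#'   `dipep_rsy_comp`, `dipep_sy_comp`, `qualifies`.
#' @export
window_compositions <- function(seq, start, length) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (length < 15L || length > 30L) stop("window length must be in 15..30")
  if (start < 1L || start + length - 1L > n) stop("window out of bounds")
  chars <- strsplit(substr(seq, start, start + length - 1L), "", fixed = TRUE)[[1L]]
  rsy <- sum(chars %in% c("R", "S", "Y")) / length
  dip <- paste0(chars[-length], chars[-1L])
  dip_rsy <- sum(dip %in% RSY_DIPEP) / (length - 1L)
  dip_sy <- sum(dip %in% SY_DIPEP) / (length - 1L)
  data.frame(start = start, end = start + length - 1L, length = length,
             rsy_comp = rsy, dipep_rsy_comp = dip_rsy, dipep_sy_comp = dip_sy,
             qualifies = rsy > 0.3 && dip_rsy > 0.2 && dip_sy > 0)
}

#' Scan a protein sequence for RSY-rich windows
#'
#' Evaluates every start position and every window length 15..30 that fits
#' and returns the qualifying windows.
#'
#' @param seq protein sequence (single string).
#' @return data.frame of qualifying windows (columns as
#'   [window_compositions()]), zero rows when none qualify. Sequences
#'   shorter than 15 residues return zero rows with a warning.
#' @export
scan_rsy <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      rsy_comp = numeric(), dipep_rsy_comp = numeric(),
                      dipep_sy_comp = numeric(), qualifies = logical())
  if (n < 15L) {
    warning("sequence shorter than 15 residues; nothing to scan")
    return(empty)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  is_rsy <- chars %in% c("R", "S", "Y")
  dip <- paste0(chars[-n], chars[-1L])
  in_rsy_dip <- dip %in% RSY_DIPEP
  in_sy_dip <- dip %in% SY_DIPEP
  crsy <- c(0L, cumsum(is_rsy))
  cdr <- c(0L, cumsum(in_rsy_dip))
  cds <- c(0L, cumsum(in_sy_dip))
  out <- vector("list", 16L)
  for (L in 15L:min(30L, n)) {
    starts <- seq_len(n - L + 1L)
    ends <- starts + L - 1L
    rsy <- (crsy[ends + 1L] - crsy[starts]) / L
    dr <- (cdr[ends] - cdr[starts]) / (L - 1L)
    ds <- (cds[ends] - cds[starts]) / (L - 1L)
    q <- rsy > 0.3 & dr > 0.2 & ds > 0
    if (any(q))
      out[[L - 14L]] <- data.frame(start = starts[q], end = ends[q],
                                   length = L, rsy_comp = rsy[q],
                                   dipep_rsy_comp = dr[q],
                                   dipep_sy_comp = ds[q], qualifies = TRUE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res)) return(empty)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge qualifying windows into maximal RSY-rich segments
#'
#' Union of overlapping or adjacent qualifying windows from one sequence;
#' segments are maximal, non-overlapping and sorted.
#'
#' @param windows data.frame with `start` and `end` columns (e.g. from
#'   [scan_rsy()]).
#' @return data.frame: `start`, `end`, `n_windows` (supporting window
#'   count), `max_rsy_comp` (when input has `rsy_comp`).
#' @export
merge_rsy_windows <- function(windows) {
  if (nrow(windows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      n_windows = integer(), max_rsy_comp = numeric()))
  w <- windows[order(windows$start, windows$end), , drop = FALSE]
  has_comp <- "rsy_comp" %in% names(w)
  segs <- list()
  cur <- c(w$start[1L], w$end[1L]); cnt <- 1L
  mx <- if (has_comp) w$rsy_comp[1L] else NA_real_
  flush <- function() {
    segs[[length(segs) + 1L]] <<- data.frame(start = cur[1L], end = cur[2L],
                                             n_windows = cnt,
                                             max_rsy_comp = mx)
  }
  for (i in seq_len(nrow(w))[-1L]) {
    if (w$start[i] <= cur[2L] + 1L) {
      cur[2L] <- max(cur[2L], w$end[i]); cnt <- cnt + 1L
      if (has_comp) mx <- max(mx, w$rsy_comp[i])
    } else {
      flush()
      cur <- c(w$start[i], w$end[i]); cnt <- 1L
      mx <- if (has_comp) w$rsy_comp[i] else NA_real_
    }
  }
  flush()
  do.call(rbind, segs)
}

#' Scan a FASTA file of protein sequences for RSY-rich segments
#'
#' @param fasta path to a protein FASTA file.
#' @param out optional TSV output path (qualifying windows, one row per
#'   window, with a `seq_id` column).
#' @param bed optional BED-like output path for merged segments (0-based
#'   half-open coordinates).
#' @return list with `windows` and `segments` data.frames (both with
#'   `seq_id`).
#' @export
scan_rsy_fasta <- function(fasta, out = NULL, bed = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  win_list <- seg_list <- list()
  for (id in names(seqs)) {
    w <- scan_rsy(as.character(seqs[[id]]))
    segs <- merge_rsy_windows(w)
    if (nrow(w)) win_list[[id]] <- cbind(seq_id = id, w)
    if (nrow(segs)) seg_list[[id]] <- cbind(seq_id = id, segs)
  }
  windows <- if (length(win_list)) do.call(rbind, win_list) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               length = integer(), rsy_comp = numeric(),
               dipep_rsy_comp = numeric(), dipep_sy_comp = numeric(),
               qualifies = logical())
  segments <- if (length(seg_list)) do.call(rbind, seg_list) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               n_windows = integer(), max_rsy_comp = numeric())
  rownames(windows) <- rownames(segments) <- NULL
  if (!is.null(out))
    utils::write.table(windows, out, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed)) {
    bedtab <- data.frame(chrom = segments$seq_id,
                         chromStart = segments$start - 1L,
                         chromEnd = segments$end,
                         name = sprintf("RSY_segment_%d", seq_len(nrow(segments))))
    utils::write.table(bedtab, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  list(windows = windows, segments = segments)
}
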