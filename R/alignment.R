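#' Grouped ortholog alignment
#'
#' Container for a multiple sequence alignment whose sequences are
#' partitioned into two paralog ortholog groups ("A" and "B"), e.g. the
#' metazoan orthologs of two closely related NTR paralogs. Columns of this
#' alignment are the unit scored by [score_all_sites()].
#'
#' @param sequences named character vector of aligned sequences (equal
#'   lengths; gap character `-`), or an `AAStringSet`.
#' @param groups named character vector (or factor) mapping every sequence id
#'   to `"A"` or `"B"`.
#' @param reference_ids optional named character vector of length <= 2 giving
#'   one sequence id per group (`c(A = "id1", B = "id2")`) used for residue
#'   numbering in reports.
#'
#' @return an object of class `grouped_alignment` with elements `seqs`
#'   (character matrix, sequences x columns, uppercase), `group` (factor
#'   `A`/`B` per sequence), `n_columns`, `reference_ids`.
#' @export
grouped_alignment <- function(sequences, groups, reference_ids = NULL) {
  if (methods::is(sequences, "AAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named")
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequences have differing lengths (",
         paste(range(widths), collapse = "-"), ")")
  ids <- names(sequences)
  missing_ids <- setdiff(ids, names(groups))
  if (length(missing_ids))
    stop("sequence id(s) missing from group table: ",
         paste(missing_ids, collapse = ", "))
  grp <- factor(as.character(groups[ids]), levels = c("A", "B"))
  if (anyNA(grp)) stop("group labels must be 'A' or 'B'")
  if (any(tabulate(grp, 2L) == 0L)) stop("empty ortholog group")
  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  rownames(mat) <- ids
  mat[mat %in% GAP_CHARS] <- "-"
  bad <- matrix(!(mat %in% c(AA20, AA_AMBIGUOUS, "-")), nrow(mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown residue symbol '%s' (sequence %s, column %d)",
                 mat[bad][1L], ids[idx[1L]], idx[2L]))
  }
  if (!is.null(reference_ids)) {
    unknown <- setdiff(reference_ids, ids)
    if (length(unknown))
      stop("unknown reference id(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(seqs = mat, group = stats::setNames(grp, ids),
                 n_columns = ncol(mat), reference_ids = reference_ids),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  n <- tabulate(x$group, 2L)
  cat(sprintf("grouped_alignment: %d sequences (A: %d, B: %d), %d columns\n",
              nrow(x$seqs), n[1L], n[2L], x$n_columns))
  invisible(x)
}

#' Read a grouped alignment from FASTA plus a group table
#'
#' @param fasta path to an aligned FASTA file (gap `-`).
#' @param groups path to a headerless two-column TSV (sequence id, group
#'   label `A`/`B`), or a named vector as for [grouped_alignment()].
#' @param reference_ids passed to [grouped_alignment()].
#' @return a `grouped_alignment`.
#' @export
read_grouped_alignment <- function(fasta, groups, reference_ids = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    tab <- read.delim(groups, header = FALSE, stringsAsFactors = FALSE)
    groups <- stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
  }
  grouped_alignment(seqs, groups, reference_ids)
}

#' Write a grouped alignment to FASTA and a group TSV
#'
#' @param aln a `grouped_alignment`.
#' @param fasta,groups output paths (`groups = NULL` skips the table).
#' @return invisibly, `fasta`.
#' @export
write_grouped_alignment <- function(aln, fasta, groups = NULL) {
  seqs <- apply(aln$seqs, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta)
  if (!is.null(groups))
    utils::write.table(data.frame(id = names(aln$group),
                                  group = as.character(aln$group)),
                       groups, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(fasta)
}

#' Map an alignment column to a reference-sequence residue number
#'
#' Returns the 1-based residue number of the reference sequence at an
#' alignment column (the count of non-gap reference characters up to and
#' including the column), so sites can be reported in the familiar
#' "E398"-style numbering. `NA` where the reference carries a gap.
#'
#' @param aln a `grouped_alignment`.
#' @param reference_id a sequence id present in the alignment.
#' @param column column index (1-based); may be a vector.
#' @return integer vector of residue numbers (`NA` at reference gaps).
#' @export
map_column_to_residue <- function(aln, reference_id, column = seq_len(aln$n_columns)) {
  if (!reference_id %in% rownames(aln$seqs))
    stop("unknown reference id: ", reference_id)
  if (any(column < 1L | column > aln$n_columns))
    stop("column index out of range")
  chars <- aln$seqs[reference_id, ]
  nongap <- chars != "-"
  num <- cumsum(nongap)
  num[!nongap] <- NA_integer_
  as.integer(num[column])
}
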