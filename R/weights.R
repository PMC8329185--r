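# Gerstein-Sonnhammer-Chothia (GSC) sequence weights.
#
# Redundant sequences (e.g. near-identical orthologs from sister species)
# would otherwise dominate a column's amino-acid profile. GSC propagates
# branch lengths of a guide tree from the root to the leaves: each branch's
# length is divided among the leaves below it in proportion to the weight
# each leaf has already accumulated (equally while all are zero), so
# duplicated sequences share, rather than multiply, their influence.

#' Pairwise p-distances between aligned sequences
#'
#' Fraction of mismatching positions over columns where both sequences are
#' non-gap and unambiguous. Pairs with no comparable columns get distance 1.
#'
#' @param seq_mat character matrix (sequences x alignment columns).
#' @return symmetric numeric distance matrix.
#' @keywords internal
seq_pdistance <- function(seq_mat) {
  n <- nrow(seq_mat)
  ok <- matrix(seq_mat %in% AA20, n, ncol(seq_mat))
  D <- matrix(0, n, n, dimnames = list(rownames(seq_mat), rownames(seq_mat)))
  if (n == 1L) return(D)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- ok[i, ] & ok[j, ]
    ns <- sum(shared)
    d <- if (ns == 0L) 1 else sum(seq_mat[i, shared] != seq_mat[j, shared]) / ns
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Gerstein-Sonnhammer-Chothia sequence weights for one ortholog group
#'
#' Builds a UPGMA guide tree from pairwise p-distances within the group and
#' propagates branch lengths down the tree by the GSC rule (each branch's
#' length divided among the leaves below it, in proportion to their
#' accumulated weights; equally when all are still zero). Weights are
#' normalized to sum to 1 within the group. A group of identical sequences
#' (zero total tree length) gets equal weights.
#'
#' @param aln a [grouped_alignment()].
#' @param group `"A"` or `"B"`.
#' @return named numeric vector of weights (non-negative, sums to 1).
#' @export
compute_gsc_weights <- function(aln, group = c("A", "B")) {
  group <- match.arg(group)
  ids <- names(aln$group)[aln$group == group]
  if (length(ids) == 0L) stop("empty ortholog group")
  if (length(ids) == 1L) return(stats::setNames(1, ids))
  D <- seq_pdistance(aln$seqs[ids, , drop = FALSE])
  hc <- hclust(stats::as.dist(D), method = "average")
  gsc_from_hclust(hc)
}

# GSC propagation on an hclust (UPGMA) object. Node height in the
# ultrametric tree is hc$height/2; leaves sit at height 0.
#' @keywords internal
gsc_from_hclust <- function(hc) {
  n <- length(hc$labels)
  w <- numeric(n)
  node_h <- hc$height / 2
  # leaves below each internal node
  below <- vector("list", nrow(hc$merge))
  child_h <- function(k) if (k < 0) 0 else node_h[k]
  leaves <- function(k) if (k < 0) -k else below[[k]]
  for (m in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[m, ]
    below[[m]] <- c(leaves(kids[1L]), leaves(kids[2L]))
    for (k in kids) {
      lv <- leaves(k)
      br <- node_h[m] - child_h(k)      # branch length parent -> child
      if (br <= 0) next
      cur <- w[lv]
      share <- if (sum(cur) > 0) cur / sum(cur) else rep(1 / length(lv), length(lv))
      w[lv] <- cur + br * share
    }
  }
  if (sum(w) == 0) w <- rep(1, n)       # all-identical group
  stats::setNames(w / sum(w), hc$labels)
}

#' Weighted residue counts at one alignment column
#'
#' Sums sequence weights by residue identity at a column, within one group.
#' Gap weight is accumulated separately; ambiguous residues (X, B, Z, U)
#' contribute neither. With an X-free column, counts + gap weight sum to the
#' total group weight (1 for normalized weights).
#'
#' @param aln a [grouped_alignment()].
#' @param weights named weight vector as from [compute_gsc_weights()].
#' @param column column index (1-based).
#' @return list with `counts` (named 20-vector, [AA20] order), `gap_weight`,
#'   and `n_residues` (unweighted count of sequences with a real residue).
#' @export
weighted_counts <- function(aln, weights, column) {
  if (length(column) != 1L || column < 1L || column > aln$n_columns)
    stop("column must be a single index in 1..n_columns")
  ids <- names(weights)
  res <- aln$seqs[ids, column]
  bad <- !(res %in% c(AA20, AA_AMBIGUOUS, "-"))
  if (any(bad))
    stop(sprintf("unknown residue symbol '%s' at column %d (sequence %s)",
                 res[bad][1L], column, ids[bad][1L]))
  counts <- stats::setNames(numeric(20L), AA20)
  keep <- res %in% AA20
  if (any(keep)) {
    s <- tapply(weights[keep], factor(res[keep], levels = AA20), sum)
    s[is.na(s)] <- 0
    counts[] <- s
  }
  list(counts = counts,
       gap_weight = sum(weights[res == "-"]),
       n_residues = sum(keep))
}
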