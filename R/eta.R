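# Evolutionary trace analysis (ETA) of two paralog ortholog groups.
#
# A column that is conserved *within* each ortholog group but *differs
# between* the groups is a candidate determinant of the paralogs' functional
# differentiation (here: differential cargo recognition by two NTR
# paralogs). Each column is scored by the symmetric Kullback-Leibler
# divergence between the two groups' estimated amino-acid distributions.

#' Symmetric Kullback-Leibler divergence between two amino-acid profiles
#'
#' `sum_i p_i log(p_i/q_i) + sum_i q_i log(q_i/p_i)` in the chosen log base.
#' Non-negative, zero iff `p == q`. Strict positivity of both arguments is
#' required (guaranteed upstream by Dirichlet smoothing).
#'
#' @param p,q strictly positive probability vectors of equal length, each
#'   summing to 1 (tolerance 1e-6).
#' @param log_base base of the logarithm (default natural log).
#' @return non-negative scalar divergence.
#' @export
symmetric_kl <- function(p, q, log_base = exp(1)) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p <= 0) || any(q <= 0))
    stop("probabilities must be strictly positive")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("p and q must each sum to 1")
  sum((p - q) * (log(p) - log(q))) / log(log_base)
}

#' Score every alignment column for between-group differentiation
#'
#' For each column: GSC-weighted residue counts per group, counts rescaled
#' to pseudo-observation units (the number of non-gap sequences in the group
#' at that column), Dirichlet-mixture smoothing into strictly positive
#' probability pairs `(p, q)`, and the symmetric KL divergence between them.
#' Columns where the pooled weighted gap fraction exceeds 0.5 (more than
#' half of the sequences gapped, under equal weights) are skipped
#' (`retained = FALSE`, no KL). Retained columns are ranked descending by KL.
#'
#' @param aln a [grouped_alignment()].
#' @param prior a [dirichlet_mixture()]; default [default_aa_prior()].
#' @param log_base log base for the KL value (default natural log).
#' @param gap_threshold pooled weighted gap fraction above which a column is
#'   skipped (default 0.5).
#' @return object of class `site_scores`: a list with `table` (data.frame:
#'   `column`, `consensus_A`, `consensus_B`, `gap_fraction`,
#'   `gap_fraction_A`, `gap_fraction_B`, `retained`, `kl`, `rank`,
#'   `percentile`, and `residue_A`/`residue_B` numbering when reference ids
#'   are set), `p` and `q` (columns x 20 probability matrices, NA rows for
#'   skipped columns), `weights` (per-group GSC weights), `log_base`.
#' @export
score_all_sites <- function(aln, prior = default_aa_prior(),
                            log_base = exp(1), gap_threshold = 0.5) {
  stopifnot(inherits(aln, "grouped_alignment"))
  wA <- compute_gsc_weights(aln, "A")
  wB <- compute_gsc_weights(aln, "B")
  nA <- length(wA); nB <- length(wB)
  nc <- aln$n_columns
  P <- Q <- matrix(NA_real_, nc, 20L, dimnames = list(NULL, AA20))
  kl <- rep(NA_real_, nc)
  gapA <- gapB <- numeric(nc)
  consA <- consB <- rep(NA_character_, nc)
  retained <- logical(nc)
  for (j in seq_len(nc)) {
    cA <- weighted_counts(aln, wA, j)
    cB <- weighted_counts(aln, wB, j)
    gapA[j] <- cA$gap_weight
    gapB[j] <- cB$gap_weight
    gap_pooled <- (nA * cA$gap_weight + nB * cB$gap_weight) / (nA + nB)
    if (gap_pooled > gap_threshold) next
    retained[j] <- TRUE
    p <- estimate_site_probabilities(rescale_counts(cA), prior)
    q <- estimate_site_probabilities(rescale_counts(cB), prior)
    P[j, ] <- p
    Q[j, ] <- q
    consA[j] <- AA20[which.max(p)]
    consB[j] <- AA20[which.max(q)]
    kl[j] <- symmetric_kl(p, q, log_base)
  }
  if (!any(retained))
    warning("no retained columns (all exceed the gap threshold)")
  rk <- rep(NA_integer_, nc)
  pct <- rep(NA_real_, nc)
  if (any(retained)) {
    ord <- order(-kl[retained], seq_len(sum(retained)))
    rk[retained][ord] <- seq_len(sum(retained))
    pct[retained] <- 100 * (1 - (rk[retained] - 1) / sum(retained))
  }
  tab <- data.frame(column = seq_len(nc), consensus_A = consA,
                    consensus_B = consB,
                    gap_fraction = (nA * gapA + nB * gapB) / (nA + nB),
                    gap_fraction_A = gapA, gap_fraction_B = gapB,
                    retained = retained, kl = kl, rank = rk,
                    percentile = pct, stringsAsFactors = FALSE)
  if (!is.null(aln$reference_ids)) {
    refs <- aln$reference_ids
    if (!is.null(refs["A"]) && !is.na(refs["A"]))
      tab$residue_A <- map_column_to_residue(aln, refs[["A"]])
    if (!is.null(refs["B"]) && !is.na(refs["B"]))
      tab$residue_B <- map_column_to_residue(aln, refs[["B"]])
  }
  structure(list(table = tab, p = P, q = Q,
                 weights = list(A = wA, B = wB), log_base = log_base),
            class = "site_scores")
}

# Rescale normalized weighted counts so they sum to the number of non-gap
# sequences at the column (restores the data-volume information the
# weight normalization removed; the Dirichlet evidence depends on it).
rescale_counts <- function(wc) {
  s <- sum(wc$counts)
  if (s == 0 || wc$n_residues == 0) return(wc$counts * 0)
  wc$counts / s * wc$n_residues
}

#' @export
print.site_scores <- function(x, ...) {
  tab <- x$table
  cat(sprintf("site_scores: %d columns (%d retained); top KL = %s\n",
              nrow(tab), sum(tab$retained),
              if (any(tab$retained)) signif(max(tab$kl, na.rm = TRUE), 5) else "NA"))
  invisible(x)
}

#' Select the top-scoring fraction of retained sites
#'
#' Returns the `ceiling(fraction * n_retained)` highest-KL sites; KL ties at
#' the boundary are all included (the result may exceed the ceiling count),
#' so equally scoring candidates are never silently dropped.
#'
#' @param scores a `site_scores` object from [score_all_sites()].
#' @param fraction fraction in (0, 1] (default 0.10, the top-10% criterion).
#' @return the retained rows of `scores$table` that make the cut, with a
#'   logical `top_fraction` column, ordered by rank; also reports the KL
#'   cutoff as attribute `"kl_cutoff"` (lowest KL inside the selection).
#' @export
top_sites <- function(scores, fraction = 0.10) {
  stopifnot(inherits(scores, "site_scores"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  ret <- scores$table[scores$table$retained, , drop = FALSE]
  if (nrow(ret) == 0L) stop("no retained sites")
  ret <- ret[order(ret$rank), , drop = FALSE]
  k <- ceiling(fraction * nrow(ret))
  cutoff <- ret$kl[k]
  sel <- ret[ret$kl >= cutoff, , drop = FALSE]
  sel$top_fraction <- TRUE
  attr(sel, "kl_cutoff") <- cutoff
  sel
}

#' Write per-site ETA scores to TSV
#'
#' @param scores a `site_scores` object.
#' @param path output path.
#' @param probabilities also write the 20 `p_*` and 20 `q_*` probability
#'   columns (default FALSE).
#' @param top_fraction fraction used to flag top sites (default 0.10).
#' @return invisibly, the written data.frame.
#' @export
write_site_scores <- function(scores, path, probabilities = FALSE,
                              top_fraction = 0.10) {
  tab <- scores$table
  tab$top_fraction <- FALSE
  if (any(tab$retained)) {
    sel <- top_sites(scores, top_fraction)
    tab$top_fraction[tab$column %in% sel$column] <- TRUE
  }
  if (probabilities) {
    p <- scores$p; colnames(p) <- paste0("p_", AA20)
    q <- scores$q; colnames(q) <- paste0("q_", AA20)
    tab <- cbind(tab, p, q)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
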