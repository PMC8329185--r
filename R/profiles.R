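# Clustering of cargoes by discretized mutant-binding profiles.
#
# Each cargo's row of WT-normalized, three-level-discretized binding ranks
# (one entry per NTR mutant, values 0 / 0.5 / 1) is a binding profile;
# cargoes are clustered with Euclidean distance and Ward's minimum-variance
# method and the dendrogram is cut into a chosen number of groups.

#' Validate a discretized binding-profile matrix
#'
#' @param x numeric matrix (cargoes x mutants) with entries in
#'   `{0, 0.5, 1}`; `NA` marks missing measurements. Row and column names
#'   are the cargo and mutant ids.
#' @return the validated matrix, classed `profile_matrix`.
#' @export
profile_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("cargo", seq_len(nrow(x)))
  vals <- x[!is.na(x)]
  if (!all(vals %in% c(0, 0.5, 1)))
    stop("profile entries must be 0, 0.5 or 1")
  empty <- rowSums(!is.na(x)) == 0
  if (any(empty))
    stop("row(s) with no measurements: ",
         paste(rownames(x)[empty], collapse = ", "))
  structure(x, class = c("profile_matrix", class(x)))
}

#' Pairwise Euclidean distances between binding profiles
#'
#' Plain Euclidean distance over the mutant columns. Pairs with missing
#' entries are compared over their shared non-missing columns (with a
#' warning); a pair with no shared columns is an error naming the pair.
#'
#' @param x a [profile_matrix()] (or any numeric matrix).
#' @return a `dist` object.
#' @export
profile_distances <- function(x) {
  x <- unclass(as.matrix(x))
  n <- nrow(x)
  if (anyNA(x)) {
    warning("missing entries: distances computed over shared non-missing columns")
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      shared <- !is.na(x[i, ]) & !is.na(x[j, ])
      if (!any(shared))
        stop("no shared measurements between ", rownames(x)[i], " and ",
             rownames(x)[j])
      D[i, j] <- D[j, i] <- sqrt(sum((x[i, shared] - x[j, shared])^2))
    }
    rownames(D) <- rownames(x)
    stats::as.dist(D)
  } else dist(x, method = "euclidean")
}

#' Ward's-method hierarchical clustering with deterministic tie-breaking
#'
#' Agglomerates with the Ward minimum-variance criterion on Euclidean
#' distances ("ward.D2" semantics: merge heights are the square root of the
#' Lance-Williams updated squared distances, so heights are in the input
#' distance units). Discretized profiles produce frequent exactly tied
#' merge costs; ties are broken deterministically in favor of the pair
#' containing the lowest leaf index, so results are reproducible across
#' platforms. A `"ward.D"` variant (no squaring of the input) is available
#' for comparability with older defaults.
#'
#' @param d a `dist` object (e.g. from [profile_distances()]).
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return an object of class `hclust` (usable with [stats::cutree()],
#'   `plot()`, [ape::as.phylo()], ...).
#' @export
ward_linkage <- function(d, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 observations")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # work on squared distances for ward.D2, raw for ward.D
  W <- if (method == "ward.D2") dm^2 else dm
  diag(W) <- Inf
  active <- seq_len(n)
  size <- rep(1, n)
  node <- -seq_len(n)                 # hclust coding: leaves negative
  min_leaf <- seq_len(n)              # lowest original leaf in each cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    sub <- W[active, active, drop = FALSE]
    dmin <- min(sub)
    tol <- 1e-9 * max(1, abs(dmin))
    cand <- which(sub <= dmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # deterministic tie-break: pair containing the lowest leaf index,
    # then the lowest leaf index of the partner
    key1 <- pmin(min_leaf[active[cand[, 1L]]], min_leaf[active[cand[, 2L]]])
    key2 <- pmax(min_leaf[active[cand[, 1L]]], min_leaf[active[cand[, 2L]]])
    pick <- order(key1, key2)[1L]
    i <- active[cand[pick, 1L]]; j <- active[cand[pick, 2L]]
    hij <- if (method == "ward.D2") sqrt(W[i, j]) else W[i, j]
    pair <- sort(c(node[i], node[j]))
    # hclust convention: singletons (negative) before clusters, both ascending
    merge[s, ] <- if (pair[1L] < 0 && pair[2L] > 0) pair
                  else if (pair[1L] < 0) -sort(-pair)  # both leaves: ascending abs
                  else pair
    height[s] <- hij
    # Lance-Williams Ward update against every other active cluster
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      upd <- ((ni + nk) * W[i, others] + (nj + nk) * W[j, others] -
                nk * W[i, j]) / (ni + nj + nk)
      W[i, others] <- W[others, i] <- upd
    }
    size[i] <- size[i] + size[j]
    node[i] <- s
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
    active <- setdiff(active, j)
  }
  out <- structure(list(merge = merge, height = height,
                        order = hclust_leaf_order(merge),
                        labels = labels, method = method,
                        dist.method = "euclidean",
                        call = match.call()),
                   class = "hclust")
  out
}

# Leaf plotting order from a merge matrix (left-to-right traversal).
hclust_leaf_order <- function(merge) {
  expand <- function(k)
    if (k < 0) -k else c(expand(merge[k, 1L]), expand(merge[k, 2L]))
  expand(nrow(merge))
}

#' Cut a linkage into k groups
#'
#' @param linkage an `hclust` object (e.g. from [ward_linkage()]).
#' @param k number of groups, `1 <= k <= n`.
#' @return named integer vector: group id per cargo.
#' @export
cut_profiles <- function(linkage, k) {
  n <- length(linkage$labels)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  cutree(linkage, k = k)
}

#' Export a dendrogram as a Newick tree
#'
#' @param linkage an `hclust` object.
#' @param path output file path.
#' @return invisibly, the Newick string.
#' @export
write_dendrogram_newick <- function(linkage, path) {
  tree <- ape::as.phylo(linkage)
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}
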