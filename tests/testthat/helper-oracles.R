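# Independent oracle implementations and small fixture builders, coded
# separately from the package internals so tests cross-check two routes.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Direct elementwise evaluation of the symmetric KL sum.
oracle_sym_kl <- function(p, q, base = exp(1)) {
  s <- 0
  for (i in seq_along(p))
    s <- s + p[i] * log(p[i] / q[i], base = base) +
      q[i] * log(q[i] / p[i], base = base)
  s
}

# Full-chain closed form for equal-weight groups under a single-component
# Dirichlet prior: counts rescaled to the number of non-gap residues, then
# posterior mean (n_i + alpha_i) / (N + |alpha|).
oracle_column_probs <- function(residues, alpha) {
  res <- residues[residues %in% AA]
  n <- length(res)
  cnt <- table(factor(res, levels = AA))
  as.numeric(cnt + alpha) / (n + sum(alpha))
}

# Exhaustive Mann-Whitney enumeration via rank sums over all assignments.
oracle_mwu <- function(a, b, alternative) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u(seq_len(na))
  u_all <- apply(combn(n, na), 2, u)
  mu <- na * nb / 2
  switch(alternative,
         less = mean(u_all <= u_obs),
         greater = mean(u_all >= u_obs),
         two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu)))
}

# Brute-force RSY window scan: every start, every length 15..30, naive
# substring counting.
oracle_scan_rsy <- function(seq) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  rows <- list()
  for (L in 15:30) {
    if (L > n) next
    for (s in 1:(n - L + 1)) {
      w <- chars[s:(s + L - 1)]
      rsy <- sum(w %in% c("R", "S", "Y")) / L
      dip <- paste0(w[-L], w[-1])
      dr <- sum(dip %in% c("RS", "SR", "SY", "YS")) / (L - 1)
      ds <- sum(dip %in% c("SY", "YS")) / (L - 1)
      if (rsy > 0.3 && dr > 0.2 && ds > 0)
        rows[[length(rows) + 1]] <- data.frame(start = s, end = s + L - 1,
                                               length = L, rsy_comp = rsy,
                                               dipep_rsy_comp = dr,
                                               dipep_sy_comp = ds)
    }
  }
  if (!length(rows)) return(data.frame(start = integer(), end = integer()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), ]
}

# Naive O(n^3) Ward agglomerator working directly on coordinates: at each
# step merge the pair minimizing the increase in within-cluster sum of
# squares (cost reported as sqrt(2 * increase), the ward.D2 height scale),
# ties broken in favor of the pair containing the lowest leaf index.
oracle_ward <- function(x) {
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- Inf; bi <- bj <- 0; bkey <- c(Inf, Inf)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      ci <- colMeans(x[clusters[[i]], , drop = FALSE])
      cj <- colMeans(x[clusters[[j]], , drop = FALSE])
      ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
      cost <- sqrt(2 * ni * nj / (ni + nj) * sum((ci - cj)^2))
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      tol <- 1e-9 * max(1, best)
      if (cost < best - tol ||
          (abs(cost - best) <= tol &&
           (key[1] < bkey[1] || (key[1] == bkey[1] && key[2] < bkey[2])))) {
        best <- cost; bi <- i; bj <- j; bkey <- key
      }
    }
    heights <- c(heights, best)
    merges[[length(merges) + 1]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Partition implied by the first n-k oracle merges.
oracle_ward_partition <- function(merges, n, k) {
  grp <- seq_len(n)
  for (s in seq_len(n - k)) {
    ids <- merges[[s]]
    grp[grp %in% grp[ids]] <- min(grp[ids])
  }
  as.integer(factor(grp))
}

same_partition <- function(p1, p2) {
  length(unique(paste(p1, p2))) == length(unique(p1)) &&
    length(unique(p1)) == length(unique(p2))
}

# Random two-group toy alignment.
random_toy_alignment <- function(n_a = 3, n_b = 2, n_col = 8,
                                 gap_prob = 0.1) {
  n <- n_a + n_b
  mat <- matrix(sample(AA, n * n_col, replace = TRUE), n, n_col)
  mat[matrix(runif(n * n_col) < gap_prob, n, n_col)] <- "-"
  ids <- c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b)))
  seqs <- setNames(apply(mat, 1, paste, collapse = ""), ids)
  grouped_alignment(seqs, setNames(rep(c("A", "B"), c(n_a, n_b)), ids))
}

# A centered disk image pair with uniform intensities (no noise).
disk_pair <- function(diameter_um, field_px = 256, pixel_size = 1,
                      load = 1000, ratio = 1.5, center = NULL, bg_gfp = 0) {
  coord <- (seq_len(field_px) - 0.5) * pixel_size
  X <- matrix(coord, field_px, field_px)
  Y <- matrix(coord, field_px, field_px, byrow = TRUE)
  if (is.null(center)) center <- rep(field_px * pixel_size / 2, 2)
  inside <- sqrt((X - center[1])^2 + (Y - center[2])^2) <= diameter_um / 2
  mch <- matrix(0, field_px, field_px); mch[inside] <- load
  gfp <- matrix(bg_gfp, field_px, field_px); gfp[inside] <- load * ratio
  channel_image_pair(mch, gfp, pixel_size = pixel_size)
}
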