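test_that("symmetric KL matches direct evaluation and is a divergence", {
  # two-point case: 2 * (0.8 - 0.2) * ln(0.8/0.2)
  expect_equal(symmetric_kl(c(0.8, 0.2), c(0.2, 0.8)),
               2 * 0.6 * log(4), tolerance = 1e-12)
  expect_equal(symmetric_kl(c(0.8, 0.2), c(0.2, 0.8), log_base = 2),
               2 * 0.6 * log2(4), tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:50) {
    p <- as.numeric(rexp(20)); p <- p / sum(p)
    q <- as.numeric(rexp(20)); q <- q / sum(q)
    expect_equal(symmetric_kl(p, q), oracle_sym_kl(p, q), tolerance = 1e-12)
    expect_equal(symmetric_kl(p, q), symmetric_kl(q, p), tolerance = 1e-12)
    expect_gte(symmetric_kl(p, q), 0)
    expect_equal(symmetric_kl(p, p), 0)
  }
  expect_error(symmetric_kl(c(1, 0), c(0.5, 0.5)), "strictly positive")
  expect_error(symmetric_kl(c(0.9, 0.3), c(0.5, 0.5)), "sum to 1")
})

test_that("score_all_sites agrees with an independent closed-form chain", {
  # identical sequences within each group -> equal weights, and the
  # default single-component prior admits a hand-computable posterior
  seqs <- c(a1 = "EWC", a2 = "EWC", a3 = "EWC",
            b1 = "RWC", b2 = "RWC")
  aln <- grouped_alignment(seqs, setNames(c("A", "A", "A", "B", "B"),
                                          names(seqs)))
  sc <- score_all_sites(aln)
  alpha <- default_aa_prior()$alpha[1, ]
  for (j in 1:3) {
    p <- oracle_column_probs(aln$seqs[1:3, j], alpha)
    q <- oracle_column_probs(aln$seqs[4:5, j], alpha)
    expect_equal(unname(sc$p[j, ]), p, tolerance = 1e-9)
    expect_equal(unname(sc$q[j, ]), q, tolerance = 1e-9)
    expect_equal(sc$table$kl[j], oracle_sym_kl(p, q), tolerance = 1e-9)
  }
  # differentiated column scores above the identical ones
  expect_identical(sc$table$rank[1], 1L)
  # identical composition in both groups is NOT exactly zero here because
  # group sizes (3 vs 2) differ; with equal-size groups it is exact:
  seqs2 <- c(a1 = "WC", a2 = "WC", b1 = "WC", b2 = "WC")
  aln2 <- grouped_alignment(seqs2, setNames(c("A", "A", "B", "B"),
                                            names(seqs2)))
  sc2 <- score_all_sites(aln2)
  expect_equal(sc2$table$kl, c(0, 0), tolerance = 1e-12)
})

test_that("KL per column equals the direct sum on random toy alignments", {
  set.seed(32)
  for (rep in 1:25) {
    aln <- random_toy_alignment(n_a = 3, n_b = 2, n_col = 6)
    sc <- score_all_sites(aln)
    for (j in which(sc$table$retained)) {
      expect_lt(abs(sc$table$kl[j] -
                    oracle_sym_kl(sc$p[j, ], sc$q[j, ])), 1e-9)
    }
    ret <- sc$table$retained
    expect_true(all(abs(rowSums(sc$p[ret, , drop = FALSE]) - 1) < 1e-9))
    expect_true(all(sc$p[ret, ] > 0))
    expect_true(all(sc$table$kl[ret] >= 0))
    expect_setequal(sc$table$rank[ret], seq_len(sum(ret)))
  }
})

test_that("gap-majority columns are skipped", {
  # 10 sequences, 6 gaps at column 1
  seqs <- setNames(c(rep("-A", 4), rep("-A", 2), rep("EA", 2), rep("EA", 2)),
                   paste0("s", 1:10))
  grp <- setNames(rep(c("A", "B"), each = 5), paste0("s", 1:10))
  aln <- grouped_alignment(seqs, grp)
  sc <- score_all_sites(aln)
  expect_false(sc$table$retained[1])
  expect_true(is.na(sc$table$kl[1]))
  expect_true(sc$table$retained[2])
  # an alignment with no retained columns warns and ranks nothing
  seqs2 <- setNames(rep("--", 4), paste0("s", 1:4))
  grp2 <- setNames(rep(c("A", "B"), each = 2), paste0("s", 1:4))
  expect_warning(sc2 <- score_all_sites(grouped_alignment(seqs2, grp2)),
                 "no retained")
  expect_true(all(!sc2$table$retained))
})

test_that("a between-group differentiated column outranks a shared one", {
  seqs <- c(a1 = "EQ", a2 = "EQ", a3 = "EQ",
            b1 = "RQ", b2 = "RQ", b3 = "RQ")
  grp <- setNames(rep(c("A", "B"), each = 3), names(seqs))
  sc <- score_all_sites(grouped_alignment(seqs, grp))
  expect_gt(sc$table$kl[1], sc$table$kl[2])
  expect_equal(sc$table$kl[2], 0, tolerance = 1e-12)
  expect_identical(sc$table$consensus_A[1], "E")
  expect_identical(sc$table$consensus_B[1], "R")
})

test_that("top_sites applies the ceiling and boundary-tie rules", {
  mk_scores <- function(kl) {
    n <- length(kl)
    rk <- integer(n); rk[order(-kl, seq_len(n))] <- seq_len(n)
    structure(list(table = data.frame(column = seq_len(n), retained = TRUE,
                                      kl = kl, rank = rk)),
              class = "site_scores")
  }
  sc <- mk_scores(seq(100, 1))           # 100 distinct scores
  ts <- top_sites(sc, 0.10)
  expect_identical(nrow(ts), 10L)
  expect_setequal(ts$column, 1:10)
  expect_equal(attr(ts, "kl_cutoff"), 91)

  # all-tied: the boundary tie rule returns everything
  tied <- mk_scores(rep(5, 10))
  expect_identical(nrow(top_sites(tied, 0.10)), 10L)

  expect_identical(nrow(top_sites(sc, 1.0)), 100L)
  expect_error(top_sites(sc, 0), "fraction")
  expect_error(top_sites(sc, 1.2), "fraction")
})

test_that("site score TSV export carries ranks, flags and probabilities", {
  seqs <- c(a1 = "EQW", a2 = "EQW", b1 = "RQW", b2 = "RQW")
  grp <- setNames(c("A", "A", "B", "B"), names(seqs))
  aln <- grouped_alignment(seqs, grp, reference_ids = c(A = "a1", B = "b1"))
  sc <- score_all_sites(aln)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_scores(sc, path, probabilities = TRUE, top_fraction = 0.34)
  back <- read.delim(path)
  expect_identical(nrow(back), 3L)
  expect_true(back$top_fraction[1])
  expect_identical(back$residue_A, 1:3)
  expect_equal(rowSums(back[, paste0("p_", AA)]), rep(1, 3),
               tolerance = 1e-6)
})
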