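# Generator tests use 256-px fields over a 256 um optical field (1 um/px)
# to keep the suite fast; physics and noise defaults are unchanged.

small_cfg <- function(...) image_sim_config(pixels = 256L, field_um = 256, ...)

test_that("noise-free bead images are exact constructions", {
  cfg <- small_cfg(shot_noise = FALSE, read_noise_sd = 0,
                   free_cargo_background = 20)
  sim <- simulate_bead_pair(bead_specs(128, 128, 100, 500, 2), cfg)
  inside <- sim$pair$mcherry == 500
  expect_true(any(inside))
  expect_true(all(sim$pair$gfp[inside] == 1000))      # load x ratio
  expect_true(all(sim$pair$gfp[!inside] == 20))       # free cargo outside
  expect_true(all(sim$pair$mcherry[!inside] == 0))
  # clipping at 12 bits
  simc <- simulate_bead_pair(bead_specs(128, 128, 100, 3000, 2), cfg)
  expect_true(all(simc$pair$gfp <= 4095))
  expect_error(simulate_bead_pair(bead_specs(128, 128, 400, 100, 1), cfg),
               "exceeds the field")
})

test_that("bead image generation is deterministic under a seed", {
  cfg <- small_cfg()
  set.seed(99); s1 <- simulate_bead_pair(sample_bead_specs(2, 1, cfg), cfg)
  set.seed(99); s2 <- simulate_bead_pair(sample_bead_specs(2, 1, cfg), cfg)
  expect_identical(s1$pair$mcherry, s2$pair$mcherry)
  expect_identical(s1$pair$gfp, s2$pair$gfp)
  expect_identical(s1$truth, s2$truth)
})

test_that("with noise disabled the pipeline recovers the ratio to <= 2%", {
  cfg <- small_cfg(shot_noise = FALSE, read_noise_sd = 0,
                   free_cargo_background = 0, load_cv = 0, ratio_cv = 0)
  sim <- simulate_bead_pair(bead_specs(128, 128, 110, 300, 1.5), cfg)
  m <- measure_image(sim$pair, segment_beads(sim$pair))
  expect_equal(m$ratio, 1.5, tolerance = 0.02)
})

test_that("assay panels produce the full replicate grid and truth record", {
  cfg <- small_cfg()
  truth <- rbind(WT = c(c1 = 1, c2 = 0.8, c3 = 0.5),
                 m1 = c(0.5, 0.8, 0.1), m2 = c(1, 0.1, 0.5))
  panel <- simulate_assay_panel(truth, reps = 3, cfg = cfg,
                                beads_per_image = 1, seed = 5)
  expect_identical(nrow(panel$sample_sheet), 27L)   # 3 NTRs x 3 cargoes x 3
  expect_length(panel$images, 3)
  expect_length(panel$images[["WT"]][["c2"]], 3)
  expect_s3_class(panel$images[["m1"]][["c3"]][[2]], "channel_image_pair")
  expect_error(simulate_assay_panel(truth[2:3, ], cfg = cfg, seed = 1),
               "WT")
  # written panels include sample sheet + truth json
  out <- withr::local_tempdir()
  simulate_assay_panel(truth[, 1, drop = FALSE], reps = 1, cfg = cfg,
                       beads_per_image = 1, seed = 5, out_dir = out)
  expect_true(file.exists(file.path(out, "samples.csv")))
  expect_true(file.exists(file.path(out, "truth.json")))
  sheet <- read.csv(file.path(out, "samples.csv"))
  expect_true(all(file.exists(file.path(out, sheet$mcherry_path))))
})

test_that("simulated alignments carry truth and reproduce byte-identically", {
  cls <- c(rep("shared-conserved", 6), rep("differentiated", 2),
           rep("variable", 6), "gappy")
  cfg <- alignment_sim_config(n_per_group = c(A = 12L, B = 10L),
                              column_classes = cls)
  s1 <- simulate_grouped_alignment(cfg, seed = 7)
  s2 <- simulate_grouped_alignment(cfg, seed = 7)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_grouped_alignment(s1$alignment, f1)
  write_grouped_alignment(s2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth$class, cls)
  # analytic KL is zero exactly for identical generating distributions
  expect_true(all(s1$truth$analytic_kl[s1$truth$class != "differentiated"] == 0))
  expect_true(all(s1$truth$analytic_kl[s1$truth$class == "differentiated"] > 0))
})

test_that("gappy columns propagate to the downstream skip rule", {
  cls <- c(rep("variable", 4), rep("gappy", 3))
  cfg <- alignment_sim_config(n_per_group = c(A = 30L, B = 30L),
                              column_classes = cls, gap_prob = 0.6)
  hits <- 0
  for (seed in 1:5) {
    sim <- simulate_grouped_alignment(cfg, seed = seed)
    sc <- score_all_sites(sim$alignment)
    hits <- hits + sum(!sc$table$retained[sim$truth$class == "gappy"])
  }
  expect_gte(hits / 15, 0.9)  # gap_prob 0.6 occasionally samples under half
})

test_that("differentiated columns rank in the top decile of their alignment", {
  cls <- c(rep("shared-conserved", 20), rep("variable", 17),
           rep("differentiated", 3))
  cfg <- alignment_sim_config(column_classes = cls)   # 78 + 72 sequences
  ok <- 0
  for (seed in 1:5) {
    sim <- simulate_grouped_alignment(cfg, seed = seed)
    sc <- score_all_sites(sim$alignment)
    diff_cols <- which(sim$truth$class == "differentiated")
    top <- top_sites(sc, 0.10)$column
    if (all(diff_cols %in% top)) ok <- ok + 1
    # mean KL ordering: differentiated far above both other classes
    m <- tapply(sc$table$kl, sim$truth$class, mean, na.rm = TRUE)
    expect_gt(m[["differentiated"]], 10 * m[["shared-conserved"]])
    expect_gt(m[["differentiated"]], 10 * m[["variable"]])
  }
  expect_gte(ok, 5 * 0.95)
})

test_that("embedded-segment sequences are seeded and RSY-poor by default", {
  e1 <- embed_rsy_segments(300, "RSYSRSYSRSYSRSY", 101, seed = 9)
  e2 <- embed_rsy_segments(300, "RSYSRSYSRSYSRSY", 101, seed = 9)
  expect_identical(e1$sequence, e2$sequence)
  expect_identical(e1$truth$end, 115L)
  expect_error(embed_rsy_segments(50, c("RSYSRSYSRSYSRSY", "RSYSRSYSRSYSRSY"),
                                  c(10, 20), seed = 1), "overlap")
  expect_error(embed_rsy_segments(20, "RSYSRSYSRSYSRSY", 10, seed = 1),
               "out of bounds")
  # false-positive control: backgrounds alone rarely produce hits
  clean <- 0
  for (seed in 1:10)
    clean <- clean +
      (nrow(scan_rsy(embed_rsy_segments(300, seed = seed)$sequence)) == 0)
  expect_gte(clean, 9.5)
})
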