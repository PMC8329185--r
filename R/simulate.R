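# Seeded synthetic-data generators with ground truth.
#
# Every generator is deterministic under a fixed seed and returns (or
# writes) a machine-readable truth record, so each pipeline stage can be
# verified end-to-end without the study's raw data.

#' Image simulation configuration
#'
#' Defaults emulate the assay's acquisition: a 317 um field on a
#' 1024 x 1024 px 12-bit sensor; free GFP-cargo background outside beads
#' only (beads exclude free cargo, so background rings carry it while bead
#' interiors do not); Poisson shot noise on the expected intensity plus
#' Gaussian read noise; clipping to 0..4095. Intensity scales are chosen so
#' the brightest assayed condition stays inside 12 bits: mean bead mCherry
#' load 300 counts with a lognormal bead-to-bead C.V. of 0.22 (the reported
#' per-bead fluorescence C.V. regime), per-bead binding-ratio jitter
#' C.V. 0.15, free-cargo background 6 counts, read noise s.d. 4 counts.
#'
#' @param field_um field size, microns (square).
#' @param pixels sensor pixels per side.
#' @param free_cargo_background mean free-cargo GFP level outside beads,
#'   counts.
#' @param shot_noise apply Poisson shot noise?
#' @param read_noise_sd Gaussian read noise s.d., counts.
#' @param mcherry_load mean bead mCherry load, counts.
#' @param load_cv lognormal bead-to-bead C.V. of the mCherry load.
#' @param ratio_cv lognormal bead-to-bead C.V. of the binding ratio.
#' @param bit_depth sensor bit depth (clip ceiling `2^bit_depth - 1`).
#' @return object of class `image_sim_config`.
#' @export
image_sim_config <- function(field_um = 317, pixels = 1024L,
                             free_cargo_background = 6,
                             shot_noise = TRUE, read_noise_sd = 4,
                             mcherry_load = 300, load_cv = 0.22,
                             ratio_cv = 0.15, bit_depth = 12L) {
  stopifnot(field_um > 0, pixels >= 16, free_cargo_background >= 0,
            read_noise_sd >= 0, mcherry_load > 0, load_cv >= 0,
            ratio_cv >= 0, bit_depth >= 8)
  structure(list(field_um = field_um, pixels = as.integer(pixels),
                 pixel_size = field_um / pixels,
                 free_cargo_background = free_cargo_background,
                 shot_noise = shot_noise, read_noise_sd = read_noise_sd,
                 mcherry_load = mcherry_load, load_cv = load_cv,
                 ratio_cv = ratio_cv, bit_depth = as.integer(bit_depth)),
            class = "image_sim_config")
}

#' Bead specification table
#'
#' @param center_x_um,center_y_um bead centers, microns.
#' @param diameter_um bead diameters, microns.
#' @param mcherry_load per-bead mCherry load, counts.
#' @param true_ratio per-bead GFP per mCherry (ground-truth binding index).
#' @param axis_ratio major/minor axis ratio (1 = circle; larger values give
#'   elongated, low-circularity objects).
#' @param theta orientation of the major axis, radians.
#' @return data.frame of bead specs.
#' @export
bead_specs <- function(center_x_um, center_y_um, diameter_um, mcherry_load,
                       true_ratio, axis_ratio = 1, theta = 0) {
  stopifnot(all(diameter_um > 0), all(mcherry_load >= 0),
            all(true_ratio >= 0), all(axis_ratio >= 1))
  data.frame(center_x_um = center_x_um, center_y_um = center_y_um,
             diameter_um = diameter_um, mcherry_load = mcherry_load,
             true_ratio = true_ratio, axis_ratio = axis_ratio,
             theta = theta)
}

#' Draw random non-edge bead specs for one image
#'
#' Bead diameters uniform in `diameter_range`, centers placed so beads
#' stay clear of the field border, loads lognormal around
#' `cfg$mcherry_load` with C.V. `cfg$load_cv`, and per-bead ratios
#' lognormal around `true_ratio` with C.V. `cfg$ratio_cv` (bead-to-bead
#' variation in receptor load and binding).
#'
#' @param n_beads number of beads.
#' @param true_ratio target mean binding ratio.
#' @param cfg an [image_sim_config()].
#' @param diameter_range bead diameter range, microns.
#' @return a [bead_specs()] data.frame.
#' @export
sample_bead_specs <- function(n_beads, true_ratio, cfg = image_sim_config(),
                              diameter_range = c(90, 140)) {
  d <- runif(n_beads, diameter_range[1L], diameter_range[2L])
  margin <- d / 2 + 8 * cfg$pixel_size   # keep bead + bg ring off the border
  cx <- cy <- numeric(n_beads)
  for (i in seq_len(n_beads)) {
    # rejection placement: avoid overlapping previously placed beads
    for (try in 1:200) {
      x <- runif(1, margin[i], cfg$field_um - margin[i])
      y <- runif(1, margin[i], cfg$field_um - margin[i])
      if (i == 1L || all(sqrt((x - cx[seq_len(i - 1L)])^2 +
                              (y - cy[seq_len(i - 1L)])^2) >
                         (d[i] + d[seq_len(i - 1L)]) / 2 + 12 * cfg$pixel_size))
        break
    }
    cx[i] <- x; cy[i] <- y
  }
  lsd <- sqrt(log(1 + cfg$load_cv^2))
  rsd <- sqrt(log(1 + cfg$ratio_cv^2))
  bead_specs(cx, cy, d,
             mcherry_load = rlnorm(n_beads, log(cfg$mcherry_load) - lsd^2 / 2, lsd),
             true_ratio = if (true_ratio == 0) rep(0, n_beads) else
               rlnorm(n_beads, log(true_ratio) - rsd^2 / 2, rsd))
}

#' Simulate a two-channel bead image pair
#'
#' mCherry intensity inside a bead equals its load; GFP inside equals
#' load x true_ratio; free-cargo background is added to the GFP channel
#' outside beads only; shot and read noise are applied and values clipped
#' to the sensor range. Deterministic given the RNG state (seed the RNG
#' before calling for byte-identical output).
#'
#' @param specs a [bead_specs()] data.frame.
#' @param cfg an [image_sim_config()].
#' @return list: `pair` (a [channel_image_pair()]) and `truth` (the spec
#'   table plus each bead's area in um^2).
#' @export
simulate_bead_pair <- function(specs, cfg = image_sim_config()) {
  if (any(specs$diameter_um > cfg$field_um))
    stop("bead diameter exceeds the field size")
  np <- cfg$pixels
  ps <- cfg$pixel_size
  # pixel-center coordinates in microns
  coord <- (seq_len(np) - 0.5) * ps
  X <- matrix(coord, np, np)                # rows: x
  Y <- matrix(coord, np, np, byrow = TRUE)  # cols: y
  mch <- matrix(0, np, np)
  gfp <- matrix(0, np, np)
  inside_any <- matrix(FALSE, np, np)
  for (i in seq_len(nrow(specs))) {
    a <- specs$diameter_um[i] / 2
    b <- a / specs$axis_ratio[i]
    th <- specs$theta[i]
    dx <- X - specs$center_x_um[i]; dy <- Y - specs$center_y_um[i]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    mch[inside] <- specs$mcherry_load[i]
    gfp[inside] <- specs$mcherry_load[i] * specs$true_ratio[i]
    inside_any <- inside_any | inside
  }
  gfp[!inside_any] <- gfp[!inside_any] + cfg$free_cargo_background
  noisify <- function(img) {
    if (cfg$shot_noise) img[] <- rpois(length(img), lambda = img)
    if (cfg$read_noise_sd > 0)
      img <- img + rnorm(length(img), 0, cfg$read_noise_sd)
    matrix(pmin(2^cfg$bit_depth - 1, pmax(0, round(img))), np, np)
  }
  pair <- channel_image_pair(noisify(mch), noisify(gfp), pixel_size = ps)
  truth <- specs
  truth$area_um2 <- pi * (specs$diameter_um / 2)^2 / specs$axis_ratio
  list(pair = pair, truth = truth)
}

#' Simulate a full assay panel of replicate bead images
#'
#' For a truth matrix of mean binding ratios (rows = NTR constructs
#' including a `WT` row, columns = cargoes) generates `reps` images per
#' NTR-cargo pair (in memory, or written as 16-bit TIFF pairs with a
#' sample sheet when `out_dir` is given) plus a truth record.
#'
#' @param truth_matrix numeric matrix of true mean GFP/mCherry ratios;
#'   must contain a row named `"WT"`.
#' @param reps replicate images per pair (default 3).
#' @param cfg an [image_sim_config()].
#' @param beads_per_image beads per image (the real assay mostly yielded
#'   one or two accepted beads per image).
#' @param seed integer seed (single RNG stream for the whole panel).
#' @param out_dir optional directory: writes `<ntr>_<cargo>_rep<k>_{mcherry,gfp}.tif`,
#'   `samples.csv` and `truth.json`.
#' @return list: `images` (nested list `[[ntr]][[cargo]][[rep]]` of
#'   [channel_image_pair()]s; omitted when `out_dir` is given),
#'   `sample_sheet` (data.frame), `truth_matrix`, `seed`.
#' @export
simulate_assay_panel <- function(truth_matrix, reps = 3L,
                                 cfg = image_sim_config(),
                                 beads_per_image = 2L, seed = 1L,
                                 out_dir = NULL) {
  truth_matrix <- as.matrix(truth_matrix)
  if (!"WT" %in% rownames(truth_matrix))
    stop("truth matrix must contain a 'WT' row")
  if (is.null(colnames(truth_matrix)))
    colnames(truth_matrix) <- paste0("cargo", seq_len(ncol(truth_matrix)))
  set.seed(seed)
  keep <- is.null(out_dir)
  if (!keep) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  images <- list()
  sheet <- list()
  for (ntr in rownames(truth_matrix)) {
    images[[ntr]] <- list()
    for (cargo in colnames(truth_matrix)) {
      images[[ntr]][[cargo]] <- list()
      for (k in seq_len(reps)) {
        specs <- sample_bead_specs(beads_per_image, truth_matrix[ntr, cargo], cfg)
        sim <- simulate_bead_pair(specs, cfg)
        base <- sprintf("%s_%s_rep%d", ntr, cargo, k)
        if (keep) {
          images[[ntr]][[cargo]][[k]] <- sim$pair
        } else {
          write_image_pair(sim$pair,
                           file.path(out_dir, paste0(base, "_mcherry.tif")),
                           file.path(out_dir, paste0(base, "_gfp.tif")))
        }
        sheet[[base]] <- data.frame(
          mcherry_path = if (keep) NA_character_ else paste0(base, "_mcherry.tif"),
          gfp_path = if (keep) NA_character_ else paste0(base, "_gfp.tif"),
          ntr = ntr, wt = identical(ntr, "WT"), cargo = cargo,
          condition = "none", replicate = k,
          true_ratio = truth_matrix[ntr, cargo])
      }
    }
  }
  sheet <- do.call(rbind, sheet); rownames(sheet) <- NULL
  if (!keep) {
    write.csv(sheet, file.path(out_dir, "samples.csv"), row.names = FALSE)
    jsonlite::write_json(list(seed = seed,
                              truth = as.data.frame(as.table(truth_matrix))),
                         file.path(out_dir, "truth.json"), auto_unbox = TRUE)
  }
  out <- list(sample_sheet = sheet, truth_matrix = truth_matrix, seed = seed)
  if (keep) out$images <- images
  out
}

#' Alignment simulation configuration
#'
#' @param n_per_group sequences per ortholog group, `c(A, B)`.
#' @param column_classes character vector over
#'   `{"shared-conserved", "differentiated", "variable", "gappy"}`: one
#'   entry per alignment column (defines the truth).
#' @param conservation probability mass on the conserved residue in
#'   conserved/differentiated columns (rest spread uniformly).
#' @param gap_prob gap probability in gappy columns (> 0.5 so they trip
#'   the downstream skip rule).
#' @return object of class `alignment_sim_config`.
#' @export
alignment_sim_config <- function(n_per_group = c(A = 78L, B = 72L),
                                 column_classes,
                                 conservation = 0.95, gap_prob = 0.6) {
  stopifnot(all(n_per_group >= 1), conservation > 0.5, conservation <= 1,
            gap_prob > 0.5, gap_prob <= 1)
  cls <- as.character(column_classes)
  known <- c("shared-conserved", "differentiated", "variable", "gappy")
  if (!all(cls %in% known))
    stop("unknown column class: ",
         paste(setdiff(cls, known), collapse = ", "))
  structure(list(n_per_group = n_per_group, column_classes = cls,
                 conservation = conservation, gap_prob = gap_prob),
            class = "alignment_sim_config")
}

#' Simulate a grouped ortholog alignment with per-column truth
#'
#' Draws residues per column class: `shared-conserved` columns use one
#' conserved residue in both groups; `differentiated` columns use a
#' different conserved residue per group; `variable` columns draw
#' uniformly from the 20 amino acids in both groups; `gappy` columns are
#' gapped with probability `gap_prob` (residues otherwise uniform). The
#' truth table records each column's class and the analytic symmetric KL
#' divergence between the two generating distributions.
#'
#' @param cfg an [alignment_sim_config()].
#' @param seed integer seed.
#' @return list: `alignment` (a [grouped_alignment()]) and `truth`
#'   (data.frame: `column`, `class`, `residue_A`, `residue_B`,
#'   `analytic_kl` in nats).
#' @export
simulate_grouped_alignment <- function(cfg, seed = 1L) {
  set.seed(seed)
  nA <- cfg$n_per_group[[1L]]; nB <- cfg$n_per_group[[2L]]
  nc <- length(cfg$column_classes)
  cons_dist <- function(res) {
    p <- rep((1 - cfg$conservation) / 19, 20L)
    p[match(res, AA20)] <- cfg$conservation
    p
  }
  unif <- rep(1 / 20, 20L)
  A <- matrix("-", nA, nc); B <- matrix("-", nB, nc)
  truth <- data.frame(column = seq_len(nc), class = cfg$column_classes,
                      residue_A = NA_character_, residue_B = NA_character_,
                      analytic_kl = 0)
  draw <- function(n, p) sample(AA20, n, replace = TRUE, prob = p)
  for (j in seq_len(nc)) {
    cl <- cfg$column_classes[j]
    if (cl == "shared-conserved") {
      r <- sample(AA20, 1L)
      pA <- pB <- cons_dist(r)
      truth$residue_A[j] <- truth$residue_B[j] <- r
    } else if (cl == "differentiated") {
      rr <- sample(AA20, 2L)
      pA <- cons_dist(rr[1L]); pB <- cons_dist(rr[2L])
      truth$residue_A[j] <- rr[1L]; truth$residue_B[j] <- rr[2L]
    } else {
      pA <- pB <- unif
    }
    truth$analytic_kl[j] <- sum((pA - pB) * (log(pA) - log(pB)))
    A[, j] <- draw(nA, pA)
    B[, j] <- draw(nB, pB)
    if (cl == "gappy") {
      A[runif(nA) < cfg$gap_prob, j] <- "-"
      B[runif(nB) < cfg$gap_prob, j] <- "-"
    }
  }
  ids <- c(sprintf("A_%03d", seq_len(nA)), sprintf("B_%03d", seq_len(nB)))
  seqs <- stats::setNames(c(apply(A, 1L, paste, collapse = ""),
                            apply(B, 1L, paste, collapse = "")), ids)
  groups <- stats::setNames(rep(c("A", "B"), c(nA, nB)), ids)
  list(alignment = grouped_alignment(seqs, groups,
                                     reference_ids = c(A = ids[1L],
                                                       B = ids[nA + 1L])),
       truth = truth)
}

#' Generate a protein sequence with embedded RSY-rich segments
#'
#' The background is drawn from an RSY-poor composition (so spurious hits
#' are rare) and the given segment strings are planted at the requested
#' positions.
#'
#' @param background_length total sequence length.
#' @param segments character vector of segment strings to embed.
#' @param positions 1-based start positions (same length as `segments`;
#'   placements must fit and not overlap).
#' @param seed integer seed.
#' @return list: `sequence` (string) and `truth` (data.frame `start`,
#'   `end`, `segment`).
#' @export
embed_rsy_segments <- function(background_length, segments = character(),
                               positions = integer(), seed = 1L) {
  stopifnot(length(segments) == length(positions))
  set.seed(seed)
  # RSY-poor background: R/S/Y at a few percent, bulk on other residues
  bg <- aa_background_frequencies()
  bg[c("R", "S", "Y")] <- c(0.02, 0.03, 0.01)
  bg <- bg / sum(bg)
  chars <- sample(AA20, background_length, replace = TRUE, prob = bg)
  if (length(segments)) {
    ends <- positions + nchar(segments) - 1L
    if (any(positions < 1L) || any(ends > background_length))
      stop("segment placement out of bounds")
    ord <- order(positions)
    if (any(positions[ord][-1L] <= ends[ord][-length(ord)]))
      stop("overlapping segment placements")
    for (i in seq_along(segments)) {
      idx <- positions[i]:ends[i]
      chars[idx] <- strsplit(toupper(segments[i]), "", fixed = TRUE)[[1L]]
    }
  }
  list(sequence = paste(chars, collapse = ""),
       truth = data.frame(start = as.integer(positions),
                          end = as.integer(positions + nchar(segments) - 1L),
                          segment = as.character(segments)))
}
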