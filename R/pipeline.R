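# End-to-end pipeline: quantify -> aggregate -> threshold -> normalize ->
# discretize -> test -> cluster.

#' Default run configuration
#'
#' All defaults equal the assay's printed parameter regime: segmentation
#' filters (area 5020-17700 um^2, circularity 0.80-1.00, exclude edges,
#' 5-px rings), negative-binding thresholds (0.1 TrnSR-like / 0.05
#' Imp13-like), discretization cutoffs (0.6, 0.2), ETA options (natural
#' log, top fraction 0.10) and clustering options (ward.D2, k = 5).
#'
#' @param ... name-value overrides of any default.
#' @return nested configuration list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    segmentation = unclass(segmentation_config()),
    pixel_size = 317 / 1024,
    negative_thresholds = list(`TrnSR-like` = 0.1, `Imp13-like` = 0.05),
    discretization = list(upper = 0.6, lower = 0.2),
    eta = list(log_base = exp(1), top_fraction = 0.10, prior_path = NULL),
    cluster = list(k = 5L, method = "ward.D2"),
    mwu_alternative = "less",
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unspecified fields keep their [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_run_config())
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge_in(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  structure(merge_in(cfg, user), class = "run_config")
}

#' Run the full bead halo assay reanalysis pipeline
#'
#' Quantifies every image in the sample sheet, averages replicates per
#' NTR-cargo pair, applies the negative-binding threshold to wild type,
#' normalizes mutants to WT, discretizes into 0/0.5/1 ranks, tests each
#' mutant against WT (exact Mann-Whitney on the per-image ratios), and
#' Ward-clusters the cargo binding profiles.
#'
#' @param sample_sheet data.frame with columns `ntr`, `wt` (logical),
#'   `cargo`, `replicate`, and either `mcherry_path`+`gfp_path` (TIFFs,
#'   relative to `image_dir`) or an index into `images`.
#' @param config a `run_config` (default [default_run_config()]).
#' @param images optional named-nested list `[[ntr]][[cargo]][[replicate]]`
#'   of in-memory [channel_image_pair()]s (as produced by
#'   [simulate_assay_panel()]); used instead of file paths when given.
#' @param image_dir directory that image paths are relative to.
#' @param ntr_class `"TrnSR-like"` or `"Imp13-like"` (selects the
#'   negative-binding threshold).
#' @param out_dir optional output directory for [write_results()].
#' @return list of class `halo_run`: `image_table` (per-image
#'   measurements), `assay_table` (per NTR-cargo mean ratios and bound
#'   flags), `profile_table` (long normalized + discrete values + MWU p),
#'   `profile_matrix` (cargoes x mutants, discrete), `excluded_cargoes`
#'   (not WT-bound), `linkage`, `clusters`, `config`.
#' @export
run_pipeline <- function(sample_sheet, config = default_run_config(),
                         images = NULL, image_dir = ".",
                         ntr_class = "TrnSR-like", out_dir = NULL) {
  seg_cfg <- do.call(segmentation_config, config$segmentation)
  threshold <- config$negative_thresholds[[ntr_class]]
  if (is.null(threshold)) stop("no negative threshold for class ", ntr_class)

  img_rows <- list()
  for (r in seq_len(nrow(sample_sheet))) {
    row <- sample_sheet[r, ]
    pair <- if (!is.null(images))
      images[[row$ntr]][[row$cargo]][[row$replicate]]
    else
      read_image_pair(file.path(image_dir, row$mcherry_path),
                      file.path(image_dir, row$gfp_path),
                      pixel_size = config$pixel_size)
    regions <- segment_beads(pair, seg_cfg)
    meas <- if (length(regions) == 0L) {
      warning(sprintf("no beads detected (%s ~ %s rep %d)",
                      row$ntr, row$cargo, row$replicate))
      data.frame(roi_mcherry = NA, bg_mcherry = NA, roi_gfp = NA,
                 bg_gfp = NA, ratio = NA_real_, n_beads = 0L, valid = FALSE)
    } else measure_image(pair, regions)
    img_rows[[r]] <- cbind(ntr = row$ntr, cargo = row$cargo,
                           replicate = row$replicate, meas)
  }
  image_table <- do.call(rbind, img_rows)

  pairs_tab <- unique(image_table[, c("ntr", "cargo")])
  assays <- list()
  for (r in seq_len(nrow(pairs_tab))) {
    sel <- image_table$ntr == pairs_tab$ntr[r] &
      image_table$cargo == pairs_tab$cargo[r]
    am <- aggregate_assay(image_table[sel, ], ntr = pairs_tab$ntr[r],
                          cargo = pairs_tab$cargo[r])
    assays[[paste(am$ntr, am$cargo, sep = "\r")]] <- am
  }
  assay_table <- do.call(rbind, lapply(assays, function(a)
    data.frame(ntr = a$ntr, cargo = a$cargo, mean_ratio = a$mean_ratio,
               n_images = a$n,
               bound = apply_negative_threshold(a, threshold = threshold))))
  rownames(assay_table) <- NULL

  cargoes <- unique(assay_table$cargo)
  mutants <- setdiff(unique(assay_table$ntr), "WT")
  wt_bound <- vapply(cargoes, function(cg) {
    a <- assays[[paste("WT", cg, sep = "\r")]]
    !is.null(a) && apply_negative_threshold(a, threshold = threshold)
  }, logical(1L))
  excluded <- cargoes[!wt_bound]
  kept <- cargoes[wt_bound]

  prof_rows <- list()
  for (cg in kept) {
    wt <- assays[[paste("WT", cg, sep = "\r")]]
    for (mt in mutants) {
      a <- assays[[paste(mt, cg, sep = "\r")]]
      if (is.null(a)) next
      norm <- normalize_to_wt(a, wt)
      mwu <- mann_whitney_exact(a$ratios, wt$ratios,
                                alternative = config$mwu_alternative)
      prof_rows[[paste(cg, mt)]] <- data.frame(
        cargo = cg, mutant = mt, normalized = norm,
        discrete = discretize_binding(norm), mwu_p = mwu$p.value)
    }
  }
  profile_table <- do.call(rbind, prof_rows)
  rownames(profile_table) <- NULL

  pm <- NULL; linkage <- NULL; clusters <- NULL
  if (!is.null(profile_table) && length(kept) >= 1L) {
    pm_raw <- matrix(NA_real_, length(kept), length(mutants),
                     dimnames = list(kept, mutants))
    for (r in seq_len(nrow(profile_table)))
      pm_raw[profile_table$cargo[r], profile_table$mutant[r]] <-
        profile_table$discrete[r]
    pm <- profile_matrix(pm_raw)
    if (length(kept) >= 2L) {
      linkage <- ward_linkage(profile_distances(pm),
                              method = config$cluster$method)
      k <- min(config$cluster$k, length(kept))
      clusters <- cut_profiles(linkage, k)
    }
  }

  res <- structure(list(image_table = image_table, assay_table = assay_table,
                        profile_table = profile_table, profile_matrix = pm,
                        excluded_cargoes = excluded, linkage = linkage,
                        clusters = clusters, config = config),
                   class = "halo_run")
  if (!is.null(out_dir)) {
    tables <- list(images = image_table, assays = assay_table)
    if (!is.null(profile_table)) tables$profiles <- profile_table
    if (!is.null(clusters))
      tables$clusters <- data.frame(cargo = names(clusters),
                                    cluster = as.integer(clusters))
    tables$exclusions <- data.frame(cargo = excluded)
    write_results(tables, out_dir, config = unclass(config),
                  seed = config$seed)
    if (!is.null(linkage))
      write_dendrogram_newick(linkage, file.path(out_dir, "dendrogram.nwk"))
  }
  res
}

#' @export
print.halo_run <- function(x, ...) {
  cat(sprintf("halo_run: %d images, %d assays, %d cargo(es) profiled, %d excluded\n",
              nrow(x$image_table), nrow(x$assay_table),
              if (is.null(x$profile_matrix)) 0L else nrow(x$profile_matrix),
              length(x$excluded_cargoes)))
  invisible(x)
}
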