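# File input/output: 16-bit TIFF image pairs and result tables.

#' Read a two-channel image pair from TIFF
#'
#' Reads 12-bit intensities stored in 16-bit TIFF containers, either as two
#' single-page files or one multi-page file with a channel map. Values
#' above 4095 trigger a "not 12-bit" warning but are kept.
#'
#' @param mcherry_path path to the mCherry TIFF (or the multi-page file).
#' @param gfp_path path to the GFP TIFF; `NULL` for multi-page input.
#' @param channel_map for multi-page input, named integer vector
#'   `c(mcherry = 1, gfp = 2)` selecting pages.
#' @param pixel_size microns per pixel (default 317/1024).
#' @return a [channel_image_pair()].
#' @export
read_image_pair <- function(mcherry_path, gfp_path = NULL,
                            channel_map = c(mcherry = 1L, gfp = 2L),
                            pixel_size = 317 / 1024) {
  to_counts <- function(x) {
    m <- round(x * 65535)
    storage.mode(m) <- "integer"
    m
  }
  if (is.null(gfp_path)) {
    pages <- tiff::readTIFF(mcherry_path, all = TRUE)
    if (length(pages) < max(channel_map))
      stop("multi-page TIFF has fewer pages than the channel map needs")
    mch <- to_counts(pages[[channel_map[["mcherry"]]]])
    gfp <- to_counts(pages[[channel_map[["gfp"]]]])
  } else {
    mch <- to_counts(tiff::readTIFF(mcherry_path))
    gfp <- to_counts(tiff::readTIFF(gfp_path))
  }
  channel_image_pair(mch, gfp, pixel_size = pixel_size)
}

#' Write a two-channel image pair as 16-bit TIFFs
#'
#' Integer counts round-trip exactly through [read_image_pair()].
#'
#' @param pair a [channel_image_pair()].
#' @param mcherry_path,gfp_path output paths.
#' @return invisibly, `c(mcherry_path, gfp_path)`.
#' @export
write_image_pair <- function(pair, mcherry_path, gfp_path) {
  stopifnot(inherits(pair, "channel_image_pair"))
  tiff::writeTIFF(pair$mcherry / 65535, mcherry_path, bits.per.sample = 16L)
  tiff::writeTIFF(pair$gfp / 65535, gfp_path, bits.per.sample = 16L)
  invisible(c(mcherry_path, gfp_path))
}

#' Write result tables with a provenance record
#'
#' Writes each table as CSV with stable column order plus a
#' `provenance.json` recording the configuration, seed and package
#' version, so a run can be reproduced from its output directory.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if missing).
#' @param config optional configuration list stored in the provenance.
#' @param seed optional seed stored in the provenance.
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  prov <- list(package = "halotrace",
               version = as.character(utils::packageVersion("halotrace")),
               seed = seed, config = config)
  pj <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, pj, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(c(paths, pj))
}
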