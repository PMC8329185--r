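# Bead segmentation from the mCherry channel.
#
# NTR-coated Sepharose beads appear as bright disks/rings on a dark
# background. Beads are binarized (Otsu by default), hole-filled, labeled,
# and filtered by area (80-150 um diameter), circularity and an
# exclude-on-edges rule, mirroring particle-analysis practice. Each kept
# bead gets a 5-px ring ROI along the inside of its outline and a 5-px
# background ring 5 px outside it (Euclidean distance bands).

#' Two-channel confocal image pair
#'
#' @param mcherry,gfp numeric matrices of identical shape; 12-bit intensities
#'   (values in 0..4095) in arbitrary detector counts.
#' @param pixel_size microns per pixel (default 317/1024, a 317 um field on
#'   a 1024 px sensor).
#' @return object of class `channel_image_pair`.
#' @export
channel_image_pair <- function(mcherry, gfp, pixel_size = 317 / 1024) {
  mcherry <- as.matrix(mcherry); gfp <- as.matrix(gfp)
  if (!all(dim(mcherry) == dim(gfp)))
    stop("channel shapes differ: ", paste(dim(mcherry), collapse = "x"),
         " vs ", paste(dim(gfp), collapse = "x"))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (max(mcherry, gfp) > 4095)
    warning("intensities exceed 4095: not 12-bit data")
  if (min(mcherry, gfp) < 0) stop("negative intensities")
  structure(list(mcherry = mcherry, gfp = gfp, pixel_size = pixel_size),
            class = "channel_image_pair")
}

#' Bead segmentation configuration
#'
#' Defaults are the assay's printed acquisition/filter settings: area
#' 5020-17700 um^2 (diameter 80-150 um), circularity 0.80-1.00, exclude on
#' edges, 5-px ROI and background rings with a 5-px gap.
#'
#' @param min_area,max_area accepted bead area, um^2.
#' @param circularity_min,circularity_max accepted circularity
#'   (`4*pi*area/perimeter^2`, clamped at 1).
#' @param exclude_edges drop beads touching the image border.
#' @param roi_width_px,bg_gap_px,bg_width_px ring geometry, pixels.
#' @param threshold_method `"otsu"` or a fixed numeric threshold in counts.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(min_area = 5020, max_area = 17700,
                                circularity_min = 0.80, circularity_max = 1.00,
                                exclude_edges = TRUE,
                                roi_width_px = 5L, bg_gap_px = 5L,
                                bg_width_px = 5L,
                                threshold_method = "otsu") {
  stopifnot(min_area > 0, min_area < max_area,
            circularity_min >= 0, circularity_max <= 1,
            circularity_min <= circularity_max,
            roi_width_px >= 1, bg_gap_px >= 1, bg_width_px >= 1)
  structure(list(min_area = min_area, max_area = max_area,
                 circularity_min = circularity_min,
                 circularity_max = circularity_max,
                 exclude_edges = exclude_edges,
                 roi_width_px = roi_width_px, bg_gap_px = bg_gap_px,
                 bg_width_px = bg_width_px,
                 threshold_method = threshold_method),
            class = "segmentation_config")
}

# Chain-code perimeter with Kulpa's corner correction. Plain boundary-pixel
# counts (e.g. a contour's vertex count) misestimate length on digitized
# disks enough to push circularity past 1.2; weighting axial steps 1 and
# diagonal steps sqrt(2), scaled by pi/8*(1+sqrt(2)), is accurate to ~1%
# for smooth convex outlines.
contour_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2L) return(0)
  nxt <- rbind(contour[-1L, , drop = FALSE], contour[1L, , drop = FALSE])
  st <- abs(nxt - contour)
  n_diag <- sum(st[, 1L] == 1L & st[, 2L] == 1L)
  n_axial <- sum((st[, 1L] + st[, 2L]) == 1L)
  (n_axial + sqrt(2) * n_diag) * pi / 8 * (1 + sqrt(2))
}

#' Segment beads in an image pair
#'
#' Runs on the mCherry channel (the NTR-load channel, present on every
#' bead). Binarizes, fills holes, labels connected components, filters by
#' area/circularity/edge contact, and attaches ring ROI and background
#' masks via [build_rings()].
#'
#' @param pair a [channel_image_pair()].
#' @param cfg a [segmentation_config()].
#' @return list of `bead_region` objects; each has `label`, `mask` (logical
#'   filled mask), `area_um2`, `diameter_um` (equivalent-circle),
#'   `perimeter_um`, `circularity`, `touches_edge`, `roi_mask`, `bg_mask`.
#'   Empty list when nothing passes the filters.
#' @export
segment_beads <- function(pair, cfg = segmentation_config()) {
  stopifnot(inherits(pair, "channel_image_pair"))
  img <- pair$mcherry
  thr <- if (identical(cfg$threshold_method, "otsu")) {
    EBImage::otsu(EBImage::Image(img / 4095), range = c(0, 1), levels = 4096) * 4095
  } else if (is.numeric(cfg$threshold_method)) {
    cfg$threshold_method
  } else stop("unknown threshold_method: ", cfg$threshold_method)
  bin <- EBImage::fillHull(img > thr)
  lab <- EBImage::bwlabel(bin)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  labm <- EBImage::imageData(lab)
  contours <- EBImage::ocontour(lab)
  px2 <- pair$pixel_size^2
  nr <- nrow(img); ncl <- ncol(img)
  all_mask <- labm > 0
  regions <- list()
  for (k in seq_len(nlab)) {
    mask <- labm == k
    area_px <- sum(mask)
    area <- area_px * px2
    if (area < cfg$min_area || area > cfg$max_area) next
    per_px <- contour_perimeter(contours[[k]])
    circ <- if (per_px > 0) min(1, 4 * pi * area_px / per_px^2) else 1
    if (circ < cfg$circularity_min || circ > cfg$circularity_max) next
    idx <- which(mask, arr.ind = TRUE)
    touches <- any(idx[, 1L] == 1L | idx[, 1L] == nr |
                   idx[, 2L] == 1L | idx[, 2L] == ncl)
    if (cfg$exclude_edges && touches) next
    rings <- build_rings(mask, cfg$roi_width_px, cfg$bg_gap_px,
                         cfg$bg_width_px, other_beads = all_mask & !mask)
    regions[[length(regions) + 1L]] <- structure(
      list(label = k, mask = mask, area_um2 = area,
           diameter_um = 2 * sqrt(area / pi),
           perimeter_um = per_px * pair$pixel_size,
           circularity = circ, touches_edge = touches,
           roi_mask = rings$roi_mask, bg_mask = rings$bg_mask),
      class = "bead_region")
  }
  regions
}

#' Build the ring ROI and background ring for one bead mask
#'
#' The ROI is the band of bead pixels whose Euclidean distance to the
#' exterior is at most `roi_width_px` (the ring along the inside of the
#' outline); the background ring is the band of non-bead pixels whose
#' distance to the bead is greater than `bg_gap_px` and at most
#' `bg_gap_px + bg_width_px`, with pixels of any other detected bead
#' removed. Both bands are clipped at the image border.
#'
#' @param mask logical matrix, the bead's filled mask.
#' @param roi_width_px,bg_gap_px,bg_width_px ring geometry, pixels.
#' @param other_beads optional logical matrix of all other beads' filled
#'   pixels to exclude from the background ring.
#' @return list with logical `roi_mask` and `bg_mask`.
#' @export
build_rings <- function(mask, roi_width_px = 5L, bg_gap_px = 5L,
                        bg_width_px = 5L, other_beads = NULL) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("empty bead mask")
  d_in <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  roi <- mask & d_in <= roi_width_px
  if (all(roi == mask))
    warning("ROI ring consumes the whole bead mask")
  d_out <- EBImage::imageData(EBImage::distmap(EBImage::Image((!mask) * 1)))
  bg <- !mask & d_out > bg_gap_px & d_out <= bg_gap_px + bg_width_px
  if (!is.null(other_beads)) bg <- bg & !other_beads
  list(roi_mask = roi, bg_mask = bg)
}
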