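# Intensity measurement and assay-level aggregation.
#
# The binding index is the background-subtracted GFP/mCherry ratio
#   (ROI_GFP - BG_GFP) / (ROI_mCherry - BG_mCherry)
# with ROI/BG means pooled over all accepted beads' ring pixels in an
# image. mCherry (NTR load) in the denominator normalizes away
# bead-to-bead variation in receptor coating; the BG ring subtracts
# free-cargo and detector background.

#' Measure the pooled binding ratio of one image
#'
#' Pools ROI and background pixels over all accepted beads, per channel,
#' and computes the background-subtracted GFP/mCherry ratio. A
#' non-positive mCherry contrast (ROI - BG <= 0, i.e. no receptor on the
#' beads) flags the measurement invalid.
#'
#' @param pair a [channel_image_pair()].
#' @param regions list of `bead_region` from [segment_beads()].
#' @return data.frame (1 row): `roi_mcherry`, `bg_mcherry`, `roi_gfp`,
#'   `bg_gfp`, `ratio`, `n_beads`, `valid`.
#' @export
measure_image <- function(pair, regions) {
  stopifnot(inherits(pair, "channel_image_pair"))
  if (length(regions) == 0L) stop("no accepted bead regions to measure")
  roi <- Reduce(`|`, lapply(regions, `[[`, "roi_mask"))
  bg <- Reduce(`|`, lapply(regions, `[[`, "bg_mask"))
  roi_m <- mean(pair$mcherry[roi]); bg_m <- mean(pair$mcherry[bg])
  roi_g <- mean(pair$gfp[roi]);     bg_g <- mean(pair$gfp[bg])
  denom <- roi_m - bg_m
  valid <- is.finite(denom) && denom > 0
  data.frame(roi_mcherry = roi_m, bg_mcherry = bg_m,
             roi_gfp = roi_g, bg_gfp = bg_g,
             ratio = if (valid) (roi_g - bg_g) / denom else NA_real_,
             n_beads = length(regions), valid = valid)
}

#' Per-bead background-subtracted measurements
#'
#' One row per accepted bead: its own ROI/BG means, background-subtracted
#' intensities and per-bead ratio. Input for [assay_qc()].
#'
#' @inheritParams measure_image
#' @return data.frame: `diameter_um`, `circularity`, `mcherry`, `gfp`
#'   (BG-subtracted means), `ratio`.
#' @export
measure_beads <- function(pair, regions) {
  stopifnot(inherits(pair, "channel_image_pair"))
  if (length(regions) == 0L) return(data.frame(diameter_um = numeric(),
                                               circularity = numeric(),
                                               mcherry = numeric(),
                                               gfp = numeric(),
                                               ratio = numeric()))
  rows <- lapply(regions, function(r) {
    m <- mean(pair$mcherry[r$roi_mask]) - mean(pair$mcherry[r$bg_mask])
    g <- mean(pair$gfp[r$roi_mask]) - mean(pair$gfp[r$bg_mask])
    data.frame(diameter_um = r$diameter_um, circularity = r$circularity,
               mcherry = m, gfp = g,
               ratio = if (is.finite(m) && m > 0) g / m else NA_real_)
  })
  do.call(rbind, rows)
}

#' Aggregate replicate image ratios into one assay measurement
#'
#' Replicate images of one NTR-cargo pair (three in the standard design)
#' are averaged; invalid measurements are dropped with a warning.
#'
#' @param measurements data.frame of [measure_image()] rows (rbind-ed), or a
#'   numeric vector of per-image ratios.
#' @param ntr,cargo,condition identifying labels stored on the result.
#' @return object of class `assay_measurement`: list with `ntr`, `cargo`,
#'   `condition`, `ratios` (valid per-image ratios), `mean_ratio`, `n`.
#' @export
aggregate_assay <- function(measurements, ntr = NA_character_,
                            cargo = NA_character_,
                            condition = NA_character_) {
  ratios <- if (is.data.frame(measurements)) {
    n_invalid <- sum(!measurements$valid)
    if (n_invalid > 0L)
      warning(n_invalid, " invalid measurement(s) dropped")
    measurements$ratio[measurements$valid]
  } else as.numeric(measurements[is.finite(measurements)])
  if (length(ratios) == 0L) stop("no valid measurements to aggregate")
  if (length(ratios) < 3L)
    warning("fewer than 3 replicate images (n = ", length(ratios), ")")
  structure(list(ntr = ntr, cargo = cargo, condition = condition,
                 ratios = ratios, mean_ratio = mean(ratios),
                 n = length(ratios)),
            class = "assay_measurement")
}

#' @export
print.assay_measurement <- function(x, ...) {
  cat(sprintf("assay_measurement %s ~ %s: mean GFP/mCherry = %.4g (n = %d)\n",
              x$ntr, x$cargo, x$mean_ratio, x$n))
  invisible(x)
}

#' Negative-binding threshold on the unnormalized ratio
#'
#' Binding is called when the mean unnormalized GFP/mCherry ratio strictly
#' exceeds the class threshold: 0.1 for TrnSR-like receptors and 0.05 for
#' Imp13-like ones (weak nonspecific GFP binding differs between the two).
#' A value exactly at the threshold is unbound.
#'
#' @param assay an [aggregate_assay()] result (or a bare mean ratio).
#' @param ntr_class `"TrnSR-like"` or `"Imp13-like"`; ignored when
#'   `threshold` is given explicitly.
#' @param threshold explicit threshold overriding the class default.
#' @return logical: bound?
#' @export
apply_negative_threshold <- function(assay, ntr_class = c("TrnSR-like", "Imp13-like"),
                                     threshold = NULL) {
  mean_ratio <- if (inherits(assay, "assay_measurement")) assay$mean_ratio
                else as.numeric(assay)
  if (is.null(threshold)) {
    ntr_class <- match.arg(ntr_class)
    threshold <- c("TrnSR-like" = 0.1, "Imp13-like" = 0.05)[[ntr_class]]
  }
  isTRUE(mean_ratio > threshold)
}

#' Normalize a mutant measurement to wild type
#'
#' Mutant mean ratio divided by the wild-type mean ratio for the same
#' cargo. Undefined (error) when the cargo is not a wild-type binder.
#'
#' @param mutant,wt [aggregate_assay()] results (or bare mean ratios).
#' @param wt_bound is the WT measurement above its negative threshold?
#'   (checked by the caller against the proper class threshold).
#' @return normalized ratio (may exceed 1 when a mutation increases binding).
#' @export
normalize_to_wt <- function(mutant, wt, wt_bound = TRUE) {
  m <- if (inherits(mutant, "assay_measurement")) mutant$mean_ratio else as.numeric(mutant)
  w <- if (inherits(wt, "assay_measurement")) wt$mean_ratio else as.numeric(wt)
  if (!isTRUE(wt_bound) || !is.finite(w) || w <= 0)
    stop("cargo not a WT binder; normalized profile undefined")
  m / w
}

#' Discretize a WT-normalized ratio into three binding ranks
#'
#' `> 0.6` -> 1 (not reduced); `<= 0.6` and `> 0.2` -> 0.5 (reduced);
#' `<= 0.2` -> 0 (much reduced). Boundaries fall on the lower rank.
#'
#' @param value non-negative normalized ratio(s).
#' @return numeric vector over `{0, 0.5, 1}`.
#' @export
discretize_binding <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop("normalized ratio must be >= 0")
  ifelse(value > 0.6, 1, ifelse(value > 0.2, 0.5, 0))
}

#' Assay quality-control summary from per-bead measurements
#'
#' Computes, over per-bead background-subtracted values, the coefficients
#' of variation (S.D./mean) of the GFP intensity and of the GFP/mCherry
#' ratio, the Pearson correlation between the two channels, and each
#' channel's correlation with bead diameter. A proportional GFP~mCherry
#' relationship (cargo binding tracking receptor load) shows up as high
#' channel correlation and a ratio C.V. below the raw GFP C.V.
#'
#' @param bead_table data.frame from [measure_beads()] (rows poolable
#'   across images); needs >= 3 beads.
#' @return list: `beads` (the table), `n_beads`, `cv_mcherry`, `cv_gfp`,
#'   `cv_ratio`, `corr_channels`, `corr_mcherry_diameter`,
#'   `corr_gfp_diameter`, `corr_ratio_diameter`.
#' @export
assay_qc <- function(bead_table) {
  if (nrow(bead_table) < 3L) stop("insufficient beads for QC (need >= 3)")
  cv <- function(x) if (mean(x) == 0) 0 else sd(x) / mean(x)
  safe_cor <- function(x, y)
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  list(beads = bead_table, n_beads = nrow(bead_table),
       cv_mcherry = cv(bead_table$mcherry),
       cv_gfp = cv(bead_table$gfp),
       cv_ratio = cv(bead_table$ratio),
       corr_channels = safe_cor(bead_table$mcherry, bead_table$gfp),
       corr_mcherry_diameter = safe_cor(bead_table$mcherry, bead_table$diameter_um),
       corr_gfp_diameter = safe_cor(bead_table$gfp, bead_table$diameter_um),
       corr_ratio_diameter = safe_cor(bead_table$ratio, bead_table$diameter_um))
}
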