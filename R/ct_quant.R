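# CT-side quantification: density segmentation of the lung ROI and mean
# lung density (MLD).

#' Lung density thresholds
#'
#' The conventional bands: aerated (normal) lung in `[-800, -100)` HU and
#' dense (non-aerated, fibrotic consolidation) lung in `[-100, 300]` HU.
#' The boundary value -100 HU belongs to the dense band, keeping the two
#' compartments disjoint.
#'
#' @param aerated_low,aerated_high,dense_high band edges in HU, strictly
#'   increasing.
#' @return An object of class `density_thresholds`.
#' @export
density_thresholds <- function(aerated_low = -800, aerated_high = -100,
                               dense_high = 300) {
  if (!(aerated_low < aerated_high && aerated_high < dense_high))
    stop("thresholds must satisfy aerated_low < aerated_high < dense_high")
  structure(list(aerated_low = aerated_low, aerated_high = aerated_high,
                 dense_high = dense_high), class = "density_thresholds")
}

#' Segment a lung ROI by CT density
#'
#' Partitions the lung mask into three disjoint compartments by voxel HU:
#' aerated `[aerated_low, aerated_high)`, dense
#' `[aerated_high, dense_high]`, and excluded (air-like values below the
#' aerated band, bone/metal-like values above the dense band). The three
#' masks always union exactly to the input lung mask.
#'
#' @param ct a CT [volume_grid()].
#' @param lung a non-empty [roi_mask()] congruent with `ct`.
#' @param thresholds a [density_thresholds()].
#' @return An object of class `density_segmentation` with `aerated`,
#'   `dense` and `excluded` masks, the thresholds used, and a fingerprint
#'   of the source grid.
#' @export
segment_density <- function(ct, lung, thresholds = density_thresholds()) {
  if (ct$modality != "CT") stop("modality mismatch: expected a CT volume")
  check_congruent(ct, lung)
  if (!any(lung$membership)) stop("empty lung mask")
  th <- thresholds
  v <- ct$values
  aer <- lung$membership & v >= th$aerated_low & v < th$aerated_high
  den <- lung$membership & v >= th$aerated_high & v <= th$dense_high
  exc <- lung$membership & !aer & !den
  mk <- function(m, lab) roi_mask(m, spacing = ct$spacing, origin = ct$origin,
                                  label = lab)
  structure(list(aerated = mk(aer, "aerated"), dense = mk(den, "dense"),
                 excluded = mk(exc, "excluded"), thresholds = th,
                 grid_id = grid_id(ct)),
            class = "density_segmentation")
}

#' @export
print.density_segmentation <- function(x, ...) {
  n <- vapply(list(x$aerated, x$dense, x$excluded),
              function(m) sum(m$membership), integer(1))
  cat(sprintf("<density_segmentation> aerated %d | dense %d | excluded %d voxels\n",
              n[1], n[2], n[3]))
  invisible(x)
}

#' Mean lung density
#'
#' Arithmetic mean HU over the full lung ROI, including voxels outside the
#' aerated/dense bands. Rises as fibrosis replaces air with tissue.
#'
#' @inheritParams segment_density
#' @param bands_only if `TRUE`, restrict the mean to voxels inside the
#'   aerated or dense bands.
#' @return mean density in HU.
#' @export
mean_lung_density <- function(ct, lung, bands_only = FALSE,
                              thresholds = density_thresholds()) {
  if (ct$modality != "CT") stop("modality mismatch: expected a CT volume")
  if (bands_only) {
    seg <- segment_density(ct, lung, thresholds)
    m <- seg$aerated$membership | seg$dense$membership
    if (!any(m)) stop("empty lung mask after band restriction")
    return(mean(ct$values[m]))
  }
  mask_statistics(ct, lung)$mean
}

#' CT quantification result
#'
#' Volumes of the density compartments, mean lung density, and the fibrosis
#' fraction `dense / (aerated + dense)`.
#'
#' @param seg a [segment_density()] result produced from `ct` and `lung`.
#' @inheritParams segment_density
#' @return An object of class `ct_result` with fields `mean_lung_density`,
#'   `lung_volume_mL`, `aerated_volume_mL`, `dense_volume_mL` and
#'   `fibrosis_fraction`.
#' @export
ct_result <- function(seg, ct, lung) {
  if (!identical(seg$grid_id, grid_id(ct)))
    stop("stale segmentation: it was not produced from this CT grid")
  vox_mL <- prod(ct$spacing) / 1000
  n_aer <- sum(seg$aerated$membership)
  n_den <- sum(seg$dense$membership)
  structure(list(
    mean_lung_density = mean_lung_density(ct, lung),
    lung_volume_mL = sum(lung$membership) * vox_mL,
    aerated_volume_mL = n_aer * vox_mL,
    dense_volume_mL = n_den * vox_mL,
    fibrosis_fraction = if (n_aer + n_den > 0) n_den / (n_aer + n_den)
                        else NA_real_),
    class = "ct_result")
}

#' @export
print.ct_result <- function(x, ...) {
  cat(sprintf("<ct_result> MLD %.1f HU | lung %.3f mL | fibrosis fraction %.3f\n",
              x$mean_lung_density, x$lung_volume_mL, x$fibrosis_fraction))
  invisible(x)
}
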