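# Shared image data model: volumes, ROI masks, acquisition metadata, NIfTI I/O.
# World convention: RAS, millimetres; voxel centre of array index (i,j,k)
# (1-based in R) sits at origin + (index - 0.5) * spacing.

#' Construct a 3D image volume
#'
#' A `volume_grid` holds one 3D scalar field — CT attenuation in Hounsfield
#' units (HU) or PET activity concentration in kBq/mL — together with the
#' voxel geometry and, for PET, the frame timing relative to tracer
#' injection. PET frames store the activity concentration as measured at
#' acquisition time: radioactive decay is *not* pre-corrected, so decay
#' correction is an explicit, testable quantification step (see
#' [decay_factor()]).
#'
#' @param values numeric 3D array. CT values must lie in `[-1024, 3071]` HU;
#'   PET values must be non-negative.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param modality `"CT"` or `"PET"`.
#' @param origin numeric length-3 world offset in mm.
#' @param frame_start,frame_duration frame timing in minutes post-injection
#'   (PET only); the frame covers the half-open interval
#'   `[frame_start, frame_start + frame_duration)`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing, modality, origin = c(0, 0, 0),
                        frame_start = NULL, frame_duration = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("non-3D image: `values` must be a 3D array")
  if (any(!is.finite(values)))
    stop("`values` must be finite everywhere")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive voxel edge lengths (mm)")
  modality <- match.arg(modality, c("CT", "PET"))
  if (modality == "CT" && (min(values) < -1024 || max(values) > 3071))
    stop("CT values must lie within [-1024, 3071] HU")
  if (modality == "PET") {
    if (min(values) < 0) stop("PET values must be non-negative")
    if (!is.null(frame_start)) {
      stopifnot(is.numeric(frame_start), frame_start >= 0)
      stopifnot(is.numeric(frame_duration), frame_duration > 0)
    }
  }
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         modality = modality,
         frame_start = if (modality == "PET") frame_start else NULL,
         frame_duration = if (modality == "PET") frame_duration else NULL),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %s  %d x %d x %d voxels @ (%g, %g, %g) mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (x$modality == "PET" && !is.null(x$frame_start))
    cat(sprintf("  frame [%g, %g) min p.i.\n",
                x$frame_start, x$frame_start + x$frame_duration))
  cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' Boolean voxel membership congruent with a [volume_grid()]. The mask
#' carries its own geometry so congruence with an image can be verified;
#' no registration is performed — PET and CT are assumed hardware
#' co-registered and a mask on a different grid must be brought over
#' explicitly with [resample_mask()].
#'
#' @param membership logical 3D array.
#' @param spacing,origin voxel geometry, as for [volume_grid()].
#' @param label free-text ROI label, e.g. `"lung"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(membership, spacing, origin = c(0, 0, 0), label = "roi") {
  if (!is.array(membership) || length(dim(membership)) != 3L)
    stop("mask must be a 3D array")
  storage.mode(membership) <- "logical"
  if (anyNA(membership)) stop("mask must not contain NA")
  structure(list(membership = membership, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), label = label),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d of %d voxels set\n",
              x$label, sum(x$membership), length(x$membership)))
  invisible(x)
}

#' Acquisition metadata for a PET study
#'
#' @param injected_activity_MBq activity injected at time zero, MBq (> 0).
#' @param half_life_min isotope physical half-life in minutes; default is
#'   the gallium-68 half-life, 67.71 min.
#' @param tracer_amount_nmol injected peptide amount (metadata only).
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(injected_activity_MBq = 5,
                             half_life_min = 67.71,
                             tracer_amount_nmol = 1.5) {
  stopifnot(injected_activity_MBq > 0, half_life_min > 0)
  structure(list(injected_activity_MBq = injected_activity_MBq,
                 half_life_min = half_life_min,
                 tracer_amount_nmol = tracer_amount_nmol),
            class = "acquisition_meta")
}

# internal: geometric congruence of two grid-bearing objects
congruent_geometry <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "roi_mask")) dim(a$membership) else dim(a$values)
  db <- if (inherits(b, "roi_mask")) dim(b$membership) else dim(b$values)
  identical(da, db) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_congruent <- function(grid, mask) {
  if (!congruent_geometry(grid, mask))
    stop("shape mismatch: mask is not congruent with the image grid")
  invisible(TRUE)
}

#' Summary statistics of an image over a mask
#'
#' @param grid a [volume_grid()].
#' @param mask an [roi_mask()] congruent with `grid` and non-empty.
#' @return list with `mean` (mean voxel value over the mask),
#'   `voxel_count`, and `volume_mL` (count times voxel volume).
#' @export
mask_statistics <- function(grid, mask) {
  check_congruent(grid, mask)
  n <- sum(mask$membership)
  if (n == 0L) stop("empty mask")
  vox_mm3 <- prod(grid$spacing)
  list(mean = mean(grid$values[mask$membership]),
       voxel_count = n,
       volume_mL = n * vox_mm3 / 1000)
}

#' Nearest-neighbour resampling of a mask onto another grid
#'
#' Maps each target voxel centre to the nearest source voxel. Used to carry
#' CT-derived masks (lung ROI, density compartments) onto the coarser PET
#' grid; both grids must share the same world frame.
#'
#' @param mask an [roi_mask()].
#' @param to a [volume_grid()] (or `roi_mask`) defining the target geometry.
#' @return An [roi_mask()] on the target grid.
#' @export
resample_mask <- function(mask, to) {
  to_dim <- if (inherits(to, "roi_mask")) dim(to$membership) else dim(to$values)
  src_dim <- dim(mask$membership)
  idx <- lapply(1:3, function(ax) {
    w <- to$origin[ax] + (seq_len(to_dim[ax]) - 0.5) * to$spacing[ax]
    i <- floor((w - mask$origin[ax]) / mask$spacing[ax]) + 1L
    pmin(pmax(i, 1L), src_dim[ax])
  })
  memb <- mask$membership[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(memb) <- to_dim
  roi_mask(memb, spacing = to$spacing, origin = to$origin, label = mask$label)
}

# ---- NIfTI I/O with JSON sidecar --------------------------------------------

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a volume to NIfTI-1 with a JSON sidecar
#'
#' The image is written as a standard NIfTI-1 file readable by any viewer;
#' modality, units and (for PET) frame timing go into `<name>.json` next to
#' it rather than into header extensions.
#'
#' @param grid a [volume_grid()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  side <- list(modality = grid$modality,
               units = if (grid$modality == "CT") "HU" else "kBq/mL",
               origin_mm = grid$origin)
  if (grid$modality == "PET" && !is.null(grid$frame_start)) {
    side$frame_start_min <- grid$frame_start
    side$frame_duration_min <- grid$frame_duration
  }
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path a NIfTI-1 file with an accompanying `<name>.json` sidecar
#'   declaring the modality and, for PET, frame timing.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) != 3L) stop("non-3D image")
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing modality metadata (sidecar JSON): ", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(side$modality)) stop("sidecar lacks 'modality'")
  volume_grid(arr, spacing = RNifti::pixdim(img)[1:3],
              modality = side$modality,
              origin = if (!is.null(side$origin_mm)) side$origin_mm else c(0, 0, 0),
              frame_start = side$frame_start_min,
              frame_duration = side$frame_duration_min)
}

#' Write / read an ROI mask as uint8 NIfTI
#'
#' @param mask an [roi_mask()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path` (write) or an [roi_mask()] (read).
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$membership),
                               dim = dim(mask$membership)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  jsonlite::write_json(list(label = mask$label, origin_mm = mask$origin),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) != 3L) stop("non-3D image")
  label <- "roi"; origin <- c(0, 0, 0)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(side$label)) label <- side$label
    if (!is.null(side$origin_mm)) origin <- side$origin_mm
  }
  roi_mask(arr != 0, spacing = RNifti::pixdim(img)[1:3], origin = origin,
           label = label)
}
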