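# PET-side quantification: decay correction, %ID/g, compartmental uptake,
# time-activity curves (TACs) and window-averaged uptake.

#' Radioactive decay-correction factor
#'
#' Factor by which a measured activity must be multiplied to refer it back
#' to the injection time: `2^(elapsed / half_life)`.
#'
#' @param elapsed_min minutes elapsed since injection (>= 0).
#' @param half_life_min isotope half-life in minutes (> 0).
#' @return correction factor (>= 1).
#' @export
decay_factor <- function(elapsed_min, half_life_min) {
  if (half_life_min <= 0) stop("half_life_min must be positive")
  if (any(elapsed_min < 0)) stop("negative elapsed time")
  2^(elapsed_min / half_life_min)
}

frame_mid_time <- function(pet) {
  if (is.null(pet$frame_start) || is.null(pet$frame_duration))
    stop("missing frame timing on PET volume")
  pet$frame_start + pet$frame_duration / 2
}

#' Percent injected dose per gram over an ROI
#'
#' Decay-corrects the frame's voxel concentrations to injection time using
#' the frame mid-time, then converts the ROI mean to percent of injected
#' dose per gram of tissue:
#' `%ID/g = 100 x mean corrected concentration / (injected activity x density)`
#' (with concentration in kBq/mL and activity in MBq this is
#' `0.1 x mean_kBq_mL / (MBq x g/mL)`). The quantity is intensive: it does
#' not depend on voxel size for a uniform field.
#'
#' @param pet a PET [volume_grid()] with frame timing.
#' @param mask a non-empty [roi_mask()] congruent with `pet`.
#' @param meta an [acquisition_meta()].
#' @param density_g_per_mL tissue mass density used for the gram
#'   denominator; default 1.0.
#' @param decay_correct if `FALSE`, skip the physical-decay correction.
#' @return uptake in %ID/g.
#' @export
percent_id_per_gram <- function(pet, mask, meta, density_g_per_mL = 1.0,
                                decay_correct = TRUE) {
  if (pet$modality != "PET") stop("modality mismatch: expected a PET volume")
  if (meta$injected_activity_MBq <= 0) stop("nonpositive injected dose")
  stats <- mask_statistics(pet, mask)
  conc <- stats$mean
  if (decay_correct)
    conc <- conc * decay_factor(frame_mid_time(pet), meta$half_life_min)
  # kBq/mL over (MBq * g/mL): 100 * conc*1e3 / (inj*1e6 * density)
  100 * conc / (1000 * meta$injected_activity_MBq * density_g_per_mL)
}

#' HU-derived tissue density
#'
#' Mean mass density of an ROI estimated from CT attenuation as
#' `1 + HU/1000` g/mL (water = 0 HU = 1 g/mL), clamped below at 0.05 g/mL.
#' Can be passed as `density_g_per_mL` to [percent_id_per_gram()] when a
#' lung-realistic mass model is preferred over the unit-density default.
#'
#' @param ct a CT [volume_grid()].
#' @param mask a non-empty [roi_mask()] congruent with `ct`.
#' @return density in g/mL.
#' @export
hu_density <- function(ct, mask) {
  if (ct$modality != "CT") stop("modality mismatch: expected a CT volume")
  check_congruent(ct, mask)
  if (!any(mask$membership)) stop("empty mask")
  mean(pmax(1 + ct$values[mask$membership] / 1000, 0.05))
}

#' Compartmental uptake from a density segmentation
#'
#' %ID/g computed separately over the whole lung and the aerated and dense
#' CT compartments. Segmentation masks living on the (finer) CT grid are
#' brought onto the PET grid by nearest-neighbour resampling. An empty
#' dense compartment (no fibrotic tissue) yields `NA` for the dense uptake
#' — "no fibrotic tissue" is distinct from "no signal".
#'
#' @param pet a PET [volume_grid()] with frame timing.
#' @param seg a [segment_density()] result.
#' @param meta an [acquisition_meta()].
#' @param lung optional whole-lung [roi_mask()]; defaults to the union of
#'   the segmentation's three compartments.
#' @inheritParams percent_id_per_gram
#' @return An object of class `uptake_result` with `whole_lung`, `aerated`
#'   and `dense` %ID/g, the frame window, and the density used.
#' @export
compartment_uptake <- function(pet, seg, meta, lung = NULL,
                               density_g_per_mL = 1.0,
                               decay_correct = TRUE) {
  if (is.null(lung)) {
    lm <- seg$aerated$membership | seg$dense$membership |
      seg$excluded$membership
    lung <- roi_mask(lm, spacing = seg$aerated$spacing,
                     origin = seg$aerated$origin, label = "lung")
  }
  fit <- function(mask) {
    if (!congruent_geometry(pet, mask)) mask <- resample_mask(mask, pet)
    if (!any(mask$membership)) return(NA_real_)
    percent_id_per_gram(pet, mask, meta, density_g_per_mL, decay_correct)
  }
  structure(list(whole_lung = fit(lung), aerated = fit(seg$aerated),
                 dense = fit(seg$dense),
                 window = c(pet$frame_start,
                            pet$frame_start + pet$frame_duration),
                 decay_corrected = decay_correct,
                 tissue_density = density_g_per_mL),
            class = "uptake_result")
}

#' @export
print.uptake_result <- function(x, ...) {
  cat(sprintf("<uptake_result> window %g-%g min p.i.\n",
              x$window[1], x$window[2]))
  cat(sprintf("  whole lung %.4g | aerated %.4g | dense %.4g %%ID/g\n",
              x$whole_lung, x$aerated, x$dense))
  invisible(x)
}

#' Build a time-activity curve from a dynamic frame series
#'
#' One point per frame at the frame mid-time; uptake is that frame's
#' decay-corrected [percent_id_per_gram()] over the ROI.
#'
#' @param frames list of PET [volume_grid()] frames with strictly
#'   increasing timing.
#' @param mask ROI mask (resampled to the PET grid if needed).
#' @param meta an [acquisition_meta()].
#' @inheritParams percent_id_per_gram
#' @return An object of class `tac`: a data.frame with columns
#'   `mid_time_min` and `pct_id_per_g`, with the ROI label and
#'   decay-correction flag as attributes.
#' @export
build_tac <- function(frames, mask, meta, density_g_per_mL = 1.0,
                      decay_correct = TRUE) {
  if (length(frames) < 2L) stop("a TAC needs at least 2 frames")
  mids <- vapply(frames, frame_mid_time, numeric(1))
  if (any(diff(mids) <= 0)) stop("unordered frames")
  if (!congruent_geometry(frames[[1]], mask))
    mask <- resample_mask(mask, frames[[1]])
  up <- vapply(frames, percent_id_per_gram, numeric(1), mask = mask,
               meta = meta, density_g_per_mL = density_g_per_mL,
               decay_correct = decay_correct)
  structure(data.frame(mid_time_min = mids, pct_id_per_g = up),
            roi = mask$label, decay_corrected = decay_correct,
            class = c("tac", "data.frame"))
}

#' @export
plot.tac <- function(x, ...) {
  plot(x$mid_time_min, x$pct_id_per_g, type = "b", pch = 16,
       xlab = "time (min p.i.)", ylab = "%ID/g",
       main = paste0("TAC: ", attr(x, "roi")), ...)
  invisible(x)
}

#' Window-averaged uptake
#'
#' Frame-duration-weighted mean %ID/g over the frames whose mid-time lies
#' inside the uptake window (default 15-75 min post-injection, the late
#' window in which washout has completed and specific binding dominates).
#' With `mode = "endpoint"` the last in-window frame is used instead.
#'
#' @inheritParams build_tac
#' @param seg optional [segment_density()] result; when given, aerated and
#'   dense compartment uptakes are window-averaged too.
#' @param window numeric length-2, minutes post-injection.
#' @param mode `"mean"` (duration-weighted) or `"endpoint"`.
#' @return An `uptake_result` (see [compartment_uptake()]).
#' @export
window_uptake <- function(frames, mask, meta, seg = NULL,
                          window = c(15, 75), mode = c("mean", "endpoint"),
                          density_g_per_mL = 1.0, decay_correct = TRUE) {
  mode <- match.arg(mode)
  stopifnot(window[1] < window[2])
  mids <- vapply(frames, frame_mid_time, numeric(1))
  keep <- which(mids >= window[1] & mids <= window[2])
  if (!length(keep)) stop("no frames in window")
  if (mode == "endpoint") keep <- keep[length(keep)]
  durs <- vapply(frames[keep], function(f) f$frame_duration, numeric(1))
  w <- durs / sum(durs)
  one_roi <- function(m) {
    if (!congruent_geometry(frames[[keep[1]]], m))
      m <- resample_mask(m, frames[[keep[1]]])
    if (!any(m$membership)) return(NA_real_)
    v <- vapply(frames[keep], percent_id_per_gram, numeric(1), mask = m,
                meta = meta, density_g_per_mL = density_g_per_mL,
                decay_correct = decay_correct)
    sum(w * v)
  }
  structure(list(whole_lung = one_roi(mask),
                 aerated = if (!is.null(seg)) one_roi(seg$aerated) else NA_real_,
                 dense = if (!is.null(seg)) one_roi(seg$dense) else NA_real_,
                 window = window, decay_corrected = decay_correct,
                 tissue_density = density_g_per_mL),
            class = "uptake_result")
}

#' Earliest persistent divergence time of two TACs
#'
#' Scans two TACs sharing one mid-time grid for the earliest time `t*` from
#' which `tac_b - tac_a > tolerance` holds at every subsequent point. Used
#' to locate when a fibrotic lung curve separates from the control washout.
#'
#' @param tac_a,tac_b [build_tac()] results on identical mid-time grids.
#' @param tolerance minimum persistent excess, %ID/g.
#' @return divergence mid-time in minutes, or `NULL` if the curves never
#'   diverge persistently.
#' @export
tac_divergence <- function(tac_a, tac_b, tolerance = 0.5) {
  if (nrow(tac_a) != nrow(tac_b) ||
      any(abs(tac_a$mid_time_min - tac_b$mid_time_min) > 1e-9))
    stop("mismatched TAC time grids")
  above <- (tac_b$pct_id_per_g - tac_a$pct_id_per_g) > tolerance
  # earliest index from which `above` holds through the end
  ok <- rev(cumprod(rev(above))) == 1
  if (!any(ok)) return(NULL)
  tac_a$mid_time_min[which(ok)[1]]
}
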