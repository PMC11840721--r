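# Digital mouse-thorax phantom: CT morphology with controllable fibrotic
# burden, and a two-term tracer kinetic model (perfusion washout plus
# saturating collagen-specific binding) driving dynamic PET rendering.

#' Phantom configuration
#'
#' Geometry and tissue parameters of the digital thorax. CT is simulated on
#' a fine grid and PET on a coarser grid sharing the same field of view
#' (hardware co-registration). Hounsfield-unit (HU) tissue distributions
#' follow the conventional lung-density bands: aerated lung in
#' `(-800, -100)` HU, fibrotic consolidation in `(-100, 300)` HU.
#'
#' @param grid_shape CT grid dimensions (voxels).
#' @param spacing CT voxel size, mm.
#' @param pet_shape,pet_spacing PET grid dimensions and voxel size, mm; the
#'   defaults cover the same 16 mm field of view as the CT grid.
#' @param lung_volume_mL total lung volume target (both lungs).
#' @param aerated_hu_mean,aerated_hu_sd HU distribution of aerated lung.
#' @param dense_hu_mean,dense_hu_sd HU distribution of consolidations.
#' @param body_hu_mean,body_hu_sd HU distribution of the soft-tissue body
#'   shell.
#' @param air_hu HU assigned outside the body.
#' @param lesion_radius_mm min/max radius of spherical consolidation blobs.
#' @param body_blood_scale blood-pool perfusion amplitude of the body shell
#'   relative to the lung perfusion amplitude.
#' @param sensitivity detector sensitivity used for Poisson noise, in
#'   expected counts per kBq per minute in one voxel volume.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(40L, 40L, 40L),
                           spacing = c(0.4, 0.4, 0.4),
                           pet_shape = c(20L, 20L, 20L),
                           pet_spacing = c(0.8, 0.8, 0.8),
                           lung_volume_mL = 0.25,
                           aerated_hu_mean = -650, aerated_hu_sd = 80,
                           dense_hu_mean = 60, dense_hu_sd = 60,
                           body_hu_mean = 40, body_hu_sd = 20,
                           air_hu = -1000,
                           lesion_radius_mm = c(0.6, 1.8),
                           body_blood_scale = 0.6,
                           sensitivity = 2e4) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            all(spacing > 0), all(pet_spacing > 0),
            lung_volume_mL > 0, length(lesion_radius_mm) == 2L,
            lesion_radius_mm[1] > 0,
            lesion_radius_mm[2] >= lesion_radius_mm[1])
  if (aerated_hu_mean <= -800 || aerated_hu_mean >= -100)
    stop("aerated_hu_mean must lie inside the aerated band (-800, -100)")
  if (dense_hu_mean <= -100 || dense_hu_mean >= 300)
    stop("dense_hu_mean must lie inside the dense band (-100, 300)")
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 pet_shape = as.integer(pet_shape), pet_spacing = pet_spacing,
                 lung_volume_mL = lung_volume_mL,
                 aerated_hu_mean = aerated_hu_mean,
                 aerated_hu_sd = aerated_hu_sd,
                 dense_hu_mean = dense_hu_mean, dense_hu_sd = dense_hu_sd,
                 body_hu_mean = body_hu_mean, body_hu_sd = body_hu_sd,
                 air_hu = air_hu, lesion_radius_mm = lesion_radius_mm,
                 body_blood_scale = body_blood_scale,
                 sensitivity = sensitivity),
            class = "phantom_config")
}

#' Tracer kinetic parameters
#'
#' Decay-free lung concentration model, per unit injected activity:
#' \deqn{C(t) = A e^{-\alpha t} + C_0 + f\,B\,b\,(1 - e^{-\beta t})}
#' where `b` is the local collagen burden (0 in healthy aerated tissue) and
#' `f` the blocking factor. The first term is perfusion-driven washout, the
#' constant is a nonspecific baseline, and the saturating term is specific
#' collagen binding. The default washout rate satisfies
#' `exp(-washout_rate * 12) = 0.05`: the perfusion signal has decayed to 5%
#' by 12 min post-injection, after which curves of healthy and fibrotic
#' lungs separate. Measured (acquired) activity additionally decays
#' physically as `2^(-t / half_life)`.
#'
#' @param perfusion_amplitude `A`, kBq/mL per MBq injected.
#' @param washout_rate `alpha`, 1/min.
#' @param binding_amplitude `B`, kBq/mL per MBq per unit collagen burden.
#' @param binding_rate `beta`, 1/min.
#' @param baseline `C0`, kBq/mL per MBq: nonspecific background.
#' @param blocking_factor `f` in `[0, 1]`: fraction of specific binding
#'   remaining; 1 = no blocking, 0.1 emulates a x100 cold-peptide excess.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(perfusion_amplitude = 100,
                           washout_rate = log(20) / 12,
                           binding_amplitude = 100,
                           binding_rate = 0.08,
                           baseline = 1.0,
                           blocking_factor = 1.0) {
  stopifnot(perfusion_amplitude > 0, washout_rate > 0, binding_rate > 0,
            binding_amplitude >= 0, baseline >= 0,
            blocking_factor >= 0, blocking_factor <= 1)
  structure(list(perfusion_amplitude = perfusion_amplitude,
                 washout_rate = washout_rate,
                 binding_amplitude = binding_amplitude,
                 binding_rate = binding_rate, baseline = baseline,
                 blocking_factor = blocking_factor),
            class = "kinetic_params")
}

# voxel-centre coordinate arrays for a grid
coord_arrays <- function(shape, spacing, origin = c(0, 0, 0)) {
  x <- origin[1] + (seq_len(shape[1]) - 0.5) * spacing[1]
  y <- origin[2] + (seq_len(shape[2]) - 0.5) * spacing[2]
  z <- origin[3] + (seq_len(shape[3]) - 0.5) * spacing[3]
  list(X = array(x, dim = shape),
       Y = array(rep(y, each = shape[1]), dim = shape),
       Z = array(rep(z, each = shape[1] * shape[2]), dim = shape))
}

#' Build one thorax CT with a target fibrotic burden
#'
#' Renders an air background, a soft-tissue body cylinder and two
#' ellipsoidal lungs, then inserts spherical consolidation blobs until the
#' fraction of lung voxels carrying dense-band HU is within 0.02 of
#' `burden`. Each blob receives one HU value drawn from the consolidation
#' distribution (truncated to stay inside the dense band); the ground-truth
#' collagen burden of a lesion voxel is proportional to its HU excess over
#' -100 HU, zero elsewhere, so tracer binding co-localises with density by
#' construction.
#'
#' @param config a [phantom_config()].
#' @param burden target fibrosis fraction of the lung volume, in `[0, 0.8]`.
#' @param seed integer seed for reproducible rendering, or `NULL` to use
#'   the ambient RNG stream.
#' @param noise `"gaussian"` adds voxelwise HU texture (aerated sd from the
#'   config, half the consolidation sd within lesions); `"none"` renders
#'   the structural values only.
#' @return list with `ct` (a [volume_grid()]), `lung` (an [roi_mask()]) and
#'   `truth` (class `ground_truth`: achieved `fibrosis_fraction`, voxelwise
#'   `collagen` burden map, `mean_burden` over the lung, and the `body`
#'   mask used for PET background rendering).
#' @export
build_thorax_ct <- function(config = phantom_config(), burden = 0,
                            seed = NULL, noise = c("gaussian", "none")) {
  noise <- match.arg(noise)
  if (burden < 0 || burden > 0.8)
    stop("burden must lie in [0, 0.8]")
  with_seed(seed, {
    shape <- config$grid_shape; sp <- config$spacing
    ext <- shape * sp; ctr <- ext / 2
    cc <- coord_arrays(shape, sp)
    body <- ((cc$X - ctr[1])^2 + (cc$Y - ctr[2])^2) <=
      (0.42 * min(ext[1], ext[2]))^2

    # two ellipsoidal lungs, semi-axis ratio 1 : 1.2 : 2, sized to the
    # volume target
    r0 <- (config$lung_volume_mL / 2 * 1000 * 3 / (4 * pi * 1.2 * 2))^(1 / 3)
    ax <- r0 * c(1, 1.2, 2)
    dx <- 0.21 * ext[1]
    lungL <- ((cc$X - (ctr[1] - dx)) / ax[1])^2 +
      ((cc$Y - ctr[2]) / ax[2])^2 + ((cc$Z - ctr[3]) / ax[3])^2 <= 1
    lungR <- ((cc$X - (ctr[1] + dx)) / ax[1])^2 +
      ((cc$Y - ctr[2]) / ax[2])^2 + ((cc$Z - ctr[3]) / ax[3])^2 <= 1
    lung <- (lungL | lungR) & body
    n_lung <- sum(lung)
    if (n_lung < 50) stop("lung volume target too small for this grid")

    hu <- array(config$air_hu, dim = shape)
    hu[body] <- config$body_hu_mean
    hu[lung] <- config$aerated_hu_mean

    lesion <- array(FALSE, dim = shape)
    vox_mm3 <- prod(sp)
    if (burden > 0) {
      lung_idx <- which(lung)
      attempts <- 0L
      repeat {
        frac <- sum(lesion) / n_lung
        if (frac >= burden - 0.01) break
        attempts <- attempts + 1L
        if (attempts > 3000L)
          stop("unreachable fibrosis target after bounded placement attempts")
        remaining <- (burden - frac) * n_lung
        r_mm <- stats::runif(1, config$lesion_radius_mm[1],
                             config$lesion_radius_mm[2])
        # shrink candidate blobs so the target is approached, not overshot
        r_cap <- (remaining * 1.2 * vox_mm3 * 3 / (4 * pi))^(1 / 3)
        r_mm <- max(min(r_mm, r_cap), 0.75 * min(sp))
        ci <- arrayInd(sample(lung_idx, 1L), shape)
        cw <- (as.numeric(ci) - 0.5) * sp
        lo <- pmax(floor((cw - r_mm) / sp), 1)
        hi <- pmin(ceiling((cw + r_mm) / sp) + 1, shape)
        ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
        bx <- (ii - 0.5) * sp[1] - cw[1]
        by <- (jj - 0.5) * sp[2] - cw[2]
        bz <- (kk - 0.5) * sp[3] - cw[3]
        inside <- outer(outer(bx^2, by^2, "+"), bz^2, "+") <= r_mm^2
        sub_lung <- lung[ii, jj, kk, drop = FALSE]
        sub_les <- lesion[ii, jj, kk, drop = FALSE]
        new_vox <- inside & sub_lung & !sub_les
        n_new <- sum(new_vox)
        if (n_new == 0L) next
        if (frac + n_new / n_lung > burden + 0.015) next
        blob_hu <- rnorm_trunc(1, config$dense_hu_mean, config$dense_hu_sd,
                               -40, 240)
        sub_hu <- hu[ii, jj, kk, drop = FALSE]
        sub_hu[new_vox] <- blob_hu
        hu[ii, jj, kk] <- sub_hu
        sub_les[new_vox] <- TRUE
        lesion[ii, jj, kk] <- sub_les
      }
    }
    achieved <- sum(lesion) / n_lung
    if (abs(achieved - burden) > 0.02)
      stop("unreachable fibrosis target: achieved ", round(achieved, 3))

    collagen <- array(0, dim = shape)
    collagen[lesion] <- pmax(hu[lesion] + 100, 0) / 200

    if (noise == "gaussian") {
      nz <- stats::rnorm(length(hu))
      sdmap <- array(0, dim = shape)
      sdmap[body] <- config$body_hu_sd
      sdmap[lung] <- config$aerated_hu_sd
      sdmap[lesion] <- config$dense_hu_sd / 2
      hu <- hu + nz * sdmap
    }
    hu <- pmin(pmax(hu, -1024), 3071)

    ct <- volume_grid(hu, spacing = sp, modality = "CT")
    lung_mask <- roi_mask(lung, spacing = sp, label = "lung")
    truth <- structure(
      list(fibrosis_fraction = achieved, collagen = collagen,
           mean_burden = sum(collagen) / n_lung,
           body = roi_mask(body, spacing = sp, label = "body"),
           spacing = sp, origin = c(0, 0, 0)),
      class = "ground_truth")
    list(ct = ct, lung = lung_mask, truth = truth)
  })
}

#' Decay-free lung tracer concentration
#'
#' Evaluates the kinetic model of [kinetic_params()] at times `t_min`
#' (minutes post-injection) for a voxel/region collagen burden. The
#' physically measured concentration is this value times
#' `2^(-t / half_life)`.
#'
#' @param t_min vector of times, minutes post-injection (all >= 0).
#' @param kinetics a [kinetic_params()].
#' @param burden scalar collagen burden.
#' @param meta an [acquisition_meta()] supplying the injected activity.
#' @return concentration in kBq/mL, same length as `t_min`.
#' @export
lung_concentration <- function(t_min, kinetics, burden,
                               meta = acquisition_meta()) {
  if (any(t_min < 0)) stop("negative time")
  k <- kinetics
  meta$injected_activity_MBq *
    (k$perfusion_amplitude * exp(-k$washout_rate * t_min) + k$baseline +
       k$blocking_factor * k$binding_amplitude * burden *
         (1 - exp(-k$binding_rate * t_min)))
}

# average of exp(-r t) over [t0, t1]
exp_avg <- function(r, t0, t1) {
  (exp(-r * t0) - exp(-r * t1)) / (r * (t1 - t0))
}

#' Frame-averaged tracer concentration (closed form)
#'
#' Analytic time-average of the kinetic model over a PET frame
#' `[start, start + duration)`, either decay-free or as physically measured
#' (decayed with the isotope half-life). This is the rendering primitive of
#' [render_pet_series()] and the independent closed-form oracle for
#' end-to-end quantification checks. Vectorised over `burden`.
#'
#' @param frame_start,frame_duration frame timing, minutes post-injection.
#' @param kinetics a [kinetic_params()].
#' @param burden collagen burden value(s).
#' @param meta an [acquisition_meta()].
#' @param decayed if `TRUE` (default) return the measured concentration
#'   including physical decay.
#' @return concentration(s) in kBq/mL.
#' @export
frame_average_concentration <- function(frame_start, frame_duration,
                                        kinetics, burden,
                                        meta = acquisition_meta(),
                                        decayed = TRUE) {
  stopifnot(frame_start >= 0, frame_duration > 0)
  k <- kinetics
  t0 <- frame_start; t1 <- frame_start + frame_duration
  spec <- k$blocking_factor * k$binding_amplitude * burden
  if (decayed) {
    lam <- log(2) / meta$half_life_min
    meta$injected_activity_MBq *
      (k$perfusion_amplitude * exp_avg(k$washout_rate + lam, t0, t1) +
         (k$baseline + spec) * exp_avg(lam, t0, t1) -
         spec * exp_avg(k$binding_rate + lam, t0, t1))
  } else {
    meta$injected_activity_MBq *
      (k$perfusion_amplitude * exp_avg(k$washout_rate, t0, t1) +
         k$baseline + spec * (1 - exp_avg(k$binding_rate, t0, t1)))
  }
}

#' Dynamic and static PET frame schedules
#'
#' `dynamic_frame_schedule()` reproduces a dynamic acquisition reconstructed
#' in 2-minute intervals from 2 to 75 minutes post-injection: 37 contiguous
#' frames with mid-times 3, 5, ..., 75 min. `static_frame_schedule()`
#' covers an uptake window (default 15-75 min p.i.) with a few longer
#' frames, matching a static late acquisition.
#'
#' @param start,end,duration dynamic schedule bounds and frame length, min.
#' @param window static window, min p.i.
#' @param n_frames number of equal frames covering the window.
#' @return data.frame with columns `start` and `duration` (minutes p.i.).
#' @export
dynamic_frame_schedule <- function(start = 2, end = 76, duration = 2) {
  starts <- seq(start, end - duration, by = duration)
  data.frame(start = starts, duration = duration)
}

#' @rdname dynamic_frame_schedule
#' @export
static_frame_schedule <- function(window = c(15, 75), n_frames = 6) {
  d <- (window[2] - window[1]) / n_frames
  data.frame(start = window[1] + (seq_len(n_frames) - 1) * d, duration = d)
}

check_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule), all(c("start", "duration") %in%
                                           names(schedule)))
  if (nrow(schedule) > 1) {
    ends <- schedule$start + schedule$duration
    if (any(diff(schedule$start) <= 0))
      stop("frame schedule must be strictly increasing")
    if (any(schedule$start[-1] < ends[-nrow(schedule)] - 1e-9))
      stop("overlapping frames")
  }
  invisible(schedule)
}

#' Render a dynamic PET series from phantom ground truth
#'
#' Each frame holds, per voxel, the frame-averaged *measured* (physically
#' decayed) concentration for that voxel's collagen burden; the body shell
#' outside the lungs carries a blood-pool curve (perfusion amplitude scaled
#' by the config's `body_blood_scale`, no specific binding). With
#' `noise = "poisson"`, expected counts per voxel are
#' `concentration x voxel volume x sensitivity x frame duration`; a Poisson
#' draw is converted back to concentration.
#'
#' @param truth `ground_truth` from [build_thorax_ct()].
#' @param lung lung [roi_mask()] on the CT grid.
#' @param kinetics a [kinetic_params()].
#' @param meta an [acquisition_meta()].
#' @param frame_schedule data.frame from [dynamic_frame_schedule()] or
#'   [static_frame_schedule()].
#' @param noise `"none"` or `"poisson"`.
#' @param seed reproducibility seed or `NULL`.
#' @param config the [phantom_config()] supplying the PET grid geometry and
#'   detector sensitivity.
#' @return list of PET [volume_grid()] frames.
#' @export
render_pet_series <- function(truth, lung, kinetics,
                              meta = acquisition_meta(),
                              frame_schedule = dynamic_frame_schedule(),
                              noise = c("none", "poisson"), seed = NULL,
                              config = phantom_config()) {
  noise <- match.arg(noise)
  check_schedule(frame_schedule)
  with_seed(seed, {
    pet_ref <- volume_grid(array(0, dim = config$pet_shape),
                           spacing = config$pet_spacing, modality = "PET",
                           origin = truth$origin)
    # nearest-neighbour pull of the CT-grid burden map onto the PET grid
    src_dim <- dim(truth$collagen)
    idx <- lapply(1:3, function(ax) {
      w <- truth$origin[ax] +
        (seq_len(config$pet_shape[ax]) - 0.5) * config$pet_spacing[ax]
      i <- floor((w - truth$origin[ax]) / truth$spacing[ax]) + 1L
      pmin(pmax(i, 1L), src_dim[ax])
    })
    burden_pet <- truth$collagen[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(burden_pet) <- config$pet_shape
    lung_pet <- resample_mask(lung, pet_ref)$membership
    body_pet <- resample_mask(truth$body, pet_ref)$membership & !lung_pet

    blood_kin <- kinetics
    blood_kin$perfusion_amplitude <-
      kinetics$perfusion_amplitude * config$body_blood_scale
    blood_kin$binding_amplitude <- 0

    vox_mL <- prod(config$pet_spacing) / 1000
    lapply(seq_len(nrow(frame_schedule)), function(f) {
      t0 <- frame_schedule$start[f]; dur <- frame_schedule$duration[f]
      vals <- array(0, dim = config$pet_shape)
      vals[lung_pet] <- frame_average_concentration(
        t0, dur, kinetics, burden_pet[lung_pet], meta, decayed = TRUE)
      vals[body_pet] <- frame_average_concentration(
        t0, dur, blood_kin, 0, meta, decayed = TRUE)
      if (noise == "poisson") {
        lam <- vals * vox_mL * config$sensitivity * dur
        pos <- lam > 0
        vals[pos] <- stats::rpois(sum(pos), lam[pos]) /
          (vox_mL * config$sensitivity * dur)
      }
      volume_grid(vals, spacing = config$pet_spacing, modality = "PET",
                  origin = truth$origin, frame_start = t0,
                  frame_duration = dur)
    })
  })
}
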