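# Study design and cohort simulation: virtual animals imaged longitudinally
# with per-subject random effects on the fibrotic-burden trajectory.

default_trajectories <- function() {
  m <- rbind(
    "NaCl"            = c(0, 0.00, 0.00, 0.00),
    "BLM"             = c(0, 0.15, 0.25, 0.35),
    "BLM+nintedanib"  = c(0, 0.15, 0.13, 0.10),
    "BLM+tofacitinib" = c(0, 0.15, 0.16, 0.11),
    "BLM+blocking"    = c(0, 0.15, 0.25, 0.35))
  colnames(m) <- c("D0", "D8", "D15", "D22")
  m
}

#' Longitudinal study design
#'
#' Group sizes, imaging schedule and per-group fibrosis-fraction
#' trajectories of the simulated bleomycin study. Defaults follow the
#' five-arm design: saline controls; bleomycin with progressive fibrosis
#' from day 8 to day 22; two treated arms that share the bleomycin
#' trajectory up to day 8 (treatment start) and then regress, with
#' nintedanib acting earlier (day 15) than tofacitinib (day 22); and a
#' blocking arm that is fibrotic like the bleomycin arm but imaged under a
#' x100 cold-peptide excess, leaving a fraction `blocking_factor` of
#' specific binding.
#'
#' @param groups named integer vector of group sizes.
#' @param timepoints imaging days, strictly increasing.
#' @param trajectories matrix (group x timepoint) of target fibrosis
#'   fractions in `[0, 0.8]`.
#' @param subject_sd sd (log scale) of the per-subject lognormal burden
#'   multiplier; creates inter-animal variability.
#' @param blocking_factor fraction of specific binding remaining in the
#'   blocking arm.
#' @param frame_schedule PET frame schedule used at each timepoint; the
#'   default static schedule covers the 15-75 min p.i. uptake window.
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups = c("NaCl" = 4, "BLM" = 4,
                                    "BLM+nintedanib" = 4,
                                    "BLM+tofacitinib" = 4,
                                    "BLM+blocking" = 4),
                         timepoints = c(0, 8, 15, 22),
                         trajectories = default_trajectories(),
                         subject_sd = 0.25,
                         blocking_factor = 0.1,
                         frame_schedule = static_frame_schedule()) {
  stopifnot(all(groups >= 1), all(diff(timepoints) > 0))
  trajectories <- trajectories[names(groups), , drop = FALSE]
  if (ncol(trajectories) != length(timepoints))
    stop("trajectories must have one column per timepoint")
  if (any(trajectories < 0) || any(trajectories > 0.8))
    stop("trajectories must lie within [0, 0.8]")
  check_schedule(frame_schedule)
  structure(list(groups = groups, timepoints = timepoints,
                 trajectories = trajectories, subject_sd = subject_sd,
                 blocking_factor = blocking_factor,
                 frame_schedule = frame_schedule),
            class = "study_design")
}

#' Simulate a longitudinal phantom cohort
#'
#' For every virtual animal and study day: a thorax CT at the trajectory's
#' fibrotic burden (scaled by the subject's lognormal random effect), the
#' lung mask and ground truth, a rendered PET frame series, acquisition
#' metadata (5 MBq injected, gallium-68 half-life), and a synthetic
#' biodistribution table. The blocking arm is rendered with the design's
#' `blocking_factor` on specific binding. Identical
#' (design, config, kinetics, seed) inputs reproduce the cohort exactly.
#'
#' @param design a [study_design()].
#' @param config a [phantom_config()].
#' @param kinetics a [kinetic_params()].
#' @param seed integer seed, or `NULL` for the ambient RNG stream.
#' @param meta an [acquisition_meta()].
#' @param biodist a [biodist_params()].
#' @param ct_noise,pet_noise noise modes for [build_thorax_ct()] and
#'   [render_pet_series()].
#' @return An object of class `fibropet_cohort`: a list of subject records
#'   plus the design/config/kinetics used. Each subject record holds
#'   `subject_id`, `group`, `burden_multiplier`, and one entry per
#'   timepoint (`ct`, `lung`, `truth`, `frames`, `meta`, `biodist`).
#' @export
simulate_cohort <- function(design = study_design(),
                            config = phantom_config(),
                            kinetics = kinetic_params(),
                            seed = NULL,
                            meta = acquisition_meta(),
                            biodist = biodist_params(),
                            ct_noise = c("gaussian", "none"),
                            pet_noise = c("poisson", "none")) {
  ct_noise <- match.arg(ct_noise); pet_noise <- match.arg(pet_noise)
  with_seed(seed, {
    subjects <- list()
    for (g in names(design$groups)) {
      kin_g <- kinetics
      if (g == "BLM+blocking")
        kin_g$blocking_factor <- design$blocking_factor
      for (s in seq_len(design$groups[[g]])) {
        sid <- sprintf("%s_%02d", g, s)
        mult <- stats::rlnorm(1, 0, design$subject_sd)
        tps <- list()
        for (ti in seq_along(design$timepoints)) {
          day <- design$timepoints[ti]
          burden <- min(design$trajectories[g, ti] * mult, 0.8)
          ph <- build_thorax_ct(config, burden, seed = NULL,
                                noise = ct_noise)
          frames <- render_pet_series(ph$truth, ph$lung, kin_g, meta,
                                      design$frame_schedule,
                                      noise = pet_noise, seed = NULL,
                                      config = config)
          up <- window_uptake(frames, ph$lung, meta)$whole_lung
          bd <- synthesize_biodist_core(g, up, sid, day, biodist)
          tps[[paste0("D", day)]] <-
            list(day = day, ct = ph$ct, lung = ph$lung, truth = ph$truth,
                 frames = frames, meta = meta, biodist = bd)
        }
        subjects[[sid]] <- list(subject_id = sid, group = g,
                                burden_multiplier = mult,
                                timepoints = tps)
      }
    }
    structure(list(subjects = subjects, design = design, config = config,
                   kinetics = kinetics),
              class = "fibropet_cohort")
  })
}

#' @export
print.fibropet_cohort <- function(x, ...) {
  cat(sprintf("<fibropet_cohort> %d subjects in %d groups, days %s\n",
              length(x$subjects), length(x$design$groups),
              paste(x$design$timepoints, collapse = ", ")))
  invisible(x)
}

#' Quantify every subject and timepoint of a simulated cohort
#'
#' Runs the full imaging pipeline per subject-timepoint: CT density
#' segmentation, mean lung density, window-averaged whole-lung and
#' compartmental %ID/g, biodistribution ratios and the elimination metric.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param thresholds a [density_thresholds()].
#' @param window uptake window in minutes p.i.
#' @return data.frame with one row per subject-timepoint and columns
#'   `subject_id`, `group`, `day`, `uptake` (whole-lung %ID/g), `aerated`,
#'   `dense` (compartment %ID/g), `mld` (HU), `fibrosis_fraction`
#'   (CT-estimated), `true_fibrosis_fraction`, `lung_to_blood`,
#'   `lung_to_muscle`, `excreted_pct_id`.
#' @export
quantify_cohort <- function(cohort, thresholds = density_thresholds(),
                            window = c(15, 75)) {
  rows <- lapply(cohort$subjects, function(sub) {
    do.call(rbind, lapply(sub$timepoints, function(tp) {
      seg <- segment_density(tp$ct, tp$lung, thresholds)
      ctr <- ct_result(seg, tp$ct, tp$lung)
      up <- window_uptake(tp$frames, tp$lung, tp$meta, seg = seg,
                          window = window)
      rat <- tissue_ratios(tp$biodist)
      data.frame(subject_id = sub$subject_id, group = sub$group,
                 day = tp$day, uptake = up$whole_lung,
                 aerated = up$aerated, dense = up$dense,
                 mld = ctr$mean_lung_density,
                 fibrosis_fraction = ctr$fibrosis_fraction,
                 true_fibrosis_fraction = tp$truth$fibrosis_fraction,
                 lung_to_blood = rat$lung_to_blood,
                 lung_to_muscle = rat$lung_to_muscle,
                 excreted_pct_id = elimination_metric(tp$biodist))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
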