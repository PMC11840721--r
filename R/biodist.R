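# Ex vivo biodistribution: synthetic gamma-counting organ tables, tissue
# ratios and the urinary elimination metric.

#' Biodistribution synthesis parameters
#'
#' Reference organ %ID/g values for a renally cleared peptide tracer at
#' sacrifice (~75-90 min post-injection) in a healthy mouse, nominal organ
#' masses used to interconvert %ID/g and %ID, multiplicative effects of the
#' fibrotic (bleomycin) state, and the lognormal measurement noise.
#' Kidneys carry the highest organ concentration (renal elimination route);
#' the synthesizer enforces this ordering even under noise.
#'
#' @param reference_pct_id_g named numeric: control %ID/g per organ
#'   (lungs are driven by the imaging-derived uptake instead).
#' @param organ_mass_g named numeric: nominal mouse organ masses, grams.
#' @param blm_multipliers named numeric: factors (> 1) applied to blood,
#'   heart and lungs in fibrotic animals.
#' @param excreted_control %ID eliminated in urine in controls.
#' @param excreted_blm_factor multiplier (< 1) on the excreted fraction in
#'   fibrotic animals (elimination is slowed).
#' @param noise_sdlog lognormal sd of the per-organ measurement noise.
#' @return An object of class `biodist_params`.
#' @export
biodist_params <- function(
    reference_pct_id_g = c(kidneys = 20, bladder_urine = 12, liver = 1.2,
                           spleen = 0.8, blood = 0.3, heart = 0.25,
                           muscle = 0.08),
    organ_mass_g = c(lungs = 0.15, kidneys = 0.4, bladder_urine = 0.5,
                     liver = 1.3, spleen = 0.1, blood = 1.8, heart = 0.15,
                     muscle = 8.0),
    blm_multipliers = c(blood = 2.0, heart = 1.8, lungs = 1.1),
    excreted_control = 60, excreted_blm_factor = 0.75,
    noise_sdlog = 0.15) {
  stopifnot(all(reference_pct_id_g >= 0), all(organ_mass_g > 0),
            all(blm_multipliers >= 1),
            excreted_control >= 0, excreted_control <= 100,
            excreted_blm_factor > 0, excreted_blm_factor <= 1,
            noise_sdlog >= 0)
  structure(list(reference_pct_id_g = reference_pct_id_g,
                 organ_mass_g = organ_mass_g,
                 blm_multipliers = blm_multipliers,
                 excreted_control = excreted_control,
                 excreted_blm_factor = excreted_blm_factor,
                 noise_sdlog = noise_sdlog),
            class = "biodist_params")
}

# core synthesis from a group label and the imaging-derived lung uptake;
# assumes the caller manages the RNG stream
synthesize_biodist_core <- function(group, lung_uptake, subject_id,
                                    timepoint, params = biodist_params()) {
  p <- params
  fibrotic <- group != "NaCl"
  organs <- p$reference_pct_id_g
  organs["lungs"] <- lung_uptake
  if (fibrotic) {
    for (o in names(p$blm_multipliers))
      organs[o] <- organs[o] * p$blm_multipliers[o]
  }
  excreted <- p$excreted_control * if (fibrotic) p$excreted_blm_factor else 1
  if (p$noise_sdlog > 0) {
    organs <- organs * stats::rlnorm(length(organs), 0, p$noise_sdlog)
    excreted <- excreted * stats::rlnorm(1, 0, p$noise_sdlog / 2)
  }
  # renal elimination route: kidneys stay the hottest organ
  other <- setdiff(names(organs), "kidneys")
  organs[other] <- pmin(organs[other], 0.95 * organs[["kidneys"]])
  excreted <- min(excreted, 100)
  # %ID bookkeeping: tabulated organs plus urine must not exceed the dose
  organ_pct_id <- organs * p$organ_mass_g[names(organs)]
  total <- sum(organ_pct_id) + excreted
  if (total > 100) organs <- organs * (100 - excreted) / sum(organ_pct_id)
  structure(list(organs_pct_id_g = organs, excreted_percent_id = excreted,
                 subject_id = subject_id, group = group,
                 timepoint = timepoint),
            class = "biodistribution_table")
}

#' Synthesize an ex vivo biodistribution table for one subject/timepoint
#'
#' Emulates gamma-counting of harvested organs: kidneys dominate (renal
#' elimination), the lung value is proportional to the imaging-derived
#' window uptake, fibrotic animals show elevated blood/heart/lung values
#' and a reduced urinary elimination fraction, and every organ carries
#' lognormal measurement noise.
#'
#' @param subject a subject record from [simulate_cohort()].
#' @param timepoint study day (must exist in the record).
#' @param seed reproducibility seed or `NULL`.
#' @param params a [biodist_params()].
#' @param window uptake window passed to [window_uptake()].
#' @return An object of class `biodistribution_table`.
#' @export
synthesize_biodistribution <- function(subject, timepoint, seed = NULL,
                                       params = biodist_params(),
                                       window = c(15, 75)) {
  tp <- subject$timepoints[[paste0("D", timepoint)]]
  if (is.null(tp)) stop("missing ground truth for timepoint D", timepoint)
  up <- window_uptake(tp$frames, tp$lung, tp$meta, window = window)$whole_lung
  with_seed(seed,
    synthesize_biodist_core(subject$group, up, subject$subject_id,
                            timepoint, params))
}

#' @export
print.biodistribution_table <- function(x, ...) {
  cat(sprintf("<biodistribution_table> %s (%s) D%s\n",
              x$subject_id, x$group, x$timepoint))
  print(round(x$organs_pct_id_g, 3))
  cat(sprintf("  excreted: %.1f %%ID\n", x$excreted_percent_id))
  invisible(x)
}

#' Lung-to-reference tissue ratios
#'
#' @param table a `biodistribution_table`.
#' @return list with `lung_to_blood` and `lung_to_muscle`.
#' @export
tissue_ratios <- function(table) {
  o <- table$organs_pct_id_g
  if (is.na(o["blood"]) || o["blood"] <= 0 ||
      is.na(o["muscle"]) || o["muscle"] <= 0)
    stop("zero denominator: blood and muscle values must be positive")
  list(lung_to_blood = unname(o["lungs"] / o["blood"]),
       lung_to_muscle = unname(o["lungs"] / o["muscle"]))
}

#' Urinary elimination metric
#'
#' The %ID excreted in urine at sacrifice — the operational definition of
#' tracer elimination used for group comparisons.
#'
#' @param table a `biodistribution_table`.
#' @return excreted %ID.
#' @export
elimination_metric <- function(table) {
  if (is.null(table$excreted_percent_id)) stop("missing excreted fraction")
  table$excreted_percent_id
}
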