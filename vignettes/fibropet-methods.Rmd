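---
title: "Methods: phantom, kinetic model and quantification conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom, kinetic model and quantification conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibropet)
```

# Scope

`fibropet` quantifies collagen-targeted PET/CT in the bleomycin (BLM)
mouse model of lung fibrosis: CT density segmentation, decay-corrected
%ID/g uptake, time-activity curve (TAC) analysis, biodistribution ratios,
and the nonparametric longitudinal statistics of a therapy-monitoring
study. Because the package is validated on synthetic data, this vignette
documents precisely what the digital phantom emulates, what it does not,
and every numerical convention the quantification relies on.

# The digital thorax phantom

## CT morphology

`build_thorax_ct()` renders, on a 40³ grid of 0.4 mm voxels (16 mm field
of view), an air background (−1000 HU), a soft-tissue body cylinder
(40 ± 20 HU) and two ellipsoidal lungs (semi-axis ratio 1 : 1.2 : 2)
sized to a 0.25 mL total volume — typical of an adult mouse. Aerated lung
tissue carries −650 ± 80 HU and fibrotic consolidations 60 ± 60 HU,
placing the two tissues well inside the conventional aerated
(`[-800, -100)` HU) and dense (`[-100, 300]` HU) bands.

Consolidations are spherical blobs (radius 0.6–1.8 mm) placed at random
lung locations until the lesion fraction of lung voxels is within 0.01 of
the target `burden`; candidate radii shrink as the target is approached so
it is never overshot by more than 0.015, and an unreachable target is an
error rather than a silent miss. Each blob receives a single HU value
drawn from the consolidation distribution truncated to [−40, 240] — the
truncation keeps noisy lesion voxels inside the dense band with high
probability, so density segmentation recovers the ground-truth fraction
within ±0.02 noise-free and ±0.05 under default noise. With
`noise = "gaussian"`, voxelwise texture is added on top of the structure
(full aerated/body sd; half the consolidation sd inside lesions, since the
blob-level draw already carries between-lesion variability).

The ground-truth collagen burden of a lesion voxel is proportional to its
HU excess over the aerated/dense boundary: `max(HU + 100, 0) / 200`
(≈ 0.8 for a typical 60 HU lesion), zero in aerated tissue. This makes
"tracer binding correlates with collagen content" true by construction —
deliberately, so the pipeline's recovery of that relationship is a
testable property rather than an empirical claim.

## Tracer kinetics

Lung concentration per unit injected activity is modelled as

$$C(t) = A e^{-\alpha t} + C_0 + f\,B\,b\,(1 - e^{-\beta t}),$$

the simplest form that reproduces the described behaviour of a
collagen-binding peptide tracer: an early perfusion peak washing out to a
nonspecific baseline in healthy lung, and a persistent, slowly rising
plateau in fibrotic lung. No compartmental ODE fit is claimed. Defaults:

| parameter | default | unit | rationale |
|---|---|---|---|
| `A` (perfusion amplitude) | 100 | kBq·mL⁻¹·MBq⁻¹ | early lung concentration ≈ 2–3× the whole-body average for a 5 MBq injection |
| `α` (washout rate) | `log(20)/12` ≈ 0.25 | min⁻¹ | perfusion signal decayed to 5% by 12 min p.i., when control and fibrotic curves separate |
| `C₀` (baseline) | 1.0 | kBq·mL⁻¹·MBq⁻¹ | control washes out *to a baseline*, not to zero; keeps the 12-min control value below 10% of its 2-min value |
| `B` (binding amplitude) | 100 | kBq·mL⁻¹·MBq⁻¹·burden⁻¹ | late fibrotic uptake ≈ 2–3 %ID/g at a 0.3 fibrosis fraction |
| `β` (binding rate) | 0.08 | min⁻¹ | binding plateaus after ~12 min and keeps rising slightly across the 15–75 min window |
| `f` (blocking factor) | 1 (0.1 in the blocking arm) | — | a ×100 cold-peptide excess leaves ~10% of specific binding; no quantitative displacement value is available, so this is a declared phantom parameter |

Measured activity decays physically as $2^{-t/T_{1/2}}$ with the
gallium-68 half-life (67.71 min, a physical constant). Decay is *not*
pre-corrected in rendered frames: correction is an explicit quantification
step, which makes it testable (`decay_factor()` satisfies
$f(t_1+t_2) = f(t_1) f(t_2)$ exactly).

`render_pet_series()` uses the closed-form frame average of the decayed
curve — per frame, a voxel's value is exactly the analytic time-average
for its burden, so the noise-free pipeline admits a machine-precision
oracle. PET frames live on a 20³ grid of 0.8 mm voxels over the same
field of view; CT-derived masks are brought over by nearest-neighbour
resampling (the modalities are treated as hardware co-registered — no
registration is implemented, only a congruence check). Poisson noise acts
on expected counts per voxel,
`counts = concentration × voxel volume × sensitivity × frame duration`,
with a default sensitivity of 2×10⁴ counts·kBq⁻¹·min⁻¹ giving ROI-mean
noise well below 1%.

## Study design

`study_design()` defaults encode the five-arm longitudinal experiment:
saline control (flat zero burden), BLM (fibrosis fraction 0 → 0.15 →
0.25 → 0.35 over days 0/8/15/22), nintedanib and tofacitinib arms that
share the BLM trajectory to day 8 (treatment start) and then regress
(nintedanib earlier: 0.13/0.10; tofacitinib later: 0.16/0.11), and a
blocking arm with the BLM trajectory imaged at blocking factor 0.1.
Group size defaults to n = 4, the study scale of the underlying design.
Inter-animal variability is a per-subject lognormal multiplier
(sd 0.25 on the log scale) applied to the whole trajectory; because one
multiplier scales both baseline severity and subsequent change, baseline
uptake predicts progression positively in the untreated arm and treatment
response negatively in treated arms — the predictive-correlation structure
the analysis layer is built to detect.

Imaging at each timepoint uses six 10-min frames covering the 15–75 min
window (a static late acquisition); the 37-frame 2-min dynamic schedule
(`dynamic_frame_schedule()`, mid-times 3, 5, …, 75 min) is used for TAC
work.

## What the phantom does not emulate

Realistic anatomy (airway trees, vasculature, heart), respiratory and
cardiac motion, scanner point-spread function and partial-volume effects,
attenuation and scatter, reconstruction artefacts, and the inflammatory
(pre-fibrotic) phase of the bleomycin model. Passing tests therefore
demonstrate the *correctness of the quantification pipeline* on signals
with known truth — not the biological validity of any specific uptake
value. Absolute %ID/g scales are parameter choices tuned to the described
curve shapes, not measurements.

# Quantification conventions

- **World frame**: RAS, millimetres; voxel centre of (1-based) index
  `i` at `origin + (i − 0.5) · spacing`. Frame timing intervals are
  half-open `[start, start + duration)`.
- **Density bands**: aerated `[-800, -100)`, dense `[-100, 300]` HU. The
  boundary −100 HU is assigned to the dense band, keeping the compartments
  disjoint and total; thresholds are configurable. Voxels outside both
  bands stay in the lung ROI for MLD but are excluded from compartmental
  uptake; `mean_lung_density(bands_only = TRUE)` restricts the MLD to the
  two bands instead. No morphological smoothing is applied to compartment
  masks — segmentation is pure density thresholding.
- **Decay correction**: reference time is the injection; each frame is
  corrected by `2^(mid/T½)` at its mid-time. Correction to scan start can
  be obtained by disabling correction and rescaling, and
  `decay_correct = FALSE` is available throughout.
- **%ID/g mass model**: unit tissue density by default; `hu_density()`
  offers a CT-derived alternative (`1 + HU/1000` g/mL, clamped at
  0.05).
- **Window uptake**: duration-weighted mean of per-frame %ID/g over
  frames with mid-time in `[15, 75]` min p.i.; `mode = "endpoint"` uses
  the last in-window frame instead.
- **TAC divergence**: earliest mid-time from which curve B exceeds curve A
  by more than the tolerance (default 0.5 %ID/g) at *every* subsequent
  point; `NULL` if never.
- **Quartiles**: linear interpolation (type 7), fixed and documented since
  "median ± IQR" admits several conventions.
- **Rank tests**: Mann-Whitney p is exact (enumeration-equivalent) for
  combined n ≤ 14 without ties, else a tie-corrected normal approximation
  without continuity correction; Kruskal-Wallis uses the tie-corrected H
  with a chi-square p (optional full enumeration for total n ≤ 8);
  Spearman p is an exact permutation value for n ≤ 8 without ties, else
  the t approximation. These thresholds keep exact computation at
  desk-scale runtime; above them the approximations are standard.
- **Post-hoc**: Dunn's z on pooled mid-ranks with tie correction,
  Bonferroni-multiplied and clipped at 1 — the standard rank-based
  pairwise follow-up when only "Bonferroni post-hoc" is specified.
- **Correlation estimator**: Spearman by default, consistent with the
  otherwise fully nonparametric framework; this is a package choice, not a
  claim about any particular study's estimator. Tests are two-sided and
  unpaired throughout.
- **Elimination**: operationalised as urinary excreted %ID at sacrifice —
  a declared stand-in, since "elimination rate" lacks a standard
  operational definition in this context. Organ tables are %ID/g with
  fixed nominal mouse organ masses so %ID and %ID/g interconvert
  deterministically; the synthesizer keeps kidneys the hottest organ and
  total accounted dose ≤ 100 %ID.

# Degenerate inputs and edge behaviour

Empty masks, shape/geometry mismatches, modality mismatches, overlapping
or unordered frame schedules, negative times and stale segmentations
(fingerprint mismatch between a segmentation and the CT it is applied to)
are all hard errors. An empty dense compartment yields `NA` uptake — "no
fibrotic tissue" is distinct from "no signal". Constant input to the
correlation estimator yields an `NA` rho with a warning; groups below
n = 3 are skipped with a warning in per-group correlation analyses.

# Problem sizes and determinism

Default grids (40³ CT / 20³ PET) make one subject-timepoint ≈ 20 ms to
simulate and quantify, so property-style checks can sweep burdens, seeds
and whole cohorts (e.g. 20 replicate five-arm studies at n = 8) in
minutes on one core — these sizes were chosen as the smallest at which
lungs contain several thousand voxels and ROI statistics are stable.
All randomness flows through explicit seeds (`with_seed` semantics leave
the caller's RNG stream untouched), and identical
(design, config, kinetics, seed) inputs reproduce cohorts bit-exactly.

# Known limitations

- Nearest-neighbour mask resampling slightly biases compartment volumes at
  lesion boundaries on the coarse PET grid; at default geometry the effect
  on ROI means is negligible relative to group effects, but single-voxel
  ROIs on the PET grid are not meaningful.
- The kinetic model's specific-binding term starts growing at t = 0, so
  simulated control/fibrotic median TACs separate somewhat earlier than
  the ~12 min landmark a washout-dominated real signal shows; the
  divergence-time operation reports whatever the curves support.
- Biodistribution reference values are plausible for a renally cleared
  gallium-68 peptide but are synthesis parameters, not measurements; only
  directional group contrasts on them are meaningful.
- The statistics layer covers the design it was built for (unpaired
  nonparametric contrasts, Bonferroni-only adjustment); mixed-effects
  longitudinal modelling is out of scope.
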