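# fibropet

Quantitative PET/CT analysis of collagen-targeted tracer imaging in
experimental pulmonary fibrosis.

## The problem

Idiopathic pulmonary fibrosis and related progressive fibrosing
interstitial lung diseases are characterised by excessive collagen
deposition, yet CT imaging alone cannot predict disease progression or
monitor anti-fibrotic therapy. Collagen-binding PET tracers (gallium-68
labelled peptides) address this: in the bleomycin (BLM) mouse model,
lung uptake rises with fibrotic burden, localises to non-aerated (dense)
lung regions, drops under anti-fibrotic treatment, and — measured early —
predicts subsequent progression.

`fibropet` implements the full quantification pipeline such a study needs,
for preclinical imaging scientists and methodologists:

- **CT density segmentation** of a lung ROI into *aerated*
  (`[-800, -100)` HU) and *dense / non-aerated* (`[-100, 300]` HU)
  compartments, mean lung density (MLD), and the fibrosis fraction
  `dense / (aerated + dense)`.
- **PET quantification**: decay correction to injection time
  (factor `2^(t / T½)`, gallium-68 `T½ = 67.71` min), uptake as percent
  injected dose per gram,
  `%ID/g = 100 · C̄ / (injected activity · tissue density)`,
  per compartment, per dynamic frame (time-activity curves, TACs), and
  duration-weighted over the 15–75 min post-injection window.
- **Biodistribution analysis**: organ %ID/g tables, lung-to-blood and
  lung-to-muscle ratios, urinary elimination.
- **Cohort statistics**: median ± IQR summaries, Mann-Whitney and
  Kruskal-Wallis tests with Dunn-Bonferroni post-hoc, Spearman
  correlations with exact permutation p-values at small n, within-subject
  Δ metrics (D8→D22), and predictive baseline-uptake-vs-progression
  correlations.
- A **digital mouse-thorax phantom** that generates CT + dynamic PET
  cohorts with known ground truth. Lung tracer kinetics follow a two-term
  model, per unit injected activity:

  `C(t) = A·e^(−αt) + C₀ + f·B·b·(1 − e^(−βt))`

  (perfusion washout + nonspecific baseline + saturating specific
  binding on local collagen burden `b`; `f` is the blocking factor).
  Measured activity decays physically as `2^(−t/T½)`; decay correction is
  a pipeline step, not baked into the data. Every quantification claim in
  the package is validated against this generator's ground truth and the
  model's closed form.

## Worked example

```r
library(fibropet)

# one fibrotic thorax at 30% target burden
ph  <- build_thorax_ct(phantom_config(), burden = 0.3, seed = 42)
seg <- segment_density(ph$ct, ph$lung)
ct_result(seg, ph$ct, ph$lung)
#> <ct_result> MLD -426.9 HU | lung 0.252 mL | fibrosis fraction 0.300

meta   <- acquisition_meta(injected_activity_MBq = 5)
frames <- render_pet_series(ph$truth, ph$lung, kinetic_params(), meta,
                            static_frame_schedule(), noise = "poisson",
                            seed = 42)
window_uptake(frames, ph$lung, meta, seg = seg)
#> <uptake_result> window 15-75 min p.i.
#>   whole lung 2.987 | aerated 0.1159 | dense 9.746 %ID/g
```

The CT estimate recovers the 0.30 ground-truth fibrosis fraction exactly,
and tracer binding localises to the dense compartment (9.7 vs
0.12 %ID/g). A full five-arm longitudinal study (saline control, BLM,
BLM + nintedanib, BLM + tofacitinib, BLM + blocking; days 0/8/15/22,
n = 4 per arm):

```r
report <- run_study_analysis(simulate_cohort(study_design(), seed = 42))
report
#> Whole-lung uptake (%ID/g), median [IQR]:
#>   D0    NaCl 0.12 ... BLM 0.12 ...                        (KW p = 0.336)
#>   D8    NaCl 0.12 ... BLM 1.38 [1.00-1.72] ...            (KW p = 0.0053 **)
#>   D15   NaCl 0.12 ... BLM 2.11 ... BLM+nintedanib 1.05 ...(KW p = 0.00349 **)
#>   D22   NaCl 0.12 ... BLM 3.23 ... BLM+tofacitinib 0.73 ..(KW p = 0.00182 **)
#>
#> Predictive correlations (baseline uptake vs density change):
#>   BLM              rho = +0.800, p = 0.333  (n = 4)
#>   BLM+nintedanib   rho = -1.000, p = 0.0833 (n = 4)
#>   BLM+tofacitinib  rho = -0.800, p = 0.333  (n = 4)
```

Uptake rises with fibrosis from D8, treated arms fall away from BLM after
treatment start, the blocking arm collapses toward control, and baseline
uptake correlates positively with progression in the untreated arm,
negatively in the treated arms.

A thin command-line front end (`inst/cli/fibropet.R`) exposes
`simulate`, `quantify-ct`, `quantify-pet` and `analyze` subcommands over
NIfTI/CSV files; see the script header for usage.

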