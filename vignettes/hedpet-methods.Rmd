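---
title: "Quantifying cardiac sympathetic innervation from dynamic HED PET: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac sympathetic innervation from dynamic HED PET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedpet)
```

## The measurement problem

Heart failure is accompanied by a loss of presynaptic sympathetic nerve
terminals in the myocardium. PET with ^11^C-hydroxyephedrine (HED), a
norepinephrine analog trapped by intact nerve terminals, images that loss
directly: poorly innervated myocardium retains little tracer. `hedpet`
implements the full quantitative chain used to turn a pair of dynamic PET
acquisitions (HED for innervation, ^11^C-acetate early frames for relative
perfusion) into four per-patient imaging parameters, and to evaluate those
parameters as prognostic markers against survival endpoints:

1. **Global HED retention index** — the LV-averaged late myocardial HED
   concentration divided by the time-integral of the arterial blood
   activity curve:
   $$R \;=\; 100\cdot\frac{\bar C_\mathrm{myo}(30\text{–}40\,\mathrm{min})}
   {\int_0^{40\,\mathrm{min}} C_\mathrm{blood}(t)\,dt} \quad [\%/\mathrm{min}]$$
2. **Perfusion defect size** (%LV) on the normalized early acetate image,
3. **HED defect size** (%LV) on the normalized late HED image,
4. **Mismatch size** = HED defect − perfusion defect: myocardium that is
   perfused but denervated.

Because no raw clinical PET data accompany this package, every stage is
exercised against a synthetic-data generator with known ground truth; the
generator is first-class, tested code, not a fixture.

## Acquisition protocols and frame conventions

Two canned dynamic protocols are built in, with 1-based frame indexing
throughout:

* HED: 40 min in 14 frames (6 × 30, 2 × 60, 2 × 150, 2 × 300, 2 × 600 s).
  The final frame is the 30–40 min late image used in the retention
  numerator.
* Acetate: 21 frames (10 × 10, 1 × 60, 5 × 100, 3 × 80, 2 × 300 s),
  1500 s total. Frames 11–13 (100–360 s post-injection) are time-averaged
  into the relative perfusion image.

Frame summation is the **duration-weighted mean**, not a raw sum: units
stay in kBq/mL and the result is invariant to re-binning frames inside the
window. All activities are assumed decay-corrected; the package contains
no decay model, reconstruction, or attenuation handling.

## The polar map and %LV arithmetic

The LV is represented as a bull's-eye grid of `n_rings × n_angles` cells
(apex to base × angular sectors), each carrying the equal weight
`1/(n_rings·n_angles)` of the LV. The default grid is **10 rings × 40
angles = 400 cells of 0.25 %LV each**. The sector granularity of clinical
polar-map software varies by vendor and is rarely documented; we chose a
grid on which all extents that are whole multiples of 0.25 %LV — in
particular the worked-example values 32, 68 and 36 %LV — are exactly
representable, which makes %LV arithmetic exact and testable. The grid is
fully configurable.

Cell adjacency is the 4-neighbourhood: ±1 angular step on the same ring
(wrapping around 360°) and ±1 ring at the same angle; there is no special
adjacency across the apex pole. `generate_study()` requires defect extents
that are exactly achievable as whole cells and errors otherwise (listing
the granularity); `snap_extent()` rounds arbitrary extents to the lattice
first, and the pipeline applies it automatically.

## Defect sizing

Each polar map is normalized to the mean of the **six connected sectors
with the highest uptake** and a cell counts as defect when its normalized
value falls **strictly below 0.60**; a cell exactly at the threshold is
healthy. The strictness convention is ours to fix — the clinical
convention is not documented anywhere we could follow — and it is pinned
by tests. Defect size is the summed weight of defect cells × 100 (%LV).
Mismatch is the literal difference of the two defect sizes and may be
negative; no flooring is applied.

### Reference-region search

Finding the maximum-mean connected 6-cell patch is a small combinatorial
problem. The package ships two searches:

* **`method = "exhaustive"`** enumerates every connected 6-subset exactly
  once (recursive extension with a forbidden set) and is exact; it is
  restricted to grids of ≤ 64 cells, where it doubles as the test oracle.
* **`method = "greedy"`** (default) is a beam-guided region growing:
  partial regions seeded at the brightest cells are extended by every
  adjacent cell, duplicates merged, and the best `max(n_seeds, 64)`
  regions survive to the next size; the final region is polished with
  connectivity-preserving one- and two-cell swaps. Plain steepest-ascent
  growing (with or without single-swap refinement) measurably misses the
  optimum on random maps, which is why the beam is part of the design; on
  200 seeded random 4×4 and 6×6 grids the beam search returns exactly the
  exhaustive optimum, and it costs ~0.1 s on the 400-cell default grid.

Ties in the mean are broken toward the lexicographically smallest sorted
cell-index set, so both searches are deterministic.

## The retention index

The blood integral is the trapezoidal integral of the sampled blood curve
from t = 0 (a zero sample is prepended; the tracer is injected at t = 0)
to the end of the acquisition, 40 min. The upper limit equals the end of
the late uptake window by design: numerator and denominator describe the
same acquisition. The raw ratio has units 1/min and is of order 0.1; the
package reports it ×100 as %/min by default, the scale on which clinical
retention values (≈ 5–12 %/min) are quoted, with
`retention_scale = "per_min"` exposing the raw ratio.

Retention is deliberately global-only: no kinetic (compartment) modelling,
no regional retention, and no oxidative-metabolism analysis of the acetate
scan are in scope.

## What the synthetic generator emulates — and what it does not

`generate_study()` builds paired HED/acetate acquisitions plus a blood
curve so that quantification provably recovers the ground truth:

* **Blood curve**: a gamma-variate bolus `A·(t/αβ)^α·e^{α−t/β}` peaking at
  `t = αβ` with peak amplitude `A` (default 20 kBq/mL, α = 2,
  β = 0.5 min), plus a recirculation plateau rising to `recirc·A`
  (default 0.15) with a fixed 5-min wash-in constant. The real arterial
  input function of a patient study is not otherwise modelled; the
  generator supplies the curve directly, sampled at frame mid-times.
* **Calibration**: noise-free late HED uptake in non-defect cells equals
  `(retention_true/100) × ∫ blood`, with the integral computed by the same
  trapezoidal rule the quantifier uses. Retention recovery is therefore
  exact (< 10⁻⁶ relative) in the noise-free case — by construction, which
  is precisely what makes the downstream arithmetic testable.
* **Defects**: contiguous angular wedges spanning all rings, the
  perfusion wedge nested inside the HED wedge (so mismatch = HED −
  perfusion by construction); inside a defect, uptake is `defect_depth ×
  normal` (default depth 0.4, comfortably below the 0.60 threshold).
* **Dynamics**: a linear wash-in for HED reaching the late value exactly
  at the final frame, and a 100-s injection ramp for acetate with frames
  11+ carrying the perfusion pattern unscaled. Only the frames the
  quantifier reads are calibrated; the earlier frames are plausible
  filler.
* **Noise**: independent Gaussian noise per cell per frame with SD
  `noise_scale·√(activity/duration_s)` — the Poisson-like scaling of
  reconstructed PET counts without count-level simulation — truncated at
  zero.

Not emulated: spatial resolution and partial-volume effects, spill-over
from blood pool to myocardium, attenuation/scatter residuals, patient
motion, irregular defect shapes, and correlated (reconstruction) noise.
Passing tests therefore demonstrate that the measurement chain is
arithmetically correct and unbiased under idealized imaging, not that it
is robust to scanner physics.

Note one deliberate consequence of global averaging: for a study with an
implanted HED defect, the measured global retention is the generating
value attenuated by the denervated fraction,
`R_meas = R_true·(1 − extent/100·(1 − depth))`. The recovery guarantee
applies to defect-free studies; tests pin the attenuated value otherwise.

## The synthetic cohort and its calibration

`generate_cohort()` draws covariates from marginal distributions matched
to a 60-patient LV-dysfunction population: age ~ N(70, 10) years, 17/60
female, BNP log-normal (median 150 pg/mL, sdlog 1.1), LVEF ~ N(42, 14) %,
HED retention ~ N(8.6, 2.4) %/min (the pooled mean of survivors at
9.0 ± 2.4 and non-survivors at 7.1 ± 2.1), perfusion defect ~ N(16, 17)
and mismatch ~ N(16, 15) %LV, all clamped to plausible clinical ranges.

All-cause death follows an exponential proportional-hazards model with
baseline hazard 0.007/month and default log hazard ratios
`β_retention = ln 0.762` per %/min and `β_age = ln 1.126` per year — the
anchor values the prognostic analysis should recover. Covariates are
centered at their generating means inside the linear predictor (Cox
estimates are invariant to centering; the baseline absorbs it). Censoring
is uniform on (0, 82] months, reproducing a mean follow-up around
30 months and roughly a fifth of patients dying; 7/13 of deaths are
labelled cardiac. Non-fatal cardiac events run on an independent
exponential clock (baseline 0.006/month, same linear predictor), and the
composite endpoint takes the first event, fatal or not. Independence of
the two clocks given covariates is a simplification; real HF
hospitalizations and deaths are more strongly coupled.

## Survival machinery

Kaplan–Meier estimation, the log-rank test and Cox partial-likelihood
maximization are delegated to the `survival` package behind this
package's interface; the tests verify them against independent oracles
(the empirical survival function, hand-accumulated 2×2 risk tables, and a
four-subject arrangement whose partial-likelihood maximum is the closed
form `β̂ = ln 2 / 2`). Design choices that required fixing:

* **Ties**: Efron approximation by default, Breslow by flag.
* **"Stepwise forward elimination"** is implemented as forward selection
  with a likelihood-ratio entry test at α = 0.05 and no removal step; the
  full selection trace (every candidate's conditional test at every step)
  is returned.
* **Degenerate covariates**: a constant column is dropped from the fit
  and reported with coefficient 0 / HR 1 plus a warning, rather than
  erroring the whole model.
* **ROC cutoffs** evaluate every midpoint between consecutive sorted
  unique marker values and maximize Youden's J, with low marker = test
  positive (low retention predicts death) and ties broken toward the
  higher cutoff; a value exactly at the cutoff belongs to the "high"
  group. Cutoffs are recomputed per endpoint.
* **Group tables**: Wilcoxon rank-sum with exact enumeration when both
  groups have ≤ 20 subjects and no ties, otherwise the midrank normal
  approximation without continuity correction; chi-square without Yates
  correction (flag available). These variants are conventions we fixed
  and test; published p values computed with other software's defaults
  can differ slightly.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit integer seed and restores
the ambient RNG state; identical inputs are bit-for-bit reproducible,
and `run_full_study()` writes byte-identical report bundles on repeated
runs (file checksums are recorded in the run log). The test-suite
problem sizes — 100 noisy replicates for the retention bias check, 200
random grids for the search-oracle sweep, 20 seeds × n = 2000 for
hazard-ratio recovery, 200 null cohorts of n = 60 for the type-I error
check — were chosen so the Monte-Carlo standard error is well below each
tolerance being asserted.

## Known limitations

* The polar-map model is weight-based, not geometric: no cell areas,
  no apex-sparing geometry, no vendor sector maps.
* The generator's defects are wedges; real defects have irregular shapes
  and graded borders, which a fixed threshold handles less cleanly.
* The exhaustive reference search is exponential in principle and capped
  at 64-cell grids; on clinical-size grids only the beam search runs.
* The cohort model is exponential with independent event clocks; it
  calibrates location and effect sizes, not the shape of real hazard
  functions.
* Group-comparison p values depend on test-variant conventions (exact vs
  asymptotic, continuity corrections); cross-software agreement is
  qualitative.
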