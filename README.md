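# hedpet

Quantification of cardiac sympathetic innervation from dynamic
^11^C-hydroxyephedrine (HED) PET, and prognostic evaluation of the
resulting imaging parameters against survival endpoints.

## The problem

In heart failure, presynaptic sympathetic nerve terminals are lost from
the myocardium. HED, a PET-labelled norepinephrine analog, is trapped by
intact terminals, so poorly innervated myocardium retains little tracer.
`hedpet` implements the quantitative chain that turns a pair of dynamic
acquisitions — HED for innervation, early-frame ^11^C-acetate for relative
perfusion — into four per-patient parameters, and evaluates them as
prognostic markers:

- **Global HED retention index** (%/min):
  `R = 100 · C̄_myo(30–40 min) / ∫₀⁴⁰ C_blood(t) dt`, the LV-averaged late
  myocardial concentration over the time-integral of arterial blood
  activity.
- **Perfusion defect size** (%LV): weight of polar-map cells below 60 % of
  the reference (six connected highest-uptake sectors) on the summed
  acetate frames 11–13.
- **HED defect size** (%LV): same rule on the late HED image.
- **Mismatch** (%LV): HED defect − perfusion defect, i.e. myocardium that
  is perfused but denervated.

The survival stage provides Kaplan–Meier curves with log-rank tests,
univariate and forward-stepwise Cox proportional-hazards models, ROC-based
(Youden J) optimal cutoffs, and baseline group-comparison tables, for
three endpoints: all-cause death, cardiac death, and a composite
(first of HF progression, life-threatening arrhythmia, acute coronary
syndrome, or death).

Because raw clinical PET data are not distributable, the package includes
a first-class synthetic-data generator: dynamic polar-map studies with
known retention and implanted wedge defects, and patient cohorts drawn
from a proportional-hazards model with known hazard ratios — so every
stage is testable against ground truth. The package is aimed at
researchers prototyping or validating polar-map quantification and
imaging-biomarker survival analyses.

## Worked example

```r
library(hedpet)

# A study with a 32 %LV perfusion defect nested inside a 68 %LV
# innervation defect (defect uptake at 40 % of normal), no noise:
truth <- study_truth(retention_true = 9, perfusion_defect_extent = 32,
                     hed_defect_extent = 68, defect_depth = 0.4)
study <- generate_study(truth, polar_grid(), seed = 42)
quantify_study(study)
#> quant_result: retention 5.33, perfusion defect 32 %LV, HED defect 68 %LV, mismatch 36 %LV
```

The implanted extents are read back exactly, and the mismatch — the
denervated-but-perfused area — is their difference, 36 %LV. The global
retention (5.33 %/min) is the generating 9 %/min attenuated by the
denervated fraction, `9 · (1 − 0.68·0.6)`: a defect lowers the global
average, which is exactly why low global retention marks severe disease.

```r
# A 600-patient synthetic cohort (HR 0.762 per %/min retention,
# 1.126 per year of age) and its prognostic analysis:
co <- generate_cohort(600, seed = 2024)
cox_univariate(co, c("retention", "age"), co$followup_months, co$death_any)
#>    variable hazard_ratio ci_low ci_high  p_value
#> 1 retention        0.832  0.783   0.884 3.33e-09
#> 2       age        1.100  1.082   1.119 1.78e-28

cut <- roc_optimal_cutoff(co$retention, co$death_any)
cut
#> cutoff_result: cutoff 8.109 (sens 0.547, spec 0.659, Youden J 0.206)

low <- co$retention < cut$cutoff
log_rank(co$followup_months[!low], co$death_any[!low],
         co$followup_months[low],  co$death_any[low])$p_value
#> 2.79e-07
```

Higher retention is protective (HR < 1 per %/min), age is adverse, and
splitting the cohort at the ROC-derived retention cutoff separates
survival significantly. `run_full_study(run_config(), "out/")` executes
the whole generator → quantification → survival pipeline and writes a
deterministic, per-endpoint report bundle (tables, KM curves, cutoffs,
run log); `inst/scripts/hedpet.R` wraps the same functions as a
`simulate` / `quantify` / `survival` / `run` command line.

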