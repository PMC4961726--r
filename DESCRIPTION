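Package: hedpet
Title: Cardiac Sympathetic Innervation PET Quantification and Prognostic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies cardiac sympathetic innervation from dynamic
    11C-hydroxyephedrine (HED) positron emission tomography studies and
    evaluates its prognostic value. Computes the global HED retention index
    (late myocardial uptake divided by the time-integral of arterial blood
    activity), polar-map (bull's-eye) perfusion and innervation defect sizes
    at a 60 percent-of-reference threshold, and the innervation/perfusion
    mismatch. Includes a synthetic-data generator producing dynamic polar-map
    studies with known ground truth and patient cohorts following a
    proportional-hazards model, plus the survival machinery used for
    prognostic evaluation: Kaplan-Meier curves, log-rank tests, univariate
    and forward-stepwise Cox models, ROC-derived optimal cutoffs, and
    group-comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
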