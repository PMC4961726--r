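#' Default covariate model for synthetic cohorts
#'
#' Marginal distributions of the patient covariates, calibrated to a
#' heart-failure population with LV dysfunction: age normal 70 +/- 10 y,
#' 17/60 female, BNP log-normal (median 150 pg/mL, sdlog 1.1), LVEF normal
#' 42 +/- 14 %, HED retention normal 8.6 +/- 2.4 %/min, perfusion defect
#' half-normal-ish (truncated normal 16 +/- 17 %LV), mismatch truncated
#' normal 16 +/- 15 %LV. All draws are truncated to plausible clinical
#' ranges by rejection at the bounds (values are clamped).
#'
#' @return A named list of distribution parameters, editable and passed to
#'   [generate_cohort()].
#' @export
cohort_covariate_defaults <- function() {
  list(
    age = list(mean = 70, sd = 10, min = 35, max = 95),
    female_fraction = 17 / 60,
    bnp = list(meanlog = log(150), sdlog = 1.1, min = 5, max = 10000),
    lvef = list(mean = 42, sd = 14, min = 10, max = 75),
    retention = list(mean = 8.6, sd = 2.4, min = 2, max = 18),
    perfusion_defect = list(mean = 16, sd = 17, min = 0, max = 80),
    mismatch = list(mean = 16, sd = 15, min = 0, max = 60)
  )
}

rnorm_clamped <- function(n, p) {
  pmin(p$max, pmax(p$min, stats::rnorm(n, p$mean, p$sd)))
}

#' Generate a synthetic patient cohort under a proportional-hazards model
#'
#' Draws covariates from the marginal model, then generates an all-cause
#' death time from an exponential proportional-hazards model
#' `h(t) = baseline_hazard * exp(lp)` with linear predictor
#' `lp = beta_retention * (retention - mean) + beta_age * (age - mean)`
#' (covariates are centered at their generating means; Cox estimates are
#' invariant to this centering). Censoring is uniform on
#' `(0, censor_window_months]`; set the window to `Inf` to disable
#' censoring. A configurable fraction of deaths is labelled cardiac.
#' Non-fatal cardiac events follow an independent exponential clock with
#' hazard `nonfatal_hazard * exp(lp)`; the composite endpoint uses the
#' first event (non-fatal event or death), per the first-event rule.
#'
#' @param n Number of patients (>= 0).
#' @param beta_age Log hazard ratio per year of age.
#' @param beta_retention Log hazard ratio per %/min of retention.
#' @param baseline_hazard Baseline death hazard, events per month, > 0.
#' @param censor_window_months Administrative censoring window, months.
#' @param covariate_model See [cohort_covariate_defaults()].
#' @param cardiac_fraction Probability that a death is cardiac.
#' @param nonfatal_hazard Baseline hazard of non-fatal cardiac events.
#' @param seed Integer seed; identical inputs reproduce the cohort exactly.
#' @return A `data.frame` with one row per patient and columns `id`,
#'   `age`, `sex`, `bnp`, `lvef`, `retention`, `perfusion_defect`,
#'   `hed_defect`, `mismatch`, `followup_months`, `death_any`,
#'   `death_cardiac`, `composite_event`, `composite_time_months`.
#' @examples
#' head(generate_cohort(5, seed = 1))
#' @export
generate_cohort <- function(n,
                            beta_age = log(1.126),
                            beta_retention = log(0.762),
                            baseline_hazard = 0.007,
                            censor_window_months = 82,
                            covariate_model = cohort_covariate_defaults(),
                            cardiac_fraction = 7 / 13,
                            nonfatal_hazard = 0.006,
                            seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be >= 0")
  if (!is.finite(baseline_hazard) || baseline_hazard <= 0) {
    stop("baseline_hazard must be > 0")
  }
  if (censor_window_months <= 0) stop("censor_window_months must be > 0")
  if (cardiac_fraction < 0 || cardiac_fraction > 1) {
    stop("cardiac_fraction must lie in [0, 1]")
  }
  cm <- covariate_model
  empty <- data.frame(
    id = integer(0), age = numeric(0), sex = character(0), bnp = numeric(0),
    lvef = numeric(0), retention = numeric(0), perfusion_defect = numeric(0),
    hed_defect = numeric(0), mismatch = numeric(0),
    followup_months = numeric(0), death_any = integer(0),
    death_cardiac = integer(0), composite_event = integer(0),
    composite_time_months = numeric(0), stringsAsFactors = FALSE
  )
  if (n == 0L) return(empty)

  with_local_seed(seed, {
    age <- rnorm_clamped(n, cm$age)
    sex <- ifelse(stats::runif(n) < cm$female_fraction, "female", "male")
    bnp <- pmin(cm$bnp$max, pmax(cm$bnp$min,
                                 stats::rlnorm(n, cm$bnp$meanlog, cm$bnp$sdlog)))
    lvef <- rnorm_clamped(n, cm$lvef)
    retention <- rnorm_clamped(n, cm$retention)
    perfusion_defect <- rnorm_clamped(n, cm$perfusion_defect)
    mismatch <- pmin(100 - perfusion_defect,
                     rnorm_clamped(n, cm$mismatch))
    hed_defect <- perfusion_defect + mismatch

    lp <- beta_retention * (retention - cm$retention$mean) +
      beta_age * (age - cm$age$mean)
    t_death <- stats::rexp(n, rate = baseline_hazard * exp(lp))
    t_nonfatal <- stats::rexp(n, rate = nonfatal_hazard * exp(lp))
    t_censor <- if (is.infinite(censor_window_months)) {
      rep(Inf, n)
    } else {
      stats::runif(n, 0, censor_window_months)
    }
    followup <- pmin(t_death, t_censor)
    death_any <- as.integer(t_death <= t_censor)
    death_cardiac <- as.integer(death_any == 1L &
                                  stats::runif(n) < cardiac_fraction)
    t_first <- pmin(t_nonfatal, t_death)
    composite_event <- as.integer(t_first <= t_censor)
    composite_time <- pmin(t_first, t_censor)

    data.frame(
      id = seq_len(n),
      age = age, sex = sex, bnp = bnp, lvef = lvef,
      retention = retention,
      perfusion_defect = perfusion_defect,
      hed_defect = hed_defect,
      mismatch = mismatch,
      followup_months = followup,
      death_any = death_any,
      death_cardiac = death_cardiac,
      composite_event = composite_event,
      composite_time_months = composite_time,
      stringsAsFactors = FALSE
    )
  })
}

#' Endpoint definitions
#'
#' The three endpoints of the prognostic analysis: all-cause death
#' (primary), cardiac death (secondary) and the composite endpoint of
#' heart-failure progression, life-threatening arrhythmia, acute coronary
#' syndrome or any death (tertiary; only the first event counts). Each
#' endpoint names the cohort columns holding its follow-up time and event
#' flag.
#'
#' @param name One of `"all_cause_death"`, `"cardiac_death"`, `"composite"`.
#' @return A list with `name`, `time_col`, `event_col`.
#' @export
endpoint_spec <- function(name = c("all_cause_death", "cardiac_death", "composite")) {
  name <- match.arg(name)
  switch(name,
    all_cause_death = list(name = name, time_col = "followup_months",
                           event_col = "death_any"),
    cardiac_death = list(name = name, time_col = "followup_months",
                         event_col = "death_cardiac"),
    composite = list(name = name, time_col = "composite_time_months",
                     event_col = "composite_event")
  )
}
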