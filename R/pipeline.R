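#' Build a run configuration
#'
#' Assembles the configuration of a full simulated study: a simulation
#' block (cohort size, hazard-model coefficients, imaging noise/depth), a
#' quantification block (grid, threshold, reference size, retention
#' scale) and a survival block (endpoints, candidate predictors, alpha).
#' Every stochastic stage derives its own seed from the single `seed`
#' field, so one integer fixes the whole run. The configuration
#' round-trips losslessly through [write_run_config()] /
#' [read_run_config()] (YAML).
#'
#' @param n Cohort size.
#' @param seed Master seed.
#' @param beta_age,beta_retention Log hazard ratios of the generator.
#' @param baseline_hazard,censor_window_months,nonfatal_hazard,cardiac_fraction
#'   Cohort-generator parameters, see [generate_cohort()].
#' @param defect_depth,noise_scale Imaging ground-truth parameters shared
#'   by all simulated studies.
#' @param n_rings,n_angles Polar grid dimensions.
#' @param threshold Defect cutoff fraction.
#' @param k_ref Reference-region size.
#' @param retention_scale `"percent_per_min"` or `"per_min"`.
#' @param endpoints Endpoints to analyse.
#' @param candidates Candidate predictors for the Cox models.
#' @param alpha Entry threshold for the forward-stepwise selection.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n = 60L,
                       seed = 20160101L,
                       beta_age = log(1.126),
                       beta_retention = log(0.762),
                       baseline_hazard = 0.007,
                       censor_window_months = 82,
                       nonfatal_hazard = 0.006,
                       cardiac_fraction = 7 / 13,
                       defect_depth = 0.4,
                       noise_scale = 0.5,
                       n_rings = 10L,
                       n_angles = 40L,
                       threshold = 0.60,
                       k_ref = 6L,
                       retention_scale = "percent_per_min",
                       endpoints = c("all_cause_death", "cardiac_death", "composite"),
                       candidates = c("sex_female", "age", "lvef", "bnp",
                                      "retention", "hed_defect", "mismatch"),
                       alpha = 0.05) {
  cfg <- list(
    simulation = list(
      n = as.integer(n), seed = as.integer(seed),
      beta_age = beta_age, beta_retention = beta_retention,
      baseline_hazard = baseline_hazard,
      censor_window_months = censor_window_months,
      nonfatal_hazard = nonfatal_hazard,
      cardiac_fraction = cardiac_fraction,
      defect_depth = defect_depth, noise_scale = noise_scale
    ),
    quantification = list(
      n_rings = as.integer(n_rings), n_angles = as.integer(n_angles),
      threshold = threshold, k_ref = as.integer(k_ref),
      retention_scale = retention_scale
    ),
    survival = list(
      endpoints = endpoints, candidates = candidates, alpha = alpha
    )
  )
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(
    raw$simulation[c("n", "seed", "beta_age", "beta_retention",
                     "baseline_hazard", "censor_window_months",
                     "nonfatal_hazard", "cardiac_fraction",
                     "defect_depth", "noise_scale")],
    raw$quantification[c("n_rings", "n_angles", "threshold", "k_ref",
                         "retention_scale")],
    raw$survival[c("endpoints", "candidates", "alpha")]
  ))
}

#' Run the full simulated study
#'
#' Orchestrates generator, quantification and survival analysis into one
#' reproducible run:
#'
#' 1. generate a cohort of `n` patients with true imaging parameters and
#'    proportional-hazards outcomes;
#' 2. simulate one dynamic PET study per patient from those true
#'    parameters (extents snapped to the grid) and quantify it; the
#'    measured retention, defect and mismatch values replace the true
#'    ones in the analysis table;
#' 3. for every configured endpoint: ROC-derived retention cutoff,
#'    Kaplan-Meier curves of the low/high retention strata with log-rank
#'    test, a group-comparison table (event vs no event), univariate Cox
#'    screens of all candidates and a forward-stepwise multivariate model.
#'
#' All outputs are plain text under `out_dir`: `config.yaml`,
#' `cohort.csv` (measured values), `cohort_true.csv` (generator truth),
#' per-endpoint directories with `table_groups.csv`, `table_cox.csv`,
#' `km_<endpoint>.csv`, `cutoff.json`, `logrank.json`, plus a structured
#' stage log `run_log.json` recording each stage's seed and output file
#' checksums. Running twice with the same configuration produces
#' byte-identical files.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the merged analysis table and the
#'   per-endpoint results.
#' @export
run_full_study <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$simulation
  qc <- config$quantification
  sv <- config$survival
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  log <- list()

  grid <- polar_grid(qc$n_rings, qc$n_angles)
  cohort_true <- generate_cohort(
    n = sim$n, beta_age = sim$beta_age, beta_retention = sim$beta_retention,
    baseline_hazard = sim$baseline_hazard,
    censor_window_months = sim$censor_window_months,
    cardiac_fraction = sim$cardiac_fraction,
    nonfatal_hazard = sim$nonfatal_hazard,
    seed = derive_seed(sim$seed, 101L)
  )
  log$cohort <- list(stage = "generate_cohort", n = sim$n,
                     seed = derive_seed(sim$seed, 101L))

  cohort <- cohort_true
  if (sim$n > 0L) {
    measured <- vapply(seq_len(sim$n), function(i) {
      rec <- cohort_true[i, ]
      perf <- snap_extent(grid, rec$perfusion_defect)
      hed <- snap_extent(grid, rec$hed_defect)
      truth <- study_truth(
        retention_true = rec$retention,
        perfusion_defect_extent = perf,
        hed_defect_extent = max(hed, perf),
        defect_depth = sim$defect_depth,
        noise_scale = sim$noise_scale
      )
      st <- generate_study(truth, grid, seed = derive_seed(sim$seed, 1000L + i))
      qr <- quantify_study(st, threshold = qc$threshold, k_ref = qc$k_ref,
                           retention_scale = qc$retention_scale)
      c(qr$retention, qr$perfusion_defect, qr$hed_defect, qr$mismatch)
    }, numeric(4))
    cohort$retention <- measured[1, ]
    cohort$perfusion_defect <- measured[2, ]
    cohort$hed_defect <- measured[3, ]
    cohort$mismatch <- measured[4, ]
  }
  cohort$sex_female <- as.integer(cohort$sex == "female")
  log$quantification <- list(stage = "quantify_studies", n = sim$n,
                             grid = c(qc$n_rings, qc$n_angles))

  write_cohort(cohort_true, file.path(out_dir, "cohort_true.csv"))
  write_cohort(cohort[, setdiff(names(cohort), "sex_female")],
               file.path(out_dir, "cohort.csv"))

  results <- list()
  for (ep_name in sv$endpoints) {
    ep <- endpoint_spec(ep_name)
    ep_dir <- file.path(out_dir, ep$name)
    dir.create(ep_dir, recursive = TRUE, showWarnings = FALSE)
    times <- cohort[[ep$time_col]]
    events <- cohort[[ep$event_col]]

    res <- list(endpoint = ep$name)
    if (sum(events) > 0 && sum(events) < length(events)) {
      cut <- roc_optimal_cutoff(cohort$retention, events)
      jsonlite::write_json(unclass(cut), file.path(ep_dir, "cutoff.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      low <- cohort$retention < cut$cutoff
      km_rows <- list()
      for (stratum in c("high", "low")) {
        sel <- if (stratum == "low") low else !low
        if (any(sel)) {
          km <- km_estimate(times[sel], events[sel])
          km$stratum <- stratum
          km_rows[[stratum]] <- as.data.frame(km)
        }
      }
      utils::write.csv(do.call(rbind, km_rows),
                       file.path(ep_dir, paste0("km_", ep$name, ".csv")),
                       row.names = FALSE)
      if (any(low) && any(!low) &&
          sum(events[low]) + sum(events[!low]) > 0) {
        lr <- log_rank(times[!low], events[!low], times[low], events[low])
        jsonlite::write_json(lr, file.path(ep_dir, "logrank.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        res$logrank <- lr
      }
      res$cutoff <- cut

      groups <- group_compare(
        cohort, events,
        continuous = c("age", "bnp", "lvef", "retention",
                       "perfusion_defect", "hed_defect", "mismatch"),
        categorical = "sex"
      )
      utils::write.csv(groups, file.path(ep_dir, "table_groups.csv"),
                       row.names = FALSE)
      res$groups <- groups

      uni <- cox_univariate(cohort, sv$candidates, times, events)
      step <- stepwise_forward(cohort, sv$candidates, times, events,
                               alpha_enter = sv$alpha)
      uni$model <- "univariate"
      multi <- as.data.frame(step$model)
      if (nrow(multi)) multi$model <- "multivariate"
      cox_tab <- rbind(as.data.frame(uni), multi)
      utils::write.csv(cox_tab, file.path(ep_dir, "table_cox.csv"),
                       row.names = FALSE)
      res$cox <- cox_tab
      res$selected <- step$selected
    } else {
      res$note <- "endpoint skipped: needs both events and non-events"
      jsonlite::write_json(res, file.path(ep_dir, "skipped.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    results[[ep$name]] <- res
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "run_log.json"))
  rel <- substring(files, nchar(file.path(out_dir, "")) + 1L)
  log$outputs <- lapply(
    stats::setNames(files, rel),
    function(f) unname(tools::md5sum(f))
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, results = results))
}
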