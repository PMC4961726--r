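#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function. Censored subjects
#' leave the risk set at their recorded time. The curve starts at
#' S(0) = 1 and is non-increasing.
#'
#' @param times Follow-up times, months, > 0.
#' @param events Event indicators (0 censored / 1 event).
#' @return A `data.frame` of class `km_curve` with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, including a `time = 0`
#'   row with survival 1.
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  out <- data.frame(
    time = c(0, fit$time),
    n_risk = c(length(times), fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    survival = c(1, fit$surv)
  )
  class(out) <- c("km_curve", "data.frame")
  out
}

check_surv_input <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (length(times) != length(events)) {
    stop("times and events must have the same length")
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("times must be finite and > 0")
  }
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  invisible(TRUE)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic with 1 degree of freedom
#' comparing the survival distributions of two groups; the p value is the
#' chi-square upper tail.
#'
#' @param times_a,events_a Follow-up times and event flags of group A.
#' @param times_b,events_b Follow-up times and event flags of group B.
#' @return A list with `chi_square` and `p_value`.
#' @export
log_rank <- function(times_a, events_a, times_b, events_b) {
  check_surv_input(times_a, events_a)
  check_surv_input(times_b, events_b)
  if (sum(events_a) + sum(events_b) == 0) {
    stop("no events in either group; log-rank statistic undefined")
  }
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  group <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(times, events) ~ group, rho = 0)
  chi <- unname(sd$chisq)
  list(chi_square = chi, p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model by partial-likelihood maximization and reports, per
#' covariate, the coefficient, hazard ratio, Wald 95% confidence interval,
#' Wald chi-square and p value. Ties are handled with the Efron
#' approximation by default (Breslow available). Constant (zero-variance)
#' covariates cannot be estimated: they are dropped from the fit, reported
#' with coefficient 0 / hazard ratio 1, and flagged with a warning.
#' Non-convergence of the partial-likelihood maximization is reported as a
#' warning and flagged in the result.
#'
#' @param x Covariate matrix or data.frame (numeric columns).
#' @param times Follow-up times, > 0.
#' @param events Event indicators (0/1), at least one event.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `data.frame` of class `cox_result` with one row per
#'   covariate: `variable`, `coef`, `hazard_ratio`, `ci_low`, `ci_high`,
#'   `chi_square`, `p_value`, `converged`. The model log-likelihoods are
#'   attached as attributes `loglik_null` and `loglik`.
#' @export
cox_fit <- function(x, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.data.frame(x)
  if (ncol(x) == 0L) stop("no covariates supplied")
  check_surv_input(times, events)
  if (sum(events) < 1) stop("at least one event is required")
  if (nrow(x) != length(times)) stop("covariate rows must match times")
  if (nrow(x) <= ncol(x)) stop("need more subjects than covariates")

  vars <- names(x)
  constant <- vapply(x, function(v) stats::var(as.numeric(v)) == 0, logical(1))
  if (any(constant)) {
    warning("degenerate (constant) covariate(s): ",
            paste(vars[constant], collapse = ", "),
            "; reported with coefficient 0")
  }
  fit_vars <- vars[!constant]

  res <- data.frame(
    variable = vars, coef = 0, hazard_ratio = 1,
    ci_low = NA_real_, ci_high = NA_real_,
    chi_square = 0, p_value = 1, converged = TRUE,
    stringsAsFactors = FALSE
  )
  ll0 <- ll1 <- NA_real_
  if (length(fit_vars)) {
    dat <- cbind(x[fit_vars], .time = times, .event = events)
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", fit_vars), collapse = " + ")
    ))
    converged <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(fml, data = dat, ties = ties),
      warning = function(w) {
        if (grepl("converge|infinite|out of iterations|beta may be", conditionMessage(w))) {
          converged <<- FALSE
          warning("Cox partial-likelihood maximization did not converge cleanly: ",
                  conditionMessage(w), call. = FALSE)
          invokeRestart("muffleWarning")
        }
      }
    )
    s <- summary(fit)
    idx <- match(fit_vars, vars)
    co <- s$coefficients
    res$coef[idx] <- co[, "coef"]
    res$hazard_ratio[idx] <- exp(co[, "coef"])
    se <- co[, "se(coef)"]
    res$ci_low[idx] <- exp(co[, "coef"] - stats::qnorm(0.975) * se)
    res$ci_high[idx] <- exp(co[, "coef"] + stats::qnorm(0.975) * se)
    res$chi_square[idx] <- (co[, "coef"] / se)^2
    res$p_value[idx] <- stats::pchisq(res$chi_square[idx], 1, lower.tail = FALSE)
    res$converged[idx] <- converged
    ll0 <- fit$loglik[1]
    ll1 <- fit$loglik[2]
  }
  attr(res, "loglik_null") <- ll0
  attr(res, "loglik") <- ll1
  class(res) <- c("cox_result", "data.frame")
  res
}

#' Univariate Cox screen
#'
#' Fits one single-covariate Cox model per candidate variable, mirroring
#' the univariate column of a prognostic-factor table.
#'
#' @param data Data frame holding the candidate columns.
#' @param candidates Character vector of column names.
#' @inheritParams cox_fit
#' @return A `cox_result` data.frame with one row per candidate.
#' @export
cox_univariate <- function(data, candidates, times, events,
                           ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  rows <- lapply(candidates, function(v) {
    cox_fit(data[v], times, events, ties = ties)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Forward-stepwise Cox model selection
#'
#' Builds a multivariate Cox model by forward selection: at each step the
#' candidate with the smallest likelihood-ratio p value below
#' `alpha_enter` (against the current model) is added; selection stops
#' when no candidate qualifies. There is no removal step. The selection
#' trace records every candidate's conditional LR test at every step.
#'
#' @param data Data frame with candidate columns.
#' @param candidates Character vector of candidate variable names.
#' @param times,events Survival outcome.
#' @param alpha_enter Entry threshold on the LR p value (default 0.05).
#' @param ties Tie handling, see [cox_fit()].
#' @return A list with `model` (final `cox_result`, zero rows if nothing
#'   entered), `selected` (character vector in entry order) and `trace`
#'   (data.frame: step, variable, lr_chi_square, p_value, entered).
#' @export
stepwise_forward <- function(data, candidates, times, events,
                             alpha_enter = 0.05,
                             ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(candidates) == 0L) stop("candidate list must be nonempty")
  selected <- character(0)
  remaining <- candidates
  trace <- data.frame(
    step = integer(0), variable = character(0),
    lr_chi_square = numeric(0), p_value = numeric(0), entered = logical(0),
    stringsAsFactors = FALSE
  )
  ll_current <- NA_real_
  step <- 0L
  repeat {
    step <- step + 1L
    best_p <- Inf
    best_var <- NULL
    step_rows <- list()
    for (v in remaining) {
      fit <- suppressWarnings(cox_fit(data[c(selected, v)], times, events, ties = ties))
      ll1 <- attr(fit, "loglik")
      ll0 <- if (length(selected)) ll_current else attr(fit, "loglik_null")
      lr <- 2 * (ll1 - ll0)
      p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
      step_rows[[v]] <- data.frame(
        step = step, variable = v, lr_chi_square = lr, p_value = p,
        entered = FALSE, stringsAsFactors = FALSE
      )
      if (!is.na(p) && p < best_p) {
        best_p <- p
        best_var <- v
      }
    }
    rows <- do.call(rbind, step_rows)
    if (!is.null(best_var) && best_p < alpha_enter) {
      rows$entered[rows$variable == best_var] <- TRUE
      selected <- c(selected, best_var)
      remaining <- setdiff(remaining, best_var)
      ll_current <- attr(
        suppressWarnings(cox_fit(data[selected], times, events, ties = ties)),
        "loglik"
      )
      trace <- rbind(trace, rows)
      if (length(remaining) == 0L) break
    } else {
      trace <- rbind(trace, rows)
      break
    }
  }
  model <- if (length(selected)) {
    cox_fit(data[selected], times, events, ties = ties)
  } else {
    empty <- data.frame(
      variable = character(0), coef = numeric(0), hazard_ratio = numeric(0),
      ci_low = numeric(0), ci_high = numeric(0), chi_square = numeric(0),
      p_value = numeric(0), converged = logical(0), stringsAsFactors = FALSE
    )
    class(empty) <- c("cox_result", "data.frame")
    empty
  }
  list(model = model, selected = selected, trace = trace)
}

#' ROC-derived optimal cutoff for a prognostic marker
#'
#' Evaluates every midpoint between consecutive sorted unique marker
#' values and returns the cutoff maximizing the Youden index
#' J = sensitivity + specificity - 1. The marker direction follows the
#' clinical convention here: a LOW marker value predicts the event, so a
#' subject tests positive when `marker < cutoff`, and the "high" group is
#' `marker >= cutoff` (a value exactly at the cutoff is high/negative).
#' Ties in J are broken toward the higher cutoff.
#'
#' @param marker Numeric marker values (e.g. HED retention, %/min).
#' @param outcome Binary outcome (1 = event).
#' @return A list of class `cutoff_result`: `cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`.
#' @export
roc_optimal_cutoff <- function(marker, outcome) {
  marker <- as.numeric(marker)
  if (length(marker) != length(outcome)) stop("marker/outcome length mismatch")
  if (any(!is.finite(marker))) stop("marker values must be finite")
  if (!all(outcome %in% c(0, 1))) stop("outcome must be 0/1")
  if (length(unique(outcome)) < 2L) {
    stop("both outcome classes must be present")
  }
  u <- sort(unique(marker))
  if (length(u) < 2L) stop("marker must take at least two distinct values")
  cuts <- (utils::head(u, -1) + utils::tail(u, -1)) / 2
  pos <- marker[outcome == 1]
  neg <- marker[outcome == 0]
  best <- NULL
  for (cut in cuts) {  # ascending; >= keeps the highest cutoff among ties
    sens <- mean(pos < cut)
    spec <- mean(neg >= cut)
    j <- sens + spec - 1
    if (is.null(best) || j >= best$youden_j) {
      best <- list(cutoff = cut, sensitivity = sens, specificity = spec,
                   youden_j = j)
    }
  }
  class(best) <- "cutoff_result"
  best
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "cutoff_result: cutoff %.4g (sens %.3f, spec %.3f, Youden J %.3f)\n",
    x$cutoff, x$sensitivity, x$specificity, x$youden_j
  ))
  invisible(x)
}

#' Two-group comparison table
#'
#' Mirrors a baseline-characteristics table: continuous variables are
#' summarized as mean +/- SD per group and compared with the Wilcoxon
#' rank-sum test (exact enumeration when both groups have <= 20 subjects
#' and there are no ties; otherwise the normal approximation with midranks
#' and tie correction, without continuity correction); categorical
#' variables as count (percent) per group with a chi-square test (no Yates
#' continuity correction unless `yates = TRUE`).
#'
#' @param data Data frame of subjects.
#' @param group Logical or 0/1 vector splitting the rows into two groups
#'   (`TRUE`/1 = group B, e.g. patients with the event).
#' @param continuous Character vector of continuous column names.
#' @param categorical Character vector of categorical column names.
#' @param yates Apply Yates continuity correction to chi-square tests.
#' @return A `data.frame` with one row per variable: `variable`, `type`,
#'   group A and B summaries (`mean_a`, `sd_a`, `mean_b`, `sd_b` or
#'   `count_a`, `pct_a`, `count_b`, `pct_b` for the first non-reference
#'   level), `test` and `p_value`.
#' @export
group_compare <- function(data, group, continuous = character(0),
                          categorical = character(0), yates = FALSE) {
  group <- as.logical(group)
  if (any(is.na(group))) stop("group must be logical or 0/1 without NA")
  if (length(group) != nrow(data)) stop("group length must match data rows")
  n_a <- sum(!group)
  n_b <- sum(group)
  if (n_a == 0L || n_b == 0L) stop("both groups must be nonempty")

  rows <- list()
  for (v in continuous) {
    xa <- data[[v]][!group]
    xb <- data[[v]][group]
    exact <- max(n_a, n_b) <= 20 && !anyDuplicated(c(xa, xb))
    p <- stats::wilcox.test(xa, xb, exact = exact, correct = FALSE)$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "continuous",
      mean_a = mean(xa), sd_a = stats::sd(xa),
      mean_b = mean(xb), sd_b = stats::sd(xb),
      count_a = NA_real_, pct_a = NA_real_,
      count_b = NA_real_, pct_b = NA_real_,
      test = "wilcoxon", p_value = p, stringsAsFactors = FALSE
    )
  }
  for (v in categorical) {
    f <- factor(data[[v]])
    tab <- table(f, group)
    p <- suppressWarnings(stats::chisq.test(tab, correct = yates)$p.value)
    lev <- utils::tail(levels(f), 1)  # report the last level's counts
    ca <- sum(f[!group] == lev)
    cb <- sum(f[group] == lev)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = paste0(v, "=", lev), type = "categorical",
      mean_a = NA_real_, sd_a = NA_real_, mean_b = NA_real_, sd_b = NA_real_,
      count_a = ca, pct_a = 100 * ca / n_a,
      count_b = cb, pct_b = 100 * cb / n_b,
      test = if (yates) "chi-square (Yates)" else "chi-square",
      p_value = p, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
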