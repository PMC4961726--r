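test_that("KM with no censoring equals the empirical survival function", {
  set.seed(1)
  times <- round(rexp(40, 0.1) + 0.5, 2)
  km <- km_estimate(times, rep(1, 40))
  ev <- km[km$time > 0, ]
  expect_equal(ev$survival, empirical_survival(times, ev$time))
  # invariants: starts at 1, non-increasing, within [0, 1]
  expect_equal(km$survival[1], 1)
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
})

test_that("KM handles censoring and degenerate inputs", {
  # single subject with an event at 5: S = 1 before, 0 at 5
  km <- km_estimate(5, 1)
  expect_equal(km$survival, c(1, 0))
  # no events: S(t) = 1 throughout
  km <- km_estimate(c(3, 7, 9), c(0, 0, 0))
  expect_true(all(km$survival == 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "> 0")
})

test_that("log-rank: identical groups give chi-square 0, labels are symmetric", {
  t <- c(2, 4, 6, 8, 10)
  e <- c(1, 0, 1, 1, 0)
  lr <- log_rank(t, e, t, e)
  expect_equal(lr$chi_square, 0, tolerance = 1e-9)
  expect_equal(lr$p_value, 1, tolerance = 1e-9)
  # swapping group labels leaves the statistic unchanged
  ta <- c(1, 3, 5, 9); ea <- c(1, 1, 0, 1)
  tb <- c(2, 6, 7);    eb <- c(0, 1, 1)
  expect_equal(log_rank(ta, ea, tb, eb)$chi_square,
               log_rank(tb, eb, ta, ea)$chi_square)
})

test_that("log-rank matches the hand-computed 6-subject risk tables", {
  # worked example: two groups of three, four events
  ta <- c(1, 3, 5); ea <- c(1, 1, 0)
  tb <- c(2, 4, 6); eb <- c(1, 0, 1)
  got <- log_rank(ta, ea, tb, eb)
  oracle <- logrank_oracle(ta, ea, tb, eb)
  expect_equal(got$chi_square, oracle$chi_square, tolerance = 1e-9)
  expect_equal(got$p_value, oracle$p_value, tolerance = 1e-9)
  # and on a larger random instance with ties and censoring
  set.seed(9)
  ta <- sample(1:8, 30, TRUE); ea <- rbinom(30, 1, 0.6)
  tb <- sample(1:8, 25, TRUE); eb <- rbinom(25, 1, 0.4)
  got <- log_rank(ta, ea, tb, eb)
  oracle <- logrank_oracle(ta, ea, tb, eb)
  expect_equal(got$chi_square, oracle$chi_square, tolerance = 1e-9)
})

test_that("log-rank separates early-event from event-free groups", {
  ta <- c(1, 2, 2, 3, 3); ea <- rep(1, 5)
  tb <- rep(30, 6); eb <- rep(0, 6)
  expect_lt(log_rank(ta, ea, tb, eb)$p_value, 0.05)
  expect_error(log_rank(ta, rep(0, 5), tb, eb), "undefined")
})

test_that("Cox fit matches the closed-form partial-likelihood maximum", {
  # 4 subjects, 2 events, binary covariate: the score equation reduces to
  # 2 - exp(2 b) = 0, so the MLE is b = log(2) / 2
  x <- data.frame(z = c(1, 0, 1, 0))
  fit <- cox_fit(x, times = c(1, 2, 3, 4), events = c(1, 1, 0, 0))
  expect_equal(fit$coef, log(2) / 2, tolerance = 1e-6)
  expect_equal(fit$hazard_ratio, exp(fit$coef))
  expect_true(fit$ci_low < fit$hazard_ratio & fit$hazard_ratio < fit$ci_high)
})

test_that("constant covariates are reported degenerate with a warning", {
  co <- generate_cohort(100, seed = 2)
  x <- data.frame(retention = co$retention, flat = rep(3, 100))
  expect_warning(
    fit <- cox_fit(x, co$followup_months, co$death_any),
    "degenerate"
  )
  flat <- fit[fit$variable == "flat", ]
  expect_equal(flat$coef, 0)
  expect_equal(flat$hazard_ratio, 1)
})

test_that("Efron and Breslow tie handling agree without ties and differ with", {
  co <- generate_cohort(150, seed = 6)
  a <- cox_fit(co["retention"], co$followup_months, co$death_any, ties = "efron")
  b <- cox_fit(co["retention"], co$followup_months, co$death_any, ties = "breslow")
  expect_equal(a$coef, b$coef, tolerance = 1e-8)  # continuous times: no ties
  tied_t <- ceiling(co$followup_months)           # heavy ties
  a <- cox_fit(co["retention"], tied_t, co$death_any, ties = "efron")
  b <- cox_fit(co["retention"], tied_t, co$death_any, ties = "breslow")
  expect_false(isTRUE(all.equal(a$coef, b$coef, tolerance = 1e-8)))
})

test_that("forward selection picks the truly prognostic covariate first", {
  picks_first <- 0
  contains <- 0
  n_runs <- 40
  for (s in 1:n_runs) {
    co <- generate_cohort(250, beta_retention = log(0.5), beta_age = 0,
                          seed = 400 + s)
    co$noise1 <- with_seed_rnorm(500 + s, 250)
    co$noise2 <- with_seed_rnorm(900 + s, 250)
    st <- stepwise_forward(co, c("retention", "noise1", "noise2"),
                           co$followup_months, co$death_any)
    if (length(st$selected) && st$selected[1] == "retention") {
      picks_first <- picks_first + 1
    }
    if ("retention" %in% st$selected) contains <- contains + 1
    # trace always records every candidate's conditional test at step 1
    expect_equal(sort(unique(st$trace$variable[st$trace$step == 1])),
                 c("noise1", "noise2", "retention"))
  }
  expect_gte(picks_first / n_runs, 0.95)
  expect_gte(contains / n_runs, 0.95)
})

test_that("forward selection on null candidates returns an empty model", {
  co <- generate_cohort(120, beta_retention = 0, beta_age = 0, seed = 77)
  co$noise1 <- with_seed_rnorm(78, 120)
  st <- stepwise_forward(co, "noise1", co$followup_months, co$death_any,
                         alpha_enter = 1e-6)
  expect_length(st$selected, 0)
  expect_equal(nrow(st$model), 0L)
  expect_gt(nrow(st$trace), 0L)
})

test_that("correlated strong predictors: one enters, the other's conditional p is traced", {
  co <- generate_cohort(400, beta_retention = log(0.6), seed = 55)
  co$retention_b <- co$retention + with_seed_rnorm(56, 400, sd = 0.3)
  st <- stepwise_forward(co, c("retention", "retention_b"),
                         co$followup_months, co$death_any)
  expect_gte(length(st$selected), 1)
  first <- st$selected[1]
  other <- setdiff(c("retention", "retention_b"), first)
  cond <- st$trace[st$trace$step == 2 & st$trace$variable == other, ]
  if (nrow(cond)) expect_true(is.finite(cond$p_value))
})

test_that("ROC cutoff maximizes Youden J and matches brute force", {
  # perfect separation: all events below all non-events
  marker <- c(1, 2, 3, 10, 11, 12)
  outcome <- c(1, 1, 1, 0, 0, 0)
  cut <- roc_optimal_cutoff(marker, outcome)
  expect_equal(cut$youden_j, 1)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)
  expect_gt(cut$cutoff, 3); expect_lt(cut$cutoff, 10)

  # random markers: equality with the exhaustive-midpoint oracle
  for (s in 1:20) {
    set.seed(s)
    m <- round(rnorm(200, 8.6, 2.4), 2)
    o <- rbinom(200, 1, 0.25)
    if (length(unique(o)) < 2) next
    got <- roc_optimal_cutoff(m, o)
    want <- roc_cutoff_bruteforce(m, o)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden_j, want$youden_j)
    expect_equal(got$youden_j, got$sensitivity + got$specificity - 1)
  }
  expect_error(roc_optimal_cutoff(1:5, rep(1, 5)), "both outcome classes")
})

test_that("the dichotomization convention puts the cutoff value in the high group", {
  # marker exactly at the cutoff counts as high (test-negative)
  marker <- c(7, 8, 9, 10)
  outcome <- c(1, 1, 0, 0)
  cut <- roc_optimal_cutoff(marker, outcome)
  expect_equal(cut$cutoff, 8.5)
  high <- marker >= cut$cutoff
  expect_equal(sum(high), 2)
})

test_that("group comparison: identical groups, hand-enumerated Wilcoxon, 2x2 chi-square", {
  # identical groups: Wilcoxon p = 1, proportions equal
  d <- data.frame(v = c(1, 2, 3, 4, 1, 2, 3, 4),
                  s = rep(c("f", "m"), 4))
  g <- rep(c(0, 1), each = 4)
  tab <- group_compare(d, g, continuous = "v", categorical = "s")
  expect_equal(tab$p_value[tab$type == "continuous"], 1)
  expect_equal(tab$count_a[tab$type == "categorical"],
               tab$count_b[tab$type == "categorical"])

  # small worked example (4 vs 3, no ties): exact enumeration oracle
  xa <- c(1.1, 2.3, 3.1, 4.5)
  xb <- c(0.5, 2.8, 5.0)
  d <- data.frame(v = c(xa, xb))
  g <- rep(c(0, 1), c(4, 3))
  tab <- group_compare(d, g, continuous = "v")
  expect_equal(tab$p_value, wilcoxon_exact_oracle(xa, xb))

  # 2x2 chi-square without continuity correction vs the direct formula:
  # 11/47 vs 6/13 female
  sex <- c(rep(c("female", "male"), c(11, 36)), rep(c("female", "male"), c(6, 7)))
  d <- data.frame(s = sex)
  g <- rep(c(0, 1), c(47, 13))
  tab <- group_compare(d, g, categorical = "s")
  oracle <- chisq_2x2_oracle(11, 36, 6, 7)
  expect_equal(tab$p_value, oracle$p_value, tolerance = 1e-9)
  expect_gt(tab$p_value, 0.05)  # female proportion not significantly different
  expect_equal(tab$count_a, 36)  # reported level is the last factor level (male)

  expect_error(group_compare(d, rep(0, 60), categorical = "s"), "nonempty")
})
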