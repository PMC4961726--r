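# Independent oracles used across the suite. These re-derive expected
# values by direct counting / enumeration / closed forms, never by
# calling the code paths they check.

# Reproducible covariate noise without touching the ambient RNG stream.
with_seed_rnorm <- function(seed, n, sd = 1) {
  set.seed(seed)
  rnorm(n, sd = sd)
}

# Textbook two-group log-rank: build the 2x2 risk table at every distinct
# event time and accumulate observed-minus-expected and hypergeometric
# variance for group A.
logrank_oracle <- function(times_a, events_a, times_b, events_b) {
  event_times <- sort(unique(c(times_a[events_a == 1], times_b[events_b == 1])))
  o_minus_e <- 0
  v <- 0
  for (t in event_times) {
    n_a <- sum(times_a >= t)
    n_b <- sum(times_b >= t)
    d_a <- sum(times_a == t & events_a == 1)
    d_b <- sum(times_b == t & events_b == 1)
    n <- n_a + n_b
    d <- d_a + d_b
    e_a <- d * n_a / n
    o_minus_e <- o_minus_e + (d_a - e_a)
    if (n > 1) {
      v <- v + d * (n_a / n) * (n_b / n) * (n - d) / (n - 1)
    }
  }
  chi <- o_minus_e^2 / v
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

# Empirical survival function (no censoring): S(t) = 1 - ECDF over event
# times, evaluated at each event time.
empirical_survival <- function(event_times, at) {
  vapply(at, function(t) mean(event_times > t), numeric(1))
}

# Brute-force maximum-mean connected k-subset on a small grid, by
# filtering all k-combinations for connectivity. Only feasible for
# grids around 16 cells.
ref_region_bruteforce <- function(pm, k) {
  g <- pm$grid
  nb <- hedpet:::grid_neighbors(g)
  combos <- utils::combn(g$n_cells, k)
  best <- NULL
  best_sum <- -Inf
  for (j in seq_len(ncol(combos))) {
    set <- combos[, j]
    if (!hedpet:::cells_connected(g, set, nb)) next
    s <- sum(pm$values[set])
    if (s > best_sum ||
        (s == best_sum && paste(set, collapse = ",") <
           paste(best, collapse = ","))) {
      best <- set
      best_sum <- s
    }
  }
  as.integer(best)
}

# Exhaustive Youden-J search by direct counting over every midpoint
# between consecutive sorted unique marker values (low marker = test
# positive; ties in J resolved toward the higher cutoff).
roc_cutoff_bruteforce <- function(marker, outcome) {
  u <- sort(unique(marker))
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- list(youden_j = -Inf, cutoff = NA_real_)
  for (cut in cuts) {
    tp <- sum(marker < cut & outcome == 1)
    fn <- sum(marker >= cut & outcome == 1)
    tn <- sum(marker >= cut & outcome == 0)
    fp <- sum(marker < cut & outcome == 0)
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j >= best$youden_j) best <- list(youden_j = j, cutoff = cut)
  }
  best
}

# Exact two-sided Wilcoxon rank-sum p value by full enumeration of group
# assignments (no ties assumed), using the Mann-Whitney U statistic and
# the doubled-smaller-tail convention.
wilcoxon_exact_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  p <- if (u_obs > mu) {
    2 * mean(u_all >= u_obs)
  } else {
    2 * mean(u_all <= u_obs)
  }
  min(p, 1)
}

# Pearson chi-square for a 2x2 table, direct formula, no continuity
# correction.
chisq_2x2_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  chi <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

# Closed-form integral of the gamma-variate bolus
# A (t / (alpha beta))^alpha exp(alpha - t / beta) from 0 to T.
gamma_bolus_integral <- function(amplitude, alpha, beta, t_end) {
  amplitude * exp(alpha) * (alpha * beta)^(-alpha) * beta^(alpha + 1) *
    gamma(alpha + 1) * stats::pgamma(t_end / beta, alpha + 1)
}

# A minimal noise-free study built by hand (bypassing generate_study) so
# quantification can be exercised on fully transparent inputs.
handmade_study <- function(grid, hed_uptake, perf_values, blood) {
  hs <- hed_schedule()
  as <- acetate_schedule()
  hed_vals <- outer(frame_mid_min(hs) / max(frame_mid_min(hs)), hed_uptake)
  ace_vals <- outer(rep(1, n_frames(as)), perf_values)
  list(
    hed = dynamic_polar_map(grid, hs, hed_vals),
    acetate = dynamic_polar_map(grid, as, ace_vals),
    blood_hed = blood,
    grid = grid
  )
}
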