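make_map <- function(grid, values) polar_map(grid, values)

test_that("sum_frames: identity on a single frame, zero map, re-binning invariance", {
  g <- polar_grid(2, 4)
  sched <- frame_schedule(c(10, 20, 30))
  vals <- matrix(seq_len(3 * g$n_cells), nrow = 3)
  dpm <- dynamic_polar_map(g, sched, vals)
  for (k in 1:3) {
    expect_equal(sum_frames(dpm, k, k)$values, vals[k, ])
  }
  # duration-weighted mean over the full window
  expect_equal(sum_frames(dpm, 1, 3)$values,
               colSums(vals * c(10, 20, 30)) / 60)
  zero <- dynamic_polar_map(g, sched, matrix(0, 3, g$n_cells))
  expect_equal(sum_frames(zero, 1, 3)$values, rep(0, g$n_cells))
  expect_error(sum_frames(dpm, 0, 2), "out of range")
  expect_error(sum_frames(dpm, 2, 4), "out of range")
  expect_error(sum_frames(dpm, 3, 2), "out of range")
})

test_that("normalization: uniform map, threshold cell, scale invariance", {
  g <- polar_grid(3, 8)
  u <- make_map(g, rep(4.2, g$n_cells))
  nu <- normalize_polar_map(u, 1:6)
  expect_true(nu$normalized)
  expect_equal(nu$values, rep(1, g$n_cells))

  # a cell at 0.6 x the reference mean lands exactly on the threshold
  v <- rep(10, g$n_cells)
  v[12] <- 6
  m <- normalize_polar_map(make_map(g, v), c(1:5, 7))
  expect_equal(m$values[12], 0.6)

  # doubling all inputs leaves the normalized map unchanged
  m2 <- normalize_polar_map(make_map(g, 2 * v), c(1:5, 7))
  expect_equal(m$values, m2$values)

  expect_error(normalize_polar_map(make_map(g, rep(0, g$n_cells)), 1:6),
               "positive")
})

test_that("defect size counts strictly-below-threshold weight in %LV", {
  g <- polar_grid()  # 400 cells
  ones <- polar_map(g, rep(1, g$n_cells), normalized = TRUE)
  expect_equal(defect_size(ones), 0)

  v <- rep(1, g$n_cells)
  v[1:128] <- 0.4  # 32 % of the LV weight
  pm <- polar_map(g, v, normalized = TRUE)
  expect_equal(defect_size(pm), 32)

  all_low <- polar_map(g, rep(0.59, g$n_cells), normalized = TRUE)
  expect_equal(defect_size(all_low), 100)

  # a cell exactly at the threshold is not defect
  at <- polar_map(g, c(rep(0.6, 10), rep(1, g$n_cells - 10)), normalized = TRUE)
  expect_equal(defect_size(at), 0)

  expect_error(defect_size(ones, threshold = 0), "strictly inside")
  expect_error(defect_size(ones, threshold = 1), "strictly inside")
  expect_error(defect_size(make_map(g, v)), "normalized")
})

test_that("mismatch is the literal difference, negatives allowed", {
  expect_equal(mismatch_size(68, 32), 36)
  expect_equal(mismatch_size(12.5, 12.5), 0)
  expect_equal(mismatch_size(30, 40), -10)
  expect_error(mismatch_size(-1, 0))
  expect_error(mismatch_size(101, 0))
})

test_that("retention index: ratio of late uptake to blood integral", {
  g <- polar_grid(2, 4)
  sched <- hed_schedule()
  bc <- blood_curve(frame_mid_min(sched),
                    20 * exp(-frame_mid_min(sched) / 10))
  integral <- integrate_blood_curve(bc, 40)

  # late uptake numerically equal to the blood integral -> retention 100
  vals <- outer(rep(1, n_frames(sched)), rep(integral, g$n_cells))
  dpm <- dynamic_polar_map(g, sched, vals)
  expect_equal(retention_index(dpm, bc), 100)
  expect_equal(retention_index(dpm, bc, retention_scale = "per_min"), 1)

  zero_blood <- blood_curve(frame_mid_min(sched), rep(0, n_frames(sched)))
  expect_error(retention_index(dpm, zero_blood), "positive")
})

test_that("quantification is invariant to a global intensity rescale", {
  g <- polar_grid(6, 12)
  truth <- study_truth(9, 25, 50, defect_depth = 0.4)
  st <- generate_study(truth, g, seed = 5)
  q1 <- quantify_study(st)
  scaled <- st
  scaled$hed <- dynamic_polar_map(g, st$hed$schedule, st$hed$values * 3.7)
  scaled$acetate <- dynamic_polar_map(g, st$acetate$schedule,
                                      st$acetate$values * 3.7)
  scaled$blood_hed <- blood_curve(st$blood_hed$mid_time_min,
                                  st$blood_hed$activity * 3.7)
  q2 <- quantify_study(scaled)
  expect_equal(q2$retention, q1$retention)
  expect_equal(q2$perfusion_defect, q1$perfusion_defect)
  expect_equal(q2$hed_defect, q1$hed_defect)
})

test_that("defect size is monotone in depth and extent", {
  g <- polar_grid(6, 12)
  # deeper defects never shrink the measured size
  sizes <- vapply(c(0.8, 0.59, 0.3, 0.1), function(d) {
    truth <- study_truth(9, 25, 25, defect_depth = d)
    quantify_study(generate_study(truth, g, seed = 1))$hed_defect
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  # wider wedges never shrink it either
  sizes <- vapply(c(0, 25, 50, 75), function(e) {
    truth <- study_truth(9, e, e, defect_depth = 0.4)
    quantify_study(generate_study(truth, g, seed = 1))$hed_defect
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("defect and non-defect weights always partition 100 %LV", {
  g <- polar_grid(5, 9)
  set.seed(42)
  for (i in 1:20) {
    pm <- polar_map(g, runif(g$n_cells, 0.2, 1.4), normalized = TRUE)
    d <- defect_size(pm, 0.6)
    nond <- 100 * sum(pm$values >= 0.6) * g$cell_weight
    expect_equal(d + nond, 100)
  }
})
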