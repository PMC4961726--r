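test_that("study_truth enforces its invariants", {
  expect_error(study_truth(9, defect_depth = 1.0), "defect_depth")
  expect_error(study_truth(9, perfusion_defect_extent = 50,
                           hed_defect_extent = 40), ">=")
  expect_error(study_truth(9, perfusion_defect_extent = -1), "\\[0, 100\\]")
  expect_error(study_truth(-2))
  expect_error(study_truth(9, blood_params = list(amplitude = -1, alpha = 2,
                                                  beta_min = 1, recirc = 0)))
})

test_that("regeneration with the same truth, grid and seed is bit-identical", {
  truth <- study_truth(9, 12.5, 25, defect_depth = 0.3, noise_scale = 1)
  g <- polar_grid(6, 12)
  a <- generate_study(truth, g, seed = 7)
  b <- generate_study(truth, g, seed = 7)
  expect_identical(a$hed$values, b$hed$values)
  expect_identical(a$acetate$values, b$acetate$values)
  expect_identical(a$blood_hed, b$blood_hed)
  c <- generate_study(truth, g, seed = 8)
  expect_false(identical(a$hed$values, c$hed$values))
})

test_that("noise-free studies recover the true retention exactly", {
  g <- polar_grid(6, 12)
  for (r in c(5, 7.1, 9.0, 12)) {
    st <- generate_study(study_truth(r), g, seed = 1)
    q <- quantify_study(st)
    expect_lt(abs(q$retention - r) / r, 1e-6)
    expect_equal(q$perfusion_defect, 0)
    expect_equal(q$hed_defect, 0)
    expect_equal(q$mismatch, 0)
  }
})

test_that("implanted wedge extents are recovered exactly when detectable", {
  g <- polar_grid()  # 400 cells, 0.25 %LV each
  cases <- list(c(10, 25), c(32, 68), c(0, 40), c(25, 25))
  for (cs in cases) {
    truth <- study_truth(9, cs[1], cs[2], defect_depth = 0.4)
    q <- quantify_study(generate_study(truth, g, seed = 3))
    expect_equal(q$perfusion_defect, cs[1])
    expect_equal(q$hed_defect, cs[2])
    expect_equal(q$mismatch, cs[2] - cs[1])
  }
})

test_that("a shallow defect (depth above threshold) is invisible", {
  g <- polar_grid()
  truth <- study_truth(9, 32, 68, defect_depth = 0.99)
  q <- quantify_study(generate_study(truth, g, seed = 2))
  expect_equal(q$perfusion_defect, 0)
  expect_equal(q$hed_defect, 0)
})

test_that("unrepresentable extents error and list the achievable granularity", {
  g <- polar_grid(2, 4)  # 8 cells, 12.5 %LV each
  expect_error(generate_study(study_truth(9, 5, 5), g),
               "achievable extents are multiples of 12.5")
  expect_equal(snap_extent(g, 5), 0)
  expect_equal(snap_extent(g, 30), 25)
  # exactly representable extents pass through snap_extent unchanged
  expect_equal(snap_extent(polar_grid(), 32), 32)
})

test_that("noisy retention estimates are unbiased within 2 %", {
  g <- polar_grid(6, 12)
  truth <- study_truth(9, noise_scale = 1)
  est <- vapply(1:100, function(s) {
    st <- generate_study(truth, g, seed = s)
    retention_index(st$hed, st$blood_hed)
  }, numeric(1))
  expect_lt(abs(mean(est) - 9) / 9, 0.02)
})

test_that("noisy defect sizes stay close to the implanted extents", {
  g <- polar_grid()
  truth <- study_truth(9, 32, 68, defect_depth = 0.4, noise_scale = 0.5)
  q <- quantify_study(generate_study(truth, g, seed = 11))
  expect_lt(abs(q$perfusion_defect - 32), 3)
  expect_lt(abs(q$hed_defect - 68), 3)
})
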