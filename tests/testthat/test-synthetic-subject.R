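test_that("covariance specs validate and repair their target matrix", {
  expect_error(network_cov_spec(c("a", "b"),
                                matrix(c(1, 0.2, 0.4, 1), 2)), "symmetric")
  expect_error(network_cov_spec(c("a", "b"),
                                matrix(c(2, 0, 0, 1), 2)), "unit diagonal")
  # clearly indefinite: all pairwise r = -0.9 among 3 variables
  bad <- matrix(-0.9, 3, 3); diag(bad) <- 1
  expect_error(network_cov_spec(letters[1:3], bad), "positive semidefinite")
  # borderline case within tolerance is repaired, not rejected
  m <- matrix(c(1, 1 + 1e-9, 1 + 1e-9, 1), 2)
  spec <- network_cov_spec(c("a", "b"), m)
  ev <- eigen(spec$target_corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
})

test_that("empirical ROI correlations recover the target within sampling error", {
  # identity target: all off-diagonal correlations near zero
  sp0 <- network_cov_spec(letters[1:4], diag(4))
  r0 <- simulate_rest_run(sp0, n_volumes = 10000, seed = 2)
  m0 <- roi_matrix(preprocess_rest_run(r0))
  expect_lt(max(abs(m0$r[upper.tri(m0$r)])), 0.05)
  # the pre-training anticorrelation level
  sp <- network_cov_spec(c("lM1", "lLP"), matrix(c(1, -0.3, -0.3, 1), 2))
  rr <- simulate_rest_run(sp, n_volumes = 10000, seed = 3)
  m <- roi_matrix(preprocess_rest_run(rr))
  expect_equal(m$r["lM1", "lLP"], -0.3, tolerance = 0.05 / 0.3)
  expect_lt(abs(m$r["lM1", "lLP"] + 0.3), 0.05)
})

test_that("rest runs are reproducible and reject degenerate lengths", {
  sp <- network_cov_spec(c("a", "b"), matrix(c(1, 0.5, 0.5, 1), 2))
  r1 <- simulate_rest_run(sp, n_volumes = 50, seed = 4)
  r2 <- simulate_rest_run(sp, n_volumes = 50, seed = 4)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$confounds, r2$confounds)
  expect_error(simulate_rest_run(sp, n_volumes = 1), "at least 3")
})

test_that("volume-mode runs place ROI signal on the registry grid", {
  g <- vol_grid(c(10, 10, 6), c(3, 3, 3.5), c(-13.5, -13.5, -8.75))
  reg <- roi_registry(tibble::tibble(
    name = c("a", "b"), network = c("MVN", "DMN"),
    x = c(-6, 6), y = 0, z = 0, radius_mm = 4), g)
  sp <- network_cov_spec(c("a", "b"), matrix(c(1, -0.5, -0.5, 1), 2),
                         hrf_smoothing = 0)
  b <- simulate_rest_run(sp, n_volumes = 400, registry = reg, seed = 5)
  expect_s3_class(b, "cf_bold")
  expect_equal(dim(b$data), c(g$shape, 400))
  m <- roi_matrix(b, registry = reg)
  expect_equal(m$r["a", "b"], -0.5, tolerance = 0.4)
  expect_lt(m$r["a", "b"], -0.2)
})

test_that("study bookkeeping records group sizes and exact injected deltas", {
  st <- simulate_study(seed = 1)
  expect_equal(nrow(st$subjects), 33)
  expect_equal(unname(table(st$subjects$group)[c("neurofeedback", "sham",
                                                 "imagery")]),
               c(12L, 12L, 9L), ignore_attr = TRUE)
  gt <- st$ground_truth
  expect_equal(gt$delta[gt$group == "neurofeedback" &
                          gt$pair_type == "MVN-DMN"], 0.2)
  expect_true(all(gt$delta[!(gt$group == "neurofeedback" &
                               gt$pair_type == "MVN-DMN")] == 0))
  # null study: zero deltas everywhere
  st0 <- simulate_study(study_config(delta = 0), seed = 1)
  expect_true(all(st0$ground_truth$delta == 0))
  expect_true(all(st0$runs$delta == 0))
})

test_that("study runs regenerate bit-identically from their stored seeds", {
  st <- simulate_study(study_config(groups = c(neurofeedback = 2, sham = 2),
                                    sessions = c("pre", "post")), seed = 6)
  r1 <- study_run(st, st$runs$subject[1], "pre")
  r2 <- study_run(st, st$runs$subject[1], "pre")
  expect_identical(r1$series, r2$series)
  expect_error(study_run(st, "nobody", "pre"), "no run")
})

test_that("null studies differ between sessions only by sampling noise", {
  st0 <- simulate_study(study_config(delta = 0,
                                     groups = c(neurofeedback = 6),
                                     sessions = c("pre", "post")), seed = 8)
  mats <- study_matrices(st0)
  d <- difference_matrices(mats, "post-pre")
  m <- d$group_mean$neurofeedback
  vals <- m[upper.tri(m)]
  # group-mean difference cells should be centered near zero
  expect_lt(abs(mean(vals)), 0.05)
  expect_lt(max(abs(vals)), 0.5)
})
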