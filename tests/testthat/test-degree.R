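test_that("Gaussian smoothing matches the sampled kernel and conserves mass", {
  g <- small_grid(c(9, 9, 9), c(2, 2, 2))
  vol <- array(0, g$shape); vol[5, 5, 5] <- 1
  sm <- smooth_volume(vol, fwhm_mm = 4, vox_mm = g$vox_mm)
  # oracle: separable product of sampled, normalized 1D Gaussians
  sigma <- 4 / (2 * sqrt(2 * log(2))) / 2
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  expected <- array(0, g$shape)
  for (i in -r:r) for (j in -r:r) for (k in -r:r) {
    expected[5 + i, 5 + j, 5 + k] <- k1[i + r + 1] * k1[j + r + 1] * k1[k + r + 1]
  }
  expect_lt(max(abs(sm - expected)), 1e-6)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # identity at zero width
  expect_identical(smooth_volume(vol, 0, g$vox_mm), vol)
  expect_error(smooth_volume(vol, -1, g$vox_mm), ">= 0")
})

test_that("blockwise degree map equals brute-force pairwise correlation counts", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(144 * 40), 144)
    for (bs in c(7, 50, 1000)) {
      d <- degree_map(X, degree_params(-0.25, "less"), block_size = bs)
      cc <- cor(t(X)); diag(cc) <- NA
      expect_identical(as.integer(d), as.integer(rowSums(cc < -0.25,
                                                         na.rm = TRUE)))
    }
  }
  # explicit double-loop oracle on one small volume
  set.seed(99)
  Y <- matrix(rnorm(30 * 25), 30)
  oracle <- integer(30)
  for (i in 1:30) for (j in 1:30) {
    if (i != j && cor(Y[i, ], Y[j, ]) < -0.25) oracle[i] <- oracle[i] + 1L
  }
  expect_identical(as.integer(degree_map(Y, degree_params(-0.25, "less"))),
                   oracle)
})

test_that("each below-threshold pair contributes one count to both voxels", {
  X <- single_pair_volume(20, a = 3, b = 11, r = -0.4)
  d <- degree_map(X, degree_params(-0.25, "less"))
  expect_equal(d[3], 1L)
  expect_equal(d[11], 1L)
  expect_true(all(d[-c(3, 11)] == 0L))
})

test_that("directional duality holds per voxel under series negation", {
  set.seed(7)
  X <- matrix(rnorm(40 * 30), 40)
  d_less <- degree_map(X, degree_params(-0.3, "less"))
  for (v in c(1, 17, 40)) {
    Xn <- X; Xn[v, ] <- -Xn[v, ]
    d_gr <- degree_map(Xn, degree_params(0.3, "greater"))
    # negating one voxel's series flips all its correlations, so its degree
    # under the mirrored relation matches (minus the self-pair convention)
    expect_equal(d_gr[v], d_less[v])
  }
})

test_that("zero-variance voxels are excluded with a warning", {
  X <- rbind(matrix(rnorm(10 * 20), 10), rep(1, 20))
  expect_warning(d <- degree_map(X, degree_params(-0.25, "less")),
                 "zero-variance")
  expect_true(is.na(d[11]))
  expect_false(anyNA(d[1:10]))
})

test_that("paired degree t map matches the textbook formula", {
  pre <- list(array(c(3, 5), c(1, 1, 2)), array(c(4, 5), c(1, 1, 2)),
              array(c(6, 5), c(1, 1, 2)))
  post <- list(array(c(1, 5), c(1, 1, 2)), array(c(3, 5), c(1, 1, 2)),
               array(c(2, 5), c(1, 1, 2)))
  res <- degree_change_test(pre, post)
  d <- c(1 - 3, 3 - 4, 2 - 6)
  expect_equal(res$t[1, 1, 1], mean(d) / (sd(d) / sqrt(3)))
  expect_equal(res$t[1, 1, 2], 0) # unchanged voxel
  expect_equal(res$df, 2)
  # sign flip of all differences negates the map
  res_fl <- degree_change_test(post, pre)
  expect_equal(res_fl$t, -res$t)
  # identical maps: t = 0 everywhere
  res0 <- degree_change_test(pre, pre)
  expect_true(all(res0$t == 0))
})

test_that("cluster extraction finds hand-crafted components", {
  stat <- array(0, c(6, 6, 3))
  # L-shaped 5-voxel blob (edge-connected)
  stat[2, 2:4, 2] <- 1; stat[3:4, 4, 2] <- 1
  cl <- find_clusters(stat, 0.5, connectivity = 18)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$size, 5)
  # an isolated voxel is dropped below min_size
  stat2 <- array(0, c(6, 6, 3)); stat2[1, 1, 1] <- 1
  expect_equal(nrow(find_clusters(stat2, 0.5, min_size = 2)$clusters), 0)
  # diagonal-in-plane voxels: connected at 18, separate at 6
  stat3 <- array(0, c(4, 4, 1)); stat3[1, 1, 1] <- 1; stat3[2, 2, 1] <- 1
  expect_equal(nrow(find_clusters(stat3, 0.5, connectivity = 6)$clusters), 2)
  expect_equal(nrow(find_clusters(stat3, 0.5, connectivity = 18)$clusters), 1)
  # full suprathreshold mask is one cluster
  cl_all <- find_clusters(array(1, c(3, 3, 2)), 0.5)
  expect_equal(cl_all$clusters$size, 18)
  expect_error(find_clusters(stat, 0.5, connectivity = 10), "connectivity")
})

test_that("Monte-Carlo cluster threshold is deterministic and grows with smoothing", {
  mask <- array(TRUE, c(8, 8, 4))
  m1 <- cluster_threshold_mc(mask, c(3, 3, 3.5), fwhm_mm = 0,
                             voxel_p = 0.001, n_iter = 200, seed = 1)
  expect_lte(m1$min_cluster_size, 3)
  m1b <- cluster_threshold_mc(mask, c(3, 3, 3.5), fwhm_mm = 0,
                              voxel_p = 0.001, n_iter = 200, seed = 1)
  expect_identical(m1$max_sizes, m1b$max_sizes)
  m2 <- cluster_threshold_mc(mask, c(3, 3, 3.5), fwhm_mm = 8,
                             voxel_p = 0.001, n_iter = 200, seed = 1)
  expect_gte(m2$min_cluster_size, m1$min_cluster_size)
  expect_error(cluster_threshold_mc(array(FALSE, c(2, 2, 2)), c(3, 3, 3),
                                    4, n_iter = 200), "empty")
  expect_error(cluster_threshold_mc(mask, c(3, 3, 3.5), 4, n_iter = 10),
               "at least 100")
})

test_that("ROI significance ratios count suprathreshold voxels per region", {
  g <- vol_grid(c(10, 10, 6), c(3, 3, 3.5), c(-13.5, -13.5, -8.75))
  reg <- roi_registry(tibble::tibble(
    name = c("a", "b"), network = c("MVN", "DMN"),
    x = c(-6, 6), y = 0, z = 0, radius_mm = 4), g)
  sig <- array(FALSE, g$shape)
  r0 <- roi_significance_ratio(sig, reg)
  expect_true(all(r0$pct == 0))
  sig[] <- TRUE
  r1 <- roi_significance_ratio(sig, reg)
  expect_true(all(r1$pct == 100))
  # hand case: 3 of n voxels significant
  vox <- voxelize_roi(reg[1, ], g)
  sig[] <- FALSE
  sig[attr(vox, "linear")[1:3]] <- TRUE
  r2 <- roi_significance_ratio(sig, reg)
  expect_equal(r2$pct[r2$name == "a"], 300 / nrow(vox))
})

test_that("the degree pipeline flags injected anticorrelation weakening only where present", {
  dd <- degree_demo(seed = 2, n_subjects = 5, n_volumes = 120, mc_iter = 150)
  cl_tr <- dd$results$trained$clusters$clusters
  cl_ct <- dd$results$control$clusters$clusters
  expect_gt(nrow(cl_tr), 0)
  expect_equal(nrow(cl_ct), 0)
  # the detected decrease lies inside the two target ROIs
  vox <- voxelize_registry(dd$registry)
  labels <- dd$results$trained$clusters$labels
  inside <- which(labels > 0)
  expect_true(all(inside %in% vox$linear))
})

test_that("threshold sweep reduces to the pipeline at a single threshold", {
  set.seed(5)
  mask <- array(TRUE, c(5, 5, 3))
  g <- vol_grid(c(5, 5, 3), c(3, 3, 3.5), c(-6, -6, -3.5))
  pre <- replicate(3, matrix(rnorm(75 * 40), 75), simplify = FALSE)
  post <- replicate(3, matrix(rnorm(75 * 40), 75), simplify = FALSE)
  sw <- threshold_sweep(pre, post, mask, g, thetas = -0.25, n_iter = 150,
                        seed = 3)
  direct <- degree_pipeline(pre, post, mask, g, threshold = -0.25,
                            n_iter = 150, seed = 3)
  expect_equal(sw$n_clusters, nrow(direct$clusters$clusters))
})
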