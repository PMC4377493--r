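test_that("default registry reproduces the 16-ROI network layout", {
  reg <- load_roi_registry("default")
  expect_equal(nrow(reg), 16)
  counts <- table(reg$network)
  expect_equal(unname(counts[c("MVN", "DMN", "control")]),
               c(8L, 4L, 4L), ignore_attr = TRUE)
  expect_true(all(c("lM1", "lLP", "PCC", "MPF", "rFEF", "lA1") %in% reg$name))
  # published sphere centers carried verbatim
  llp <- reg[reg$name == "lLP", ]
  expect_equal(c(llp$x, llp$y, llp$z), c(-45, -67, 36))
  expect_equal(llp$radius_mm, 7.5)
  expect_false(llp$synthetic)
  # anatomically defined regions are flagged as synthetic stand-ins
  expect_true(all(reg$synthetic[reg$name %in% c("lM1", "rSMA", "lV1", "rA1")]))
})

test_that("registry validation rejects malformed input", {
  expect_error(roi_registry(tibble::tibble(
    name = c("lM1", "lM1"), network = "MVN", x = 0, y = 0, z = 0,
    radius_mm = 7.5)), "duplicate")
  expect_error(roi_registry(tibble::tibble(
    name = "a", network = "motor", x = 0, y = 0, z = 0, radius_mm = 7.5)),
    "unknown network")
  expect_error(roi_registry(tibble::tibble(
    name = "a", network = "MVN", x = 0, y = 0, z = 0, radius_mm = 0)),
    "radius")
  expect_error(roi_registry(tibble::tibble(name = "a", network = "MVN")),
    "sphere center")
})

test_that("registry round-trips through its TSV format losslessly", {
  reg <- load_roi_registry("default")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_roi_registry(reg, f)
  reg2 <- load_roi_registry(f)
  expect_equal(tibble::as_tibble(reg), tibble::as_tibble(reg2))
})

test_that("sphere voxelization equals the brute-force distance test", {
  # 1-mm isotropic grid, the published 7.5-mm sphere
  g <- vol_grid(c(21, 21, 21), c(1, 1, 1), c(-10, -10, -10))
  roi <- list(name = "s", x = 0, y = 0, z = 0, radius_mm = 7.5,
              mask_path = NA)
  vox <- voxelize_roi(roi, g)
  # oracle: exhaustive triple loop over the containing neighborhood
  brute <- 0L
  for (i in -10:10) for (j in -10:10) for (k in -10:10) {
    if (i^2 + j^2 + k^2 <= 7.5^2) brute <- brute + 1L
  }
  expect_equal(nrow(vox), brute)
  # anisotropic grid agrees with the distance test too
  g2 <- small_grid(c(11, 11, 7))
  vox2 <- voxelize_roi(list(name = "s", x = 0, y = 0, z = 0,
                            radius_mm = 6, mask_path = NA), g2)
  mm <- vox_to_mni(as.matrix(expand.grid(0:10, 0:10, 0:6)), g2)
  expect_equal(nrow(vox2), sum(rowSums(mm^2) <= 36))
})

test_that("degenerate and out-of-grid spheres behave as specified", {
  g <- vol_grid(c(9, 9, 9), c(1, 1, 1), c(-4, -4, -4))
  vox <- voxelize_roi(list(name = "pt", x = 0, y = 0, z = 0,
                           radius_mm = 0.1, mask_path = NA), g)
  expect_equal(nrow(vox), 1)
  expect_equal(unname(vox[1, ]), c(4L, 4L, 4L))
  expect_error(voxelize_roi(list(name = "far", x = 1000, y = 0, z = 0,
                                 radius_mm = 5, mask_path = NA), g),
               "outside the grid")
})

test_that("mask-defined ROIs are read from NIfTI and grid-checked", {
  g <- small_grid(c(6, 6, 4))
  mask <- array(0, g$shape)
  mask[2:3, 2:3, 2] <- 1
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(mask), f)
  vox <- voxelize_roi(list(name = "m", x = NA, y = NA, z = NA,
                           radius_mm = NA, mask_path = f), g)
  expect_equal(nrow(vox), 4)
  g_bad <- small_grid(c(5, 5, 4))
  expect_error(voxelize_roi(list(name = "m", x = NA, y = NA, z = NA,
                                 radius_mm = NA, mask_path = f), g_bad),
               "does not match")
})

test_that("network-pair partition is exhaustive with the expected cell counts", {
  part <- default_partition()
  expect_equal(nrow(part), 16 * 15 / 2)
  counts <- table(part$pair_type)
  expect_equal(unname(counts[network_pair_types()]),
               c(28L, 32L, 6L, 32L, 16L, 6L), ignore_attr = TRUE)
  # every unordered pair appears exactly once
  keys <- paste(pmin(part$roi_a, part$roi_b), pmax(part$roi_a, part$roi_b))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("pair partition stays exhaustive and disjoint for random registries", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(2:12, 1)
    reg <- tibble::tibble(
      name = paste0("r", seq_len(n)),
      network = sample(c("MVN", "DMN", "control"), n, replace = TRUE),
      x = 0, y = 0, z = 0, radius_mm = 5)
    part <- partition_network_pairs(roi_registry(reg))
    expect_equal(nrow(part), n * (n - 1) / 2)
    expect_false(anyNA(part$pair_type))
  }
  # single-network registry: one nonempty type with k(k-1)/2 pairs
  reg1 <- roi_registry(tibble::tibble(name = paste0("m", 1:5),
                                      network = "MVN", x = 0, y = 0, z = 0,
                                      radius_mm = 5))
  p1 <- partition_network_pairs(reg1)
  expect_equal(nrow(p1), 10)
  expect_true(all(p1$pair_type == "MVN-MVN"))
})
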