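test_that("nuisance regression leaves residuals orthogonal to confounds", {
  sp <- network_cov_spec(c("a", "b"), matrix(c(1, -0.3, -0.3, 1), 2))
  run <- simulate_rest_run(sp, n_volumes = 100, seed = 1)
  cl <- preprocess_rest_run(run)
  X <- as.matrix(cl$confounds)
  for (j in seq_len(ncol(X))) {
    cors <- abs(cl$series %*% (X[, j] - mean(X[, j])))
    expect_lt(max(cors), 1e-8)
  }
  expect_equal(cl$n_volumes, 98) # first two volumes discarded
})

test_that("a signal equal to a confound is regressed to zero", {
  conf <- tibble::tibble(c1 = rnorm(50))
  Y <- matrix(rep(conf$c1, 3), 3, byrow = TRUE) * c(1, -2, 0.5)
  res <- connfeed:::residualize(Y, as.matrix(conf))
  expect_lt(max(abs(res)), 1e-10)
})

test_that("rank-deficient confounds give the same residuals via pseudo-inverse", {
  set.seed(2)
  Y <- matrix(rnorm(5 * 60), 5)
  X <- matrix(rnorm(60 * 3), 60)
  X_dup <- cbind(X, X[, 1], 2 * X[, 2])
  expect_equal(connfeed:::residualize(Y, X),
               connfeed:::residualize(Y, X_dup), tolerance = 1e-10)
})

test_that("confound/volume count mismatches are rejected", {
  sp <- network_cov_spec("a", matrix(1))
  run <- simulate_rest_run(sp, n_volumes = 30, seed = 3)
  expect_error(preprocess_rest_run(run, confounds = run$confounds[1:10, ]),
               "match neither")
})

test_that("Fisher z transform matches the closed form and caps degeneracy", {
  series <- rbind(a = sin(1:50), b = numeric(50), c = cos(1:50))
  series["b", ] <- 0.5 * series["a", ] +
    sqrt(0.75) * rnorm(50)
  m <- roi_matrix(series)
  expect_equal(m$z["a", "b"], atanh(m$r["a", "b"]))
  expect_equal(atanh(0.5), 0.5493061, tolerance = 1e-6)
  expect_true(all(is.na(diag(m$z))))
  expect_equal(m$z, t(m$z))
  # identical ROI series: capped with a warning, not infinite
  dup <- rbind(a = sin(1:50) + 0.01 * (1:50), b = sin(1:50) + 0.01 * (1:50))
  expect_warning(md <- roi_matrix(dup), "capped")
  expect_equal(md$z["a", "b"], atanh(1 - 1e-6))
  expect_error(roi_matrix(rbind(a = rep(1, 20), b = rnorm(20))),
               "zero-variance ROI")
})

test_that("difference matrices subtract sessions and average within groups", {
  z1 <- matrix(c(NA, 0.2, 0.2, NA), 2, dimnames = list(c("a", "b"), c("a", "b")))
  z2 <- z1; z2[1, 2] <- z2[2, 1] <- 0.5
  mats <- tibble::tibble(
    group = "g", subject = c("s1", "s1", "s2", "s2"),
    session = c("pre", "post", "pre", "post"),
    z = list(z1, z2, z1, z1))
  d <- difference_matrices(mats, "post-pre")
  expect_equal(d$per_subject$delta[[1]][1, 2], 0.3)
  expect_equal(d$per_subject$delta[[2]][1, 2], 0)
  expect_equal(d$group_mean$g[1, 2], 0.15)
  # swapping the contrast negates the result
  d2 <- difference_matrices(mats, "pre-post")
  expect_equal(d2$group_mean$g[1, 2], -0.15)
  # identical sessions give a zero matrix
  mats0 <- dplyr::mutate(mats, z = list(z1, z1, z1, z1))
  d0 <- difference_matrices(mats0, "post-pre")
  expect_true(all(d0$group_mean$g[upper.tri(z1)] == 0))
})

test_that("colored-cell threshold is pooled mean + SD with strict exceedance", {
  # hand-built: 3 ROIs (one per network), two groups
  reg <- roi_registry(tibble::tibble(name = c("m", "d", "c"),
                                     network = c("MVN", "DMN", "control"),
                                     x = 0, y = 0, z = 0, radius_mm = 5))
  part <- partition_network_pairs(reg)
  mk <- function(v) {
    m <- matrix(0, 3, 3, dimnames = list(reg$name, reg$name))
    m[upper.tri(m)] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  gm <- list(g1 = mk(c(0.30, 0.00, 0.05)), g2 = mk(c(-0.05, 0.02, 0.04)))
  cc <- colored_cells(gm, part)
  pool <- c(0.30, 0.00, 0.05, -0.05, 0.02, 0.04)
  expect_equal(cc$threshold, mean(pool) + sd(pool))
  expect_equal(sum(cc$cells$colored), sum(pool > mean(pool) + sd(pool)))
  expect_equal(cc$counts$n_colored[cc$counts$group == "g1" &
                                     cc$counts$pair_type == "MVN-DMN"], 1L)
  # the printed-moments rule: mean -0.02 and SD 0.09 give threshold 0.07
  expect_equal(-0.02 + 0.09, 0.07)
  # all cells equal: SD 0, nothing colored under strict inequality
  cc0 <- colored_cells(list(g1 = mk(rep(0.1, 3)), g2 = mk(rep(0.1, 3))), part)
  expect_equal(sum(cc0$cells$colored), 0)
})

test_that("bootstrap pair test matches a binomial-tail oracle on a constructed case", {
  part <- default_partition()
  mk16 <- function() {
    m <- matrix(0, 16, 16)
    rn <- load_roi_registry("default")$name
    dimnames(m) <- list(rn, rn)
    m
  }
  # one pair type entirely colored, everything else at zero
  nf <- mk16()
  ut <- which(upper.tri(nf))
  nf[ut[part$pair_type == "MVN-DMN"]] <- 1
  gm <- list(neurofeedback = nf, sham = mk16(), imagery = mk16())
  cc <- colored_cells(gm, part)
  bt <- bootstrap_pair_test(cc, n_boot = 3000, seed = 5)
  sig <- bt[bt$significant, ]
  expect_equal(nrow(sig), 1)
  expect_equal(as.character(sig$pair_type), "MVN-DMN")
  expect_equal(sig$group, "neurofeedback")
  # oracle: resampled colored counts are Binomial(m, pooled coloring rate)
  p_pool <- 32 / 360
  level <- 1 - (0.05 / 18) / 2
  for (m_cells in c(32, 6)) {
    row <- bt[bt$group == "sham" & bt$n_cells == m_cells, ][1, ]
    expect_lte(abs(row$ci_upper - qbinom(level, m_cells, p_pool)), 2)
  }
  # determinism
  bt2 <- bootstrap_pair_test(cc, n_boot = 3000, seed = 5)
  expect_identical(tibble::as_tibble(bt), tibble::as_tibble(bt2))
  # nothing colored anywhere: no significance possible
  cc0 <- colored_cells(list(neurofeedback = mk16(), sham = mk16(),
                            imagery = mk16()), part)
  bt0 <- bootstrap_pair_test(cc0, n_boot = 3000, seed = 1)
  expect_false(any(bt0$significant))
  expect_error(bootstrap_pair_test(cc, n_boot = 200), "too small")
})

test_that("matrix statistics are invariant under registry permutation", {
  st <- simulate_study(study_config(groups = c(neurofeedback = 3),
                                    sessions = c("pre", "post")), seed = 9)
  mats <- study_matrices(st)
  reg <- roi_registry(st$roi_table)
  part <- partition_network_pairs(reg)
  cc <- colored_cells(difference_matrices(mats, "post-pre"), part)
  # permute ROIs consistently everywhere
  set.seed(1); perm <- sample(16)
  reg_p <- roi_registry(st$roi_table[perm, ])
  mats_p <- dplyr::mutate(mats, z = purrr::map(z, ~ .x[perm, perm]))
  cc_p <- colored_cells(difference_matrices(mats_p, "post-pre"),
                        partition_network_pairs(reg_p))
  expect_equal(cc_p$threshold, cc$threshold)
  expect_equal(dplyr::arrange(cc_p$counts, group, pair_type),
               dplyr::arrange(cc$counts, group, pair_type))
})
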