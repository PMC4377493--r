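# Shared fixtures: small grids and exact-correlation series constructions.

small_grid <- function(shape = c(6L, 6L, 4L), vox = c(3, 3, 3.5)) {
  vol_grid(shape, vox, -(shape - 1) / 2 * vox)
}

# n mutually orthonormal, exactly mean-zero series of length t_len.
# Orthogonality in the centered space makes every pairwise Pearson
# correlation exactly 0.
orth_series <- function(n, t_len, seed = 1) {
  stopifnot(t_len >= n + 2)
  set.seed(seed)
  m <- matrix(rnorm(t_len * n), t_len, n)
  m <- sweep(m, 2, colMeans(m))
  q <- qr.Q(qr(m))
  sweep(q, 2, colMeans(q)) # numerically re-center
}

# Two series with Pearson correlation exactly r, built from an orthonormal
# mean-zero basis.
corr_pair <- function(r, basis) {
  cbind(basis[, 1], r * basis[, 1] + sqrt(1 - r^2) * basis[, 2])
}

# Voxels x time matrix for the single-pair degree example: voxels `a` and
# `b` correlate exactly r; every other voxel is pairwise uncorrelated with
# everything.
single_pair_volume <- function(n_vox, a, b, r, t_len = n_vox + 5, seed = 1) {
  basis <- orth_series(n_vox + 1, t_len, seed)
  X <- t(basis[, seq_len(n_vox) + 1])
  pair <- corr_pair(r, basis[, 1:2])
  X[a, ] <- pair[, 1]
  X[b, ] <- pair[, 2]
  X
}

# Two-block volume: ROI A voxels share one series, ROI B voxels share
# another, cross-correlation exactly r; background voxels uncorrelated.
two_block_volume <- function(n_a, n_b, n_bg, r, t_len = NULL, seed = 1) {
  if (is.null(t_len)) t_len <- n_bg + 8
  basis <- orth_series(n_bg + 2, t_len, seed)
  pair <- corr_pair(r, basis[, 1:2])
  rbind(
    matrix(rep(pair[, 1], n_a), n_a, t_len, byrow = TRUE),
    matrix(rep(pair[, 2], n_b), n_b, t_len, byrow = TRUE),
    t(basis[, seq_len(n_bg) + 2, drop = FALSE])
  )
}

default_partition <- function() {
  partition_network_pairs(load_roi_registry("default"))
}
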