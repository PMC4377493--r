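#' Spatial Gaussian smoothing of a volume or 4D run
#'
#' Separable 3D Gaussian smoothing with per-axis sigma
#' `fwhm_mm / 2.3548 / voxel_size`. Kernels are sampled, normalized to unit
#' sum and truncated at 4 sigma; borders use zero padding. `fwhm_mm = 0` is
#' the identity.
#'
#' @param x 3D array, 4D array (smoothed volume-by-volume) or [bold_run()].
#' @param fwhm_mm full width at half maximum (mm), >= 0.
#' @param vox_mm voxel sizes (mm, length 3); taken from the run for
#'   `cf_bold` input.
#' @return Smoothed object of the same type.
#' @export
smooth_volume <- function(x, fwhm_mm, vox_mm = NULL) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (inherits(x, "cf_bold")) {
    x$data <- smooth_volume(x$data, fwhm_mm, x$grid$vox_mm)
    return(x)
  }
  stopifnot(!is.null(vox_mm), length(vox_mm) == 3)
  if (fwhm_mm == 0) return(x)
  nd <- length(dim(x))
  stopifnot(nd %in% c(3, 4))
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox_mm
  if (nd == 4) {
    for (t in seq_len(dim(x)[4])) {
      x[, , , t] <- smooth_volume(x[, , , t], fwhm_mm, vox_mm)
    }
    return(x)
  }
  for (ax in 1:3) {
    x <- convolve_axis(x, gauss_kernel(sigma[ax]), ax)
  }
  x
}

gauss_kernel <- function(sigma) {
  if (sigma < 1e-12) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# zero-padded 1D convolution along axis `ax` of a 3D array
convolve_axis <- function(x, kernel, ax) {
  if (length(kernel) == 1) return(x * kernel)
  d <- dim(x)
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  m <- matrix(xp, dim(x)[ax])
  r <- (length(kernel) - 1L) / 2L
  pad <- matrix(0, r, ncol(m))
  mp <- rbind(pad, m, pad)
  out <- stats::filter(mp, kernel, method = "convolution", sides = 2)
  out <- out[(r + 1L):(r + nrow(m)), , drop = FALSE]
  aperm(array(out, d[perm]), order(perm))
}

#' Degree-of-connectivity parameters
#'
#' @param threshold correlation threshold (|threshold| < 1); the analysis of
#'   weakening anticorrelation counts connections with `r < -0.25`.
#' @param direction `"less"` counts voxels correlated below the threshold,
#'   `"greater"` above.
#' @param mask logical 3D array (or `NULL` for all voxels).
#' @return A `cf_degree_params` list.
#' @export
degree_params <- function(threshold = -0.25, direction = c("less", "greater"),
                          mask = NULL) {
  direction <- match.arg(direction)
  if (abs(threshold) >= 1) stop("|threshold| must be < 1")
  structure(list(threshold = threshold, direction = direction, mask = mask),
            class = "cf_degree_params")
}

#' Voxelwise degree-of-connectivity map
#'
#' For every mask voxel, the number of *other* mask voxels whose time-course
#' correlation with it satisfies the threshold relation (e.g. `r < -0.25`).
#' Computed blockwise on standardized series so memory stays bounded by the
#' block size; results are independent of the block partition. Zero-variance
#' voxels are excluded from the mask with a warning and get `NA` degree.
#'
#' @param x a [bold_run()] or a voxels x time matrix (>= 3 time points).
#' @param params a [degree_params()].
#' @param block_size rows per correlation block.
#' @return For matrix input, an integer vector of degrees (`NA` for excluded
#'   voxels). For `cf_bold` input, a 3D array of degrees (`NA` outside the
#'   mask) with the effective mask and params as attributes.
#' @export
degree_map <- function(x, params = degree_params(), block_size = 512) {
  if (inherits(x, "cf_bold")) {
    mat <- matrix(x$data, prod(x$grid$shape), x$n_volumes)
    mask <- if (is.null(params$mask)) rep(TRUE, nrow(mat)) else {
      stopifnot(all(dim(params$mask) == x$grid$shape))
      as.vector(params$mask)
    }
    deg <- rep(NA_real_, nrow(mat))
    deg[mask] <- degree_map(mat[mask, , drop = FALSE],
                            degree_params(params$threshold, params$direction),
                            block_size)
    out <- array(deg, x$grid$shape)
    attr(out, "mask") <- array(mask & !is.na(deg), x$grid$shape)
    attr(out, "params") <- params
    return(out)
  }
  X <- as.matrix(x)
  if (ncol(X) < 3) stop("need at least 3 time points")
  if (!is.null(params$mask)) X <- X[as.vector(params$mask), , drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  ok <- sds > 0
  if (!all(ok)) warning(sum(!ok), " zero-variance voxel(s) excluded from mask")
  Xs <- X[ok, , drop = FALSE]
  Xs <- Xs - rowMeans(Xs)
  Xs <- Xs / sqrt(rowSums(Xs^2))
  n <- nrow(Xs)
  deg_ok <- integer(n)
  for (start in seq(1, n, by = block_size)) {
    idx <- start:min(start + block_size - 1, n)
    cc <- Xs[idx, , drop = FALSE] %*% t(Xs)
    hit <- if (params$direction == "less") cc < params$threshold else
      cc > params$threshold
    # remove self-pairs (r = 1, counted only under "greater")
    self <- cbind(seq_along(idx), idx)
    hit[self] <- FALSE
    deg_ok[idx] <- rowSums(hit)
  }
  deg <- rep(NA_integer_, length(ok))
  deg[ok] <- deg_ok
  deg
}

#' Voxelwise paired t-test of degree change
#'
#' Paired t statistic of (post - pre) degree per voxel across subjects. A
#' training-induced weakening of anticorrelation appears as a *decrease* in
#' negative-threshold degree, i.e. negative t.
#'
#' @param pre,post lists (one element per subject) of equal-shape degree
#'   maps (arrays or vectors).
#' @return A `cf_tmap` list: `t` (same shape as the maps, `NA` where any
#'   subject is `NA`), `mean_diff`, `df`, `n_subjects`.
#' @export
degree_change_test <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  dims <- dim(pre[[1]])
  diffs <- vapply(seq_along(pre), function(i) {
    stopifnot(identical(dim(pre[[i]]), dims), identical(dim(post[[i]]), dims))
    as.vector(post[[i]]) - as.vector(pre[[i]])
  }, numeric(length(pre[[1]])))
  n <- length(pre)
  m <- rowMeans(diffs)
  s <- apply(diffs, 1, stats::sd)
  t <- m / (s / sqrt(n))
  t[s == 0 & m == 0] <- 0
  shape_back <- function(v) if (is.null(dims)) v else array(v, dims)
  structure(list(t = shape_back(t), mean_diff = shape_back(m), df = n - 1,
                 n_subjects = n), class = "cf_tmap")
}

neighbor_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  steps <- rowSums(abs(off))
  switch(as.character(connectivity),
         "6" = off[steps == 1, , drop = FALSE],
         "18" = off[steps <= 2, , drop = FALSE],
         "26" = off,
         stop("connectivity must be 6, 18 or 26"))
}

#' Connected suprathreshold clusters of a statistic map
#'
#' Connected components (default 18-connectivity: faces + edges) of voxels
#' whose statistic exceeds the cluster-forming threshold; only clusters of at
#' least `min_size` voxels are reported.
#'
#' @param stat 3D statistic array (`NA` treated as subthreshold).
#' @param threshold cluster-forming threshold (strict `>`).
#' @param connectivity 6, 18 or 26.
#' @param min_size minimum cluster size (voxels).
#' @return A `cf_clusters` list: `clusters` (tibble with `cluster`, `size`,
#'   `peak_value` and 0-based peak voxel indices), and `labels` (integer
#'   array, 0 = background).
#' @export
find_clusters <- function(stat, threshold, connectivity = 18, min_size = 1) {
  stopifnot(length(dim(stat)) == 3)
  off <- neighbor_offsets(connectivity)
  d <- dim(stat)
  supra <- !is.na(stat) & stat > threshold
  labels <- array(0L, d)
  idx <- which(supra, arr.ind = TRUE)
  comp <- 0L
  rows <- list()
  for (s in seq_len(nrow(idx))) {
    v <- idx[s, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    comp <- comp + 1L
    queue <- matrix(v, 1)
    labels[v[1], v[2], v[3]] <- comp
    members <- queue
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      nb <- sweep(off, 2, cur, "+")
      keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[keep, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        w <- nb[q, ]
        if (supra[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- comp
          queue <- rbind(queue, w)
          members <- rbind(members, w)
        }
      }
    }
    vals <- stat[members]
    pk <- members[which.max(vals), ]
    rows[[comp]] <- tibble::tibble(cluster = comp, size = nrow(members),
                                   peak_value = max(vals),
                                   peak_i = pk[1] - 1L, peak_j = pk[2] - 1L,
                                   peak_k = pk[3] - 1L)
  }
  clusters <- if (length(rows) > 0) dplyr::bind_rows(rows) else {
    tibble::tibble(cluster = integer(), size = integer(),
                   peak_value = numeric(), peak_i = integer(),
                   peak_j = integer(), peak_k = integer())
  }
  keep <- clusters$size >= min_size
  labels[!(labels %in% clusters$cluster[keep])] <- 0L
  clusters <- clusters[keep, , drop = FALSE]
  ord <- order(-clusters$size)
  clusters <- clusters[ord, , drop = FALSE]
  structure(list(clusters = clusters, labels = labels,
                 threshold = threshold, connectivity = connectivity,
                 min_size = min_size),
            class = "cf_clusters")
}

#' Monte-Carlo cluster-size threshold
#'
#' Simulates smooth Gaussian noise fields on the mask (white noise smoothed
#' at the nominal applied FWHM, standardized over mask voxels), thresholds at
#' the voxelwise p, and records the maximum cluster size per iteration. The
#' minimum significant cluster size is the smallest k with
#' `P(max cluster >= k) <= corrected_p`, i.e. familywise cluster-size
#' correction in the spirit of AFNI's AlphaSim.
#'
#' @param mask logical 3D array.
#' @param vox_mm voxel sizes (mm).
#' @param fwhm_mm smoothness of the null fields (the nominal applied
#'   smoothing).
#' @param voxel_p cluster-forming voxelwise p (one-sided).
#' @param corrected_p familywise cluster-level p.
#' @param n_iter Monte-Carlo iterations (>= 100).
#' @param seed integer seed.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @return A `cf_mcthresh` list: `min_cluster_size`, `max_sizes` (per
#'   iteration), and the parameters.
#' @export
cluster_threshold_mc <- function(mask, vox_mm, fwhm_mm, voxel_p = 0.005,
                                 corrected_p = 0.05, n_iter = 1000, seed = 1,
                                 connectivity = 18) {
  stopifnot(length(dim(mask)) == 3)
  if (!any(mask)) stop("mask is empty")
  if (n_iter < 100) stop("n_iter must be at least 100")
  local_rng(seed)
  zc <- stats::qnorm(1 - voxel_p)
  d <- dim(mask)
  max_sizes <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    noise <- array(stats::rnorm(prod(d)), d)
    if (fwhm_mm > 0) noise <- smooth_volume(noise, fwhm_mm, vox_mm)
    v <- noise[mask]
    noise[mask] <- (v - mean(v)) / stats::sd(v)
    noise[!mask] <- NA
    cl <- find_clusters(noise, zc, connectivity = connectivity)
    max_sizes[it] <- if (nrow(cl$clusters) > 0) max(cl$clusters$size) else 0L
  }
  k <- 1L
  while (mean(max_sizes >= k) > corrected_p) k <- k + 1L
  structure(list(min_cluster_size = k, max_sizes = max_sizes,
                 voxel_p = voxel_p, corrected_p = corrected_p,
                 fwhm_mm = fwhm_mm, n_iter = n_iter, seed = seed,
                 connectivity = connectivity),
            class = "cf_mcthresh")
}

#' @export
print.cf_mcthresh <- function(x, ...) {
  cat(sprintf("<cf_mcthresh> min cluster size %d voxels (voxel p %.3g, corrected p %.3g, FWHM %g mm, %d iterations)\n",
              x$min_cluster_size, x$voxel_p, x$corrected_p, x$fwhm_mm, x$n_iter))
  invisible(x)
}

#' Degree-change cluster analysis for one group
#'
#' The full whole-brain pipeline for a set of subjects with pre and post
#' voxel data: degree maps under the signed threshold, voxelwise paired
#' t-test for a decrease, Monte-Carlo cluster-size threshold, and cluster
#' extraction.
#'
#' @param pre,post lists (one per subject) of voxels x time matrices, or
#'   `cf_bold` runs.
#' @param mask logical 3D array (required with matrix input shaped to it).
#' @param grid [vol_grid()] of the maps.
#' @param threshold counting threshold (see [degree_params()]).
#' @param direction counting direction.
#' @param voxel_p cluster-forming voxelwise p (one-sided decrease).
#' @param corrected_p familywise cluster-level p.
#' @param fwhm_mm nominal smoothness for the Monte-Carlo null.
#' @param n_iter Monte-Carlo iterations.
#' @param seed integer seed.
#' @return A `cf_degree_result` list: `tmap` (`cf_tmap`), `clusters`
#'   (`cf_clusters` of significant decreases), `mc` (`cf_mcthresh`),
#'   `t_crit`.
#' @export
degree_pipeline <- function(pre, post, mask, grid, threshold = -0.25,
                            direction = "less", voxel_p = 0.005,
                            corrected_p = 0.05, fwhm_mm = 0, n_iter = 500,
                            seed = 1) {
  p <- degree_params(threshold, direction, mask)
  as_deg <- function(x) {
    if (inherits(x, "cf_bold")) return(degree_map(x, p))
    full <- rep(NA_real_, length(mask))
    full[as.vector(mask)] <- degree_map(x[as.vector(mask), , drop = FALSE],
                                        degree_params(threshold, direction))
    array(full, dim(mask))
  }
  pre_maps <- lapply(pre, as_deg)
  post_maps <- lapply(post, as_deg)
  tmap <- degree_change_test(pre_maps, post_maps)
  t_crit <- stats::qt(1 - voxel_p, df = tmap$df)
  mc <- cluster_threshold_mc(mask, grid$vox_mm, fwhm_mm, voxel_p,
                             corrected_p, n_iter, seed)
  # decrease: threshold -t at the positive critical value
  clusters <- find_clusters(-tmap$t, t_crit, min_size = mc$min_cluster_size)
  structure(list(tmap = tmap, clusters = clusters, mc = mc, t_crit = t_crit,
                 params = p), class = "cf_degree_result")
}

#' Cluster presence across counting thresholds
#'
#' Re-runs the degree pipeline at each counting threshold and tabulates the
#' significant clusters, to check that detected effects are robust to the
#' threshold setting.
#'
#' @param pre,post,mask,grid,... see [degree_pipeline()].
#' @param thetas numeric vector of counting thresholds in (-1, 1).
#' @return Tibble: `theta`, `n_clusters`, `largest`, `any_significant`.
#' @export
threshold_sweep <- function(pre, post, mask, grid, thetas = c(-0.3, -0.25,
                                                              -0.2, -0.1),
                            ...) {
  stopifnot(all(abs(thetas) < 1))
  purrr::map_dfr(thetas, function(th) {
    res <- degree_pipeline(pre, post, mask, grid, threshold = th, ...)
    tibble::tibble(theta = th, n_clusters = nrow(res$clusters$clusters),
                   largest = if (nrow(res$clusters$clusters) > 0)
                     max(res$clusters$clusters$size) else 0L,
                   any_significant = nrow(res$clusters$clusters) > 0)
  })
}

#' Fraction of significantly changed voxels per ROI
#'
#' The percentage of each ROI's voxels at which the degree of connectivity
#' changed significantly, used to check that ROI selection is not biased
#' toward regions detected in any one group.
#'
#' @param sig_map logical 3D array of voxelwise significance.
#' @param registry a `cf_registry` voxelized on the map's grid.
#' @param grid the map's [vol_grid()] (defaults to the registry's).
#' @return Tibble: `name`, `network`, `n_vox`, `n_sig`, `pct`.
#' @export
roi_significance_ratio <- function(sig_map, registry,
                                   grid = registry_grid(registry)) {
  stopifnot(all(dim(sig_map) == grid$shape))
  vox <- voxelize_registry(registry, grid)
  vox |>
    dplyr::group_by(.data$name, .data$network) |>
    dplyr::summarise(n_vox = dplyr::n(),
                     n_sig = sum(sig_map[.data$linear], na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(pct = 100 * .data$n_sig / .data$n_vox) |>
    dplyr::arrange(match(.data$name, registry$name))
}
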