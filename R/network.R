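#' Preprocess a resting-state run
#'
#' Discards the first `discard` volumes (T1 equilibration), optionally
#' smooths full-volume runs spatially, and removes the nine nuisance
#' regressors (six motion parameters and gray-matter / white-matter / CSF
#' mean signals) from every voxel time course by least squares. Residuals
#' are exactly orthogonal to every confound column; rank-deficient confound
#' tables are handled through the pseudo-inverse, so duplicated regressors
#' give the same residuals.
#'
#' @param run a `cf_roi_run` or [bold_run()].
#' @param confounds confound table (one row per volume, either for all
#'   volumes or for the retained ones); defaults to the run's own sidecar.
#' @param smoothing_fwhm Gaussian smoothing FWHM in mm, applied to
#'   full-volume runs only (ROI-level runs have no spatial structure to
#'   smooth).
#' @param discard number of initial volumes to discard.
#' @return The run with cleaned series and updated volume count.
#' @export
preprocess_rest_run <- function(run, confounds = NULL, smoothing_fwhm = 6,
                                discard = 2) {
  is_bold <- inherits(run, "cf_bold")
  if (!is_bold && !inherits(run, "cf_roi_run")) {
    stop("run must be a cf_bold or cf_roi_run")
  }
  if (is.null(confounds)) confounds <- run$confounds
  confounds <- as.matrix(confounds)
  n_total <- run$n_volumes
  keep <- seq.int(discard + 1L, n_total)
  if (nrow(confounds) == n_total) {
    confounds <- confounds[keep, , drop = FALSE]
  } else if (nrow(confounds) != length(keep)) {
    stop("confound rows (", nrow(confounds), ") match neither the total (",
         n_total, ") nor the retained (", length(keep), ") volume count")
  }

  if (is_bold) {
    data <- run$data[, , , keep, drop = FALSE]
    if (smoothing_fwhm > 0) {
      data <- smooth_volume(data, smoothing_fwhm, run$grid$vox_mm)
    }
    mat <- matrix(data, prod(run$grid$shape), length(keep))
    mat <- residualize(mat, confounds)
    run$data <- array(mat, c(run$grid$shape, length(keep)))
  } else {
    run$series <- residualize(run$series[, keep, drop = FALSE], confounds)
  }
  run$n_volumes <- length(keep)
  run$confounds <- tibble::as_tibble(confounds)
  run$preprocessed <- TRUE
  run
}

# Residuals of each row of Y (voxels x time) on the confound columns plus an
# intercept, via the SVD pseudo-inverse (robust to rank deficiency).
residualize <- function(Y, X) {
  X <- cbind(intercept = 1, X)
  s <- svd(X)
  pos <- s$d > max(s$d) * 1e-10
  # projection onto the column space of X
  U <- s$u[, pos, drop = FALSE]
  Y - (Y %*% U) %*% t(U)
}

#' ROI-mean residual time courses
#'
#' @param run a (preferably preprocessed) `cf_roi_run`, or a voxels x time
#'   matrix with `voxel_roi` supplied.
#' @param voxel_roi factor of ROI membership per voxel (for matrix input).
#' @return Matrix (ROIs x time) with ROI names as rownames.
#' @export
roi_mean_series <- function(run, voxel_roi = NULL) {
  if (inherits(run, "cf_roi_run")) {
    series <- run$series
    voxel_roi <- run$voxel_roi
  } else {
    series <- as.matrix(run)
    stopifnot(!is.null(voxel_roi), length(voxel_roi) == nrow(series))
    voxel_roi <- as.factor(voxel_roi)
  }
  out <- rowsum(series, voxel_roi) / as.vector(table(voxel_roi))
  out[levels(voxel_roi), , drop = FALSE]
}

#' Fisher-z ROI correlation matrix
#'
#' Pairwise Pearson correlations of ROI-mean residual time courses,
#' Fisher-z transformed (`z = atanh(r)`), with `|z|` capped at
#' `atanh(1 - 1e-6)` so degenerate perfect correlations cannot produce
#' infinities (a warning is raised when capping occurs). The diagonal is set
#' to `NA`: it is excluded from every downstream statistic.
#'
#' @param x a `cf_roi_run`, a [bold_run()] with `registry`, or an
#'   ROIs x time matrix with rownames.
#' @param registry `cf_registry`, required for full-volume input.
#' @param z_cap cap on `|z|`.
#' @return A `cf_zmat`: list with `z` and `r` (named ROI x ROI matrices,
#'   `NA` diagonal) and `meta`.
#' @export
roi_matrix <- function(x, registry = NULL, z_cap = atanh(1 - 1e-6)) {
  if (inherits(x, "cf_roi_run")) {
    series <- roi_mean_series(x)
    meta <- x$meta
  } else if (inherits(x, "cf_bold")) {
    stopifnot(!is.null(registry))
    vox <- voxelize_registry(registry, x$grid)
    mat <- matrix(x$data, prod(x$grid$shape), x$n_volumes)
    series <- roi_mean_series(mat[vox$linear, , drop = FALSE],
                              factor(vox$name, levels = registry$name))
    meta <- x$meta
  } else {
    series <- as.matrix(x)
    if (is.null(rownames(series))) stop("ROI series need rownames")
    meta <- list()
  }
  sds <- apply(series, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI series: ",
         paste(rownames(series)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(series))
  rmax <- tanh(z_cap)
  if (any(abs(r[upper.tri(r)]) > rmax)) {
    warning("correlation(s) at or near |r| = 1 capped at z = ", round(z_cap, 3))
  }
  z <- atanh(pmin(pmax(r, -rmax), rmax))
  diag(z) <- NA_real_
  diag(r) <- NA_real_
  structure(list(z = z, r = r, roi_names = rownames(series), meta = meta),
            class = "cf_zmat")
}

#' @export
print.cf_zmat <- function(x, ...) {
  cat(sprintf("<cf_zmat> %d ROIs; mean off-diagonal z = %.3f\n",
              length(x$roi_names), mean(x$z[upper.tri(x$z)])))
  invisible(x)
}

parse_contrast <- function(contrast, sessions) {
  parts <- strsplit(contrast, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% sessions)) {
    stop("contrast must be '<session_b>-<session_a>' over available sessions (",
         paste(sessions, collapse = ", "), ")")
  }
  parts
}

#' Per-subject and group-mean difference matrices
#'
#' Subtracts each subject's Fisher-z matrix in session `a` from session `b`
#' (`contrast = "b-a"`, default post minus pre) and averages the differences
#' within each group.
#'
#' @param mats run-wise matrices as returned by [study_matrices()]: a tibble
#'   with `group`, `subject`, `session` and a `z` list-column.
#' @param contrast e.g. `"post-pre"` or `"2m-pre"`.
#' @return A `cf_diffmats` list: `per_subject` (tibble with a `delta`
#'   list-column) and `group_mean` (named list of matrices), plus the
#'   contrast.
#' @export
difference_matrices <- function(mats, contrast = "post-pre") {
  parts <- parse_contrast(contrast, unique(mats$session))
  wide <- mats |>
    dplyr::filter(.data$session %in% parts) |>
    tidyr::pivot_wider(names_from = "session", values_from = "z")
  roi0 <- rownames(wide[[parts[1]]][[1]])
  per_subject <- wide |>
    dplyr::mutate(delta = purrr::map2(.data[[parts[1]]], .data[[parts[2]]],
                                      function(b, a) {
      if (!identical(rownames(a), roi0) || !identical(rownames(b), roi0)) {
        stop("ROI order differs across sessions/subjects")
      }
      b - a
    })) |>
    dplyr::select("group", "subject", "delta")
  group_mean <- per_subject |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(m = list(Reduce(`+`, .data$delta) / length(.data$delta)),
                     .groups = "drop")
  gm <- stats::setNames(group_mean$m, group_mean$group)
  structure(list(per_subject = per_subject, group_mean = gm,
                 contrast = contrast), class = "cf_diffmats")
}

#' Colored-cell rule on group-mean difference matrices
#'
#' A cell (ROI pair) is "colored" when its group-mean correlation increase
#' strictly exceeds the pooled mean + SD threshold, where the pool is all
#' off-diagonal upper-triangle cells of *all* groups jointly. Counts are
#' tabulated per network-pair type and group.
#'
#' @param diff a [difference_matrices()] result, or a named list of
#'   group-mean matrices.
#' @param partition a [partition_network_pairs()] tibble matching the matrix
#'   ROI order.
#' @return A `cf_colored` list: `threshold`, `pooled_mean`, `pooled_sd`,
#'   `cells` (tibble of all cells with their values and colored flags) and
#'   `counts` (per group x pair type).
#' @export
colored_cells <- function(diff, partition) {
  gm <- if (inherits(diff, "cf_diffmats")) diff$group_mean else diff
  stopifnot(is.list(gm), length(gm) >= 1, !is.null(names(gm)))
  cells <- purrr::imap_dfr(gm, function(m, g) {
    ut <- upper.tri(m)
    stopifnot(sum(ut) == nrow(partition))
    dplyr::mutate(partition, group = g, delta = m[ut], .before = 1)
  })
  if (nrow(cells) < 2) stop("need at least 2 pooled cells")
  pooled_mean <- mean(cells$delta)
  pooled_sd <- stats::sd(cells$delta)
  threshold <- pooled_mean + pooled_sd
  cells$colored <- cells$delta > threshold
  counts <- cells |>
    dplyr::group_by(.data$group, .data$pair_type, .drop = FALSE) |>
    dplyr::summarise(n_cells = dplyr::n(), n_colored = sum(.data$colored),
                     .groups = "drop")
  structure(list(threshold = threshold, pooled_mean = pooled_mean,
                 pooled_sd = pooled_sd, cells = cells, counts = counts),
            class = "cf_colored")
}

#' @export
print.cf_colored <- function(x, ...) {
  cat(sprintf("<cf_colored> threshold %.4f (pooled mean %.4f + SD %.4f)\n",
              x$threshold, x$pooled_mean, x$pooled_sd))
  print(x$counts)
  invisible(x)
}

#' Bootstrap test for the number of colored cells per network pair
#'
#' For each network-pair type (of size m) in each group, draws m cells with
#' replacement from the pooled cell population, counts how many exceed the
#' colored-cell threshold, and repeats `n_boot` times to estimate the null
#' distribution of the colored count under random cell placement. The upper
#' confidence bound is Bonferroni-corrected across (pair types x groups): the
#' two-sided (1 - alpha) CI is raised to (1 - alpha / (types * groups)). A
#' pair type is significant when its observed colored count strictly exceeds
#' the corrected upper bound.
#'
#' @param colored a [colored_cells()] result.
#' @param n_boot number of bootstrap resamples (>= 100 and large enough to
#'   resolve the corrected percentile).
#' @param alpha significance level before correction.
#' @param seed integer seed.
#' @param pool `"all_groups"` (default: cells pooled across the group
#'   matrices, the reading of the resampling scheme used here) or
#'   `"per_group"`.
#' @return A `cf_bootstrap` tibble: `group`, `pair_type`, `n_cells`,
#'   `observed`, `ci_upper`, `p_boot`, `significant`; test parameters as
#'   attributes.
#' @export
bootstrap_pair_test <- function(colored, n_boot = 3000, alpha = 0.05,
                                seed = 1, pool = c("all_groups", "per_group")) {
  stopifnot(inherits(colored, "cf_colored"))
  pool <- match.arg(pool)
  if (n_boot < 100) stop("n_boot must be at least 100")
  counts <- colored$counts
  n_comp <- nrow(counts[counts$n_cells > 0, ])
  alpha_corr <- alpha / n_comp
  level <- 1 - alpha_corr / 2
  if ((1 - level) * n_boot < 1) {
    stop("n_boot = ", n_boot, " too small to resolve the ",
         sprintf("%.5f", level), " percentile; increase n_boot")
  }
  local_rng(seed)
  all_vals <- colored$cells$delta
  res <- counts |>
    dplyr::filter(.data$n_cells > 0) |>
    purrr::pmap_dfr(function(group, pair_type, n_cells, n_colored) {
      vals <- if (pool == "all_groups") all_vals else {
        colored$cells$delta[colored$cells$group == group]
      }
      draws <- matrix(sample(vals, n_cells * n_boot, replace = TRUE), n_boot)
      boot_counts <- rowSums(draws > colored$threshold)
      ci_upper <- stats::quantile(boot_counts, level, type = 1, names = FALSE)
      tibble::tibble(group = group, pair_type = pair_type, n_cells = n_cells,
                     observed = n_colored, ci_upper = ci_upper,
                     p_boot = (1 + sum(boot_counts >= n_colored)) / (n_boot + 1),
                     significant = n_colored > ci_upper)
    })
  structure(res, class = c("cf_bootstrap", class(res)),
            n_boot = n_boot, alpha = alpha, alpha_corrected = alpha_corr,
            threshold = colored$threshold, seed = seed, pool = pool)
}
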