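#' Network covariance specification for synthetic BOLD
#'
#' Describes the generative model of one resting-state run: ROI latent
#' signals drawn from a multivariate normal with the target correlation
#' matrix, shared within each ROI's voxels; independent voxel noise; a shared
#' slow sinusoidal drift; and optional AR(1) temporal smoothing standing in
#' for hemodynamic smoothness. ROI-mean correlations converge to the target
#' as the run length grows (the drift and voxel noise contribute a small,
#' quantified attenuation; see the package vignette).
#'
#' @param roi_names ordered ROI names.
#' @param target_corr symmetric positive-semidefinite correlation matrix
#'   (unit diagonal, entries in \[-1, 1\]) over `roi_names`. Matrices that
#'   are non-PSD within eigenvalue tolerance `1e-6` are repaired by
#'   eigenvalue clipping; worse ones raise an error.
#' @param voxel_noise_sd SD of independent per-voxel noise (latent signals
#'   have unit SD).
#' @param drift_amplitude amplitude of the shared low-frequency drift, in
#'   latent-SD units.
#' @param drift_period_s drift period (s).
#' @param hrf_smoothing AR(1) coefficient in \[0, 1) applied identically to
#'   all latent series (0 disables; marginal variance is preserved, so
#'   zero-lag correlations are unchanged).
#' @return A `cf_covspec`.
#' @export
network_cov_spec <- function(roi_names, target_corr, voxel_noise_sd = 0.6,
                             drift_amplitude = 0.2, drift_period_s = 100,
                             hrf_smoothing = 0.3) {
  k <- length(roi_names)
  target_corr <- as.matrix(target_corr)
  stopifnot(nrow(target_corr) == k, ncol(target_corr) == k,
            voxel_noise_sd >= 0, drift_amplitude >= 0, drift_period_s > 0,
            hrf_smoothing >= 0, hrf_smoothing < 1)
  if (max(abs(target_corr - t(target_corr))) > 1e-8) {
    stop("target_corr must be symmetric")
  }
  if (max(abs(diag(target_corr) - 1)) > 1e-8) stop("target_corr needs a unit diagonal")
  if (max(abs(target_corr)) > 1 + 1e-8) stop("correlations must lie in [-1, 1]")
  target_corr <- nearest_psd(target_corr)
  dimnames(target_corr) <- list(roi_names, roi_names)
  structure(list(roi_names = roi_names, target_corr = target_corr,
                 voxel_noise_sd = voxel_noise_sd,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 hrf_smoothing = hrf_smoothing),
            class = "cf_covspec")
}

# Eigenvalue-clipping PSD repair; errors if the matrix is non-PSD beyond tol.
nearest_psd <- function(m, tol = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values))) {
    stop("target correlation matrix is not positive semidefinite ",
         sprintf("(min eigenvalue %.3g)", min(e$values)))
  }
  if (min(e$values) >= 0) return(m)
  v <- pmax(e$values, 0)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  diag(m2) <- 1
  (m2 + t(m2)) / 2
}

# Unconditional PSD projection (for internally generated targets, where
# pair-level jitter can push a matrix clearly indefinite): clip negative
# eigenvalues, rescale to a unit diagonal, clamp off-diagonals.
psd_project <- function(m, r_max = 0.97) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 0)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(m2), .Machine$double.eps))
  m2 <- m2 / tcrossprod(d)
  m2 <- pmin(pmax(m2, -r_max), r_max)
  diag(m2) <- 1
  (m2 + t(m2)) / 2
}

# n x k multivariate normal rows with correlation C (unit variances).
# Symmetric (eigen) square root: works for singular PSD matrices too.
rmvn_rows <- function(n, C) {
  e <- eigen(C, symmetric = TRUE)
  R <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  matrix(stats::rnorm(n * ncol(C)), n) %*% R
}

ar1_smooth <- function(x, phi) {
  if (phi == 0) return(x)
  # unit-marginal-variance AR(1); same filter on every column preserves
  # zero-lag cross-correlations
  s <- sqrt(1 - phi^2)
  apply(x, 2, function(col) {
    as.numeric(stats::filter(s * col, phi, method = "recursive")) +
      0 # stats::filter starts from 0; early samples are slightly shrunk
  })
}

synth_confounds <- function(n_volumes, drift) {
  motion <- vapply(1:6, function(i) cumsum(stats::rnorm(n_volumes, 0, 0.05)),
                   numeric(n_volumes))
  tissue <- vapply(1:3, function(i) drift + stats::rnorm(n_volumes, 0, 0.1),
                   numeric(n_volumes))
  out <- tibble::as_tibble(cbind(motion, tissue), .name_repair = "minimal")
  names(out) <- c(paste0("motion_", 1:6), "gm_mean", "wm_mean", "csf_mean")
  out
}

#' Simulate one resting-state BOLD run
#'
#' Draws ROI latent signals from the spec's multivariate normal, assigns
#' them to voxels (plus independent voxel noise and the shared drift) and
#' writes a sidecar confound table (6 synthetic motion traces and 3 tissue
#' means; the tissue means carry the drift so that nuisance regression
#' genuinely removes it).
#'
#' With `registry = NULL` the run is ROI-level (`cf_roi_run`): only
#' `voxels_per_roi` voxels per ROI are materialized, which is the default for
#' study-scale simulation. Passing a voxelized `cf_registry` produces a full
#' 4D [bold_run()] on the registry's grid, with background voxels carrying
#' noise plus drift.
#'
#' @param spec a [network_cov_spec()].
#' @param n_volumes number of volumes (>= 3).
#' @param tr_s repetition time (s).
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @param voxels_per_roi voxels per ROI in ROI-level mode.
#' @param registry optional `cf_registry` (names must cover the spec's ROI
#'   names) for full-volume output.
#' @param meta optional named list recorded as provenance (subject, group,
#'   session, ...).
#' @return A `cf_roi_run` (fields `series` voxels x volumes, `voxel_roi`,
#'   `confounds`, `tr_s`, `ground_truth`) or a `cf_bold`.
#' @examples
#' spec <- network_cov_spec(c("A", "B"), matrix(c(1, -0.3, -0.3, 1), 2))
#' run <- simulate_rest_run(spec, n_volumes = 152, seed = 1)
#' dim(run$series)
#' @export
simulate_rest_run <- function(spec, n_volumes = 152, tr_s = 2, seed = NULL,
                              voxels_per_roi = 12, registry = NULL,
                              meta = list()) {
  stopifnot(inherits(spec, "cf_covspec"))
  if (n_volumes < 3) stop("n_volumes must be at least 3")
  if (!is.null(seed)) local_rng(seed)

  k <- length(spec$roi_names)
  latent <- ar1_smooth(rmvn_rows(n_volumes, spec$target_corr),
                       spec$hrf_smoothing)
  phase <- stats::runif(1, 0, 2 * pi)
  tt <- (seq_len(n_volumes) - 1) * tr_s
  drift <- spec$drift_amplitude * sin(2 * pi * tt / spec$drift_period_s + phase)
  confounds <- synth_confounds(n_volumes, drift)
  gt <- list(target_corr = spec$target_corr, spec = spec, seed = seed)

  if (is.null(registry)) {
    stopifnot(voxels_per_roi >= 1)
    roi_idx <- rep(seq_len(k), each = voxels_per_roi)
    series <- t(latent)[roi_idx, , drop = FALSE] +
      matrix(stats::rnorm(length(roi_idx) * n_volumes, 0, spec$voxel_noise_sd),
             length(roi_idx)) +
      matrix(drift, length(roi_idx), n_volumes, byrow = TRUE)
    return(structure(
      list(series = series,
           voxel_roi = factor(spec$roi_names[roi_idx], levels = spec$roi_names),
           confounds = confounds, tr_s = tr_s, n_volumes = n_volumes,
           ground_truth = gt, meta = meta),
      class = "cf_roi_run"))
  }

  stopifnot(inherits(registry, "cf_registry"),
            all(spec$roi_names %in% registry$name))
  grid <- registry_grid(registry)
  vox <- voxelize_registry(registry)
  vox <- vox[vox$name %in% spec$roi_names, ]
  nv <- prod(grid$shape)
  data <- matrix(stats::rnorm(nv * n_volumes), nv) +
    matrix(drift, nv, n_volumes, byrow = TRUE)
  roi_of <- match(vox$name, spec$roi_names)
  data[vox$linear, ] <- t(latent)[roi_of, , drop = FALSE] +
    matrix(stats::rnorm(nrow(vox) * n_volumes, 0, spec$voxel_noise_sd),
           nrow(vox)) +
    matrix(drift, nrow(vox), n_volumes, byrow = TRUE)
  gt$voxels <- vox
  bold_run(array(data, c(grid$shape, n_volumes)), tr_s = tr_s, grid = grid,
           confounds = confounds, ground_truth = gt, meta = meta)
}

#' Study design configuration
#'
#' Defines the simulated three-group training study: group sizes (12
#' neurofeedback, 12 sham-feedback, 9 tapping-imagery), rest sessions before
#' training, immediately after, and at two-month follow-up, and the
#' ground-truth correlation structure. Pre-training, every MVN-DMN ROI pair
#' is anticorrelated at `base_cross_r` (default -0.3); training raises the
#' MVN-DMN correlation of the neurofeedback group by `delta` (default +0.2)
#' in the post and follow-up sessions, control groups by 0. A stable
#' per-subject offset (`subject_sd`) on the MVN-DMN block models trait
#' differences in anticorrelation strength; being constant across sessions it
#' cancels in post-minus-pre differences.
#'
#' The target matrices are built from a network factor model (within-network
#' correlation `within_r`, cross-network correlation via factor correlations)
#' and are positive semidefinite by construction.
#'
#' @param groups named integer vector of group sizes.
#' @param sessions rest-session labels.
#' @param n_volumes volumes per rest run (the first two are discarded during
#'   preprocessing).
#' @param tr_s repetition time (s).
#' @param voxels_per_roi voxels materialized per ROI.
#' @param delta training-induced MVN-DMN correlation increase
#'   (neurofeedback group, post and follow-up sessions).
#' @param base_cross_r pre-training MVN-DMN correlation.
#' @param within_r named vector of within-network correlations.
#' @param subject_sd SD of the stable per-subject MVN-DMN offset.
#' @param pair_sd SD of per-run pair-level correlation jitter (session- and
#'   subject-specific heterogeneity of individual ROI-pair correlations on
#'   top of the network structure; targets are PSD-repaired after the
#'   jitter). This emulates the well-documented test-retest variability of
#'   single-pair resting correlations and keeps difference-matrix cells from
#'   moving in lockstep with their network factors.
#' @param voxel_noise_sd,drift_amplitude,drift_period_s,hrf_smoothing passed
#'   to [network_cov_spec()].
#' @return A `cf_study_config` list.
#' @export
study_config <- function(groups = c(neurofeedback = 12, sham = 12, imagery = 9),
                         sessions = c("pre", "post", "2m"),
                         n_volumes = 152, tr_s = 2, voxels_per_roi = 12,
                         delta = 0.2, base_cross_r = -0.3,
                         within_r = c(MVN = 0.6, DMN = 0.6, control = 0.4),
                         subject_sd = 0.2, pair_sd = 0.08,
                         voxel_noise_sd = 0.6,
                         drift_amplitude = 0.2, drift_period_s = 100,
                         hrf_smoothing = 0.3) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)), all(groups >= 1),
            "pre" %in% sessions,
            all(c("MVN", "DMN", "control") %in% names(within_r)),
            all(within_r > 0 & within_r < 1), abs(base_cross_r) < 1,
            subject_sd >= 0)
  structure(list(groups = groups, sessions = sessions, n_volumes = n_volumes,
                 tr_s = tr_s, voxels_per_roi = voxels_per_roi, delta = delta,
                 base_cross_r = base_cross_r, within_r = within_r,
                 subject_sd = subject_sd, pair_sd = pair_sd,
                 voxel_noise_sd = voxel_noise_sd,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 hrf_smoothing = hrf_smoothing),
            class = "cf_study_config")
}

# Factor-model target correlation over the 16-ROI layout: within-network r
# from loadings, MVN-DMN cross r via the factor correlation (clipped to keep
# the factor matrix PSD), other cross pairs 0.
build_target_corr <- function(networks, within_r, mvn_dmn_r) {
  a <- within_r[networks]
  phi_max <- 0.95
  phi <- mvn_dmn_r / sqrt(within_r["MVN"] * within_r["DMN"])
  phi <- min(phi_max, max(-phi_max, phi))
  Phi <- diag(3)
  dimnames(Phi) <- list(c("MVN", "DMN", "control"), c("MVN", "DMN", "control"))
  Phi["MVN", "DMN"] <- Phi["DMN", "MVN"] <- phi
  C <- sqrt(outer(a, a)) * Phi[networks, networks]
  diag(C) <- 1
  unname(C)
}

#' Simulate a full neurofeedback study
#'
#' Generates the design of a three-group study (rest sessions only; training
#' courses are simulated separately with [run_training_course()]): per-subject
#' trait offsets, per-run seeds, and the ground-truth correlation targets.
#' Runs are materialized lazily by [study_run()] / [study_matrices()], so the
#' study object itself is small and every run is reproducible from its stored
#' seed.
#'
#' @param config a [study_config()].
#' @param seed integer master seed.
#' @return A `cf_study` with `subjects`, `runs` (one row per subject x
#'   session with its seed and MVN-DMN target), `ground_truth` (the exact
#'   injected per-pair-type deltas per group), `roi_table`, `config`.
#' @examples
#' st <- simulate_study(study_config(groups = c(neurofeedback = 2, sham = 2)),
#'                      seed = 1)
#' st$runs
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "cf_study_config"))
  local_rng(seed)
  roi_table <- default_roi_table()
  networks <- roi_table$network

  subjects <- purrr::imap_dfr(as.list(config$groups), function(n, g) {
    tibble::tibble(group = g,
                   subject = sprintf("%s%02d", substr(g, 1, 2), seq_len(n)),
                   trait_offset = stats::rnorm(n, 0, config$subject_sd))
  })
  runs <- tidyr::expand_grid(subjects, session = config$sessions) |>
    dplyr::mutate(
      delta = ifelse(.data$group == "neurofeedback" & .data$session != "pre",
                     config$delta, 0),
      cross_target = config$base_cross_r + .data$trait_offset + .data$delta,
      run_seed = sample.int(.Machine$integer.max - 1L, dplyr::n())
    )

  gt <- tidyr::expand_grid(group = names(config$groups),
                           pair_type = network_pair_types()) |>
    dplyr::mutate(delta = ifelse(.data$group == "neurofeedback" &
                                   .data$pair_type == "MVN-DMN",
                                 config$delta, 0))
  structure(list(config = config, subjects = subjects, runs = runs,
                 ground_truth = gt, roi_table = roi_table, seed = seed),
            class = "cf_study")
}

#' @export
print.cf_study <- function(x, ...) {
  cat(sprintf("<cf_study> %s; %d rest runs (%s)\n",
              paste(sprintf("%s n=%d", names(x$config$groups),
                            x$config$groups), collapse = ", "),
              nrow(x$runs), paste(x$config$sessions, collapse = "/")))
  invisible(x)
}

#' Materialize one rest run of a simulated study
#'
#' @param study a [simulate_study()] result.
#' @param subject subject id.
#' @param session session label.
#' @return A `cf_roi_run`, regenerated bit-identically from the run's seed.
#' @export
study_run <- function(study, subject, session) {
  row <- study$runs[study$runs$subject == subject &
                      study$runs$session == session, ]
  if (nrow(row) != 1) {
    stop("no run for subject ", subject, ", session ", session)
  }
  cfg <- study$config
  local_rng(row$run_seed)
  C <- build_target_corr(study$roi_table$network, cfg$within_r,
                         row$cross_target)
  if (cfg$pair_sd > 0) {
    k <- nrow(C)
    E <- matrix(0, k, k)
    E[upper.tri(E)] <- stats::rnorm(k * (k - 1) / 2, 0, cfg$pair_sd)
    E <- E + t(E)
    C <- psd_project(C + E)
  }
  spec <- network_cov_spec(study$roi_table$name, C,
                           voxel_noise_sd = cfg$voxel_noise_sd,
                           drift_amplitude = cfg$drift_amplitude,
                           drift_period_s = cfg$drift_period_s,
                           hrf_smoothing = cfg$hrf_smoothing)
  simulate_rest_run(spec, n_volumes = cfg$n_volumes, tr_s = cfg$tr_s,
                    seed = NULL, voxels_per_roi = cfg$voxels_per_roi,
                    meta = list(subject = subject, session = session,
                                group = row$group))
}

#' ROI correlation matrices for every run of a study
#'
#' Materializes each rest run, preprocesses it (discard the first two
#' volumes, regress out the 9 confounds), averages residual time courses
#' within each ROI and computes the Fisher-z correlation matrix.
#'
#' @param study a [simulate_study()] result.
#' @param preprocess apply confound regression (recommended).
#' @return A tibble with one row per run: `group`, `subject`, `session` and a
#'   `z` list-column of named ROI x ROI Fisher-z matrices.
#' @export
study_matrices <- function(study, preprocess = TRUE) {
  study$runs |>
    dplyr::select("group", "subject", "session") |>
    dplyr::mutate(z = purrr::map2(.data$subject, .data$session, function(su, se) {
      run <- study_run(study, su, se)
      cleaned <- if (preprocess) preprocess_rest_run(run) else run
      roi_matrix(cleaned)$z
    }))
}
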