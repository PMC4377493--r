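#' Simulate training courses for all three groups
#'
#' Runs the closed training loop for a neurofeedback group of learners,
#' yokes their presented score series to a sham-feedback group (each sham
#' subject receives one distinct neurofeedback subject's series, never their
#' own), and runs a tapping-imagery group whose scores are computed but
#' never presented (so no reward-driven learning occurs).
#'
#' @param groups named group sizes (neurofeedback, sham, imagery).
#' @param schedule a [trial_schedule()].
#' @param days training days.
#' @param agent prototype [agent_state()] for every subject.
#' @param seed integer seed.
#' @return A `cf_training` list: `scores` (tibble group, subject, day,
#'   mean_score), `courses` (named list of `cf_course`), `yoking` (sham
#'   assignment tibble).
#' @export
simulate_training_groups <- function(groups = c(neurofeedback = 12, sham = 12,
                                                imagery = 9),
                                     schedule = trial_schedule(), days = 4,
                                     agent = agent_state(), seed = 1) {
  local_rng(seed)
  course_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                    sum(groups)), nrow = 1)[1, ]
  ids <- purrr::imap(as.list(groups), function(n, g) {
    sprintf("%s%02d", substr(g, 1, 2), seq_len(n))
  })
  seeds <- stats::setNames(course_seeds, unlist(ids))

  nf_courses <- purrr::map(ids$neurofeedback, function(id) {
    run_training_course(agent, schedule, days, seed = seeds[[id]])
  })
  names(nf_courses) <- ids$neurofeedback

  yoking <- yoke_sham_scores(ids$neurofeedback, ids$sham,
                             seed = sample.int(.Machine$integer.max - 1L, 1))
  sham_courses <- purrr::map(seq_along(ids$sham), function(i) {
    donor <- nf_courses[[yoking$donor[i]]]
    sham_by_day <- split(donor$trials$presented_score, donor$trials$day)
    run_training_course(agent, schedule, days,
                        seed = seeds[[ids$sham[i]]], sham_course = sham_by_day)
  })
  names(sham_courses) <- ids$sham

  # imagery group: scores computed for comparison, never presented
  no_feedback <- purrr::map(seq_len(days), function(d) {
    rep(NA_real_, schedule$blocks_per_day * schedule$trials_per_block)
  })
  im_courses <- purrr::map(ids$imagery, function(id) {
    run_training_course(agent, schedule, days, seed = seeds[[id]],
                        sham_course = no_feedback)
  })
  names(im_courses) <- ids$imagery

  courses <- c(nf_courses, sham_courses, im_courses)
  scores <- purrr::imap_dfr(
    list(neurofeedback = nf_courses, sham = sham_courses,
         imagery = im_courses),
    function(cs, g) {
      purrr::imap_dfr(cs, function(crs, id) {
        dplyr::mutate(crs$days, group = g, subject = id, .before = 1)
      })
    })
  structure(list(scores = scores, courses = courses, yoking = yoking,
                 schedule = schedule, days = days),
            class = "cf_training")
}

#' Run the full simulated experiment end to end
#'
#' Orchestrates the whole design at a reduced scale suitable for a single
#' CPU: (1) closed-loop training for the three groups with sham yoking and
#' the daily-score group comparison; (2) the rest-study simulation with
#' Fisher-z matrices, post-minus-pre (and follow-up) difference matrices,
#' the colored-cell rule and the bootstrap network-pair test; (3) the
#' one-sided negativity tests of the target pair, sensorimotor-vs-DMN and
#' MVN-vs-DMN correlations; (4) a small-volume degree-of-connectivity
#' analysis with Monte-Carlo cluster correction contrasting the trained
#' group with an untrained control; and (5) a spectral check that
#' resting-state power is dominated by frequencies below the online
#' high-pass cutoff.
#'
#' @param seed integer master seed; every stage derives its seed from it.
#' @param config rest-study [study_config()].
#' @param schedule training [trial_schedule()].
#' @param days training days.
#' @param n_boot bootstrap resamples.
#' @param degree_subjects subjects per group in the volume-level degree
#'   demo.
#' @param mc_iter Monte-Carlo iterations for the cluster threshold.
#' @param out_dir optional directory; when given, score curves, matrices,
#'   bootstrap and cluster tables are written as TSV plus a provenance JSON.
#' @return A `cf_report` list with elements `training`, `score_comparison`,
#'   `matrices`, `diff_post`, `diff_2m`, `colored_post`, `bootstrap_post`,
#'   `bootstrap_2m`, `negativity`, `degree`, `psd`, `seed`.
#' @export
run_full_pipeline <- function(seed = 1, config = study_config(),
                              schedule = trial_schedule(), days = 4,
                              n_boot = 3000, degree_subjects = 6,
                              mc_iter = 300, out_dir = NULL) {
  training <- simulate_training_groups(config$groups[names(config$groups)],
                                       schedule, days, seed = seed)
  day_means <- training$scores |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(value = mean(.data$mean_score), .groups = "drop")
  score_comparison <- score_group_comparison(day_means)

  study <- simulate_study(config, seed = seed + 1L)
  mats <- study_matrices(study)
  partition <- partition_network_pairs(
    roi_registry(study$roi_table, default_grid()))
  diff_post <- difference_matrices(mats, "post-pre")
  colored_post <- colored_cells(diff_post, partition)
  boot_post <- bootstrap_pair_test(colored_post, n_boot = n_boot,
                                   seed = seed + 2L)
  boot_2m <- NULL; diff_2m <- NULL
  if ("2m" %in% config$sessions) {
    diff_2m <- difference_matrices(mats, "2m-pre")
    boot_2m <- bootstrap_pair_test(colored_cells(diff_2m, partition),
                                   n_boot = n_boot, seed = seed + 3L)
  }

  nf_mats <- dplyr::filter(mats, .data$group == "neurofeedback")
  sets <- list(
    "lM1-lLP" = pair_set_z(nf_mats, "lM1", "lLP"),
    "SMN-DMN" = pair_set_z(nf_mats, c("lM1", "rM1", "lSMA", "rSMA"),
                           c("lLP", "rLP", "PCC", "MPF")),
    "MVN-DMN" = pair_set_z(nf_mats,
                           study$roi_table$name[study$roi_table$network == "MVN"],
                           study$roi_table$name[study$roi_table$network == "DMN"])
  )
  negativity <- purrr::map_dfr(config$sessions, function(se) {
    vals <- purrr::map(sets, function(s) s$z_mean[s$session == se])
    dplyr::mutate(negativity_tests(vals), session = se, .before = 1)
  })

  degree <- degree_demo(seed = seed + 4L, n_subjects = degree_subjects,
                        mc_iter = mc_iter)

  run1 <- study_run(study, study$runs$subject[1], "pre")
  cleaned <- preprocess_rest_run(run1)
  psd <- psd_check(roi_mean_series(cleaned)["lLP", ], tr_s = config$tr_s)

  report <- structure(
    list(training = training, score_comparison = score_comparison,
         study = study, matrices = mats, diff_post = diff_post,
         diff_2m = diff_2m, colored_post = colored_post,
         bootstrap_post = boot_post, bootstrap_2m = boot_2m,
         negativity = negativity, degree = degree, psd = psd, seed = seed),
    class = "cf_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Small-volume degree-change demonstration
#'
#' Two spherical ROIs on a compact grid, anticorrelated before training; the
#' trained group's anticorrelation is weakened after training while the
#' control group's is unchanged. Runs the full degree pipeline per group.
#'
#' @param seed integer seed.
#' @param n_subjects subjects per group.
#' @param n_volumes volumes per run.
#' @param pre_r,post_r cross-ROI correlation pre and post (trained group).
#' @param mc_iter Monte-Carlo iterations.
#' @return List with per-group `cf_degree_result`s, the registry and grid.
#' @export
degree_demo <- function(seed = 1, n_subjects = 6, n_volumes = 150,
                        pre_r = -0.4, post_r = -0.1, mc_iter = 300) {
  local_rng(seed)
  grid <- vol_grid(c(12L, 12L, 8L), c(3, 3, 3.5), c(-16.5, -16.5, -12.25))
  reg <- roi_registry(tibble::tibble(
    name = c("lM1", "lLP"), network = c("MVN", "DMN"),
    x = c(-8, 8), y = c(-8, 8), z = c(0, 0), radius_mm = 5), grid)
  mask <- array(TRUE, grid$shape)
  spec_of <- function(r) {
    network_cov_spec(c("lM1", "lLP"), matrix(c(1, r, r, 1), 2),
                     voxel_noise_sd = 0.4, hrf_smoothing = 0)
  }
  gen <- function(r) {
    simulate_rest_run(spec_of(r), n_volumes = n_volumes, registry = reg,
                      seed = sample.int(.Machine$integer.max - 1L, 1))
  }
  groups <- list(
    trained = list(pre = replicate(n_subjects, gen(pre_r), simplify = FALSE),
                   post = replicate(n_subjects, gen(post_r), simplify = FALSE)),
    control = list(pre = replicate(n_subjects, gen(pre_r), simplify = FALSE),
                   post = replicate(n_subjects, gen(pre_r), simplify = FALSE))
  )
  res <- purrr::imap(groups, function(gd, g) {
    degree_pipeline(gd$pre, gd$post, mask, grid, n_iter = mc_iter,
                    seed = sample.int(.Machine$integer.max - 1L, 1))
  })
  list(results = res, registry = reg, grid = grid,
       params = list(pre_r = pre_r, post_r = post_r,
                     n_subjects = n_subjects))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$training$scores, file.path(out_dir, "score_curves.tsv"))
  readr::write_tsv(tibble::as_tibble(report$bootstrap_post),
                   file.path(out_dir, "bootstrap_post_pre.tsv"))
  if (!is.null(report$bootstrap_2m)) {
    readr::write_tsv(tibble::as_tibble(report$bootstrap_2m),
                     file.path(out_dir, "bootstrap_2m_pre.tsv"))
  }
  readr::write_tsv(report$negativity, file.path(out_dir, "negativity_tests.tsv"))
  for (g in names(report$diff_post$group_mean)) {
    write_roi_matrix(report$diff_post$group_mean[[g]],
                     file.path(out_dir, paste0("delta_post_pre_", g, ".tsv")))
  }
  for (g in names(report$degree$results)) {
    readr::write_tsv(report$degree$results[[g]]$clusters$clusters,
                     file.path(out_dir, paste0("clusters_", g, ".tsv")))
  }
  write_provenance(list(seed = report$seed,
                        package_version = as.character(utils::packageVersion("connfeed")),
                        colored_threshold = report$colored_post$threshold,
                        n_boot = attr(report$bootstrap_post, "n_boot"),
                        filter = "butterworth order 5, 0.06 Hz highpass",
                        bootstrap_pool = attr(report$bootstrap_post, "pool"),
                        cluster_connectivity = 18),
                   file.path(out_dir, "provenance.json"))
  invisible(out_dir)
}

#' @export
print.cf_report <- function(x, ...) {
  cat("<cf_report>\n")
  cat(sprintf("  training: F(%d, %d) = %.2f, p = %.4g (daily group means)\n",
              x$score_comparison$anova$df1, x$score_comparison$anova$df2,
              x$score_comparison$anova$f, x$score_comparison$anova$p))
  sig <- dplyr::filter(tibble::as_tibble(x$bootstrap_post), .data$significant)
  cat(sprintf("  colored-cell threshold %.3f; significant pair types (post-pre): %s\n",
              x$colored_post$threshold,
              if (nrow(sig) == 0) "none" else
                paste(sig$group, sig$pair_type, sep = "/", collapse = ", ")))
  for (g in names(x$degree$results)) {
    cat(sprintf("  degree clusters (%s): %d\n", g,
                nrow(x$degree$results[[g]]$clusters$clusters)))
  }
  cat(sprintf("  resting-state dominant frequency: %.3f Hz\n", x$psd$peak_freq))
  invisible(x)
}
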