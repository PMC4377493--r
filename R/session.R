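#' Run one neurofeedback training session
#'
#' Executes the online feedback computation for one session (one day's
#' blocks): per-volume two-channel ROI-mean ingestion, causal high-pass
#' filtering, trial windowing (drop the first imagery volume, append the
#' first feedback volume), Pearson correlation of the windowed channels, and
#' baselined scoring via [feedback_score()]. During the initial block of the
#' first day (`baseline = NULL`) no scores are produced; the block's mean
#' correlation becomes the subject's baseline. At the end of each block the
#' mean trial score is the block summary shown to the subject.
#'
#' `subject` is either a [agent_state()] virtual subject, in which case the
#' loop is closed (the imagery-period activity is generated at the agent's
#' current coupling and the score drives its reward-contingent update), or an
#' `n_volumes x 2` matrix of recorded raw ROI-mean time courses in
#' acquisition order (offline replay; see [roi_pair_stream()]), which must
#' cover the full session.
#'
#' Degenerate (zero-variance) trial windows are skipped with a warning and
#' excluded from block means; the session errors if their fraction exceeds
#' `max_degenerate_frac`.
#'
#' @param subject a `cf_agent` or a numeric matrix with 2 columns.
#' @param schedule a [trial_schedule()].
#' @param baseline baseline correlation, or `NULL` on the first day (block 1
#'   then sets it and its scores are suppressed).
#' @param seed integer seed (required for a virtual subject); `NULL` uses the
#'   current RNG stream.
#' @param sham_scores optional numeric vector of yoked scores (one per trial,
#'   `NA` where suppressed) that drive the agent's learning instead of its
#'   own score; its own score is still recorded.
#' @param filter_mode `"online"` (causal, as in real time) or `"offline"`
#'   (zero-phase; replay only).
#' @param cutoff_hz high-pass cutoff (Hz).
#' @param max_degenerate_frac maximum tolerated fraction of degenerate trials.
#' @return A `cf_session` list: `trials` (tibble with block, trial,
#'   correlation, score, presented score, agent coupling), `blocks` (tibble
#'   with block mean scores), `baseline`, and the final `agent` (or `NULL`).
#' @examples
#' s <- run_session(agent_state(learning_rate = 0), seed = 1)
#' s$blocks
#' @export
run_session <- function(subject, schedule = trial_schedule(), baseline = NULL,
                        seed = NULL, sham_scores = NULL,
                        filter_mode = c("online", "offline"),
                        cutoff_hz = 0.06, max_degenerate_frac = 0.25) {
  filter_mode <- match.arg(filter_mode)
  if (!is.null(seed)) local_rng(seed)

  agent_mode <- inherits(subject, "cf_agent")
  if (agent_mode && filter_mode == "offline") {
    stop("a closed-loop virtual subject requires online (causal) filtering")
  }
  n_trials <- schedule$blocks_per_day * schedule$trials_per_block
  if (!agent_mode) {
    subject <- as.matrix(subject)
    if (ncol(subject) != 2) stop("recorded stream must have 2 channels")
    if (nrow(subject) < n_trials * schedule$trial_n) {
      stop("stream underrun: need ", n_trials * schedule$trial_n,
           " volumes, got ", nrow(subject))
    }
    filt <- apply(subject, 2, highpass_filter, cutoff_hz = cutoff_hz,
                  tr_s = schedule$tr_s, mode = filter_mode)
  }
  if (!is.null(sham_scores) && length(sham_scores) < n_trials) {
    stop("sham_scores must supply one value per trial")
  }

  agent <- if (agent_mode) subject else NULL
  stream <- if (agent_mode) matrix(numeric(0), 0, 2) else NULL
  coefs <- butter_coefs(cutoff_hz, schedule$tr_s)

  rows <- vector("list", n_trials)
  n_degenerate <- 0L
  baseline_block <- is.null(baseline)
  init_corrs <- numeric(0)

  for (t in seq_len(n_trials)) {
    block <- (t - 1L) %/% schedule$trials_per_block + 1L
    # once the initial block is complete, fix the baseline
    if (baseline_block && block > 1L && is.null(baseline)) {
      baseline <- compute_baseline(init_corrs)
    }
    coupling_try <- NA_real_
    if (agent_mode) {
      agent <- agent_explore(agent)
      coupling_try <- clip1(agent$coupling + agent$last_jitter)
      trial_raw <- rbind(rbivariate(schedule$rest_n, 0),
                         rbivariate(schedule$imagery_n + schedule$feedback_n,
                                    coupling_try))
      stream <- rbind(stream, trial_raw)
      filt <- apply(stream, 2, function(ch) as.numeric(signal::filter(coefs, ch)))
    }
    i0 <- (t - 1L) * schedule$trial_n
    im_idx <- i0 + schedule$rest_n + seq_len(schedule$imagery_n)
    fb_idx <- i0 + schedule$rest_n + schedule$imagery_n + 1L
    wa <- assemble_trial_window(filt[im_idx, 1], filt[fb_idx, 1],
                                schedule$imagery_n)
    wb <- assemble_trial_window(filt[im_idx, 2], filt[fb_idx, 2],
                                schedule$imagery_n)
    r <- tryCatch(trial_correlation(wa, wb),
                  cf_degenerate_trial = function(e) NA_real_)
    if (is.na(r)) {
      n_degenerate <- n_degenerate + 1L
      warning("degenerate trial ", t, " skipped (zero-variance window)")
    }
    suppressed <- baseline_block && block == 1L
    if (suppressed && !is.na(r)) init_corrs <- c(init_corrs, r)
    score <- if (suppressed || is.na(r)) NA_real_ else feedback_score(r, baseline)
    presented <- if (!is.null(sham_scores)) sham_scores[t] else score
    if (agent_mode) agent <- agent_learn(agent, presented)
    rows[[t]] <- tibble::tibble(
      block = block, trial = t - (block - 1L) * schedule$trials_per_block,
      trial_global = t, correlation = r, score = score,
      presented_score = presented, coupling_try = coupling_try,
      degenerate = is.na(r)
    )
  }
  if (baseline_block && is.null(baseline)) baseline <- compute_baseline(init_corrs)
  if (n_degenerate / n_trials > max_degenerate_frac) {
    stop(n_degenerate, " of ", n_trials,
         " trials were degenerate (limit ", max_degenerate_frac, ")")
  }
  trials <- dplyr::bind_rows(rows)
  blocks <- trials |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(mean_score = mean(.data$score[!is.na(.data$score)]),
                     n_valid = sum(!is.na(.data$correlation)),
                     .groups = "drop") |>
    dplyr::mutate(mean_score = ifelse(is.nan(.data$mean_score), NA_real_,
                                      .data$mean_score),
                  reward_credit = pmax(.data$mean_score, 0))
  structure(list(trials = trials, blocks = blocks, baseline = baseline,
                 agent = agent, schedule = schedule,
                 filter_mode = filter_mode),
            class = "cf_session")
}

#' @export
print.cf_session <- function(x, ...) {
  cat(sprintf("<cf_session> %d trials in %d blocks, baseline r = %.3f\n",
              nrow(x$trials), nrow(x$blocks), x$baseline))
  invisible(x)
}

#' Run a multi-day training course
#'
#' Repeats [run_session()] over training days with a single virtual subject,
#' setting the baseline from the initial block of day 1 and carrying the
#' agent's state across days.
#'
#' @param agent a [agent_state()] virtual subject.
#' @param schedule a [trial_schedule()].
#' @param days number of training days.
#' @param seed integer seed for the whole course.
#' @param sham_course optional list of per-day sham score vectors (see
#'   [run_session()]'s `sham_scores`) that drive learning instead of the
#'   subject's own scores.
#' @return A `cf_course` list: `trials` (with a `day` column), `days` (mean
#'   own score per day), `blocks`, `baseline`, final `agent`.
#' @examples
#' crs <- run_training_course(agent_state(), days = 2, seed = 1)
#' crs$days
#' @export
run_training_course <- function(agent, schedule = trial_schedule(), days = 4,
                                seed = 1, sham_course = NULL) {
  stopifnot(inherits(agent, "cf_agent"), days >= 1)
  local_rng(seed)
  baseline <- NULL
  all_trials <- list(); all_blocks <- list()
  for (d in seq_len(days)) {
    sham <- if (!is.null(sham_course)) sham_course[[d]] else NULL
    s <- run_session(agent, schedule, baseline = baseline, seed = NULL,
                     sham_scores = sham)
    baseline <- s$baseline
    agent <- s$agent
    all_trials[[d]] <- dplyr::mutate(s$trials, day = d, .before = 1)
    all_blocks[[d]] <- dplyr::mutate(s$blocks, day = d, .before = 1)
  }
  trials <- dplyr::bind_rows(all_trials)
  day_summary <- trials |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(mean_score = mean(.data$score),
                     mean_correlation = mean(.data$correlation),
                     .groups = "drop")
  structure(list(trials = trials, blocks = dplyr::bind_rows(all_blocks),
                 days = day_summary, baseline = baseline, agent = agent,
                 schedule = schedule),
            class = "cf_course")
}

#' @export
print.cf_course <- function(x, ...) {
  cat(sprintf("<cf_course> %d days, baseline r = %.3f, final coupling %.3f\n",
              max(x$trials$day), x$baseline, x$agent$coupling))
  print(x$days)
  invisible(x)
}

#' Extract the two target-ROI raw mean time courses from a BOLD run
#'
#' Builds the `n_volumes x 2` stream that [run_session()] replays offline:
#' per-volume means over each ROI's voxels, unfiltered (the session runner
#' applies the online filter itself).
#'
#' @param bold a [bold_run()].
#' @param registry a `cf_registry` containing both ROIs.
#' @param roi_a,roi_b ROI names (default the training target pair lM1, lLP).
#' @return Numeric matrix with columns named after the two ROIs.
#' @export
roi_pair_stream <- function(bold, registry, roi_a = "lM1", roi_b = "lLP") {
  stopifnot(inherits(bold, "cf_bold"))
  grid <- bold$grid
  rows <- match(c(roi_a, roi_b), registry$name)
  if (anyNA(rows)) stop("ROI not in registry: ",
                        paste(c(roi_a, roi_b)[is.na(rows)], collapse = ", "))
  va <- attr(voxelize_roi(registry[rows[1], ], grid), "linear")
  vb <- attr(voxelize_roi(registry[rows[2], ], grid), "linear")
  if (length(intersect(va, vb)) > 0) stop("target ROIs overlap on this grid")
  mat <- matrix(bold$data, prod(grid$shape), bold$n_volumes)
  out <- cbind(colMeans(mat[va, , drop = FALSE]),
               colMeans(mat[vb, , drop = FALSE]))
  colnames(out) <- c(roi_a, roi_b)
  out
}
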