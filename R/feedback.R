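#' Trial schedule for neurofeedback training
#'
#' Timing of one training trial and the block structure of a session. A trial
#' is a 14-s rest period, a 14-s imagery period and a short feedback period
#' during which the score is shown; volumes are acquired every `tr_s`
#' seconds. The imagery period must contain a whole number of volumes.
#'
#' @param rest_s rest-period duration (s).
#' @param imagery_s imagery-period duration (s).
#' @param feedback_s feedback-period duration (s); only its first volume
#'   enters the scored window.
#' @param trials_per_block trials per block; the block mean score is shown at
#'   the end of each block.
#' @param blocks_per_day blocks per training day.
#' @param tr_s repetition time (s).
#' @return A `cf_schedule` list with the above fields plus derived volume
#'   counts `rest_n`, `imagery_n`, `feedback_n`, `trial_n`.
#' @export
trial_schedule <- function(rest_s = 14, imagery_s = 14, feedback_s = 6,
                           trials_per_block = 10, blocks_per_day = 5,
                           tr_s = 2) {
  stopifnot(rest_s >= 0, imagery_s > 0, feedback_s >= tr_s,
            trials_per_block >= 1, blocks_per_day >= 1, tr_s > 0)
  if (abs(imagery_s / tr_s - round(imagery_s / tr_s)) > 1e-9) {
    stop("imagery_s must be an integer multiple of tr_s")
  }
  s <- list(rest_s = rest_s, imagery_s = imagery_s, feedback_s = feedback_s,
            trials_per_block = as.integer(trials_per_block),
            blocks_per_day = as.integer(blocks_per_day), tr_s = tr_s)
  s$rest_n <- as.integer(round(rest_s / tr_s))
  s$imagery_n <- as.integer(round(imagery_s / tr_s))
  s$feedback_n <- as.integer(max(1, round(feedback_s / tr_s)))
  s$trial_n <- s$rest_n + s$imagery_n + s$feedback_n
  structure(s, class = "cf_schedule")
}

#' High-pass filter a BOLD time course
#'
#' Butterworth high-pass filter (default 5th order) with the cutoff used
#' during online feedback computation (0.06 Hz). `mode = "online"` applies
#' the filter causally (no future samples, as required in real time);
#' `mode = "offline"` applies it forward-backward for zero phase.
#'
#' @param x numeric vector (one channel's time course).
#' @param cutoff_hz high-pass cutoff frequency (Hz); must be below Nyquist
#'   (`1 / (2 * tr_s)`).
#' @param tr_s sampling interval (s).
#' @param mode `"online"` (causal) or `"offline"` (zero-phase).
#' @param order filter order.
#' @return Filtered numeric vector, same length as `x`.
#' @examples
#' x <- sin(2 * pi * 0.1 * seq(0, 400, by = 2)) + 5
#' y <- highpass_filter(x, mode = "offline")
#' @export
highpass_filter <- function(x, cutoff_hz = 0.06, tr_s = 2,
                            mode = c("online", "offline"), order = 5) {
  mode <- match.arg(mode)
  nyq <- 1 / (2 * tr_s)
  if (cutoff_hz >= nyq) {
    stop(sprintf("cutoff %.3g Hz is not below Nyquist (%.3g Hz at TR %g s)",
                 cutoff_hz, nyq, tr_s))
  }
  if (length(x) < order + 1) stop("series too short for filter order ", order)
  filt <- signal::butter(order, cutoff_hz / nyq, type = "high")
  if (mode == "online") {
    as.numeric(signal::filter(filt, x))
  } else {
    as.numeric(signal::filtfilt(filt, x))
  }
}

butter_coefs <- function(cutoff_hz = 0.06, tr_s = 2, order = 5) {
  signal::butter(order, cutoff_hz * 2 * tr_s, type = "high")
}

#' Assemble the scored window of one trial
#'
#' The imagery period yields `length(imagery)` samples per channel; the first
#' is discarded (partial hemodynamic compensation) and the first sample of
#' the feedback period is appended, so the window length equals the number of
#' imagery volumes. At the default timing (14-s imagery, TR 2 s) that is 7
#' samples.
#'
#' @param imagery numeric vector of per-volume samples from the imagery
#'   period (one channel).
#' @param feedback_first the first feedback-period sample (scalar).
#' @param expected_n expected number of imagery samples (defaults to
#'   `length(imagery)`; supply the schedule's `imagery_n` to catch underruns).
#' @return Numeric vector: `imagery[-1]` followed by `feedback_first`.
#' @examples
#' assemble_trial_window(1:7, 99)
#' @export
assemble_trial_window <- function(imagery, feedback_first,
                                  expected_n = length(imagery)) {
  if (length(imagery) != expected_n) {
    stop("expected ", expected_n, " imagery samples, got ", length(imagery))
  }
  if (length(imagery) < 2) stop("imagery period too short to drop a volume")
  if (length(feedback_first) != 1 || !is.finite(feedback_first)) {
    stop("feedback_first must be a single finite sample")
  }
  c(imagery[-1], feedback_first)
}

#' Pearson correlation of two trial windows
#'
#' Degenerate (zero-variance) windows raise a condition of class
#' `cf_degenerate_trial` rather than silently returning 0; the session runner
#' catches it, skips the trial and logs it.
#'
#' @param window_a,window_b equal-length numeric vectors (>= 3 samples).
#' @return Pearson r in \[-1, 1\].
#' @export
trial_correlation <- function(window_a, window_b) {
  if (length(window_a) != length(window_b)) stop("windows differ in length")
  if (length(window_a) < 3) stop("windows need at least 3 samples")
  if (stats::sd(window_a) == 0 || stats::sd(window_b) == 0) {
    stop(structure(class = c("cf_degenerate_trial", "error", "condition"),
                   list(message = "zero-variance window: degenerate trial",
                        call = sys.call(-1))))
  }
  stats::cor(window_a, window_b)
}

#' Feedback score for one trial
#'
#' The score presented to the subject is the increment of the trial's
#' inter-ROI correlation over the subject's baseline, normalized so that the
#' score always lies in \[-100, 100\]:
#'
#' \deqn{score_i = \frac{r_i - r_{init}}{1 + |r_{init}|} \times 100}
#'
#' where \eqn{r_i} is the trial correlation and \eqn{r_{init}} the
#' correlation averaged over the trials of the initial block of the first
#' training day. A change from -0.6 (baseline) to -0.2 scores 25. Positive
#' scores reward any correlation increase: a positive correlation growing, a
#' negative one turning positive, or a negative one shrinking in magnitude.
#'
#' @param correlation_i trial correlation(s) in \[-1, 1\] (vectorized).
#' @param correlation_initial baseline correlation in \[-1, 1\].
#' @return Score(s) in \[-100, 100\].
#' @examples
#' feedback_score(-0.2, -0.6) # 25
#' @export
feedback_score <- function(correlation_i, correlation_initial) {
  if (any(abs(correlation_i) > 1, na.rm = TRUE) ||
      any(abs(correlation_initial) > 1, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  (correlation_i - correlation_initial) / (1 + abs(correlation_initial)) * 100
}

#' Baseline correlation from the initial block
#'
#' The arithmetic mean of the raw Pearson correlations of the initial block's
#' trials (no Fisher transform); computed once per subject from the first
#' block of the first training day, during which no score is shown.
#'
#' @param initial_block_correlations numeric vector of valid trial
#'   correlations (>= 1).
#' @return The baseline correlation (scalar).
#' @export
compute_baseline <- function(initial_block_correlations) {
  r <- initial_block_correlations[!is.na(initial_block_correlations)]
  if (length(r) == 0) stop("no valid trial correlations to average")
  if (any(abs(r) > 1)) stop("correlations must lie in [-1, 1]")
  mean(r)
}

#' Yoke sham feedback series to recipients
#'
#' Each recipient is assigned the full score time series of one donor; no
#' donor is reused, and when donor and recipient pools overlap nobody
#' receives their own series.
#'
#' @param donors character vector of donor ids (>= length of `recipients`).
#' @param recipients character vector of recipient ids.
#' @param seed integer seed.
#' @return A tibble with columns `recipient`, `donor`.
#' @examples
#' yoke_sham_scores(paste0("nf", 1:12), paste0("sham", 1:12), seed = 1)
#' @export
yoke_sham_scores <- function(donors, recipients, seed) {
  if (length(donors) < length(recipients)) {
    stop("fewer donors (", length(donors), ") than recipients (",
         length(recipients), ")")
  }
  if (anyDuplicated(donors) || anyDuplicated(recipients)) {
    stop("donor and recipient ids must be unique within each pool")
  }
  rng <- local_rng(seed)
  repeat {
    pick <- sample(donors, length(recipients))
    if (!any(pick == recipients)) break
  }
  tibble::tibble(recipient = recipients, donor = pick)
}

# Seeded RNG scoped to the calling function; restores the caller's RNG state.
local_rng <- function(seed, env = parent.frame()) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    withr::defer(assign(".Random.seed", old, envir = globalenv()), envir = env)
  } else {
    withr::defer(rm(".Random.seed", envir = globalenv()), envir = env)
  }
  set.seed(seed)
  invisible(NULL)
}
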