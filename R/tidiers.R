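#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training session or course
#'
#' @param x a `cf_session` or `cf_course`.
#' @param ... unused.
#' @return The per-trial tibble.
#' @export
tidy.cf_session <- function(x, ...) x$trials

#' @rdname tidy.cf_session
#' @export
tidy.cf_course <- function(x, ...) x$trials

#' @param x a `cf_session` or `cf_course`.
#' @param ... unused.
#' @rdname tidy.cf_session
#' @export
glance.cf_session <- function(x, ...) {
  tibble::tibble(n_trials = nrow(x$trials), n_blocks = nrow(x$blocks),
                 baseline = x$baseline,
                 mean_score = mean(x$trials$score, na.rm = TRUE),
                 n_degenerate = sum(x$trials$degenerate))
}

#' @rdname tidy.cf_session
#' @export
glance.cf_course <- function(x, ...) {
  tibble::tibble(days = max(x$trials$day), baseline = x$baseline,
                 final_coupling = x$agent$coupling,
                 day1_score = x$days$mean_score[x$days$day == 1],
                 final_day_score = x$days$mean_score[which.max(x$days$day)])
}

#' Tidy bootstrap, colored-cell, group-comparison and cluster results
#'
#' @param x the result object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.cf_bootstrap <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.cf_bootstrap
#' @export
glance.cf_bootstrap <- function(x, ...) {
  tibble::tibble(n_boot = attr(x, "n_boot"), alpha = attr(x, "alpha"),
                 alpha_corrected = attr(x, "alpha_corrected"),
                 threshold = attr(x, "threshold"), pool = attr(x, "pool"),
                 n_significant = sum(x$significant))
}

#' @rdname tidy.cf_bootstrap
#' @export
tidy.cf_colored <- function(x, ...) x$counts

#' @rdname tidy.cf_bootstrap
#' @export
glance.cf_colored <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, pooled_mean = x$pooled_mean,
                 pooled_sd = x$pooled_sd, n_cells = nrow(x$cells),
                 n_colored = sum(x$cells$colored))
}

#' @rdname tidy.cf_bootstrap
#' @export
tidy.cf_groupcomp <- function(x, ...) x$posthoc

#' @rdname tidy.cf_bootstrap
#' @export
glance.cf_groupcomp <- function(x, ...) x$anova

#' @rdname tidy.cf_bootstrap
#' @export
tidy.cf_clusters <- function(x, ...) x$clusters
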