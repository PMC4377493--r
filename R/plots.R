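#' Plot daily mean feedback scores per group
#'
#' Line plot of the mean feedback score per training day for each group
#' (error bars: standard error across subjects), the standard view of
#' whether only the group receiving veridical feedback learned.
#'
#' @param scores tibble with `group`, `subject`, `day`, `mean_score`
#'   (e.g. `simulate_training_groups()$scores`), or a `cf_training`.
#' @return A ggplot object.
#' @export
plot_score_curve <- function(scores) {
  if (inherits(scores, "cf_training")) scores <- scores$scores
  df <- scores |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(m = mean(.data$mean_score),
                     se = stats::sd(.data$mean_score) /
                       sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$m,
                                   color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$se,
                                        ymax = .data$m + .data$se),
                           width = 0.1) +
    ggplot2::labs(x = "training day", y = "mean feedback score",
                  color = NULL) +
    ggplot2::theme_minimal()
}

matrix_long <- function(m, value_name = "value") {
  tibble::tibble(roi_a = rep(rownames(m), times = ncol(m)),
                 roi_b = rep(colnames(m), each = nrow(m)),
                 !!value_name := as.vector(m)) |>
    dplyr::mutate(roi_a = factor(.data$roi_a, levels = rownames(m)),
                  roi_b = factor(.data$roi_b, levels = colnames(m)))
}

#' Heatmap of an ROI correlation or difference matrix
#'
#' @param m a named ROI x ROI matrix or `cf_zmat`.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_roi_matrix <- function(m, title = NULL) {
  if (inherits(m, "cf_zmat")) m <- m$z
  ggplot2::ggplot(matrix_long(m),
                  ggplot2::aes(x = .data$roi_b, y = .data$roi_a,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey85") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Colored-cell heatmaps per group
#'
#' Difference-matrix heatmaps with cells exceeding the pooled mean + SD
#' threshold outlined, one facet per group.
#'
#' @param object a [colored_cells()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cf_colored <- function(object, ...) {
  df <- object$cells
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_b, y = .data$roi_a,
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$colored),
                       fill = NA, color = "black", linewidth = 0.5) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("Δz (threshold %.3f)", object$threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 6),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Power spectral density plot with the high-pass cutoff marked
#'
#' @param object a [psd_check()] result.
#' @param cutoff_hz reference cutoff to mark (the online filter's 0.06 Hz).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cf_psd <- function(object, cutoff_hz = 0.06, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = cutoff_hz, linetype = "dashed") +
    ggplot2::labs(x = "frequency (Hz)", y = "power density") +
    ggplot2::theme_minimal()
}
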