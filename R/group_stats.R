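#' Extract per-subject mean Fisher-z for a set of ROI pairs
#'
#' Averages the z values of all (roi_a, roi_b) cross pairs for each subject
#' and session — e.g. the single training pair (lM1, lLP), the sensorimotor
#' network (M1 + SMA) against the DMN, or the full MVN against the DMN.
#'
#' @param mats run-wise matrices from [study_matrices()].
#' @param rois_a,rois_b character vectors of ROI names; all cross pairs
#'   between the two sets (excluding self-pairs) are averaged.
#' @return Tibble with `group`, `subject`, `session`, `z_mean`.
#' @export
pair_set_z <- function(mats, rois_a, rois_b) {
  mats |>
    dplyr::mutate(z_mean = purrr::map_dbl(.data$z, function(m) {
      stopifnot(all(rois_a %in% rownames(m)), all(rois_b %in% rownames(m)))
      sub <- m[rois_a, rois_b, drop = FALSE]
      keep <- outer(rois_a, rois_b, `!=`)
      mean(sub[keep])
    })) |>
    dplyr::select("group", "subject", "session", "z_mean")
}

#' One-sided tests for negative correlation
#'
#' One-sample t-tests of whether the Fisher-z correlation is significantly
#' smaller than zero, for each named set of per-subject values, with
#' Bonferroni correction across the sets (p multiplied by the number of
#' sets, capped at 1).
#'
#' @param values named list of numeric vectors (one value per subject), or a
#'   data frame with columns `set` and `z`.
#' @return A tibble: `set`, `n`, `mean_z`, `t`, `df`, `p`, `p_adj`,
#'   `significant` (at 0.05 after correction).
#' @examples
#' negativity_tests(list(pre = rnorm(12, -0.3, 0.2), post = rnorm(12, 0, 0.2)))
#' @export
negativity_tests <- function(values) {
  if (is.data.frame(values)) {
    values <- split(values$z, values$set)
  }
  stopifnot(is.list(values), !is.null(names(values)))
  k <- length(values)
  purrr::imap_dfr(values, function(v, nm) {
    v <- v[!is.na(v)]
    if (length(v) < 2) stop("set '", nm, "' needs at least 2 subjects")
    if (stats::sd(v) == 0) stop("set '", nm, "' has zero variance")
    tt <- stats::t.test(v, mu = 0, alternative = "less")
    tibble::tibble(set = nm, n = length(v), mean_z = mean(v),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, p_adj = min(1, tt$p.value * k),
                   significant = min(1, tt$p.value * k) < 0.05)
  })
}

#' Group comparison: one-way ANOVA with post-hoc t-tests
#'
#' One-way ANOVA of a per-observation value across subject groups (e.g.
#' daily mean feedback scores), followed by pairwise two-sample t-tests
#' (pooled variance) with Bonferroni correction across the pairs.
#'
#' @param df data frame with a grouping column and a value column.
#' @param group,value column names.
#' @return A `cf_groupcomp` list: `anova` (tibble with `f`, `df1`, `df2`,
#'   `p`) and `posthoc` (tibble with `group_a`, `group_b`, `t`, `df`, `p`,
#'   `p_adj`).
#' @examples
#' df <- data.frame(group = rep(c("a", "b", "c"), each = 4),
#'                  value = c(rnorm(4, 2), rnorm(4), rnorm(4)))
#' score_group_comparison(df)
#' @export
score_group_comparison <- function(df, group = "group", value = "value") {
  g <- factor(df[[group]])
  v <- df[[value]]
  stopifnot(nlevels(g) >= 2)
  if (any(table(g) < 2)) stop("every group needs at least 2 observations")
  fit <- stats::aov(v ~ g)
  an <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(f = an[["F value"]][1], df1 = an[["Df"]][1],
                              df2 = an[["Df"]][2], p = an[["Pr(>F)"]][1])
  pairs <- utils::combn(levels(g), 2)
  n_pairs <- ncol(pairs)
  posthoc <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    a <- v[g == pairs[1, i]]; b <- v[g == pairs[2, i]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    tibble::tibble(group_a = pairs[1, i], group_b = pairs[2, i],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, p_adj = min(1, tt$p.value * n_pairs))
  })
  structure(list(anova = anova_tbl, posthoc = posthoc),
            class = "cf_groupcomp")
}

#' @export
print.cf_groupcomp <- function(x, ...) {
  cat(sprintf("<cf_groupcomp> F(%d, %d) = %.3g, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$f, x$anova$p))
  print(x$posthoc)
  invisible(x)
}

#' Welch-style power spectral density and dominant frequency
#'
#' Hann-windowed, overlapping-segment averaged periodogram of one time
#' course, reported on \[0, Nyquist\]. Used to verify that resting-state
#' fluctuations are dominated by frequencies below the online high-pass
#' cutoff (the resting measurements are thereby independent of the trained
#' feedback signal).
#'
#' @param x numeric time course (length >= 16).
#' @param tr_s sampling interval (s).
#' @param seg_len segment length (default: power of two near half the
#'   series, at least 16).
#' @param overlap fractional segment overlap.
#' @return A `cf_psd` list: `spectrum` (tibble `freq`, `power`),
#'   `peak_freq` (Hz, excluding DC), `nyquist`, `n_segments`.
#' @examples
#' x <- sin(2 * pi * 0.03 * seq(0, 600, by = 2))
#' psd_check(x, tr_s = 2)$peak_freq
#' @export
psd_check <- function(x, tr_s, seg_len = NULL, overlap = 0.5) {
  n <- length(x)
  if (n < 16) stop("series too short for spectral estimation (need >= 16)")
  fs <- 1 / tr_s
  if (is.null(seg_len)) seg_len <- min(n, max(16, 2^floor(log2(n / 2))))
  stopifnot(seg_len >= 16, seg_len <= n, overlap >= 0, overlap < 1)
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  nf <- floor(seg_len / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 / (fs * sum(w^2))
    half <- p[1:nf]
    # fold two-sided power into the one-sided spectrum
    inner <- 2:(nf - if (seg_len %% 2 == 0) 1 else 0)
    half[inner] <- 2 * half[inner]
    acc <- acc + half
  }
  power <- acc / length(starts)
  freq <- (0:(nf - 1)) * fs / seg_len
  peak <- freq[-1][which.max(power[-1])]
  structure(list(spectrum = tibble::tibble(freq = freq, power = power),
                 peak_freq = peak, nyquist = fs / 2,
                 n_segments = length(starts)),
            class = "cf_psd")
}
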