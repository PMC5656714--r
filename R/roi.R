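#' Rectangular region of interest
#'
#' Pixel-indexed rectangle, 0-based and half-open on both axes:
#' rows `[row0, row1)`, columns `[col0, col1)`. The same ROI is applied to
#' both modalities of a co-registered pair, so it addresses identical tissue
#' in each. At least two columns are required because the row-gradient
#' statistic needs a first difference.
#'
#' @param row0,col0 first row/column inside the ROI (0-based).
#' @param row1,col1 first row/column beyond the ROI.
#' @return an object of class `roi_rect`.
#' @export
#' @examples
#' roi_rect(35, 45, 85, 115)
roi_rect <- function(row0, col0, row1, col1) {
  for (v in list(row0, col0, row1, col1))
    if (!is.numeric(v) || length(v) != 1L || v != round(v) || v < 0)
      stopf("ROI bounds must be single non-negative integers")
  if (row1 <= row0) stopf("ROI needs row1 > row0 (got rows [%d, %d))", row0, row1)
  if (col1 - col0 < 2)
    stopf("ROI needs at least 2 columns for gradients (got cols [%d, %d))",
          col0, col1)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 row1 = as.integer(row1), col1 = as.integer(col1)),
            class = "roi_rect")
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("roi_rect: rows [%d, %d) x cols [%d, %d)  (%d x %d px)\n",
              x$row0, x$row1, x$col0, x$col1,
              x$row1 - x$row0, x$col1 - x$col0))
  invisible(x)
}

as_intensity_matrix <- function(image) {
  if (inherits(image, "modality_image")) image$intensity
  else if (is.matrix(image) && is.numeric(image)) image
  else stopf("`image` must be a modality_image or a numeric matrix")
}

#' Extract the ROI line profiles of an image
#'
#' Returns the ROI sub-grid verbatim — one line profile (intensity versus
#' column) per pixel row, no resampling or normalisation.
#'
#' @param image a [modality_image()] or numeric intensity matrix.
#' @param roi an [roi_rect()]; must lie inside the image.
#' @return an object of class `profile_set`: matrix `profiles` of size
#'   (rows x cols) of the ROI, plus the source `modality` tag.
#' @export
extract_roi <- function(image, roi) {
  x <- as_intensity_matrix(image)
  if (!inherits(roi, "roi_rect")) stopf("`roi` must be an roi_rect")
  if (roi$row1 > nrow(x))
    stopf("ROI row1 = %d exceeds image rows = %d", roi$row1, nrow(x))
  if (roi$col1 > ncol(x))
    stopf("ROI col1 = %d exceeds image cols = %d", roi$col1, ncol(x))
  profiles <- x[(roi$row0 + 1):roi$row1, (roi$col0 + 1):roi$col1,
                drop = FALSE]
  structure(list(profiles = profiles,
                 modality = if (inherits(image, "modality_image"))
                   image$modality else "image",
                 roi = roi),
            class = "profile_set")
}

#' Signed first-difference gradients of line profiles
#'
#' For each row profile, `gradients[r, c] = profiles[r, c + 1] -
#' profiles[r, c]`, exact arithmetic on the stored values.
#'
#' @param p a `profile_set` from [extract_roi()].
#' @return an object of class `gradient_set`: matrix `gradients` of shape
#'   (rows, cols - 1).
#' @export
profile_gradients <- function(p) {
  if (!inherits(p, "profile_set")) stopf("`p` must be a profile_set")
  m <- p$profiles
  if (ncol(m) < 2L) stopf("profiles need at least 2 columns for gradients")
  g <- m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  structure(list(gradients = g, modality = p$modality),
            class = "gradient_set")
}

#' Mean absolute intensity change of a gradient set
#'
#' The arithmetic mean of `|gradients|` over all entries — the per-modality
#' "average intensity change" that the percent-increase statistic compares.
#' Absolute (not signed) gradients are averaged so the statistic is
#' orientation-independent and does not cancel over near-periodic texture.
#'
#' @param g a `gradient_set` from [profile_gradients()].
#' @return a non-negative scalar.
#' @export
mean_intensity_change <- function(g) {
  if (!inherits(g, "gradient_set")) stopf("`g` must be a gradient_set")
  if (length(g$gradients) == 0L) stopf("empty gradient set")
  mean(abs(g$gradients))
}

#' Percent increase of the NBI statistic over the WLI baseline
#'
#' `100 * (nbi_stat - wli_stat) / wli_stat`; may be negative. The baseline is
#' WLI: the comparison asks how much larger the NBI gradients are.
#'
#' @param nbi_stat,wli_stat mean absolute intensity change of each modality;
#'   `wli_stat` must be strictly positive (a zero baseline leaves the ratio
#'   undefined).
#' @return percent increase (a plain number, e.g. `22` for +22%).
#' @export
percent_increase <- function(nbi_stat, wli_stat) {
  assert_scalar_num(nbi_stat, "nbi_stat", min = 0)
  if (!is.numeric(wli_stat) || length(wli_stat) != 1L || !is.finite(wli_stat) ||
      wli_stat <= 0)
    stopf("`wli_stat` must be > 0: percent increase is undefined for a zero baseline")
  100 * (nbi_stat - wli_stat) / wli_stat
}

#' Data behind an intensity-change diagram
#'
#' Per-row gradient traces plus the column-wise mean absolute gradient
#' aggregate, ready for plotting.
#'
#' @param g a `gradient_set`.
#' @return an object of class `intensity_change_diagram`: matrix `traces`
#'   (the signed per-row gradients) and vector `column_mean_abs`.
#' @export
intensity_change_diagram <- function(g) {
  if (!inherits(g, "gradient_set")) stopf("`g` must be a gradient_set")
  if (length(g$gradients) == 0L) stopf("empty gradient set")
  structure(list(traces = g$gradients,
                 column_mean_abs = colMeans(abs(g$gradients)),
                 modality = g$modality),
            class = "intensity_change_diagram")
}

#' Plot an intensity-change diagram
#'
#' Thin grey lines: signed gradient trace of every ROI row; heavy line: the
#' column-wise mean absolute gradient.
#'
#' @param x an `intensity_change_diagram`.
#' @param main plot title.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.intensity_change_diagram <- function(x, main = NULL, ...) {
  if (is.null(main))
    main <- sprintf("Intensity change (%s)", x$modality)
  graphics::matplot(t(x$traces), type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", alpha.f = 0.25),
                    xlab = "ROI column", ylab = "intensity gradient",
                    main = main, ...)
  graphics::lines(x$column_mean_abs, col = "firebrick", lwd = 2)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Compare NBI and WLI gradients over a matched ROI
#'
#' The core comparison: the same ROI is cropped from both co-registered
#' modalities, per-row line profiles are differentiated (signed first
#' differences), the mean absolute intensity change is computed per modality,
#' and the NBI-over-WLI percent increase is reported.
#'
#' @param pair an `image_pair` from [simulate_pair()] (or any list with
#'   `wli`/`nbi` [modality_image()]s of identical shape).
#' @param roi an [roi_rect()], in the shared pixel coordinates of the pair.
#' @param normalize if `TRUE`, each modality's ROI is divided by its own mean
#'   intensity before the statistic (gain-free comparison; the NBI image is
#'   physically dimmer). Off by default: the raw statistic is reported.
#' @return an object of class `contrast_report` with fields
#'   `mean_abs_gradient_wli`, `mean_abs_gradient_nbi`, `percent_increase`,
#'   `roi`, `n_pixels_used` and `meta`.
#' @export
analyze_pair <- function(pair, roi, normalize = FALSE) {
  if (!all(c("wli", "nbi") %in% names(pair)))
    stopf("`pair` must have elements `wli` and `nbi`")
  wli <- as_intensity_matrix(pair$wli); nbi <- as_intensity_matrix(pair$nbi)
  if (!identical(dim(wli), dim(nbi)))
    stopf("WLI and NBI images must have identical shapes")
  p_wli <- extract_roi(pair$wli, roi)
  p_nbi <- extract_roi(pair$nbi, roi)
  if (normalize) {
    m_w <- mean(p_wli$profiles); m_n <- mean(p_nbi$profiles)
    if (m_w <= 0 || m_n <= 0)
      stopf("cannot mean-normalize an ROI with non-positive mean intensity")
    p_wli$profiles <- p_wli$profiles / m_w
    p_nbi$profiles <- p_nbi$profiles / m_n
  }
  g_wli <- profile_gradients(p_wli)
  g_nbi <- profile_gradients(p_nbi)
  stat_wli <- mean_intensity_change(g_wli)
  stat_nbi <- mean_intensity_change(g_nbi)
  structure(list(
    mean_abs_gradient_wli = stat_wli,
    mean_abs_gradient_nbi = stat_nbi,
    percent_increase = percent_increase(stat_nbi, stat_wli),
    roi = roi,
    n_pixels_used = nrow(g_wli$gradients) * ncol(g_wli$gradients),
    normalized = normalize,
    meta = list(scene_seed = pair$scene_seed,
                scenario = attr(pair, "scenario"),
                fibre = isTRUE(pair$wli$meta$fibre))),
    class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("Matched-ROI gradient contrast report\n")
  cat(sprintf("  ROI: rows [%d, %d) x cols [%d, %d)   (%d gradient samples)\n",
              x$roi$row0, x$roi$row1, x$roi$col0, x$roi$col1, x$n_pixels_used))
  cat(sprintf("  mean |gradient|  WLI: %.5f\n", x$mean_abs_gradient_wli))
  cat(sprintf("  mean |gradient|  NBI: %.5f\n", x$mean_abs_gradient_nbi))
  cat(sprintf("  NBI percent increase over WLI: %+.1f%%\n", x$percent_increase))
  if (isTRUE(x$normalized))
    cat("  (per-ROI mean normalization was applied)\n")
  invisible(x)
}

#' Turn a contrast report into a one-row data frame
#'
#' @param x a `contrast_report`.
#' @param ... unused.
#' @return a one-row `data.frame`.
#' @export
as.data.frame.contrast_report <- function(x, ...) {
  data.frame(scenario = if (is.null(x$meta$scenario)) NA_character_
             else x$meta$scenario,
             scene_seed = if (is.null(x$meta$scene_seed)) NA_integer_
             else x$meta$scene_seed,
             fibre = isTRUE(x$meta$fibre),
             row0 = x$roi$row0, col0 = x$roi$col0,
             row1 = x$roi$row1, col1 = x$roi$col1,
             n_pixels_used = x$n_pixels_used,
             mean_abs_gradient_wli = x$mean_abs_gradient_wli,
             mean_abs_gradient_nbi = x$mean_abs_gradient_nbi,
             percent_increase = x$percent_increase,
             stringsAsFactors = FALSE)
}
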