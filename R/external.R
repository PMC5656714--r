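#' Analyze a user-supplied co-registered WLI/NBI image pair
#'
#' Applies the matched-ROI gradient statistic to images on disk (grayscale or
#' RGB PNG/TIFF; RGB is reduced to intensity by the per-pixel channel mean).
#' The two images must be co-registered — same shape and same pixel
#' coordinates for the same tissue — which for external data is the caller's
#' responsibility. Note that the percent-increase statistic depends on the
#' ROI choice: it should cover the lesion plus part of the surrounding
#' tissue.
#'
#' @param wli_path,nbi_path image paths (`.png`, `.tif`, `.tiff`).
#' @param roi an [roi_rect()] in the shared pixel coordinates.
#' @param normalize per-ROI mean normalization (see [analyze_pair()]).
#' @param output_csv,output_json optional report output paths.
#' @return a `contrast_report`.
#' @export
analyze_external <- function(wli_path, nbi_path, roi, normalize = FALSE,
                             output_csv = NULL, output_json = NULL) {
  wli <- read_image_file(wli_path)
  nbi <- read_image_file(nbi_path)
  if (!identical(dim(wli), dim(nbi)))
    stopf("images have different shapes: %s is %d x %d, %s is %d x %d",
          wli_path, nrow(wli), ncol(wli), nbi_path, nrow(nbi), ncol(nbi))
  pair <- list(wli = modality_image(clip01(wli), "WLI",
                                    meta = list(path = wli_path)),
               nbi = modality_image(clip01(nbi), "NBI",
                                    meta = list(path = nbi_path)))
  report <- analyze_pair(pair, roi, normalize = normalize)
  report$meta$wli_path <- wli_path
  report$meta$nbi_path <- nbi_path
  if (!is.null(output_csv)) write_reports_csv(report, output_csv)
  if (!is.null(output_json)) write_report_json(report, output_json)
  report
}
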