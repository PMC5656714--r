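#' Quantize intensities to a stored bit depth
#'
#' Maps `[0, 1]` intensities onto the `2^bits - 1` integer levels used by the
#' grayscale image writers and back, i.e. `round(x * (2^bits - 1)) /
#' (2^bits - 1)`. Writing a quantized image and reading it back reproduces
#' the quantized values exactly.
#'
#' @param x numeric vector/matrix in `[0, 1]`.
#' @param bits 8 or 16.
#' @return quantized values on the same scale.
#' @export
quantize_intensity <- function(x, bits = 8L) {
  if (!bits %in% c(8L, 16L)) stopf("`bits` must be 8 or 16")
  levels <- 2^bits - 1
  round(x * levels) / levels
}

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") "png"
  else if (ext %in% c("tif", "tiff")) "tiff"
  else stopf("unsupported image extension '.%s' (use .png, .tif or .tiff)", ext)
}

#' Write a grayscale image to PNG or TIFF
#'
#' Intensity is mapped linearly to the full integer range of the stored bit
#' depth. PNG is written at 8 bits; TIFF at 8 or 16 bits. The round trip
#' write -> [read_image_file()] is lossless at the stored depth.
#'
#' @param image a [modality_image()] or numeric matrix in `[0, 1]`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits stored bit depth, 8 or 16 (PNG supports 8 only).
#' @return `path`, invisibly.
#' @export
write_image_file <- function(image, path, bits = 8L) {
  x <- as_intensity_matrix(image)
  fmt <- image_format(path)
  if (!bits %in% c(8L, 16L)) stopf("`bits` must be 8 or 16")
  if (fmt == "png") {
    if (bits != 8L) stopf("PNG output is written at 8 bits; use TIFF for 16")
    png::writePNG(x, target = path)
  } else {
    tiff::writeTIFF(x, where = path, bits.per.sample = as.integer(bits))
  }
  invisible(path)
}

#' Read a grayscale (or RGB) image from PNG or TIFF
#'
#' Returns intensities in `[0, 1]`. RGB input is reduced to intensity by the
#' per-pixel channel mean; an alpha channel, if present, is ignored.
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @return a numeric intensity matrix.
#' @export
read_image_file <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  fmt <- image_format(path)
  x <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (is.matrix(x)) return(x)
  if (length(dim(x)) == 3L) {
    nch <- min(dim(x)[3], 3L)  # drop alpha
    return(apply(x[, , seq_len(nch), drop = FALSE], c(1, 2), mean))
  }
  stopf("unsupported image layout in %s", path)
}

#' Write contrast reports to CSV
#'
#' One row per report (scenario x replicate), columns as in
#' [as.data.frame.contrast_report()].
#'
#' @param reports a single `contrast_report`, a list of them, or a
#'   data frame already in report layout.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_reports_csv <- function(reports, path) {
  df <- if (is.data.frame(reports)) reports
  else if (inherits(reports, "contrast_report")) as.data.frame(reports)
  else do.call(rbind, lapply(reports, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a contrast report to JSON
#'
#' @param report a `contrast_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, "contrast_report"))
    stopf("`report` must be a contrast_report")
  out <- list(mean_abs_gradient_wli = report$mean_abs_gradient_wli,
              mean_abs_gradient_nbi = report$mean_abs_gradient_nbi,
              percent_increase = report$percent_increase,
              roi = unclass(report$roi),
              n_pixels_used = report$n_pixels_used,
              normalized = isTRUE(report$normalized),
              meta = report$meta)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
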