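#' Spectral band of an illumination source
#'
#' @param center_nm centre wavelength, nm (visible range 380-780).
#' @param fwhm_nm full width at half maximum, nm (> 0).
#' @param weight relative power of the band (> 0); weights are normalised to
#'   sum to 1 inside [illumination()].
#' @return an object of class `spectral_band`.
#' @export
spectral_band <- function(center_nm, fwhm_nm, weight = 1) {
  assert_scalar_num(center_nm, "center_nm", min = 380, max = 780)
  assert_scalar_num(fwhm_nm, "fwhm_nm", min = 0, strict_min = TRUE)
  assert_scalar_num(weight, "weight", min = 0, strict_min = TRUE)
  structure(list(center_nm = center_nm, fwhm_nm = fwhm_nm, weight = weight),
            class = "spectral_band")
}

#' Illumination spectrum as a set of weighted bands
#'
#' @param name label, e.g. `"WLI"` or `"NBI"`.
#' @param bands list of [spectral_band()]s; their weights are normalised to
#'   sum to 1, so scaling all weights by a common factor leaves rendering
#'   unchanged.
#' @return an object of class `illumination_spec`.
#' @export
illumination <- function(name, bands) {
  if (!is.character(name) || length(name) != 1L) stopf("`name` must be a string")
  if (!is.list(bands) || length(bands) < 1L ||
      !all(vapply(bands, inherits, logical(1), "spectral_band")))
    stopf("`bands` must be a non-empty list of spectral_band objects")
  w <- vapply(bands, `[[`, numeric(1), "weight")
  w <- w / sum(w)
  for (i in seq_along(bands)) bands[[i]]$weight <- w[i]
  structure(list(name = name, bands = bands), class = "illumination_spec")
}

#' Default broadband white-light illumination
#'
#' Thirteen equally weighted 25 nm bands spanning 400-700 nm, a flat stand-in
#' for a xenon white-light source.
#'
#' @return an `illumination_spec` named `"WLI"`.
#' @export
wli_illumination <- function() {
  illumination("WLI", lapply(seq(400, 700, by = 25),
                             function(l) spectral_band(l, fwhm_nm = 25)))
}

#' Default narrow-band illumination
#'
#' Two equally weighted narrow bands at 415 nm (blue, superficial
#' penetration) and 540 nm (green, deeper penetration), centred on the
#' haemoglobin absorption maxima of the shipped absorption table.
#'
#' @return an `illumination_spec` named `"NBI"`.
#' @export
nbi_illumination <- function() {
  illumination("NBI", list(spectral_band(415, fwhm_nm = 30),
                           spectral_band(540, fwhm_nm = 20)))
}

#' Haemoglobin absorption table
#'
#' Absorption coefficient per (a.u. concentration x a.u. path length) as a
#' function of wavelength; evaluation interpolates linearly between knots and
#' clamps at the table ends.
#'
#' @param wavelengths_nm strictly increasing wavelengths, nm.
#' @param mu non-negative absorption coefficients, one per wavelength.
#' @return an object of class `absorption_table`.
#' @seealso [default_absorption()], [read_absorption_csv()]
#' @export
absorption_table <- function(wavelengths_nm, mu) {
  if (!is.numeric(wavelengths_nm) || length(wavelengths_nm) < 1L)
    stopf("`wavelengths_nm` must be a non-empty numeric vector")
  if (is.unsorted(wavelengths_nm, strictly = TRUE))
    stopf("`wavelengths_nm` must be strictly increasing")
  if (!is.numeric(mu) || length(mu) != length(wavelengths_nm) || any(mu < 0) ||
      any(!is.finite(mu)))
    stopf("`mu` must be non-negative and match `wavelengths_nm` in length")
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 mu = as.numeric(mu)),
            class = "absorption_table")
}

#' Read an absorption table from a two-column CSV
#'
#' Expects columns `wavelength_nm` and `mu`; lines starting with `#` are
#' comments.
#'
#' @param path CSV file path.
#' @return an [absorption_table()].
#' @export
read_absorption_csv <- function(path) {
  if (!file.exists(path)) stopf("absorption table file not found: %s", path)
  x <- utils::read.csv(path, comment.char = "#")
  if (!all(c("wavelength_nm", "mu") %in% names(x)))
    stopf("absorption CSV must have columns 'wavelength_nm' and 'mu'")
  absorption_table(x$wavelength_nm, x$mu)
}

#' Shipped synthetic haemoglobin-like absorption table
#'
#' The default fixture: a synthetic curve (arbitrary units) with local maxima
#' exactly at 415 nm and 540 nm and a trough near 650-700 nm. It is shaped
#' only so the narrow illumination bands sit on absorption maxima; it does
#' not reproduce literature haemoglobin spectra.
#'
#' @return an [absorption_table()].
#' @export
default_absorption <- function() {
  read_absorption_csv(system.file("extdata", "hb_absorption_synthetic.csv",
                                  package = "nbicontrast", mustWork = TRUE))
}

mu_at <- function(table, wavelengths) {
  if (length(table$wavelengths_nm) == 1L)
    return(rep(table$mu, length(wavelengths)))
  stats::approx(table$wavelengths_nm, table$mu, xout = wavelengths,
                rule = 2)$y
}

#' Fraction of the deep haemoglobin layer reached by a wavelength
#'
#' Penetration depth grows with wavelength: short (blue) light probes only
#' the superficial layer while longer (green and beyond) light also reaches
#' the deep layer. Modelled as a piecewise-linear ramp from 0 at 450 nm to 1
#' at 600 nm, clamped outside; a package constant chosen to encode that
#' qualitative ordering, configurable by passing a different function to
#' [band_transmission()].
#'
#' @param wavelength_nm wavelength(s), nm.
#' @return values in `[0, 1]`, non-decreasing in wavelength.
#' @export
deep_fraction <- function(wavelength_nm) {
  clip01((wavelength_nm - 450) / 150)
}

## Gaussian quadrature-like sampling of a band: K wavelengths equally spaced
## over center +/- fwhm, weighted by the band's Gaussian line shape
band_samples <- function(band, k = 7L) {
  if (k < 1L) stopf("`k` must be >= 1")
  offsets <- if (k == 1L) 0 else seq(-1, 1, length.out = k) * band$fwhm_nm
  sigma <- band$fwhm_nm / (2 * sqrt(2 * log(2)))
  g <- exp(-offsets^2 / (2 * sigma^2))
  list(wavelengths = band$center_nm + offsets, weights = g / sum(g))
}

#' Band-integrated Beer-Lambert transmission through the haemoglobin layers
#'
#' Samples the band at `k` wavelengths with Gaussian weights over its FWHM
#' and averages the two-layer Beer-Lambert transmission
#' `exp(-mu(lambda) * (hb_surface * d_s + deep_fraction(lambda) * hb_deep * d_d))`.
#' Short wavelengths do not reach the deep layer (see [deep_fraction()]).
#'
#' @param band a [spectral_band()].
#' @param table an [absorption_table()].
#' @param hb_surface,hb_deep haemoglobin concentration grids (a.u.).
#' @param depths numeric length-2, path lengths (surface, deep).
#' @param k number of spectral samples per band (default 7).
#' @param deep_fraction_fn function mapping wavelength (nm) to the reached
#'   fraction of the deep layer.
#' @return a transmission grid with values in `(0, 1]`.
#' @export
band_transmission <- function(band, table, hb_surface, hb_deep, depths,
                              k = 7L, deep_fraction_fn = deep_fraction) {
  if (!inherits(band, "spectral_band")) stopf("`band` must be a spectral_band")
  if (!inherits(table, "absorption_table"))
    stopf("`table` must be an absorption_table")
  rng <- range(table$wavelengths_nm)
  if (band$center_nm + band$fwhm_nm < rng[1] ||
      band$center_nm - band$fwhm_nm > rng[2])
    stopf("band at %g nm lies outside the absorption table span [%g, %g] nm",
          band$center_nm, rng[1], rng[2])
  if (!identical(dim(hb_surface), dim(hb_deep)))
    stopf("hb_surface and hb_deep must have identical dimensions")
  s <- band_samples(band, k)
  mu <- mu_at(table, s$wavelengths)
  df <- deep_fraction_fn(s$wavelengths)
  t_grid <- 0
  for (i in seq_along(s$wavelengths)) {
    path <- hb_surface * depths[1] + df[i] * hb_deep * depths[2]
    t_grid <- t_grid + s$weights[i] * exp(-mu[i] * path)
  }
  t_grid
}

## radial illumination falloff: 1 at the optical centre,
## 1 - strength at the farthest corner
vignette_field <- function(shape, strength) {
  if (strength <= 0) return(matrix(1, shape[1], shape[2]))
  rows <- shape[1]; cols <- shape[2]
  cr <- (rows - 1) / 2; cc <- (cols - 1) / 2
  dr <- matrix((seq_len(rows) - 1 - cr)^2, rows, cols)
  dc <- matrix((seq_len(cols) - 1 - cc)^2, rows, cols, byrow = TRUE)
  d2 <- dr + dc
  1 - strength * d2 / max(d2)
}

#' Construct a modality image
#'
#' @param intensity grid with values in `[0, 1]`.
#' @param modality `"WLI"` or `"NBI"`.
#' @param meta named list of provenance (illumination name, seed, fibre flag).
#' @return an object of class `modality_image`.
#' @export
modality_image <- function(intensity, modality = c("WLI", "NBI"),
                           meta = list()) {
  modality <- match.arg(modality)
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stopf("`intensity` must be a numeric matrix")
  if (any(intensity < 0) || any(intensity > 1))
    stopf("`intensity` values must lie in [0, 1]")
  structure(list(intensity = intensity, modality = modality, meta = meta),
            class = "modality_image")
}

#' Render one illumination modality from a chromophore map
#'
#' Per pixel, `intensity = clip(vignette * reflectance_base *
#' sum_b weight_b * band_transmission(b), 0, 1)`. Deterministic; sensor noise
#' belongs to [simulate_pair()].
#'
#' @param map a `chromophore_map` from [build_scene()].
#' @param illum an [illumination()] spec; its name must be `"WLI"` or
#'   `"NBI"` (the modality tag).
#' @param table an [absorption_table()].
#' @param k spectral samples per band.
#' @return a [modality_image()].
#' @export
render_modality <- function(map, illum, table = default_absorption(),
                            k = 7L) {
  if (!inherits(map, "chromophore_map")) stopf("`map` must be a chromophore_map")
  if (!inherits(illum, "illumination_spec"))
    stopf("`illum` must be an illumination_spec")
  if (!identical(dim(map$hb_surface), dim(map$reflectance_base)) ||
      !identical(dim(map$hb_surface), dim(map$hb_deep)))
    stopf("chromophore map grids have mismatching shapes")
  t_total <- 0
  for (band in illum$bands)
    t_total <- t_total + band$weight *
      band_transmission(band, table, map$hb_surface, map$hb_deep,
                        map$depths, k = k)
  v <- vignette_field(dim(map$hb_surface), map$vignette_strength)
  intensity <- clip01(v * map$reflectance_base * t_total)
  modality_image(intensity,
                 modality = if (toupper(illum$name) == "NBI") "NBI" else "WLI",
                 meta = list(illumination = illum$name, seed = map$seed,
                             fibre = FALSE))
}

#' Fibre-bundle rendering parameters
#'
#' @param n_fibres number of fibre cores in the bundle (>= 7); the flexible
#'   prototype scope has about 5000.
#' @param brightness_factor multiplicative brightness of the fibre image
#'   relative to the rigid-scope image; < 1 because the fibre image is dimmer.
#' @return an object of class `fibre_spec`.
#' @export
fibre_spec <- function(n_fibres = 5000L, brightness_factor = 0.7) {
  assert_scalar_num(n_fibres, "n_fibres", min = 7)
  assert_scalar_num(brightness_factor, "brightness_factor", min = 0,
                    strict_min = TRUE, max = 1)
  structure(list(n_fibres = as.integer(n_fibres),
                 brightness_factor = brightness_factor),
            class = "fibre_spec")
}

## nearest centre of a hexagonally packed lattice with pitch `a`, per pixel;
## returns an integer core id for every pixel
hex_core_ids <- function(rows, cols, n_fibres) {
  a <- sqrt(2 * rows * cols / (sqrt(3) * n_fibres))  # pitch for ~n cores
  dy <- a * sqrt(3) / 2
  y <- matrix(seq_len(rows) - 1, rows, cols)
  x <- matrix(seq_len(cols) - 1, rows, cols, byrow = TRUE)
  best_d2 <- matrix(Inf, rows, cols)
  best_id <- matrix(0L, rows, cols)
  i0 <- floor(y / dy)
  n_j <- ceiling(cols / a) + 2L
  for (di in 0:1) {
    i <- i0 + di
    off <- (i %% 2) * a / 2
    j <- round((x - off) / a)
    cy <- i * dy; cx <- j * a + off
    d2 <- (y - cy)^2 + (x - cx)^2
    better <- d2 < best_d2
    best_d2[better] <- d2[better]
    best_id[better] <- (i[better] + 1L) * n_j + j[better] + 2L
  }
  best_id
}

#' Degrade an image through a fibre bundle
#'
#' Emulates a low-fibre-count flexible endoscope: intensities are averaged
#' over approximately `n_fibres` hexagonally packed circular cores covering
#' the frame (each pixel contributes to its nearest core), the core mosaic is
#' resampled back to full resolution with Gaussian inter-core interpolation
#' (scale = half the core pitch), then multiplied by `brightness_factor` and
#' clipped to `[0, 1]`. The output shape equals the input shape. The
#' operation is a spatial low-pass: it never increases ROI mean absolute
#' gradients on noiseless renders.
#'
#' @param image a [modality_image()].
#' @param n_fibres number of cores (>= 7, at most the pixel count).
#' @param brightness_factor brightness scale in `(0, 1]`.
#' @return a [modality_image()] with `meta$fibre = TRUE`.
#' @export
apply_fibre_bundle <- function(image, n_fibres = 5000L,
                               brightness_factor = 0.7) {
  if (!inherits(image, "modality_image"))
    stopf("`image` must be a modality_image")
  assert_scalar_num(n_fibres, "n_fibres", min = 7)
  assert_scalar_num(brightness_factor, "brightness_factor", min = 0,
                    strict_min = TRUE, max = 1)
  x <- image$intensity
  npix <- length(x)
  if (n_fibres > npix)
    stopf("n_fibres (%d) exceeds the pixel count (%d)", n_fibres, npix)
  ids <- hex_core_ids(nrow(x), ncol(x), n_fibres)
  core_mean <- rowsum(as.numeric(x), group = as.integer(ids)) /
    as.numeric(table(as.integer(ids)))
  mosaic <- matrix(core_mean[match(as.integer(ids),
                                   as.integer(rownames(core_mean)))],
                   nrow(x), ncol(x))
  pitch <- sqrt(2 * npix / (sqrt(3) * n_fibres))
  smooth <- gaussian_smooth_periodic(mosaic, pitch / 2)
  out <- clip01(smooth * brightness_factor)
  meta <- image$meta
  meta$fibre <- TRUE
  meta$n_fibres <- as.integer(n_fibres)
  meta$brightness_factor <- brightness_factor
  modality_image(out, modality = image$modality, meta = meta)
}

#' Simulate a co-registered WLI/NBI image pair
#'
#' Builds the scene once and renders it under both illuminations, so the two
#' images share the exact same tissue texture and lesions (co-registered by
#' construction). Sensor noise is additive Gaussian (standard deviation
#' `noise_sigma` as a fraction of full scale), drawn independently per
#' modality from the seeded stream, then clipped to `[0, 1]`. Fibre
#' degradation, if requested, is applied to both images.
#'
#' @param spec a [scene_spec()]; its seed fixes the tissue texture.
#' @param illum_wli,illum_nbi illumination specs (defaults:
#'   [wli_illumination()], [nbi_illumination()]).
#' @param table an [absorption_table()].
#' @param noise_sigma sensor noise standard deviation as a fraction of full
#'   scale (default 0.01; 0 disables noise).
#' @param fibre `NULL` (rigid-scope rendering) or a [fibre_spec()].
#' @param seed seed for the sensor noise; defaults to the scene seed.
#' @param k spectral samples per band.
#' @return an object of class `image_pair` with elements `wli`, `nbi`
#'   ([modality_image()]s) and `scene_seed`.
#' @export
#' @examples
#' pair <- simulate_pair(preset_scenario("tear"), noise_sigma = 0)
#' analyze_pair(pair, preset_roi("tear"))
simulate_pair <- function(spec, illum_wli = wli_illumination(),
                          illum_nbi = nbi_illumination(),
                          table = default_absorption(), noise_sigma = 0.01,
                          fibre = NULL, seed = spec$seed, k = 7L) {
  if (!inherits(spec, "scene_spec")) stopf("`spec` must be a scene_spec")
  assert_scalar_num(noise_sigma, "noise_sigma", min = 0)
  if (!is.null(fibre) && !inherits(fibre, "fibre_spec"))
    stopf("`fibre` must be NULL or a fibre_spec")
  map <- build_scene(spec)
  wli <- render_modality(map, illum_wli, table, k = k)
  nbi <- render_modality(map, illum_nbi, table, k = k)
  if (noise_sigma > 0) {
    noise <- with_seed(seed, list(
      wli = matrix(stats::rnorm(length(wli$intensity), sd = noise_sigma),
                   nrow(wli$intensity)),
      nbi = matrix(stats::rnorm(length(nbi$intensity), sd = noise_sigma),
                   nrow(nbi$intensity))))
    wli$intensity <- clip01(wli$intensity + noise$wli)
    nbi$intensity <- clip01(nbi$intensity + noise$nbi)
  }
  if (!is.null(fibre)) {
    wli <- apply_fibre_bundle(wli, fibre$n_fibres, fibre$brightness_factor)
    nbi <- apply_fibre_bundle(nbi, fibre$n_fibres, fibre$brightness_factor)
  }
  wli$meta$noise_seed <- as.integer(seed)
  nbi$meta$noise_seed <- as.integer(seed)
  structure(list(wli = wli, nbi = nbi, scene_seed = spec$seed),
            class = "image_pair")
}

#' @export
print.modality_image <- function(x, ...) {
  cat(sprintf("modality_image [%s]: %d x %d px, intensity range [%.3f, %.3f]%s\n",
              x$modality, nrow(x$intensity), ncol(x$intensity),
              min(x$intensity), max(x$intensity),
              if (isTRUE(x$meta$fibre)) ", fibre-degraded" else ""))
  invisible(x)
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("image_pair (scene seed %d):\n", x$scene_seed))
  print(x$wli); print(x$nbi)
  invisible(x)
}

#' Display a WLI/NBI pair side by side
#'
#' @param x an `image_pair`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.image_pair <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (img in list(x$wli, x$nbi)) {
    m <- t(img$intensity)[, rev(seq_len(nrow(img$intensity))), drop = FALSE]
    graphics::image(m, zlim = c(0, 1), col = grDevices::gray.colors(256, 0, 1),
                    axes = FALSE, main = img$modality, useRaster = TRUE, ...)
  }
  invisible(x)
}
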