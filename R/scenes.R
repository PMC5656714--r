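#' Describe a vessel-wall lesion
#'
#' A lesion is a soft-edged elliptical footprint inside which surface
#' haemoglobin is locally elevated (blood accumulates at wall defects) and the
#' base reflectance may shift (charring darkens a burn). Two phenotypes are
#' distinguished: `"tear"` (scalpel-type mechanical defect, typically a
#' strongly anisotropic ellipse) and `"burn"` (thermal ablation defect,
#' roughly isotropic, usually with a reflectance drop).
#'
#' @param kind `"tear"` or `"burn"`.
#' @param center numeric length-2, lesion centre as (row, col) pixel
#'   coordinates (0-based fractional coordinates are allowed).
#' @param axis_lengths numeric length-2, elliptical semi-axes in pixels:
#'   first along the orientation direction, second perpendicular to it.
#' @param orientation rotation of the first axis relative to the image
#'   column direction, radians.
#' @param hb_multiplier factor (>= 1) applied to surface haemoglobin at the
#'   footprint centre; haemoglobin accumulates at defects for both kinds.
#' @param reflectance_delta additive change to base reflectance at the
#'   footprint centre (negative for a charred burn).
#' @param edge_softness Gaussian roll-off scale of the footprint edge,
#'   pixels; 0 gives a hard edge. Pixels farther than `4 * edge_softness`
#'   outside the ellipse are untouched.
#' @return an object of class `lesion_spec`.
#' @export
#' @examples
#' lesion_spec("tear", center = c(60, 80), axis_lengths = c(26, 7),
#'             orientation = 0.35, hb_multiplier = 3)
lesion_spec <- function(kind = c("tear", "burn"), center, axis_lengths,
                        orientation = 0, hb_multiplier = 2,
                        reflectance_delta = 0, edge_softness = 2) {
  kind <- match.arg(kind)
  if (!is.numeric(center) || length(center) != 2L || !all(is.finite(center)))
    stopf("`center` must be two finite numbers (row, col)")
  if (!is.numeric(axis_lengths) || length(axis_lengths) != 2L ||
      any(axis_lengths <= 0))
    stopf("`axis_lengths` must be two positive semi-axis lengths in pixels")
  assert_scalar_num(orientation, "orientation")
  assert_scalar_num(hb_multiplier, "hb_multiplier", min = 1)
  assert_scalar_num(reflectance_delta, "reflectance_delta", min = -1, max = 1)
  assert_scalar_num(edge_softness, "edge_softness", min = 0)
  structure(list(kind = kind, center = as.numeric(center),
                 axis_lengths = as.numeric(axis_lengths),
                 orientation = orientation, hb_multiplier = hb_multiplier,
                 reflectance_delta = reflectance_delta,
                 edge_softness = edge_softness),
            class = "lesion_spec")
}

#' Describe a synthetic vessel-wall scene
#'
#' Parametric description of a frontal vessel-wall patch: a two-layer
#' haemoglobin field (superficial and deep, in arbitrary concentration
#' units), a base diffuse reflectance, multiplicative correlated texture, an
#' optional radial vignette, and a list of lesions. Concentrations and path
#' lengths are arbitrary units: only the products absorption x concentration
#' x depth matter downstream, so no physical calibration is attempted.
#'
#' @param shape integer length-2, image size (rows, cols) in pixels.
#' @param base_hb_surface,base_hb_deep baseline haemoglobin concentration of
#'   the superficial / deep layer (a.u., >= 0).
#' @param depth_surface,depth_deep optical path length through each layer
#'   (a.u., >= 0).
#' @param base_reflectance baseline diffuse reflectance in `[0, 1]`.
#' @param texture_amplitude relative standard deviation of the multiplicative
#'   tissue texture, in `[0, 1)`; the reflectance field uses 0.35 times this
#'   amplitude (tissue reflectance varies less than its haemoglobin load).
#' @param texture_corr_length correlation length of the texture, pixels.
#' @param vignette_strength radial illumination falloff in `[0, 1)`; 0 means
#'   flat illumination.
#' @param lesions list of [lesion_spec()] objects, applied in order (later
#'   lesions win where footprints overlap).
#' @param seed integer; fixes the texture so identical specs give
#'   bit-identical maps.
#' @return an object of class `scene_spec`.
#' @seealso [build_scene()], [preset_scenario()]
#' @export
scene_spec <- function(shape = c(120L, 160L), base_hb_surface = 0.15,
                       base_hb_deep = 0.3, depth_surface = 1,
                       depth_deep = 1, base_reflectance = 0.75,
                       texture_amplitude = 0.15, texture_corr_length = 6,
                       vignette_strength = 0.25, lesions = list(),
                       seed = 1L) {
  if (!is.numeric(shape) || length(shape) != 2L || any(shape < 2) ||
      any(shape != round(shape)))
    stopf("`shape` must be two integers (rows, cols), each >= 2")
  assert_scalar_num(base_hb_surface, "base_hb_surface", min = 0)
  assert_scalar_num(base_hb_deep, "base_hb_deep", min = 0)
  assert_scalar_num(depth_surface, "depth_surface", min = 0)
  assert_scalar_num(depth_deep, "depth_deep", min = 0)
  assert_scalar_num(base_reflectance, "base_reflectance", min = 0, max = 1)
  assert_scalar_num(texture_amplitude, "texture_amplitude", min = 0)
  if (texture_amplitude >= 1) stopf("`texture_amplitude` must be in [0, 1)")
  assert_scalar_num(texture_corr_length, "texture_corr_length", min = 0)
  assert_scalar_num(vignette_strength, "vignette_strength", min = 0)
  if (vignette_strength >= 1) stopf("`vignette_strength` must be in [0, 1)")
  if (!is.list(lesions) ||
      !all(vapply(lesions, inherits, logical(1), "lesion_spec")))
    stopf("`lesions` must be a list of lesion_spec objects")
  assert_scalar_num(seed, "seed")
  structure(list(shape = as.integer(shape),
                 base_hb_surface = base_hb_surface,
                 base_hb_deep = base_hb_deep,
                 depth_surface = depth_surface, depth_deep = depth_deep,
                 base_reflectance = base_reflectance,
                 texture_amplitude = texture_amplitude,
                 texture_corr_length = texture_corr_length,
                 vignette_strength = vignette_strength,
                 lesions = lesions, seed = as.integer(seed)),
            class = "scene_spec")
}

## soft elliptical footprint weight in [0, 1]; exactly 0 beyond
## 4 * edge_softness outside the ellipse so lesions are strictly local
lesion_footprint <- function(lesion, shape) {
  rows <- shape[1]; cols <- shape[2]
  dr <- matrix(seq_len(rows) - 1 - lesion$center[1], rows, cols)
  dc <- matrix(seq_len(cols) - 1 - lesion$center[2], rows, cols, byrow = TRUE)
  co <- cos(lesion$orientation); si <- sin(lesion$orientation)
  u <- dc * co + dr * si
  v <- -dc * si + dr * co
  a <- lesion$axis_lengths[1]; b <- lesion$axis_lengths[2]
  rho <- sqrt((u / a)^2 + (v / b)^2)
  w <- matrix(0, rows, cols)
  w[rho <= 1] <- 1
  s <- lesion$edge_softness
  if (s > 0) {
    d <- (rho - 1) * mean(lesion$axis_lengths)  # pixel distance outside edge
    soft <- rho > 1 & d <= 4 * s
    w[soft] <- exp(-d[soft]^2 / (2 * s^2))
  }
  w
}

#' Apply a lesion to a chromophore map
#'
#' Inside the soft-edged elliptical footprint, surface haemoglobin is scaled
#' towards `hb_multiplier` times its local value and the base reflectance is
#' shifted by `reflectance_delta`, with Gaussian blending over
#' `edge_softness`; pixels beyond `4 * edge_softness` outside the footprint
#' are untouched.
#'
#' @param map a `chromophore_map` from [build_scene()].
#' @param lesion a [lesion_spec()].
#' @return the modified `chromophore_map`.
#' @export
apply_lesion <- function(map, lesion) {
  if (!inherits(map, "chromophore_map")) stopf("`map` must be a chromophore_map")
  if (!inherits(lesion, "lesion_spec")) stopf("`lesion` must be a lesion_spec")
  w <- lesion_footprint(lesion, dim(map$hb_surface))
  if (!any(w > 0)) stopf("lesion footprint lies fully outside the image")
  map$hb_surface <- map$hb_surface * (1 + (lesion$hb_multiplier - 1) * w)
  map$reflectance_base <- clip01(map$reflectance_base +
                                   lesion$reflectance_delta * w)
  map
}

#' Rasterize a scene into chromophore and reflectance maps
#'
#' Draws seeded Gaussian noise, smooths it to the scene's texture correlation
#' length, normalises it to unit standard deviation and applies it
#' multiplicatively to the baseline haemoglobin and reflectance fields (three
#' independent fields, drawn in a fixed order so the result is bit-identical
#' for identical specs). Lesions are then applied in list order.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `chromophore_map`: grids `hb_surface`,
#'   `hb_deep` (a.u., >= 0) and `reflectance_base` (in `[0, 1]`), plus the
#'   layer `depths` and the scene's vignette strength and seed, carried along
#'   for rendering.
#' @export
#' @examples
#' map <- build_scene(preset_scenario("tear"))
#' range(map$hb_surface)
build_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stopf("`spec` must be a scene_spec")
  rows <- spec$shape[1]; cols <- spec$shape[2]
  amp <- spec$texture_amplitude
  fields <- with_seed(spec$seed, {
    if (amp > 0) {
      z_hb_s <- correlated_noise(rows, cols, spec$texture_corr_length)
      z_hb_d <- correlated_noise(rows, cols, spec$texture_corr_length)
      z_refl <- correlated_noise(rows, cols, spec$texture_corr_length)
      list(hb_s = pmax(spec$base_hb_surface * (1 + amp * z_hb_s), 0),
           hb_d = pmax(spec$base_hb_deep * (1 + amp * z_hb_d), 0),
           refl = clip01(spec$base_reflectance * (1 + 0.35 * amp * z_refl)))
    } else {
      list(hb_s = matrix(spec$base_hb_surface, rows, cols),
           hb_d = matrix(spec$base_hb_deep, rows, cols),
           refl = matrix(spec$base_reflectance, rows, cols))
    }
  })
  map <- structure(list(hb_surface = fields$hb_s, hb_deep = fields$hb_d,
                        reflectance_base = fields$refl,
                        depths = c(surface = spec$depth_surface,
                                   deep = spec$depth_deep),
                        vignette_strength = spec$vignette_strength,
                        seed = spec$seed),
                   class = "chromophore_map")
  for (lesion in spec$lesions) map <- apply_lesion(map, lesion)
  map
}

#' Scene presets for the study's imaging scenarios
#'
#' Ready-made [scene_spec()]s matching the four qualitative imaging
#' scenarios: a saline-flushed lumen with no defect (and no residual
#' haemoglobin beyond the wall tissue itself), a scalpel tear, a solder burn,
#' and a bifurcation viewed through the low-fibre-count flexible scope. No
#' published lesion dimensions exist for this preparation; preset sizes and
#' placements are package choices, documented here and sized so the default
#' ROI (see [preset_roi()]) covers the lesion plus surrounding tissue.
#'
#' @param name one of `"flushed_lumen"`, `"tear"`, `"burn"`,
#'   `"bifurcation_fiber"`.
#' @return a `scene_spec`. For `"bifurcation_fiber"` the attribute `fibre`
#'   is `TRUE`, signalling that downstream rendering should apply
#'   [apply_fibre_bundle()].
#' @export
#' @examples
#' preset_scenario("tear")$lesions[[1]]$kind
preset_scenario <- function(name) {
  presets <- c("flushed_lumen", "tear", "burn", "bifurcation_fiber")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets))
    stopf("unknown scenario '%s'; valid presets: %s",
          paste(name, collapse = ","), paste(presets, collapse = ", "))
  spec <- switch(name,
    flushed_lumen = scene_spec(base_hb_surface = 0, base_hb_deep = 0,
                               seed = 101L),
    tear = scene_spec(lesions = list(
      # near-vertical laceration: crosses most ROI rows, two sharp
      # haemoglobin edges per row line profile
      lesion_spec("tear", center = c(60, 80), axis_lengths = c(26, 7),
                  orientation = 1.2, hb_multiplier = 3,
                  reflectance_delta = -0.05, edge_softness = 2.5)),
      seed = 102L),
    burn = scene_spec(lesions = list(
      lesion_spec("burn", center = c(60, 80), axis_lengths = c(16, 16),
                  orientation = 0, hb_multiplier = 4,
                  reflectance_delta = -0.25, edge_softness = 4)),
      seed = 103L),
    bifurcation_fiber = scene_spec(lesions = list(
      lesion_spec("tear", center = c(62, 42), axis_lengths = c(18, 6),
                  orientation = 1.1, hb_multiplier = 3,
                  reflectance_delta = -0.05, edge_softness = 2.5),
      # broad darker patch standing in for the branch opening
      lesion_spec("burn", center = c(55, 115), axis_lengths = c(28, 22),
                  orientation = 0, hb_multiplier = 1.3,
                  reflectance_delta = -0.35, edge_softness = 8)),
      seed = 104L))
  attr(spec, "scenario") <- name
  attr(spec, "fibre") <- identical(name, "bifurcation_fiber")
  spec
}

#' Default region of interest for a preset scenario
#'
#' An ROI covering the preset's lesion and part of the surrounding tissue
#' (centre of the frame for the lesion-free flushed lumen).
#'
#' @inheritParams preset_scenario
#' @return an [roi_rect()].
#' @export
preset_roi <- function(name) {
  switch(name,
    flushed_lumen = roi_rect(30, 40, 90, 120),
    tear = roi_rect(35, 45, 85, 115),
    burn = roi_rect(35, 50, 85, 110),
    bifurcation_fiber = roi_rect(38, 18, 88, 70),
    stopf("unknown scenario '%s'; valid presets: %s", name,
          "flushed_lumen, tear, burn, bifurcation_fiber"))
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("scene_spec: %d x %d px, hb surface/deep %.3g/%.3g a.u., %s\n",
              x$shape[1], x$shape[2], x$base_hb_surface, x$base_hb_deep,
              sprintf("%d lesion(s), seed %d", length(x$lesions), x$seed)))
  for (l in x$lesions)
    cat(sprintf("  - %s at (%.0f,%.0f), semi-axes %.1f x %.1f px, hb x%.2f, dR %+.2f\n",
                l$kind, l$center[1], l$center[2], l$axis_lengths[1],
                l$axis_lengths[2], l$hb_multiplier, l$reflectance_delta))
  invisible(x)
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat(sprintf("lesion_spec: %s at (%.0f,%.0f), semi-axes %.1f x %.1f px, hb x%.2f, dR %+.2f, edge %.1f px\n",
              x$kind, x$center[1], x$center[2], x$axis_lengths[1],
              x$axis_lengths[2], x$hb_multiplier, x$reflectance_delta,
              x$edge_softness))
  invisible(x)
}
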