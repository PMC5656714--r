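## scene_spec / lesion_spec <-> plain-list conversion for YAML/JSON configs

lesion_to_list <- function(l) {
  list(kind = l$kind, center = l$center, axis_lengths = l$axis_lengths,
       orientation = l$orientation, hb_multiplier = l$hb_multiplier,
       reflectance_delta = l$reflectance_delta,
       edge_softness = l$edge_softness)
}

lesion_from_list <- function(x) {
  lesion_spec(kind = x$kind, center = as.numeric(x$center),
              axis_lengths = as.numeric(x$axis_lengths),
              orientation = x$orientation %||% 0,
              hb_multiplier = x$hb_multiplier %||% 2,
              reflectance_delta = x$reflectance_delta %||% 0,
              edge_softness = x$edge_softness %||% 2)
}

scene_to_list <- function(s) {
  list(shape = s$shape, base_hb_surface = s$base_hb_surface,
       base_hb_deep = s$base_hb_deep, depth_surface = s$depth_surface,
       depth_deep = s$depth_deep, base_reflectance = s$base_reflectance,
       texture_amplitude = s$texture_amplitude,
       texture_corr_length = s$texture_corr_length,
       vignette_strength = s$vignette_strength,
       lesions = lapply(s$lesions, lesion_to_list), seed = s$seed)
}

scene_from_list <- function(x) {
  scene_spec(shape = as.integer(x$shape),
             base_hb_surface = x$base_hb_surface,
             base_hb_deep = x$base_hb_deep,
             depth_surface = x$depth_surface, depth_deep = x$depth_deep,
             base_reflectance = x$base_reflectance,
             texture_amplitude = x$texture_amplitude,
             texture_corr_length = x$texture_corr_length,
             vignette_strength = x$vignette_strength,
             lesions = lapply(x$lesions, lesion_from_list),
             seed = as.integer(x$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration of an experiment run
#'
#' Bundles everything [run_experiment()] needs: the scenarios (preset names
#' or inline [scene_spec()]s), the ROI per scenario (0-based half-open pixel
#' bounds `{row0, col0, row1, col1}`), sensor noise, fibre settings, the
#' absorption table, replicate count and base seed. Round-trips losslessly
#' through YAML or JSON via [write_run_config()] / [read_run_config()].
#'
#' @param scenarios character vector of preset names (see
#'   [preset_scenario()]) and/or a named list of `scene_spec`s.
#' @param rois optional named list of [roi_rect()]s (or
#'   `list(row0=,col0=,row1=,col1=)`), one per scenario; presets fall back to
#'   [preset_roi()].
#' @param noise_sigma sensor noise fraction of full scale.
#' @param fibre `NULL`, `TRUE` (default [fibre_spec()]) or a [fibre_spec()];
#'   applied to every scenario. Independently, a preset carrying
#'   `attr(spec, "fibre") = TRUE` (the bifurcation scenario) is rendered
#'   through the default fibre bundle.
#' @param n_replicates replicates per scenario (>= 1).
#' @param base_seed integer base seed; replicate seeds derive from it via
#'   [child_seed()].
#' @param absorption_csv optional path to an absorption CSV; `NULL` uses the
#'   shipped synthetic table. The file must exist at construction time.
#' @param normalize per-ROI mean normalization flag (see [analyze_pair()]).
#' @param output_dir optional output directory for images, CSV and JSON
#'   reports and diagram plots; `NULL` keeps everything in memory.
#' @param write_plots write PNG intensity-change diagrams and image pairs for
#'   the first replicate of each scenario (only when `output_dir` is set).
#' @return an object of class `run_config`.
#' @export
run_config <- function(scenarios = c("tear", "burn"), rois = NULL,
                       noise_sigma = 0.01, fibre = NULL, n_replicates = 10L,
                       base_seed = 1L, absorption_csv = NULL,
                       normalize = FALSE, output_dir = NULL,
                       write_plots = TRUE) {
  assert_scalar_num(n_replicates, "n_replicates", min = 1)
  assert_scalar_num(base_seed, "base_seed")
  assert_scalar_num(noise_sigma, "noise_sigma", min = 0)
  if (isTRUE(fibre)) fibre <- fibre_spec()
  if (!is.null(fibre) && !inherits(fibre, "fibre_spec"))
    stopf("`fibre` must be NULL, TRUE, or a fibre_spec")
  if (!is.null(absorption_csv) && !file.exists(absorption_csv))
    stopf("absorption_csv does not exist: %s", absorption_csv)
  scen <- list()
  if (is.character(scenarios)) {
    for (nm in scenarios) scen[[nm]] <- list(name = nm, scene = NULL)
  } else if (is.list(scenarios)) {
    if (is.null(names(scenarios)) || any(names(scenarios) == ""))
      stopf("inline scenarios must be a named list of scene_spec objects")
    for (nm in names(scenarios)) {
      s <- scenarios[[nm]]
      if (inherits(s, "scene_spec")) scen[[nm]] <- list(name = nm, scene = s)
      else if (is.character(s)) scen[[nm]] <- list(name = s, scene = NULL)
      else stopf("scenario '%s' must be a preset name or a scene_spec", nm)
    }
  } else stopf("`scenarios` must be preset names or a named list")
  if (!is.null(rois)) {
    for (nm in names(rois)) {
      r <- rois[[nm]]
      if (!inherits(r, "roi_rect"))
        rois[[nm]] <- roi_rect(r$row0, r$col0, r$row1, r$col1)
    }
  }
  structure(list(scenarios = scen, rois = rois, noise_sigma = noise_sigma,
                 fibre = fibre, n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 absorption_csv = absorption_csv, normalize = normalize,
                 output_dir = output_dir, write_plots = isTRUE(write_plots)),
            class = "run_config")
}

config_to_list <- function(config) {
  list(
    scenarios = lapply(config$scenarios, function(s)
      list(name = s$name,
           scene = if (is.null(s$scene)) NULL else scene_to_list(s$scene))),
    rois = if (is.null(config$rois)) NULL
           else lapply(config$rois, unclass),
    noise_sigma = config$noise_sigma,
    fibre = if (is.null(config$fibre)) NULL else unclass(config$fibre),
    n_replicates = config$n_replicates,
    base_seed = config$base_seed,
    absorption_csv = config$absorption_csv,
    normalize = config$normalize,
    output_dir = config$output_dir,
    write_plots = config$write_plots)
}

config_from_list <- function(x) {
  scenarios <- lapply(x$scenarios, function(s) {
    if (is.null(s$scene)) s$name else scene_from_list(s$scene)
  })
  names(scenarios) <- vapply(x$scenarios, `[[`, character(1), "name")
  run_config(scenarios = scenarios,
             rois = x$rois,
             noise_sigma = x$noise_sigma %||% 0.01,
             fibre = if (is.null(x$fibre)) NULL else
               fibre_spec(x$fibre$n_fibres, x$fibre$brightness_factor),
             n_replicates = x$n_replicates %||% 10L,
             base_seed = x$base_seed %||% 1L,
             absorption_csv = x$absorption_csv,
             normalize = isTRUE(x$normalize),
             output_dir = x$output_dir,
             write_plots = x$write_plots %||% TRUE)
}

#' Write a run configuration to YAML or JSON
#'
#' @param config a [run_config()].
#' @param path output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) stopf("`config` must be a run_config")
  lst <- config_to_list(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else stopf("config path must end in .yaml, .yml or .json")
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Validates the loaded values through the same constructors used in code, so
#' a malformed config fails with the constructor's error message before any
#' simulation starts.
#'
#' @param path config path ending in `.yaml`/`.yml` or `.json`.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE,
                                              simplifyDataFrame = FALSE,
                                              simplifyMatrix = FALSE)
  else stopf("config path must end in .yaml, .yml or .json")
  config_from_list(lst)
}

## order-independent content hash of a config (FNV-1a over its serialized
## plain-list form); provenance only, not cryptographic
config_hash <- function(config) {
  bytes <- as.integer(charToRaw(paste(
    utils::capture.output(utils::str(config_to_list(config), digits.d = 15)),
    collapse = "\n")))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: %d scenario(s) x %d replicate(s), base seed %d\n",
              length(x$scenarios), x$n_replicates, x$base_seed))
  cat(sprintf("  scenarios: %s\n",
              paste(names(x$scenarios), collapse = ", ")))
  cat(sprintf("  noise_sigma %.3g, fibre %s, normalize %s\n", x$noise_sigma,
              if (is.null(x$fibre)) "off"
              else sprintf("%d cores", x$fibre$n_fibres), x$normalize))
  invisible(x)
}
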