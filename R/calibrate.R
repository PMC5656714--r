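## mean percent increase of a scenario across a fixed seed set, as a
## function of the (first) lesion's haemoglobin multiplier
uplift_at_multiplier <- function(m, base_spec, roi, seeds, table,
                                 noise_sigma, normalize = FALSE) {
  vals <- vapply(seeds, function(s) {
    spec <- base_spec
    spec$lesions[[1]]$hb_multiplier <- m
    spec$seed <- s
    pair <- simulate_pair(spec, table = table, noise_sigma = noise_sigma,
                          seed = s)
    analyze_pair(pair, roi, normalize = normalize)$percent_increase
  }, numeric(1))
  vals
}

#' Calibrate the tear scenario to a target gradient uplift
#'
#' Tunes the lesion's haemoglobin multiplier by bisection — over a fixed set
#' of texture seeds derived from `base_seed` — until the across-replicate
#' mean percent increase is within `tol` points of `target_percent`. Before
#' bisecting, the mean uplift is scanned over a coarse multiplier grid to
#' verify it is non-decreasing and that the target is bracketed; an
#' unreachable target fails with the bracketing values.
#'
#' @param target_percent target mean percent increase (> 0).
#' @param n_replicates seeds in the calibration set (default 50).
#' @param base_seed integer; the seed set is `child_seed(base_seed, 0:(n-1))`.
#' @param scenario preset name (default `"tear"`) or a [scene_spec()] with at
#'   least one lesion.
#' @param roi optional [roi_rect()]; defaults to the preset ROI.
#' @param bounds multiplier search interval (default `c(1, 12)`).
#' @param tol convergence tolerance on the mean percent increase, points.
#' @param max_iter bisection iteration cap.
#' @param noise_sigma sensor noise during calibration.
#' @param table an [absorption_table()].
#' @return an object of class `uplift_calibration`: the tuned
#'   `hb_multiplier`, `achieved_mean` and `achieved_sd` over the calibration
#'   seeds, the calibrated `scene` (a `scene_spec` usable as an inline
#'   scenario in [run_config()]), the `roi`, the seed set, and the `trace` of
#'   evaluated multipliers.
#' @export
#' @examples
#' \donttest{
#' cal <- recover_uplift(20, n_replicates = 10, base_seed = 7)
#' cal$hb_multiplier
#' }
recover_uplift <- function(target_percent, n_replicates = 50L, base_seed = 1L,
                           scenario = "tear", roi = NULL, bounds = c(1, 12),
                           tol = 0.5, max_iter = 40L, noise_sigma = 0.01,
                           table = default_absorption()) {
  assert_scalar_num(target_percent, "target_percent", min = 0,
                    strict_min = TRUE)
  assert_scalar_num(n_replicates, "n_replicates", min = 1)
  assert_scalar_num(tol, "tol", min = 0, strict_min = TRUE)
  if (!is.numeric(bounds) || length(bounds) != 2L || bounds[1] < 1 ||
      bounds[2] <= bounds[1])
    stopf("`bounds` must be an increasing multiplier interval with lower end >= 1")
  base_spec <- if (inherits(scenario, "scene_spec")) scenario
  else preset_scenario(scenario)
  if (length(base_spec$lesions) == 0L)
    stopf("calibration needs a scenario with at least one lesion")
  if (is.null(roi)) {
    nm <- if (is.character(scenario)) scenario else attr(base_spec, "scenario")
    roi <- preset_roi(nm %||% "tear")
  }
  seeds <- child_seed(base_seed, seq_len(n_replicates) - 1L)

  evals <- new.env(parent = emptyenv())
  f <- function(m) {
    key <- sprintf("%.12g", m)
    if (!is.null(evals[[key]])) return(evals[[key]])
    vals <- uplift_at_multiplier(m, base_spec, roi, seeds, table, noise_sigma)
    res <- list(mean = mean(vals), sd = stats::sd(vals))
    evals[[key]] <- res
    res
  }

  # coarse monotonicity scan + bracket check
  grid <- bounds[1] + (bounds[2] - bounds[1]) * c(0, 0.25, 0.5, 0.75, 1)
  scan <- vapply(grid, function(m) f(m)$mean, numeric(1))
  if (any(diff(scan) < -0.25))
    stopf("mean uplift is not non-decreasing in hb_multiplier over [%g, %g]: %s",
          bounds[1], bounds[2],
          paste(sprintf("f(%.3g)=%.2f", grid, scan), collapse = ", "))
  if (scan[1] > target_percent + tol)
    stopf("target %.1f%% unreachable: uplift at the lower bound is already %.1f%% (multiplier %g)",
          target_percent, scan[1], bounds[1])
  if (scan[length(scan)] < target_percent - tol)
    stopf("target %.1f%% unreachable: uplift at the upper bound is only %.1f%% (multiplier %g)",
          target_percent, scan[length(scan)], bounds[2])

  # initial bracket from adjacent scan points
  hi_idx <- which(scan >= target_percent)[1]
  if (is.na(hi_idx)) hi_idx <- length(grid)
  lo <- if (hi_idx == 1L) grid[1] else grid[hi_idx - 1L]
  hi <- grid[hi_idx]
  best <- list(m = hi, mean = scan[hi_idx], sd = f(hi)$sd)
  iter <- 0L
  while (abs(best$mean - target_percent) > tol && iter < max_iter &&
         (hi - lo) > 1e-6) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm$mean - target_percent) < abs(best$mean - target_percent))
      best <- list(m = mid, mean = fm$mean, sd = fm$sd)
    if (fm$mean < target_percent) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  if (abs(best$mean - target_percent) > tol)
    stopf("bisection did not reach %.1f%% within +/- %.2f points (best %.2f%% at multiplier %.4f)",
          target_percent, tol, best$mean, best$m)

  calibrated <- base_spec
  calibrated$lesions[[1]]$hb_multiplier <- best$m
  trace <- data.frame(
    hb_multiplier = as.numeric(ls(evals)),
    mean_percent_increase = vapply(ls(evals),
                                   function(k) evals[[k]]$mean, numeric(1)))
  trace <- trace[order(trace$hb_multiplier), ]
  rownames(trace) <- NULL
  structure(list(target_percent = target_percent,
                 hb_multiplier = best$m,
                 achieved_mean = best$mean, achieved_sd = best$sd,
                 n_replicates = as.integer(n_replicates), seeds = seeds,
                 noise_sigma = noise_sigma, roi = roi,
                 scene = calibrated, trace = trace, iterations = iter),
            class = "uplift_calibration")
}

#' @export
print.uplift_calibration <- function(x, ...) {
  cat(sprintf("uplift_calibration: target %.1f%%\n", x$target_percent))
  cat(sprintf("  tuned hb_multiplier: %.4f (%d bisection steps)\n",
              x$hb_multiplier, x$iterations))
  cat(sprintf("  achieved mean %.2f%% (sd %.2f) over %d replicates\n",
              x$achieved_mean, x$achieved_sd, x$n_replicates))
  invisible(x)
}
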