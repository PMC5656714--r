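test_that("texture-free, lesion-free scene is constant at the base values", {
  spec <- scene_spec(shape = c(20, 30), texture_amplitude = 0, lesions = list())
  map <- build_scene(spec)
  expect_true(all(map$hb_surface == spec$base_hb_surface))
  expect_true(all(map$hb_deep == spec$base_hb_deep))
  expect_true(all(map$reflectance_base == spec$base_reflectance))
})

test_that("identical scene specs build bit-identical maps", {
  spec <- preset_scenario("tear")
  expect_identical(build_scene(spec), build_scene(spec))
})

test_that("scene building leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(build_scene(preset_scenario("burn")))
  expect_identical(.Random.seed, before)
})

test_that("tear footprint haemoglobin ratio matches a brute-force mask loop", {
  lesion <- lesion_spec("tear", center = c(10, 14), axis_lengths = c(6, 3),
                        orientation = 0.4, hb_multiplier = 3,
                        edge_softness = 0)
  spec <- scene_spec(shape = c(24, 30), texture_amplitude = 0,
                     lesions = list(lesion))
  map <- build_scene(spec)
  # brute-force: classify each pixel by the ellipse equation, loop-accumulate
  inside_sum <- 0; inside_n <- 0; outside_sum <- 0; outside_n <- 0
  for (r in 1:24) for (c in 1:30) {
    dr <- (r - 1) - 10; dc <- (c - 1) - 14
    u <- dc * cos(0.4) + dr * sin(0.4)
    v <- -dc * sin(0.4) + dr * cos(0.4)
    if ((u / 6)^2 + (v / 3)^2 <= 1) {
      inside_sum <- inside_sum + map$hb_surface[r, c]; inside_n <- inside_n + 1
    } else {
      outside_sum <- outside_sum + map$hb_surface[r, c]; outside_n <- outside_n + 1
    }
  }
  ratio <- (inside_sum / inside_n) / (outside_sum / outside_n)
  expect_equal(ratio, 3)
  # per-pixel exactness: interior pixels carry exactly multiplier x base
  for (r in 1:24) for (c in 1:30) {
    dr <- (r - 1) - 10; dc <- (c - 1) - 14
    u <- dc * cos(0.4) + dr * sin(0.4)
    v <- -dc * sin(0.4) + dr * cos(0.4)
    expected <- if ((u / 6)^2 + (v / 3)^2 <= 1) 0.15 * 3 else 0.15
    expect_identical(map$hb_surface[r, c], expected)
  }
})

test_that("identity lesion leaves the map unchanged", {
  map <- build_scene(scene_spec(shape = c(16, 20), seed = 4L))
  lesion <- lesion_spec("tear", center = c(8, 10), axis_lengths = c(4, 2),
                        hb_multiplier = 1, reflectance_delta = 0)
  expect_identical(apply_lesion(map, lesion), map)
})

test_that("hard-edge lesion multiplies haemoglobin exactly at interior pixels", {
  map <- build_scene(scene_spec(shape = c(16, 20), texture_amplitude = 0))
  lesion <- lesion_spec("burn", center = c(8, 10), axis_lengths = c(3, 3),
                        hb_multiplier = 2.5, edge_softness = 0)
  out <- apply_lesion(map, lesion)
  expect_identical(out$hb_surface[9, 11], map$hb_surface[9, 11] * 2.5)
  expect_identical(out$hb_surface[1, 1], map$hb_surface[1, 1])
})

test_that("burn reflectance blend is closed-form at the footprint centre", {
  spec <- scene_spec(shape = c(20, 20), base_reflectance = 0.8,
                     texture_amplitude = 0, lesions = list())
  map <- build_scene(spec)
  burn <- lesion_spec("burn", center = c(10, 10), axis_lengths = c(5, 5),
                      hb_multiplier = 2, reflectance_delta = -0.3,
                      edge_softness = 2)
  out <- apply_lesion(map, burn)
  expect_equal(out$reflectance_base[11, 11], 0.5)
})

test_that("lesions are strictly local beyond 4 x edge_softness", {
  base <- scene_spec(shape = c(40, 50), seed = 7L, lesions = list())
  lesion <- lesion_spec("tear", center = c(20, 25), axis_lengths = c(6, 3),
                        orientation = 1.0, hb_multiplier = 4,
                        reflectance_delta = -0.2, edge_softness = 1.5)
  lesioned <- base
  lesioned$lesions <- list(lesion)
  m0 <- build_scene(base)
  m1 <- build_scene(lesioned)
  # independent far-field mask: farther than 4*softness outside the ellipse
  far <- matrix(TRUE, 40, 50)
  for (r in 1:40) for (c in 1:50) {
    dr <- (r - 1) - 20; dc <- (c - 1) - 25
    u <- dc * cos(1) + dr * sin(1)
    v <- -dc * sin(1) + dr * cos(1)
    rho <- sqrt((u / 6)^2 + (v / 3)^2)
    if ((rho - 1) * mean(c(6, 3)) <= 4 * 1.5) far[r, c] <- FALSE
  }
  expect_identical(m1$hb_surface[far], m0$hb_surface[far])
  expect_identical(m1$reflectance_base[far], m0$reflectance_base[far])
  expect_false(identical(m1$hb_surface[!far], m0$hb_surface[!far]))
})

test_that("mean footprint haemoglobin is monotone in the multiplier", {
  lesion <- function(m) lesion_spec("tear", center = c(20, 25),
                                    axis_lengths = c(8, 4), hb_multiplier = m,
                                    edge_softness = 2)
  w_inside <- NULL
  means <- vapply(c(1, 1.5, 2, 3, 5), function(m) {
    spec <- scene_spec(shape = c(40, 50), seed = 3L, lesions = list(lesion(m)))
    map <- build_scene(spec)
    mean(map$hb_surface)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("out-of-image lesion footprints are rejected", {
  map <- build_scene(scene_spec(shape = c(20, 20)))
  outside <- lesion_spec("tear", center = c(100, 100),
                         axis_lengths = c(4, 2), hb_multiplier = 2)
  expect_error(apply_lesion(map, outside), "outside the image")
  spec <- scene_spec(shape = c(20, 20), lesions = list(outside))
  expect_error(build_scene(spec), "outside the image")
})

test_that("lesion and scene validation rejects bad parameters", {
  expect_error(lesion_spec("tear", c(5, 5), c(4, 2), hb_multiplier = 0.5),
               "hb_multiplier")
  expect_error(lesion_spec("tear", c(5, 5), c(-4, 2)), "axis_lengths")
  expect_error(lesion_spec("scratch", c(5, 5), c(4, 2)))
  expect_error(scene_spec(texture_amplitude = 1.2))
  expect_error(scene_spec(base_hb_surface = -1), "base_hb_surface")
})

test_that("presets match their scenario phenotypes", {
  tear <- preset_scenario("tear")
  expect_length(tear$lesions, 1L)
  expect_identical(tear$lesions[[1]]$kind, "tear")
  # strongly anisotropic footprint
  ax <- tear$lesions[[1]]$axis_lengths
  expect_gt(max(ax) / min(ax), 2)
  expect_length(preset_scenario("flushed_lumen")$lesions, 0L)
  expect_identical(preset_scenario("flushed_lumen")$base_hb_surface, 0)
  burn <- preset_scenario("burn")
  expect_identical(burn$lesions[[1]]$kind, "burn")
  expect_lt(burn$lesions[[1]]$reflectance_delta, 0)
  expect_true(attr(preset_scenario("bifurcation_fiber"), "fibre"))
  expect_false(attr(tear, "fibre"))
  expect_error(preset_scenario("polyp"), "flushed_lumen")
})
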