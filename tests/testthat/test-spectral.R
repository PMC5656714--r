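zero_map <- function(rows = 8, cols = 10) {
  build_scene(scene_spec(shape = c(rows, cols), base_hb_surface = 0,
                         base_hb_deep = 0, texture_amplitude = 0,
                         vignette_strength = 0))
}

test_that("zero absorber transmits everything", {
  tab <- default_absorption()
  z <- matrix(0, 6, 7)
  t_grid <- band_transmission(spectral_band(540, 20), tab, z, z, c(1, 1))
  expect_equal(t_grid, matrix(1, 6, 7), tolerance = 1e-12)
})

test_that("single-wavelength Beer-Lambert transmission is closed form", {
  tab <- absorption_table(500, 0.5)
  hb_s <- matrix(2, 3, 3)
  hb_d <- matrix(0, 3, 3)
  t_grid <- band_transmission(spectral_band(500, 10), tab, hb_s, hb_d,
                              c(1, 1), k = 1L)
  expect_identical(t_grid, matrix(exp(-1), 3, 3))
})

test_that("transmission is monotone decreasing in absorber concentration", {
  tab <- default_absorption()
  set.seed(12)
  hb <- matrix(runif(48, 0, 2), 6, 8)
  deep <- matrix(runif(48, 0, 1), 6, 8)
  for (band in list(spectral_band(415, 30), spectral_band(540, 20),
                    spectral_band(650, 25))) {
    t1 <- band_transmission(band, tab, hb, deep, c(1, 1))
    t2 <- band_transmission(band, tab, 2 * hb, deep, c(1, 1))
    expect_true(all(t2 <= t1))
    expect_true(all(t1 > 0 & t1 <= 1))
  }
})

test_that("band validation rejects out-of-span bands and empty tables", {
  tab <- absorption_table(c(400, 500), c(0.1, 0.2))
  z <- matrix(0, 2, 2)
  expect_error(band_transmission(spectral_band(700, 20), tab, z, z, c(1, 1)),
               "outside the absorption table span")
  expect_error(absorption_table(numeric(0), numeric(0)), "non-empty")
  expect_error(absorption_table(c(500, 400), c(0.1, 0.2)), "increasing")
  expect_error(absorption_table(c(400, 500), c(-0.1, 0.2)), "non-negative")
})

test_that("deep_fraction ramps monotonically from 0 at 450 nm to 1 at 600 nm", {
  wl <- seq(380, 780, by = 5)
  df <- deep_fraction(wl)
  expect_true(all(diff(df) >= 0))
  expect_identical(deep_fraction(415), 0)
  expect_identical(deep_fraction(650), 1)
  expect_equal(deep_fraction(525), 0.5)
})

test_that("zero haemoglobin with no vignette renders the reflectance map", {
  map <- zero_map()
  img <- render_modality(map, wli_illumination())
  expect_equal(img$intensity, map$reflectance_base, tolerance = 1e-12)
})

test_that("single-pixel render composes the closed-form transmission", {
  map <- structure(list(hb_surface = matrix(2, 1, 1),
                        hb_deep = matrix(1, 1, 1),
                        reflectance_base = matrix(0.8, 1, 1),
                        depths = c(surface = 1, deep = 1),
                        vignette_strength = 0, seed = 1L),
                   class = "chromophore_map")
  tab <- absorption_table(500, 0.5)
  illum <- illumination("WLI", list(spectral_band(500, 10)))
  img <- render_modality(map, illum, tab, k = 1L)
  # T = exp(-0.5 * (2*1 + deep_fraction(500)*1*1)), deep_fraction(500) = 1/3
  expect_equal(img$intensity[1, 1], 0.8 * exp(-0.5 * (2 + 1 / 3)),
               tolerance = 1e-12)
})

test_that("illumination weights are scale invariant", {
  map <- build_scene(scene_spec(shape = c(10, 12), seed = 5L))
  b1 <- list(spectral_band(415, 30, weight = 1), spectral_band(540, 20, weight = 2))
  b7 <- list(spectral_band(415, 30, weight = 7), spectral_band(540, 20, weight = 14))
  i1 <- render_modality(map, illumination("NBI", b1))
  i7 <- render_modality(map, illumination("NBI", b7))
  expect_equal(i1$intensity, i7$intensity, tolerance = 1e-12)
})

test_that("band-averaged absorption is higher under NBI than WLI", {
  tab <- default_absorption()
  band_mu <- function(band) {
    s <- nbicontrast:::band_samples(band, 7L)
    sum(s$weights * nbicontrast:::mu_at(tab, s$wavelengths))
  }
  mu_nbi <- mean(vapply(nbi_illumination()$bands, band_mu, numeric(1)))
  mu_wli <- mean(vapply(wli_illumination()$bands, band_mu, numeric(1)))
  expect_gt(mu_nbi, 2 * mu_wli)
})

test_that("an elevated-haemoglobin lesion darkens more under NBI than WLI", {
  spec <- scene_spec(shape = c(40, 50), texture_amplitude = 0,
                     vignette_strength = 0, lesions = list(
    lesion_spec("tear", center = c(20, 25), axis_lengths = c(8, 4),
                hb_multiplier = 3, edge_softness = 0)))
  map <- build_scene(spec)
  wli <- render_modality(map, wli_illumination())
  nbi <- render_modality(map, nbi_illumination())
  # lesion/background intensity ratio: lower (= more contrast) under NBI
  ratio <- function(img) img$intensity[21, 26] / img$intensity[1, 1]
  expect_lt(ratio(nbi), ratio(wli))
  # energy bound: noiseless intensity never exceeds reflectance
  expect_true(all(wli$intensity <= map$reflectance_base + 1e-12))
  expect_true(all(nbi$intensity <= map$reflectance_base + 1e-12))
})

test_that("simulate_pair is deterministic and co-registered", {
  spec <- preset_scenario("tear")
  p1 <- simulate_pair(spec)
  p2 <- simulate_pair(spec)
  expect_identical(p1, p2)
  expect_identical(dim(p1$wli$intensity), dim(p1$nbi$intensity))
  expect_identical(p1$scene_seed, spec$seed)
  # different noise seed changes the images but not the scene
  p3 <- simulate_pair(spec, seed = spec$seed + 1L)
  expect_false(identical(p1$wli$intensity, p3$wli$intensity))
})

test_that("haemoglobin-free scenes render identically under both illuminations", {
  spec <- preset_scenario("flushed_lumen")
  pair <- simulate_pair(spec, noise_sigma = 0)
  expect_equal(pair$wli$intensity, pair$nbi$intensity, tolerance = 1e-12)
})

test_that("tear lesion is relatively darker in NBI in the rendered pair", {
  pair <- simulate_pair(preset_scenario("tear"), noise_sigma = 0)
  lesion_px <- function(img) mean(img$intensity[55:65, 75:85])
  bg_px <- function(img) mean(img$intensity[10:20, 10:20])
  expect_lt(lesion_px(pair$nbi) / bg_px(pair$nbi),
            lesion_px(pair$wli) / bg_px(pair$wli))
})

test_that("spectral validation rejects malformed inputs", {
  expect_error(spectral_band(300, 20), "center_nm")
  expect_error(spectral_band(500, 0), "fwhm_nm")
  expect_error(illumination("X", list()), "non-empty")
  expect_error(simulate_pair(preset_scenario("tear"), noise_sigma = -1),
               "noise_sigma")
})
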