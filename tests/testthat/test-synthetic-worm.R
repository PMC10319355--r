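test_that("cylinder ground truth matches the closed form", {
  sp <- worm_spec(length_um = 1000, max_radius_um = 25, profile = "constant",
                  bend_amplitude_um = 0, calibration = 1, seed = 1)
  sim <- generate_worm_image(sp)
  expect_equal(sim$truth$length_um, 1000)
  expect_equal(sim$truth$mid_width_um, 50)
  expect_equal(sim$truth$volume_um3, pi * 25^2 * 1000, tolerance = 1e-8)
})

test_that("ground truth is independent of the noise seed", {
  mk <- function(seed) generate_worm_image(
    worm_spec(length_um = 300, max_radius_um = 15, calibration = 1.5,
              seed = seed))
  a <- mk(1); b <- mk(2)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$image$pixels, b$image$pixels))
})

test_that("generation is deterministic under a fixed seed", {
  mk <- function() generate_worm_image(
    worm_spec(length_um = 300, max_radius_um = 15, bend_amplitude_um = 20,
              calibration = 1.5, seed = 7))
  expect_identical(mk()$image$pixels, mk()$image$pixels)
})

test_that("curved taper truth matches an independent quadrature oracle", {
  # parabolic taper: integral of (4s(1-s))^2 ds = 8/15, a closed form
  sp <- worm_spec(length_um = 500, max_radius_um = 30,
                  bend_amplitude_um = 40, calibration = 1, seed = 1)
  sim <- generate_worm_image(sp)
  expect_equal(sim$truth$volume_um3, pi * 30^2 * 500 * 8 / 15,
               tolerance = 1e-6)
  # arbitrary smooth profile against trapezoid quadrature written here
  rf <- function(s) 10 + 5 * sin(pi * s) + 2 * sin(2 * pi * s) * (1 - abs(2 * s - 1))
  sp2 <- worm_spec(length_um = 400, profile = rf, calibration = 1, seed = 1)
  sim2 <- generate_worm_image(sp2)
  expect_equal(sim2$truth$volume_um3, quadrature_volume(rf, 400),
               tolerance = 1e-6)
})

test_that("raising the calibration leaves ground truth unchanged", {
  mk <- function(cal) generate_worm_image(
    worm_spec(length_um = 300, max_radius_um = 15, bend_amplitude_um = 15,
              calibration = cal, seed = 5))
  t1 <- mk(1.5)$truth; t2 <- mk(3)$truth
  t1$mask_area_px <- t2$mask_area_px <- NULL  # pixel counts scale, truth not
  expect_identical(t1, t2)
})

test_that("degenerate and invalid geometries are rejected", {
  expect_error(generate_worm_image(
    worm_spec(650, 25, bend_amplitude_um = 50, bend_waves = 3,
              calibration = 1)),
    "self-intersects")
  expect_error(generate_worm_image(
    worm_spec(300, 20, calibration = 2, image_shape = c(50, 700))),
    "image bounds")
  expect_error(worm_spec(300, 20, bend_amplitude_um = 400, calibration = 1) |>
                 generate_worm_image(),
    "too large for the requested length")
  # lumen wider than the tapering posterior body
  expect_error(generate_worm_image(
    worm_spec(300, 20, calibration = 1, lumen = list(width_um = 10))),
    "lumen wider")
  expect_error(worm_spec(300, -5), "max_radius_um")
})

test_that("written fixtures round-trip through TIFF plus sidecar", {
  sim <- small_worm_sim(seed = 3)
  d <- withr::local_tempdir()
  files <- write_worm_sim(sim, d, stem = "w1")
  expect_true(all(file.exists(files)))
  img <- read_calibrated_image(files[["image"]])
  expect_equal(img$calibration, sim$image$calibration)
  # 16-bit quantization: intensities equal within half a grey level
  expect_lt(max(abs(img$pixels - sim$image$pixels)), 1 / 65535)
  truth <- jsonlite::read_json(files[["truth"]])
  expect_equal(truth$length_um, sim$truth$length_um)
})
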