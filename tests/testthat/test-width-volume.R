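test_that("mid-body width of a constant-diameter worm is recovered", {
  sim <- cached_fixture("tube_w", generate_worm_image(
    worm_spec(400, 25, profile = "constant", bend_amplitude_um = 10,
              calibration = 2, seed = 41)))
  mask <- segment_worm(sim$image)
  ml <- extract_midline(mask)
  w <- width_at(ml, mask, 0.5, 2)
  expect_lt(abs(w - 50), 0.5)  # within one pixel equivalent
  # 180-degree image rotation leaves the width unchanged
  rotpx <- sim$image$pixels[nrow(sim$image$pixels):1,
                            ncol(sim$image$pixels):1]
  rot <- calibrated_image(rotpx, 2, "rot180")
  mask2 <- segment_worm(rot)
  w2 <- width_at(extract_midline(mask2), mask2, 0.5, 2)
  expect_lt(abs(w2 - w), 0.3)
  expect_error(width_at(ml, mask, 1.2, 2), "\\[0, 1\\]")
  expect_error(width_at(ml, mask, -0.1, 2), "\\[0, 1\\]")
})

test_that("width profiles have 31 boundary radii with near-zero tips", {
  sim <- cached_fixture("tube_w", generate_worm_image(
    worm_spec(400, 25, profile = "constant", bend_amplitude_um = 10,
              calibration = 2, seed = 41)))
  mask <- segment_worm(sim$image)
  ml <- extract_midline(mask)
  p <- width_profile(ml, mask, 2)
  expect_length(p$radii_um, 31)
  expect_equal(p$segment_length_um, p$length_um / 30)
  interior <- p$radii_um[2:30]
  expect_true(all(abs(interior - 25) < 1))   # constant radius recovered
  expect_true(all(p$radii_um[c(1, 31)] < 3)) # tips fall back toward zero
})

test_that("a tent-shaped radius profile is recovered linearly in k", {
  tent <- function(s) 24 * (1 - abs(2 * s - 1)) + 0.5
  sim <- cached_fixture("tube_tent", generate_worm_image(
    worm_spec(500, profile = tent, calibration = 2, seed = 42)))
  mask <- segment_worm(sim$image)
  p <- width_profile(extract_midline(mask), mask, 2)
  k <- 2:30
  expected <- tent((k - 1) / 30)
  # within 8 % away from the tips; sub-pixel absolute floor near them
  expect_true(all(abs(p$radii_um[k] - expected) <
                    pmax(0.08 * expected, 0.4)))
})

test_that("frustum sum reduces to the closed forms", {
  # cylinder identity, pure arithmetic
  v <- frustum_volume(rep(10, 31), segment_length_um = 10)
  expect_lt(abs(v - pi * 100 * 300) / (pi * 100 * 300), 1e-9)
  # cone: exact for radii linear within each segment
  v2 <- frustum_volume(seq(10, 0, length.out = 31), segment_length_um = 10)
  expect_equal(v2, pi * 100 * 300 / 3, tolerance = 1e-12)
})

test_that("frustum sum is exactly covariant under scaling", {
  set.seed(1)
  r <- runif(31, 2, 12)
  v <- frustum_volume(r, segment_length_um = 7)
  expect_identical(frustum_volume(3 * r, segment_length_um = 7), 9 * v)
  expect_identical(frustum_volume(r, segment_length_um = 21), 3 * v)
})

test_that("frustum sum tracks the quadrature oracle for smooth profiles", {
  set.seed(2)
  for (rep in 1:5) {
    a <- runif(3, -2, 2)
    rf <- function(s) 12 + a[1] * sin(pi * s) + a[2] * cos(2 * pi * s) +
      a[3] * sin(3 * pi * s)
    L <- runif(1, 200, 600)
    fr <- frustum_volume(rf((0:30) / 30), segment_length_um = L / 30)
    expect_equal(fr, quadrature_volume(rf, L), tolerance = 0.005)
  }
})

test_that("invalid profiles are rejected", {
  expect_error(frustum_volume(c(5, -1, 5), segment_length_um = 1), "negative")
  expect_error(frustum_volume(c(5, 5), segment_length_um = 0), "positive")
  expect_error(frustum_volume(5, segment_length_um = 1), "two radii")
  expect_error(frustum_volume(c(5, 5)), "segment_length_um")
})
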