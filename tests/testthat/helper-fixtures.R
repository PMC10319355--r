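# Shared fixtures, built in code and cached for the session so heavy
# renders (large calibrated worms) are paid for once.

.fixtures <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# the reference cylinder: 1000 um x 50 um diameter at 5 px/um
cylinder_sim <- function() cached_fixture("cylinder", {
  generate_worm_image(worm_spec(length_um = 1000, max_radius_um = 25,
                                profile = "constant", bend_amplitude_um = 0,
                                calibration = 5, seed = 3))
})

# a small curved tapered worm, cheap enough for per-test use
small_worm_sim <- function(seed = 1, length_um = 350, max_radius_um = 18,
                           bend_amplitude_um = 20, calibration = 2, ...) {
  generate_worm_image(worm_spec(length_um = length_um,
                                max_radius_um = max_radius_um,
                                bend_amplitude_um = bend_amplitude_um,
                                calibration = calibration, seed = seed, ...))
}

# worm with a constant-radius body and a dark posterior lumen band
lumen_worm_sim <- function(width_um, seed = 9, calibration = 4) {
  generate_worm_image(worm_spec(length_um = 500, max_radius_um = 25,
                                profile = "constant", bend_amplitude_um = 15,
                                calibration = calibration,
                                lumen = list(width_um = width_um),
                                seed = seed))
}

# hand-built midline object (polyline), for closed-form arc-length tests
polyline_midline <- function(points) {
  seg <- sqrt(diff(points[, 1])^2 + diff(points[, 2])^2)
  structure(list(points = points, cumlen_px = c(0, cumsum(seg)),
                 n_branches = 0L),
            class = "worm_midline")
}

# trapezoid quadrature of pi r(s)^2 over a length L: the independent
# solid-of-revolution oracle used against frustum sums and ground truth
quadrature_volume <- function(radius_fun, length_um, n = 1e5) {
  s <- seq(0, 1, length.out = n + 1)
  y <- pi * radius_fun(s)^2
  length_um * sum((y[-1] + y[-length(y)]) / 2) / n
}
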