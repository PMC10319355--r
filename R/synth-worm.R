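#' Specify a synthetic worm for image generation
#'
#' Describes an anesthetized, extended adult worm as a tube of circular
#' cross-section swept along a smooth planar midline: a sinusoidal bend of
#' given amplitude and period count, with a radius profile given as a
#' function of normalized arc position `s` in \[0, 1\]. Ground truth (length,
#' middle width, solid-of-revolution volume) is computed analytically from
#' this specification, never from the rendered image.
#'
#' @param length_um Tip-to-tip midline arc length in micrometres.
#' @param max_radius_um Mid-body radius in micrometres (ignored when
#'   `profile` is a function).
#' @param profile `"taper"` (parabolic taper to the tips, the default),
#'   `"constant"`, or a function of normalized arc position returning the
#'   radius in micrometres.
#' @param bend_amplitude_um Amplitude of the sinusoidal body bend (0 for a
#'   straight worm).
#' @param bend_waves Number of full sine periods along the body (0.5 gives a
#'   C shape, 1 an S shape).
#' @param calibration Pixels per micrometre of the rendered image.
#' @param margin_um Clear margin between the worm and the image border.
#' @param image_shape Optional fixed image size `c(nrow, ncol)` in pixels;
#'   by default the image is sized to hold the worm plus margins. A worm
#'   that does not fit a fixed shape is rejected.
#' @param fg,bg Foreground (worm) and background intensity on \[0, 1\].
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param lumen `NULL`, or a list with `width_um` (transverse lumen width),
#'   optional `intensity` (default midway between `fg` and `bg`) and
#'   optional `extent` (arc interval, default `c(0.6, 1)`: the posterior
#'   40 % of the body).
#' @param seed Integer seed controlling the noise realization.
#' @param id Identifier carried into the rendered image.
#' @return An object of class `worm_spec`.
#' @seealso [generate_worm_image()]
#' @export
worm_spec <- function(length_um = 1000, max_radius_um = 30,
                      profile = c("taper", "constant"),
                      bend_amplitude_um = 0, bend_waves = 1,
                      calibration = 5, margin_um = 30, image_shape = NULL,
                      fg = 0.75, bg = 0.10, noise_sd = 0.02,
                      lumen = NULL, seed = 1, id = "sim_worm") {
  if (length_um <= 0) stop("length_um must be positive")
  if (calibration <= 0) stop("calibration must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.function(profile)) {
    radius_fun <- profile
  } else {
    profile <- match.arg(profile)
    if (max_radius_um <= 0) stop("max_radius_um must be positive")
    radius_fun <- switch(profile,
      taper = local({
        rmax <- max_radius_um
        function(s) rmax * 4 * s * (1 - s)
      }),
      constant = local({
        rmax <- max_radius_um
        function(s) rep(rmax, length(s))
      }))
  }
  rmid <- radius_fun(0.5)
  rt <- radius_fun(c(0, 1))
  if (any(rt < 0) || any(rt > rmid + 1e-9))
    stop("tip radii must be >= 0 and <= the mid-body radius")
  if (!is.null(lumen)) {
    if (is.null(lumen$width_um) || lumen$width_um <= 0)
      stop("lumen$width_um must be positive")
    lumen$extent <- lumen$extent %||% c(0.6, 1)
    lumen$intensity <- lumen$intensity %||% ((fg + bg) / 2)
    if (lumen$extent[1] < 0 || lumen$extent[2] > 1 ||
        lumen$extent[1] >= lumen$extent[2])
      stop("lumen$extent must be an increasing interval within [0, 1]")
  }
  structure(list(length_um = length_um, radius_fun = radius_fun,
                 bend_amplitude_um = bend_amplitude_um,
                 bend_waves = bend_waves, calibration = calibration,
                 margin_um = margin_um, image_shape = image_shape,
                 fg = fg, bg = bg,
                 noise_sd = noise_sd, lumen = lumen,
                 seed = as.integer(seed), id = id),
            class = "worm_spec")
}

# Midline curve in micrometres: x runs along the body, y is the sinusoidal
# bend. The x extent is scaled (by root finding) so the arc length equals
# length_um exactly; returns functions of the raw parameter u in [0, 1].
worm_curve <- function(spec) {
  A <- spec$bend_amplitude_um
  w <- spec$bend_waves
  L <- spec$length_um
  arc_of_X <- function(X) {
    u <- seq(0, 1, length.out = 20001)
    dx <- X
    dy <- A * 2 * pi * w * cos(2 * pi * w * u)
    h <- u[2] - u[1]
    sp <- sqrt(dx^2 + dy^2)
    sum((sp[-1] + sp[-length(sp)]) / 2) * h
  }
  X <- if (A == 0) L else
    tryCatch(stats::uniroot(function(X) arc_of_X(X) - L, c(L * 1e-6, L),
                            tol = 1e-10)$root,
             error = function(e)
               stop("bend amplitude/waves too large for the requested length"))
  list(x = function(u) X * u,
       y = function(u) A * sin(2 * pi * w * u),
       X = X)
}

# Ground-truth quadrature at n points: cumulative arc length over u, and the
# solid-of-revolution volume L * integral of pi r(s)^2 ds (trapezoid rule).
worm_truth <- function(spec, n = 1e5) {
  s <- seq(0, 1, length.out = n + 1)
  r <- spec$radius_fun(s)
  h <- 1 / n
  vol_integrand <- pi * r^2
  volume <- spec$length_um *
    sum((vol_integrand[-1] + vol_integrand[-length(vol_integrand)]) / 2) * h
  truth <- list(length_um = spec$length_um,
                mid_width_um = 2 * spec$radius_fun(0.5),
                volume_um3 = volume)
  if (!is.null(spec$lumen)) truth$lumen_width_um <- spec$lumen$width_um
  truth
}

#' Render a synthetic worm micrograph with analytic ground truth
#'
#' Rasterizes the tube described by a [worm_spec()] into a calibrated
#' grayscale image with additive Gaussian noise, and returns the analytic
#' ground truth computed purely from the specification by quadrature
#' (lengths by curve quadrature; volume as the solid-of-revolution integral
#' of pi r(s)^2 along the midline at 1e5 samples). Self-intersecting or
#' out-of-bounds geometry is rejected with an error. Tip radii are clamped
#' to at least 0.5 px during rendering so the mask stays connected.
#'
#' @param spec A [worm_spec()].
#' @return A list of class `worm_sim` with elements `image` (a
#'   [calibrated_image()]), `truth` (list: `length_um`, `mid_width_um`,
#'   `volume_um3`, optionally `lumen_width_um`, plus `mask_area_px` of the
#'   noise-free rendered mask), and `rendered_mask` (logical matrix), the
#'   rasterized noise-free foreground used only as a segmentation oracle.
#' @export
generate_worm_image <- function(spec) {
  stopifnot(inherits(spec, "worm_spec"))
  cal <- spec$calibration
  cv <- worm_curve(spec)

  # dense arc-length parameterized samples, spacing ~1 px along the curve
  n_dense <- max(1000L, as.integer(ceiling(spec$length_um * cal)))
  u <- seq(0, 1, length.out = n_dense + 1)
  x <- cv$x(u); y <- cv$y(u)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  arc <- c(0, cumsum(seg))
  s <- arc / arc[length(arc)]
  r_um <- spec$radius_fun(s)
  if (any(r_um < 0)) stop("radius profile returned a negative radius")

  # self-intersection: coarse subsample; arc-distant points must be farther
  # apart than the sum of their radii
  idx <- unique(round(seq(1, length(s), length.out = 400)))
  D <- as.matrix(stats::dist(cbind(x[idx], y[idx])))
  arc_sep <- abs(outer(arc[idx], arc[idx], "-"))
  rsum <- outer(r_um[idx], r_um[idx], "+")
  bad <- arc_sep > 2 * rsum + 2 * max(r_um) & D < rsum
  if (any(bad))
    stop("worm geometry self-intersects (tube overlaps itself); ",
         "reduce bend amplitude or wave count")

  # place in image: pad by margin; image sized to hold the tube
  m_um <- spec$margin_um
  row_um <- y; col_um <- x
  row_lo <- min(row_um - r_um) - m_um; row_hi <- max(row_um + r_um) + m_um
  col_lo <- min(col_um - r_um) - m_um; col_hi <- max(col_um + r_um) + m_um
  if (is.null(spec$image_shape)) {
    nrow_px <- as.integer(ceiling((row_hi - row_lo) * cal)) + 1L
    ncol_px <- as.integer(ceiling((col_hi - col_lo) * cal)) + 1L
  } else {
    nrow_px <- as.integer(spec$image_shape[1])
    ncol_px <- as.integer(spec$image_shape[2])
  }
  curve_px <- cbind((row_um - row_lo) * cal + 1,
                    (col_um - col_lo) * cal + 1)
  r_px <- pmax(r_um * cal, 0.5)  # clamp tips so the mask stays connected

  if (any(curve_px[, 1] - r_px < 2) || any(curve_px[, 1] + r_px > nrow_px - 1) ||
      any(curve_px[, 2] - r_px < 2) || any(curve_px[, 2] + r_px > ncol_px - 1))
    stop("rendered worm does not fit inside the image bounds")

  has_lumen <- !is.null(spec$lumen)
  if (has_lumen) {
    ext <- spec$lumen$extent
    in_ext <- s >= ext[1] & s <= ext[2]
    if (any(spec$lumen$width_um / 2 >= r_um[in_ext]))
      stop("lumen wider than the local body at some arc position")
  }

  # adaptive stamp subsampling: spacing ~ sqrt(1.6 d) px keeps the
  # nearest-sample distance error below ~0.2 px at a feature rendered at
  # distance d from the curve -- the tube boundary, or the lumen band edge
  # where a lumen is drawn (the smallest feature wins)
  r_feat <- r_px
  if (has_lumen) {
    hw_px <- spec$lumen$width_um / 2 * cal
    in_ext <- s >= spec$lumen$extent[1] & s <= spec$lumen$extent[2]
    r_feat[in_ext] <- pmin(r_feat[in_ext], hw_px)
  }
  keep_idx <- integer(0)
  i <- 1L
  n_pts <- length(s)
  while (i <= n_pts) {
    keep_idx <- c(keep_idx, i)
    stp <- max(1, min(15, floor(sqrt(1.6 * r_feat[i]))))
    i <- i + stp
  }
  if (keep_idx[length(keep_idx)] != n_pts) keep_idx <- c(keep_idx, n_pts)
  pad <- c(diff(keep_idx), 1) + 1.5  # dense samples are ~1 px apart
  clip_frac <- min(0.45, 3 * max(r_px) / arc[length(arc)])

  rend <- render_tube_cpp(curve_px[keep_idx, , drop = FALSE],
                          r_px[keep_idx], s[keep_idx], pad,
                          nrow_px, ncol_px, spec$fg, spec$bg,
                          clip_frac, clip_frac, has_lumen,
                          rep(if (has_lumen) spec$lumen$width_um / 2 * cal
                              else 0, length(keep_idx)),
                          if (has_lumen) spec$lumen$intensity else 0,
                          if (has_lumen) spec$lumen$extent[1] else 0,
                          if (has_lumen) spec$lumen$extent[2] else 0)
  truth <- worm_truth(spec)
  truth$mask_area_px <- sum(rend$mask)

  pixels <- rend$pixels
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(rnorm(length(pixels), 0, spec$noise_sd),
                              nrow = nrow(pixels)))
    pixels <- pmin(pmax(pixels + noise, 0), 1)
  }
  structure(list(image = calibrated_image(pixels, cal, id = spec$id),
                 truth = truth,
                 rendered_mask = rend$mask),
            class = "worm_sim")
}

#' Write a worm simulation to disk (image, calibration sidecar, truth JSON)
#'
#' @param sim A `worm_sim` from [generate_worm_image()].
#' @param dir Output directory (created if needed).
#' @param stem File stem; defaults to the image id.
#' @return Named character vector of the files written, invisibly.
#' @export
write_worm_sim <- function(sim, dir, stem = NULL) {
  stopifnot(inherits(sim, "worm_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- stem %||% sim$image$id
  img_path <- file.path(dir, paste0(stem, ".tiff"))
  write_calibrated_image(sim$image, img_path)
  truth_path <- file.path(dir, paste0(stem, "_truth.json"))
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path,
              sidecar = paste0(tools::file_path_sans_ext(img_path), ".json"),
              truth = truth_path))
}
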