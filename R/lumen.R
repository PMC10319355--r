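#' Average luminal width from point measurements
#'
#' Arithmetic mean of two (or more) luminal width measurements, mirroring
#' the manual workflow of measuring the intestinal width at two points in
#' the posterior gut and averaging them.
#'
#' @param widths Numeric vector of at least two non-negative widths (um).
#' @return Mean width in micrometres.
#' @export
average_lumen_width <- function(widths) {
  if (!is.numeric(widths) || length(widths) < 2)
    stop("at least two width values are required")
  if (any(!is.finite(widths)) || any(widths < 0))
    stop("widths must be finite and non-negative")
  mean(widths)
}

#' Measure intestinal luminal width on perpendicular transects
#'
#' At each requested normalized arc position in the posterior half of the
#' body, a transect is cast perpendicular to the midline; the luminal width
#' is the extent of the contiguous dark (sub-threshold) intensity run
#' crossing the midline, with sub-pixel edge interpolation, converted to
#' micrometres. The intensity threshold is the midpoint between the local
#' body intensity (90th percentile of the transect inside the mask) and the
#' darkest central intensity.
#'
#' @param image A [calibrated_image()] whose worm carries a darker luminal
#'   band along the posterior midline.
#' @param midline A [extract_midline()] result for this image.
#' @param mask Optional `worm_mask`; segmented from `image` when omitted.
#' @param config Optional list: `positions` (default `c(0.70, 0.85)`, each
#'   must lie in (0.5, 1)), `min_contrast` (minimum relative drop below the
#'   body intensity to accept a dark band, default 0.2), `orientation`
#'   (`"auto"`, the default, picks the midline direction that places the
#'   darker band at the requested positions; `"as-is"` or `"flip"` force
#'   it), `step` (transect sampling step, px, default 0.25).
#' @return An object of class `lumen_measurement`: list with
#'   `point_widths_um`, `mean_width_um`, `positions`.
#' @export
measure_lumen <- function(image, midline, mask = NULL, config = list()) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(midline, "worm_midline"))
  positions <- config$positions %||% c(0.70, 0.85)
  if (length(positions) < 1 || any(positions <= 0.5) || any(positions >= 1))
    stop("positions must lie in (0.5, 1): the posterior body")
  if (is.null(mask)) mask <- segment_worm(image, config)
  m <- if (inherits(mask, "worm_mask")) mask$mask else mask
  mnum <- m * 1
  cal <- image$calibration
  step <- config$step %||% 0.25
  min_contrast <- config$min_contrast %||% 0.2

  orientation <- config$orientation %||% "auto"
  flip_midline <- function(ml) {
    total <- ml$cumlen_px[length(ml$cumlen_px)]
    structure(list(points = ml$points[nrow(ml$points):1, , drop = FALSE],
                   cumlen_px = total - rev(ml$cumlen_px),
                   n_branches = ml$n_branches),
              class = "worm_midline")
  }
  center_intensity <- function(ml, s) {
    p <- midline_point_tangent(ml, s)$point
    bilinear(image$pixels, p[1], p[2])
  }
  if (orientation == "flip") {
    midline <- flip_midline(midline)
  } else if (orientation == "auto") {
    fwd <- mean(vapply(positions, function(p) center_intensity(midline, p),
                       numeric(1)))
    rev_ml <- flip_midline(midline)
    bwd <- mean(vapply(positions, function(p) center_intensity(rev_ml, p),
                       numeric(1)))
    if (bwd < fwd) midline <- rev_ml
  }

  measure_one <- function(spos) {
    pt <- midline_point_tangent(midline, spos)
    # march to the mask boundary on both sides to bound the transect
    half <- function(sign) {
      d <- 0
      repeat {
        d <- d + step
        p <- pt$point + sign * d * pt$normal
        if (bilinear(mnum, p[1], p[2]) < 0.5) return(d)
        if (d > sum(dim(m)))
          stop(sprintf("transect at s = %.2f failed to exit the mask", spos))
      }
    }
    hplus <- half(1); hminus <- half(-1)
    tgrid <- seq(-hminus + step, hplus - step, by = step)
    if (length(tgrid) < 5)
      stop(sprintf("transect at s = %.2f is degenerate", spos))
    inten <- vapply(tgrid, function(t) {
      p <- pt$point + t * pt$normal
      bilinear(image$pixels, p[1], p[2])
    }, numeric(1))
    inten <- running_mean(inten, 3)  # damp pixel noise on the profile
    body_est <- as.numeric(stats::quantile(inten, 0.9, type = 7))
    lumen_est <- min(inten)
    if (body_est - lumen_est < min_contrast * body_est)
      stop(sprintf("no dark band detected at s = %.2f", spos))
    th <- (body_est + lumen_est) / 2
    i0 <- which.min(abs(tgrid))  # sample at the midline crossing
    if (inten[i0] >= th)
      stop(sprintf("no dark band crossing the midline at s = %.2f", spos))
    lo <- i0
    while (lo > 1 && inten[lo - 1] < th) lo <- lo - 1
    hi <- i0
    while (hi < length(inten) && inten[hi + 1] < th) hi <- hi + 1
    t_lo <- if (lo > 1) {
      f <- (inten[lo - 1] - th) / (inten[lo - 1] - inten[lo])
      tgrid[lo - 1] + f * step
    } else tgrid[lo]
    t_hi <- if (hi < length(inten)) {
      f <- (inten[hi + 1] - th) / (inten[hi + 1] - inten[hi])
      tgrid[hi + 1] - f * step
    } else tgrid[hi]
    (t_hi - t_lo) / cal
  }

  widths <- vapply(positions, measure_one, numeric(1))
  structure(list(point_widths_um = widths,
                 mean_width_um = mean(widths),
                 positions = positions),
            class = "lumen_measurement")
}

#' @export
print.lumen_measurement <- function(x, ...) {
  cat(sprintf("lumen: %s um at s = %s; mean %.2f um\n",
              paste(sprintf("%.2f", x$point_widths_um), collapse = ", "),
              paste(sprintf("%.2f", x$positions), collapse = ", "),
              x$mean_width_um))
  invisible(x)
}
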