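#' Measure body length, middle width and volume from one micrograph
#'
#' Full morphometry chain for a single worm image: segmentation
#' ([segment_worm()]), midline extraction ([extract_midline()]), tip-to-tip
#' arc length, middle width at the arc midpoint (`s = 0.5`), the 30-segment
#' width profile, and the frustum-of-cone volume sum ([frustum_volume()]).
#' Stage errors are propagated with the failing stage named in the message.
#'
#' @param image A [calibrated_image()].
#' @param config Optional list passed to the stages; additionally
#'   `n_segments` (default 30).
#' @return An object of class `worm_measurements`: list with `id`,
#'   `length_um`, `mid_width_um`, `volume_um3` and `qc` (list: `threshold`,
#'   `mask_area_px`, `n_branches`).
#' @export
measure_worm <- function(image, config = list()) {
  stopifnot(inherits(image, "calibrated_image"))
  cal <- image$calibration
  mask <- tryCatch(segment_worm(image, config),
                   error = function(e) stop_stage("segment_worm", e))
  midline <- tryCatch(extract_midline(mask, config),
                      error = function(e) stop_stage("extract_midline", e))
  len <- tryCatch(arc_length(midline, cal),
                  error = function(e) stop_stage("arc_length", e))
  midw <- tryCatch(width_at(midline, mask, 0.5, cal),
                   error = function(e) stop_stage("width_at", e))
  prof <- tryCatch(width_profile(midline, mask, cal,
                                 n_segments = config$n_segments %||% 30),
                   error = function(e) stop_stage("width_profile", e))
  vol <- tryCatch(frustum_volume(prof),
                  error = function(e) stop_stage("frustum_volume", e))
  structure(list(id = image$id, length_um = len, mid_width_um = midw,
                 volume_um3 = vol,
                 qc = list(threshold = mask$threshold,
                           mask_area_px = mask$area_px,
                           n_branches = midline$n_branches)),
            class = "worm_measurements")
}

#' @export
print.worm_measurements <- function(x, ...) {
  cat(sprintf("worm '%s': length %.1f um, mid-width %.2f um, volume %.0f um^3\n",
              x$id, x$length_um, x$mid_width_um, x$volume_um3))
  cat(sprintf("  qc: threshold %.3f, mask area %d px, %d side branches\n",
              x$qc$threshold, x$qc$mask_area_px, x$qc$n_branches))
  invisible(x)
}

#' @export
as.data.frame.worm_measurements <- function(x, ...) {
  data.frame(id = x$id, length_um = x$length_um,
             mid_width_um = x$mid_width_um, volume_um3 = x$volume_um3,
             qc_threshold = x$qc$threshold,
             qc_mask_area_px = x$qc$mask_area_px,
             qc_n_branches = x$qc$n_branches,
             stringsAsFactors = FALSE)
}
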