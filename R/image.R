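#' Calibrated grayscale image
#'
#' Bundles a 2-D grayscale pixel matrix (intensities on \[0, 1\]) with the
#' spatial calibration of the acquisition, in pixels per micrometre. All
#' morphometric outputs are reported in micrometres using this factor.
#'
#' @param pixels Numeric matrix of intensities, at least 32 x 32.
#' @param calibration Pixels per micrometre; must be positive.
#' @param id Source identifier (e.g. file stem) carried into output tables.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, calibration, id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 32 || ncol(pixels) < 32)
    stop("image must be at least 32 x 32 pixels")
  if (!is.numeric(calibration) || length(calibration) != 1 || calibration <= 0)
    stop("calibration (pixels/um) must be a single positive number")
  structure(list(pixels = pixels, calibration = calibration,
                 id = as.character(id)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("calibrated_image '%s': %d x %d px, %.3g px/um\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$calibration))
  invisible(x)
}

#' Write a calibrated image as 16-bit TIFF plus calibration sidecar
#'
#' The calibration factor is stored in a JSON sidecar next to the image
#' (same stem, `.json` extension) under the key `pixels_per_um`.
#'
#' @param image A [calibrated_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_calibrated_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- pmin(pmax(image$pixels, 0), 1)
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(list(pixels_per_um = image$calibration, id = image$id),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated image (TIFF or PNG) with its calibration
#'
#' Calibration is taken from `pixels_per_um` if given, otherwise from the
#' JSON sidecar written by [write_calibrated_image()].
#'
#' @param path Image path (`.tif`, `.tiff` or `.png`).
#' @param pixels_per_um Optional explicit calibration override.
#' @return A [calibrated_image()].
#' @export
read_calibrated_image <- function(path, pixels_per_um = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package")
      png::readPNG(path)
    },
    stop(sprintf("unsupported image format '%s'", ext)))
  if (length(dim(px)) == 3) px <- px[, , 1]  # first channel of multi-channel
  if (is.null(pixels_per_um)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
    if (!file.exists(sidecar))
      stop(sprintf("no calibration: neither pixels_per_um nor sidecar %s",
                   basename(sidecar)))
    meta <- jsonlite::read_json(sidecar)
    pixels_per_um <- meta$pixels_per_um
    if (is.null(pixels_per_um)) stop("sidecar JSON lacks key 'pixels_per_um'")
  }
  calibrated_image(px, as.numeric(pixels_per_um),
                   id = tools::file_path_sans_ext(basename(path)))
}
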