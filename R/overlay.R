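#' Write an inspection overlay (outline and midline) as PNG
#'
#' Renders the micrograph with the segmented outline and the extracted
#' midline drawn over it, for quick visual QC of a measurement.
#'
#' @param image A [calibrated_image()].
#' @param mask A `worm_mask` or logical matrix from [segment_worm()].
#' @param midline A [extract_midline()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, mask, midline, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing overlays requires the 'png' package")
  m <- if (inherits(mask, "worm_mask")) mask$mask else mask
  px <- pmin(pmax(image$pixels, 0), 1)
  rgb <- array(px, dim = c(dim(px), 3))
  # outline: mask pixels with at least one background 4-neighbor
  pad <- function(mm, dr, dc) {
    out <- matrix(FALSE, nrow(mm), ncol(mm))
    rs <- seq_len(nrow(mm)) + dr
    cs <- seq_len(ncol(mm)) + dc
    ok_r <- rs >= 1 & rs <= nrow(mm)
    ok_c <- cs >= 1 & cs <= ncol(mm)
    out[ok_r, ok_c] <- mm[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- m & pad(m, 1, 0) & pad(m, -1, 0) & pad(m, 0, 1) & pad(m, 0, -1)
  outline <- m & !interior
  rgb[, , 1][outline] <- 1; rgb[, , 2][outline] <- 0.2
  rgb[, , 3][outline] <- 0.2
  mid <- cbind(pmin(pmax(round(midline$points[, 1]), 1), nrow(px)),
               pmin(pmax(round(midline$points[, 2]), 1), ncol(px)))
  for (ch in 1:3) {
    lay <- rgb[, , ch]
    lay[mid] <- c(0.2, 1, 0.2)[ch]
    rgb[, , ch] <- lay
  }
  png::writePNG(rgb, path)
  invisible(path)
}
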