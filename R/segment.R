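#' Segment a single worm from a calibrated micrograph
#'
#' Global threshold (Otsu by default) followed by morphological cleanup:
#' holes are filled, objects smaller than `min_area_px` are discarded, and
#' the largest remaining connected component is retained as the worm.
#'
#' @param image A [calibrated_image()].
#' @param config Optional list: `threshold` (fixed value overriding Otsu),
#'   `polarity` (`"bright"`, the default, for a bright worm on dark
#'   background, or `"dark"` for the reverse), `min_area_px` (default 100).
#' @return An object of class `worm_mask`: list with `mask` (logical
#'   matrix), `threshold`, `area_px`.
#' @details Errors: `"no worm found"` when nothing survives cleanup;
#'   `"worm clipped"` when the retained component touches the image border.
#'   Coiled or overlapping worms are rejected downstream, during midline
#'   extraction, where the skeleton branch count is available.
#' @export
segment_worm <- function(image, config = list()) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  polarity <- config$polarity %||% "bright"
  if (polarity == "dark") px <- max(px) - px
  px <- pmin(pmax(px, 0), 1)
  if (diff(range(px)) < 1e-6) stop("no worm found")  # featureless image
  th <- config$threshold %||% EBImage::otsu(EBImage::Image(px),
                                            range = c(0, 1), levels = 256L)
  bw <- px > th
  if (!any(bw)) stop("no worm found")
  bw <- EBImage::fillHull(EBImage::Image(bw))
  lab <- EBImage::bwlabel(bw)
  labm <- EBImage::imageData(lab)
  sizes <- tabulate(labm[labm > 0])
  min_area <- config$min_area_px %||% 100
  keep <- which(sizes >= min_area)
  if (length(keep) == 0) stop("no worm found")
  largest <- keep[which.max(sizes[keep])]
  mask <- labm == largest
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)]))
    stop("worm clipped: foreground touches the image border")
  structure(list(mask = mask, threshold = as.numeric(th),
                 area_px = sum(mask)),
            class = "worm_mask")
}
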