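#' Total body volume by the frustum-of-cone sum
#'
#' Models each of the 30 (by default) body segments between consecutive
#' radius samples as a frustum of a cone and sums their volumes:
#' \deqn{V = \sum_{i=1}^{n} \frac{\pi h}{3}\,(r_{i-1}^2 + r_{i-1} r_i + r_i^2)}
#' where \eqn{h} is the common segment height along the midline. The sum is
#' exact for any radius profile that is linear within each segment, and
#' reduces to the cylinder formula \eqn{\pi r^2 L} for a constant profile.
#'
#' @param profile A [width_profile()], or a numeric vector of radii (in
#'   which case `segment_length_um` must be supplied).
#' @param segment_length_um Segment height in micrometres (only when
#'   `profile` is a bare numeric vector of radii).
#' @return Volume in cubic micrometres.
#' @export
frustum_volume <- function(profile, segment_length_um = NULL) {
  if (inherits(profile, "width_profile")) {
    r <- profile$radii_um
    h <- profile$segment_length_um
  } else {
    r <- profile
    h <- segment_length_um
    if (is.null(h)) stop("segment_length_um required for a bare radius vector")
  }
  if (length(r) < 2) stop("at least two radii required")
  if (any(!is.finite(r))) stop("radii must be finite")
  if (any(r < 0)) stop("negative radius in width profile")
  if (h <= 0) stop("segment length must be positive")
  r0 <- r[-length(r)]
  r1 <- r[-1]
  sum(pi * h / 3 * (r0^2 + r0 * r1 + r1^2))
}
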