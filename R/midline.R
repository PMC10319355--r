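#' Extract the tip-to-tip midline of a segmented worm
#'
#' The binary mask is thinned to its topological skeleton (Zhang-Suen).
#' Side branches are pruned by keeping the longest geodesic path between
#' skeleton endpoints on the 8-connected pixel graph (diagonal steps weigh
#' sqrt(2)); ties are broken by the lexicographically smallest endpoint
#' pair. The path is smoothed by a running mean, and each end is extended
#' along the local tangent to the sub-pixel mask boundary so the midline
#' spans tip to tip. Points are ordered so index 1 is the endpoint with the
#' smaller (row, col) lexicographic coordinate; anatomical head/tail
#' identity is not assigned.
#'
#' @param mask A `worm_mask` from [segment_worm()], or a logical matrix.
#' @param config Optional list: `max_branches` (skeleton side branches
#'   tolerated before the worm is rejected as coiled/overlapping, default
#'   10), `min_length_px` (default 10), `smooth_window` (running-mean
#'   window, default 9).
#' @return An object of class `worm_midline`: list with `points` (n x 2
#'   matrix of sub-pixel (row, col)), `cumlen_px` (strictly increasing
#'   cumulative arc length in pixels), `n_branches` (pruned side-branch
#'   count).
#' @export
extract_midline <- function(mask, config = list()) {
  m <- if (inherits(mask, "worm_mask")) mask$mask else mask
  stopifnot(is.matrix(m))
  storage.mode(m) <- "logical"
  skel <- thin_cpp(m)
  pix <- which(skel, arr.ind = TRUE)
  if (nrow(pix) < 2) stop("skeleton too small")

  # 8-connected pixel graph with Euclidean edge weights
  nr <- nrow(skel)
  lin <- (pix[, 2] - 1L) * nr + pix[, 1L]
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    nb_lin <- lin + offs[k, 1] + offs[k, 2] * nr
    hit <- match(nb_lin, lin)
    ok <- !is.na(hit)
    from <- c(from, which(ok)); to <- c(to, hit[ok])
    w <- c(w, rep(sqrt(sum(offs[k, ]^2)), sum(ok)))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < nrow(pix))
    g <- igraph::add_vertices(g, nrow(pix) - igraph::vcount(g))
  igraph::E(g)$weight <- w

  deg <- igraph::degree(g)
  ends <- which(deg == 1)
  if (length(ends) == 0)
    stop("skeleton has no endpoints (ring topology)")
  max_branches <- config$max_branches %||% 10
  n_branches <- max(0L, length(ends) - 2L)
  if (n_branches > max_branches)
    stop("coiled or overlapping worm: skeleton has too many side branches")

  # longest geodesic between endpoints; ties to the lexicographically
  # smallest endpoint pair (endpoints scanned in (row, col) order)
  ord <- ends[order(pix[ends, 1], pix[ends, 2])]
  D <- igraph::distances(g, v = ord, to = ord, weights = igraph::E(g)$weight)
  best <- c(NA_integer_, NA_integer_); best_d <- -Inf
  for (i in seq_along(ord)) for (j in seq_along(ord)) {
    if (j <= i) next
    if (is.finite(D[i, j]) && D[i, j] > best_d) {
      best_d <- D[i, j]; best <- c(ord[i], ord[j])
    }
  }
  if (!is.finite(best_d)) stop("skeleton endpoints are disconnected")
  min_length_px <- config$min_length_px %||% 10
  if (best_d < min_length_px)
    stop(sprintf("midline too short (%.1f px < %d px)", best_d, min_length_px))
  vp <- igraph::shortest_paths(g, from = best[1], to = best[2],
                               weights = igraph::E(g)$weight)$vpath[[1]]
  path <- pix[as.integer(vp), , drop = FALSE]

  # smooth staircase artifacts, keeping endpoints anchored
  wdw <- config$smooth_window %||% 9
  pr <- running_mean(path[, 1], wdw)
  pc <- running_mean(path[, 2], wdw)
  pts <- cbind(pr, pc)

  # Skeletons misbehave within about one local body half-width of each
  # end: blunt-ended masks sprout oblique corner branches, and the medial
  # axis stops short of the end face, while pointed tips are reached
  # almost exactly.  Trim each end by 1.7x the *local* half-width maximum
  # (distance transform along the terminal stretch of the path), then
  # replace the trimmed span by a straight extension along the local
  # tangent: where the trim is long the body is correspondingly wide, so
  # the extension cannot drift out through a thin taper.
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(m)))
  max_halfwidth <- max(dm)
  path_hw <- dm[cbind(pmin(pmax(round(pts[, 1]), 1), nrow(m)),
                      pmin(pmax(round(pts[, 2]), 1), ncol(m)))]
  seg0 <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cum0 <- c(0, cumsum(seg0))
  total0 <- cum0[length(cum0)]
  wnd <- 2 * max_halfwidth
  q0 <- min(1.7 * max(path_hw[cum0 <= wnd]), 0.25 * total0)
  q1 <- min(1.7 * max(path_hw[cum0 >= total0 - wnd]), 0.25 * total0)
  keep_tr <- cum0 >= q0 & cum0 <= total0 - q1
  if (sum(keep_tr) >= 4) pts <- pts[keep_tr, , drop = FALSE]

  # Extend both ends along the local tangent to the sub-pixel mask
  # boundary (bilinear 0.5 level).  The tangent is the chord over roughly
  # a third of the trimmed span, so it averages out residual staircase
  # wiggle without feeling the far-side curvature.
  mnum <- m * 1
  seg1 <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cum1 <- c(0, cumsum(seg1))
  total1 <- cum1[length(cum1)]
  max_ext <- 3 * max(q0, q1) + 20
  extend <- function(end_pt, inner_pt) {
    dirv <- end_pt - inner_pt
    nv <- sqrt(sum(dirv^2))
    if (nv < 1e-9) return(NULL)
    dirv <- dirv / nv
    step <- 0.25; d <- 0; prev_v <- bilinear(mnum, end_pt[1], end_pt[2])
    if (prev_v < 0.5) return(NULL)
    repeat {
      d <- d + step
      p <- end_pt + d * dirv
      v <- bilinear(mnum, p[1], p[2])
      if (v < 0.5) {
        frac <- if (prev_v > v) (prev_v - 0.5) / (prev_v - v) else 0
        return(end_pt + (d - step + frac * step) * dirv)
      }
      prev_v <- v
      if (d > max_ext) return(NULL)  # degenerate; give up extending
    }
  }
  anchor <- function(arc_pos) pts[which.min(abs(cum1 - arc_pos)), ]
  tip1 <- extend(pts[nrow(pts), ],
                 anchor(total1 - max(5, min(q1 / 3, total1 / 4))))
  tip0 <- extend(pts[1, ], anchor(max(5, min(q0 / 3, total1 / 4))))
  if (!is.null(tip0)) pts <- rbind(tip0, pts)
  if (!is.null(tip1)) pts <- rbind(pts, tip1)

  # deterministic orientation: start at the lexicographically smaller tip
  a <- pts[1, ]; b <- pts[nrow(pts), ]
  if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2]))
    pts <- pts[nrow(pts):1, , drop = FALSE]

  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  keep <- c(TRUE, seg > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  dimnames(pts) <- NULL
  structure(list(points = pts, cumlen_px = c(0, cumsum(seg)),
                 n_branches = n_branches),
            class = "worm_midline")
}

#' Midline arc length in micrometres
#'
#' Sum of Euclidean inter-point distances of the midline polyline divided
#' by the calibration factor.
#'
#' @param midline A [extract_midline()] result.
#' @param calibration Pixels per micrometre.
#' @return Length in micrometres.
#' @export
arc_length <- function(midline, calibration) {
  stopifnot(inherits(midline, "worm_midline"))
  if (nrow(midline$points) < 2) stop("midline has fewer than 2 points")
  if (calibration <= 0) stop("calibration must be positive")
  midline$cumlen_px[length(midline$cumlen_px)] / calibration
}

# Interpolated midline point and unit tangent at normalized arc position s.
# Tangent by central differences over a 5-point window around s.
midline_point_tangent <- function(midline, s) {
  cl <- midline$cumlen_px
  pts <- midline$points
  target <- s * cl[length(cl)]
  i <- findInterval(target, cl, all.inside = TRUE)
  f <- (target - cl[i]) / (cl[i + 1] - cl[i])
  p <- pts[i, ] * (1 - f) + pts[i + 1, ] * f
  lo <- max(1, i - 2); hi <- min(nrow(pts), i + 2)
  tv <- pts[hi, ] - pts[lo, ]
  nv <- sqrt(sum(tv^2))
  if (nv < 1e-9) stop("degenerate tangent at requested position")
  list(point = p, tangent = tv / nv, normal = c(-tv[2], tv[1]) / nv)
}

#' Body width at a normalized arc position
#'
#' Casts a transect perpendicular to the local midline tangent at arc
#' position `s` and measures the distance between the two sub-pixel mask
#' boundary crossings (linear interpolation of the interpolated mask edge),
#' converted to micrometres.
#'
#' @param midline A [extract_midline()] result.
#' @param mask A `worm_mask` or logical matrix.
#' @param s Normalized arc position in \[0, 1\].
#' @param calibration Pixels per micrometre.
#' @param step Transect sampling step in pixels (default 0.25).
#' @return Width in micrometres.
#' @export
width_at <- function(midline, mask, s, calibration, step = 0.25) {
  if (!is.numeric(s) || length(s) != 1 || s < 0 || s > 1)
    stop("s must be a single value in [0, 1]")
  m <- if (inherits(mask, "worm_mask")) mask$mask else mask
  mnum <- m * 1
  pt <- midline_point_tangent(midline, s)
  half_extent <- function(sign) {
    d <- 0; prev_v <- bilinear(mnum, pt$point[1], pt$point[2])
    if (prev_v < 0.5)
      stop(sprintf("transect center at s = %.3f lies outside the mask", s))
    limit <- sum(dim(m))
    repeat {
      d <- d + step
      p <- pt$point + sign * d * pt$normal
      v <- bilinear(mnum, p[1], p[2])
      if (v < 0.5) {
        frac <- if (prev_v > v) (prev_v - 0.5) / (prev_v - v) else 0
        return(d - step + frac * step)
      }
      prev_v <- v
      if (d > limit)
        stop(sprintf("transect at s = %.3f failed to exit the mask", s))
    }
  }
  (half_extent(1) + half_extent(-1)) / calibration
}

#' Radius profile over 30 equal-arc-length segments
#'
#' Samples the body width at the 31 boundaries of `n_segments` equal
#' segments of the midline (`s = k / n_segments`) and returns half-widths
#' (radii). Where the transect degenerates at a tip (first or last
#' boundary), the radius falls back to 0; transect failures at interior
#' boundaries propagate as errors.
#'
#' @param midline A [extract_midline()] result.
#' @param mask A `worm_mask` or logical matrix.
#' @param calibration Pixels per micrometre.
#' @param n_segments Number of segments (default 30).
#' @return An object of class `width_profile`: list with `radii_um`
#'   (`n_segments + 1` values), `segment_length_um`, `length_um`.
#' @export
width_profile <- function(midline, mask, calibration, n_segments = 30) {
  stopifnot(n_segments >= 1)
  L <- arc_length(midline, calibration)
  radii <- vapply(0:n_segments, function(k) {
    s <- k / n_segments
    if (k == 0 || k == n_segments) {
      tryCatch(width_at(midline, mask, s, calibration) / 2,
               error = function(e) 0)
    } else {
      width_at(midline, mask, s, calibration) / 2
    }
  }, numeric(1))
  structure(list(radii_um = radii, segment_length_um = L / n_segments,
                 length_um = L),
            class = "width_profile")
}
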