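#' Maximum Feret diameter of a point set
#'
#' Computes the maximum caliper diameter (longest distance between any pair of
#' contour points) together with the orientation of the achieving segment.
#' The maximum pairwise distance is always attained between convex-hull
#' vertices, so the search is restricted to the hull.
#'
#' @param points numeric matrix with two columns (x, y), image pixel
#'   coordinates (x rightward, y downward). At least two distinct points.
#' @return list with `length` (pixels) and `angle` (degrees in [0, 180),
#'   measured counterclockwise from the horizontal axis with the y axis
#'   flipped, so 0 = left-right and 90 = anterior-posterior). Among tied
#'   pairs the smallest angle is reported.
#' @seealso [min_feret()], [fold_angle()]
#' @export
max_feret <- function(points) {
  points <- as_points(points)
  pts <- unique(points)
  if (nrow(pts) < 2L) stop("degenerate contour: fewer than 2 distinct points")
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) < 2L) hp <- pts  # all collinear duplicates handled above
  d <- as.matrix(stats::dist(hp))
  dmax <- max(d)
  tol <- dmax * 1e-12
  idx <- which(d >= dmax - tol, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  angles <- vapply(seq_len(nrow(idx)), function(i) {
    p <- hp[idx[i, 1], ]
    q <- hp[idx[i, 2], ]
    segment_angle(p, q)
  }, numeric(1))
  list(length = dmax, angle = min(angles))
}

#' Minimum Feret diameter (minimum caliper width)
#'
#' The minimum over convex-hull edge orientations of the hull's projection
#' width perpendicular to that edge (rotating-calipers width). This is the
#' standard particle-analysis MinFeret; the literal minimum pairwise contour
#' distance would always be about one pixel pitch and carries no shape
#' information.
#'
#' @inheritParams max_feret
#' @return width in pixels; 0 (with a warning) for collinear input.
#' @export
min_feret <- function(points) {
  points <- as_points(points)
  pts <- unique(points)
  if (nrow(pts) < 2L) stop("degenerate contour: fewer than 2 distinct points")
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) {
    warning("collinear contour: minimum Feret width is 0")
    return(0)
  }
  widths <- vapply(seq_len(n), function(i) {
    p <- hp[i, ]
    q <- hp[if (i == n) 1L else i + 1L, ]
    e <- q - p
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    proj <- (hp[, 1] - p[1]) * nrm[1] + (hp[, 2] - p[2]) * nrm[2]
    max(proj) - min(proj)
  }, numeric(1))
  m <- min(widths)
  if (!is.finite(m)) {
    warning("collinear contour: minimum Feret width is 0")
    return(0)
  }
  m
}

#' Fold an orientation into the 0-90 degree quadrant
#'
#' Spot orientations on the left and right sides of the body mirror each
#' other; folding the Feret angle about 90 degrees makes the inclinations of
#' both sides comparable (a spot tilted 135 degrees is as "forward oriented"
#' as one tilted 45).
#'
#' @param theta angle in degrees; values outside [0, 180) are normalized
#'   modulo 180 first.
#' @return angle in degrees in [0, 90].
#' @export
fold_angle <- function(theta) {
  theta <- theta %% 180
  ifelse(theta > 90, 180 - theta, theta)
}

# angle of segment p->q mapped to [0, 180), math convention on y-down pixels
segment_angle <- function(p, q) {
  a <- atan2(-(q[2] - p[2]), q[1] - p[1]) * 180 / pi
  a <- a %% 180
  if (a >= 180 - 1e-9) a <- 0
  a
}

as_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be an n x 2 matrix of (x, y)")
  storage.mode(points) <- "double"
  points
}
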