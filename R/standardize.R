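#' Remove color information
#'
#' Collapses an RGB image to 8-bit grayscale with the unweighted channel mean
#' (the default 8-bit conversion of common image programs), rounding half-up.
#' Already-grayscale input is returned unchanged.
#'
#' @param image matrix (grayscale) or height x width x channels array on the
#'   0-255 scale; 1 or 3 channels.
#' @param weights optional channel weights (e.g. luma c(0.299, 0.587, 0.114));
#'   default equal weights.
#' @return numeric matrix, integer values in [0, 255].
#' @export
desaturate <- function(image, weights = NULL) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) != 3L) stop("image must be a matrix or 3-d array")
  nc <- d[3]
  if (nc == 1L) return(image[, , 1])
  if (nc != 3L)
    stop("unsupported channel count: ", nc,
         " (expected 1 or 3; alpha handling is undefined)")
  if (is.null(weights)) weights <- rep(1 / 3, 3)
  if (length(weights) != 3L) stop("weights must have length 3")
  weights <- weights / sum(weights)
  g <- image[, , 1] * weights[1] + image[, , 2] * weights[2] +
    image[, , 3] * weights[3]
  floor(g + 0.5)
}

#' Contrast-stretch to the central band of the histogram
#'
#' Reduces levels to the central part of the image histogram: intensities at
#' or below the `low_q` quantile map to 0, at or above the `high_q` quantile
#' map to 255, linear in between. The mapping is monotone non-decreasing, so
#' intensity ordering is preserved. With the defaults this clips 25% of
#' pixels into each tail, i.e. keeps the central 50% of the histogram.
#'
#' Quantiles are computed over the full image by default: on a clipped
#' specimen photograph the light background anchors the upper quantile and
#' the dark abdomen the lower one, which is what separates the spots from the
#' body. Pass `roi_mask` to restrict the histogram instead.
#'
#' @param gray numeric matrix, 0-255.
#' @param low_q,high_q quantile fractions, 0 <= low_q < high_q <= 1.
#' @param roi_mask optional logical matrix; quantiles use only these pixels.
#' @return numeric matrix, integer values in [0, 255].
#' @export
stretch_levels <- function(gray, low_q = 0.25, high_q = 0.75, roi_mask = NULL) {
  stopifnot(is.matrix(gray), low_q >= 0, high_q <= 1, low_q < high_q)
  v <- if (is.null(roi_mask)) gray else gray[roi_mask]
  qs <- stats::quantile(v, c(low_q, high_q), names = FALSE, type = 7)
  if (qs[1] == qs[2]) {
    warning("constant histogram band: levels left unchanged")
    return(gray)
  }
  out <- (gray - qs[1]) / (qs[2] - qs[1]) * 255
  round(pmin(pmax(out, 0), 255))
}

#' Standardize abdomen geometry
#'
#' Brings the abdomen into the canonical frame: rotation makes the
#' left-to-right insertion segment horizontal with the posterior below it,
#' isotropic scaling makes the abdomen polygon's horizontal extent equal
#' `ref_width`, and translation puts the polygon bounding box's upper-left
#' corner at the frame origin. Pixels outside the transformed polygon are set
#' to 0. Grayscale values are resampled bilinearly; the ROI mask uses
#' nearest-neighbor rasterization of the polygon. The canonical frame is
#' `ref_width` x 1.5 * `ref_width` pixels; content falling outside it is
#' clipped (with a warning).
#'
#' All downstream features are relativized (areas by Ta, lengths by sqrt(Ta)),
#' so any fixed `ref_width` yields equivalent features.
#'
#' @param gray numeric matrix, 0-255.
#' @param roi an [abdomen_roi()] annotation for this image.
#' @param ref_width canonical abdomen width in pixels.
#' @return a `std_image` list: `pixels`, `roi_mask`, `transform` (list with
#'   `rotation` degrees, `scale`, `translation`), `ref_width`.
#' @export
standardize_geometry <- function(gray, roi, ref_width = 1000) {
  stopifnot(is.matrix(gray), inherits(roi, "abdomen_roi"), ref_width > 0)
  v <- roi$right_insertion - roi$left_insertion
  ext0 <- diff(range(roi$polygon[, 1]))
  if (sqrt(sum(v^2)) < 0.01 * ext0)
    stop("degenerate ROI: insertion points coincide")
  theta <- atan2(v[2], v[1])          # image coords, y down
  phi <- -theta                        # rotation to apply
  rot <- function(p, a) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    t(R %*% t(p))
  }
  mid <- (roi$left_insertion + roi$right_insertion) / 2
  post <- rot(matrix(roi$posterior - mid, 1), phi)
  if (post[2] < 0) {
    message("posterior above insertion line after rotation: flipping 180 degrees")
    phi <- phi + pi
  }
  poly_r <- rot(sweep(roi$polygon, 2, mid), phi)
  extent <- max(poly_r[, 1]) - min(poly_r[, 1])
  if (extent < 1e-9) stop("degenerate ROI: polygon has no horizontal extent")
  s <- (ref_width - 1) / extent
  poly_s <- poly_r * s
  t0 <- c(1, 1) - c(min(poly_s[, 1]), min(poly_s[, 2]))
  poly_c <- sweep(poly_s, 2, t0, "+")

  W <- as.integer(round(ref_width))
  H <- as.integer(round(1.5 * ref_width))
  if (max(poly_c[, 2]) > H + 0.5)
    warning("abdomen taller than canonical frame: content clipped")

  # inverse map canonical pixel centers back into the source image
  xo <- rep(seq_len(W), each = H)
  yo <- rep(seq_len(H), times = W)
  q <- cbind(xo - t0[1], yo - t0[2]) / s
  p <- rot(q, -phi)
  px <- p[, 1] + mid[1]
  py <- p[, 2] + mid[2]
  vals <- bilinear_sample(gray, px, py)
  pixels <- matrix(vals, nrow = H, ncol = W)

  roi_mask <- matrix(in_polygon(xo, yo, poly_c), nrow = H, ncol = W)
  pixels[!roi_mask] <- 0

  structure(list(
    pixels = pixels,
    roi_mask = roi_mask,
    transform = list(rotation = phi * 180 / pi, scale = s,
                     translation = t0 + s * as.numeric(rot(matrix(-mid, 1), phi))),
    ref_width = ref_width,
    canonical_roi = {
      li <- as.numeric(rot(matrix(roi$left_insertion - mid, 1), phi)) * s + t0
      ri <- as.numeric(rot(matrix(roi$right_insertion - mid, 1), phi)) * s + t0
      po <- as.numeric(rot(matrix(roi$posterior - mid, 1), phi)) * s + t0
      if (li[1] > ri[1]) { tmp <- li; li <- ri; ri <- tmp }   # after a 180 flip
      abdomen_roi(polygon = poly_c, left_insertion = li,
                  right_insertion = ri, posterior = po)
    }
  ), class = "std_image")
}

#' Automatic abdomen ROI (lower fidelity)
#'
#' Fallback for images without a manual annotation: takes the convex hull of
#' the largest dark connected region as the abdomen outline, its leftmost and
#' rightmost hull points as the insertion landmarks and its bottommost point
#' as the posterior. This cannot separate legs or head from the abdomen the
#' way the manual clipping does; use it only for roughly pre-cropped images.
#'
#' @param gray numeric matrix, 0-255.
#' @return an [abdomen_roi()].
#' @export
auto_roi <- function(gray) {
  dark <- gray < mean(gray)
  lab <- label_components(dark, connectivity = 8L)
  if (max(lab) == 0L) stop("no dark region found")
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  abdomen_roi(
    polygon = hull,
    left_insertion = pts[which.min(pts[, 1]), ],
    right_insertion = pts[which.max(pts[, 1]), ],
    posterior = pts[which.max(pts[, 2]), ]
  )
}

# bilinear interpolation of gray at (px, py); 0 outside the image
bilinear_sample <- function(gray, px, py) {
  nr <- nrow(gray); nc <- ncol(gray)
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  ok <- x0 >= 1 & x0 <= nc & y0 >= 1 & y0 <= nr
  x1 <- pmin(x0 + 1, nc); y1 <- pmin(y0 + 1, nr)
  v <- numeric(length(px))
  i <- which(ok)
  g <- function(yy, xx) gray[cbind(yy, xx)]
  v[i] <- (1 - fx[i]) * (1 - fy[i]) * g(y0[i], x0[i]) +
    fx[i] * (1 - fy[i]) * g(y0[i], x1[i]) +
    (1 - fx[i]) * fy[i] * g(y1[i], x0[i]) +
    fx[i] * fy[i] * g(y1[i], x1[i])
  v
}

# even-odd crossing test, vectorized over points
in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
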