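#' Segmentation parameters
#'
#' @param threshold_method "minimum_auto" (Minimum histogram method) or
#'   "fixed".
#' @param fixed_threshold threshold in [0, 255] when `threshold_method` is
#'   "fixed".
#' @param outlier_radius radius (pixels) of the circular despeckle
#'   neighborhood.
#' @param outlier_threshold intensity deviation (0-255 scale) above which a
#'   pixel is replaced by its neighborhood median.
#' @param min_spot_area smallest particle kept, in squared pixels.
#' @param connectivity 4 or 8 (pixel adjacency for particle labeling).
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_method = c("minimum_auto", "fixed"),
                                fixed_threshold = NULL,
                                outlier_radius = 6,
                                outlier_threshold = 50,
                                min_spot_area = 25,
                                connectivity = 8L) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(outlier_radius >= 1, outlier_threshold >= 0,
            outlier_threshold <= 255, min_spot_area >= 1,
            connectivity %in% c(4L, 8L))
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 255))
    stop("fixed_threshold in [0, 255] required for threshold_method = 'fixed'")
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 outlier_radius = outlier_radius,
                 outlier_threshold = outlier_threshold,
                 min_spot_area = min_spot_area,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Minimum-method automatic threshold
#'
#' The 256-bin intensity histogram is repeatedly smoothed with a 3-bin mean
#' filter until exactly two local maxima remain; the threshold is the bin of
#' the minimum between them. When the minimum is a flat plateau (empty bins
#' between well-separated modes) the plateau midpoint is used, which keeps
#' the estimator symmetric under contrast inversion.
#'
#' @param gray numeric matrix, 0-255.
#' @param roi_mask optional logical matrix restricting the histogram.
#' @param max_iter smoothing passes before giving up on bimodality.
#' @return integer threshold in [0, 255].
#' @export
minimum_auto_threshold <- function(gray, roi_mask = NULL, max_iter = 10000L) {
  v <- if (is.null(roi_mask)) gray else gray[roi_mask]
  v <- as.integer(pmin(pmax(round(v), 0), 255))
  if (length(unique(v)) < 2L) stop("unimodal histogram")
  h <- tabulate(v + 1L, nbins = 256L)
  h <- as.numeric(h)
  for (iter in seq_len(max_iter)) {
    h <- (c(0, h[-256]) + h + c(h[-1], 0)) / 3
    # plateau-tolerant local maxima: strictly above the left neighbor,
    # at least the right one
    peaks <- which(h > c(-Inf, h[-256]) & h >= c(h[-1], -Inf) & h > 0)
    if (length(peaks) == 2L) {
      between <- seq(peaks[1], peaks[2])
      hb <- h[between]
      # a long flat valley (e.g. empty bins between two well-separated
      # modes) has no unique argmin; resolve to the plateau midpoint
      flat <- between[hb <= min(hb) + 1e-12]
      return(as.integer(flat[ceiling(length(flat) / 2)] - 1L))
    }
  }
  stop("unimodal histogram")
}

#' Binarize the spots
#'
#' Thresholds the image inside the ROI and keeps the class covering the
#' smaller fraction of the ROI as the spot class (the spots are the minority,
#' light-colored elements; this makes the step invariant to inverted
#' contrast). An exact 50/50 split resolves to the brighter class.
#'
#' @param gray numeric matrix, 0-255.
#' @param threshold scalar in [0, 255]; pixels strictly above it form the
#'   bright class.
#' @param roi_mask logical matrix marking the abdomen interior.
#' @return a `spot_mask` (list with logical `grid` and `roi_mask`); attribute
#'   `polarity` records which class was kept.
#' @export
binarize_spots <- function(gray, threshold, roi_mask) {
  stopifnot(threshold >= 0, threshold <= 255, is.matrix(gray))
  bright <- gray > threshold & roi_mask
  dark <- !bright & roi_mask
  nb <- sum(bright); nd <- sum(dark)
  if (nb == 0L || nd == 0L) stop("degenerate threshold: one class is empty")
  polarity <- if (nb <= nd) "bright" else "dark"
  grid <- if (polarity == "bright") bright else dark
  m <- spot_mask(grid, roi_mask)
  attr(m, "polarity") <- polarity
  m
}

#' @rdname binarize_spots
#' @param grid logical matrix of spot pixels.
#' @export
spot_mask <- function(grid, roi_mask) {
  stopifnot(is.logical(grid), is.logical(roi_mask),
            all(dim(grid) == dim(roi_mask)))
  grid <- grid & roi_mask
  structure(list(grid = grid, roi_mask = roi_mask), class = "spot_mask")
}

#' Remove outlier points from a binary mask
#'
#' Two-pass median despeckle on the 0/255 rendering of the mask, following
#' the remove-outliers semantics of standard particle-analysis software: a
#' pixel deviating from the median of its circular radius-`radius`
#' neighborhood by more than `threshold` is replaced by that median. Pass 1
#' removes bright outliers (isolated spot pixels), pass 2 dark outliers
#' (pinholes).
#'
#' @param mask a `spot_mask`.
#' @param radius neighborhood radius in pixels.
#' @param threshold intensity deviation on the 0-255 scale.
#' @return a cleaned `spot_mask`.
#' @export
clean_mask <- function(mask, radius = 6, threshold = 50) {
  stopifnot(inherits(mask, "spot_mask"), radius >= 1)
  g <- mask$grid
  if (!any(g)) return(mask)
  k <- disk_kernel(radius)
  nk <- sum(k)
  med255 <- function(grid) {
    cnt <- round(EBImage::filter2(EBImage::Image(t(grid * 1)), k,
                                  boundary = "replicate"))
    t(cnt * 2 > nk) * 255
  }
  # pass 1: bright outliers
  m <- med255(g)
  repl <- g & (255 - m > threshold)
  g[repl] <- FALSE
  # pass 2: dark outliers
  m <- med255(g)
  repl <- !g & (m - 0 > threshold)
  g[repl] <- TRUE
  spot_mask(g, mask$roi_mask)
}

#' Fill enclosed gaps in the spot mask
#'
#' Any background region not connected to the ROI border becomes spot
#' (4-connected background flood from the frame border and the region outside
#' the ROI; untouched background regions are holes). Gaps open to the border
#' are left alone.
#'
#' @param mask a `spot_mask`.
#' @return a filled `spot_mask`.
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "spot_mask"))
  g <- mask$grid
  comp <- !g
  seeds <- comp & (!mask$roi_mask | border_mask(dim(g)))
  if (!any(comp)) return(mask)
  work <- EBImage::Image(t(ifelse(comp, 1, 0)))
  remaining <- which(seeds & comp)
  while (length(remaining) > 0L) {
    i <- remaining[1]
    yy <- (i - 1L) %% nrow(g) + 1L
    xx <- (i - 1L) %/% nrow(g) + 1L
    work <- EBImage::floodFill(work, c(xx, yy), col = 2)
    reached <- t(EBImage::imageData(work)) == 2
    remaining <- which(seeds & comp & !reached)
  }
  reached <- t(EBImage::imageData(work)) == 2
  holes <- comp & !reached
  spot_mask(g | holes, mask$roi_mask)
}

#' Label connected spots and measure particles
#'
#' Connected-component labeling under the configured connectivity; particles
#' smaller than `min_spot_area` are discarded; contours are ordered boundary
#' traversals; centroids are pixel-coordinate means. Ta is the ROI pixel
#' count (the total abdomen area used to relativize every measurement).
#'
#' @param mask a cleaned and filled `spot_mask`.
#' @param params [segmentation_params()].
#' @return a `labeled_spots` list: integer `labels` grid, `components`
#'   data.frame (label, pixel_count, centroid_x, centroid_y), `contours`
#'   list of (x, y) matrices, `Ta`.
#' @export
label_spots <- function(mask, params = segmentation_params()) {
  stopifnot(inherits(mask, "spot_mask"))
  lab <- label_components(mask$grid, params$connectivity)
  n <- max(lab)
  if (n == 0L) stop("no spots detected")
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(sizes >= params$min_spot_area)
  if (length(keep) == 0L) stop("no spots detected")
  relab <- integer(n)
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  cx <- tapply(idx[, 2], l, mean)
  cy <- tapply(idx[, 1], l, mean)
  contours <- extract_contours(lab)
  structure(list(
    labels = lab,
    components = data.frame(label = seq_along(keep),
                            pixel_count = sizes[keep],
                            centroid_x = as.numeric(cx),
                            centroid_y = as.numeric(cy)),
    contours = contours,
    Ta = sum(mask$roi_mask)
  ), class = "labeled_spots")
}

#' Connected-component labeling
#'
#' Labels the true pixels of a logical matrix under 4- or 8-connectivity.
#' Components are numbered in raster-scan order of their first pixel.
#'
#' @param grid logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 = background.
#' @export
label_components <- function(grid, connectivity = 8L) {
  stopifnot(is.logical(grid), connectivity %in% c(4L, 8L))
  nr <- nrow(grid); nc <- ncol(grid)
  idx <- which(grid)
  if (length(idx) == 0L) return(matrix(0L, nr, nc))
  rank <- integer(nr * nc)
  rank[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))                 # down, right
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  edges <- integer(0)
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- rank[j] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(rank[idx[ok]][hit], rank[j][hit]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  # renumber components by first pixel in column-major scan order
  first <- tapply(seq_along(idx), memb, min)
  ord <- order(idx[first])
  newlab <- integer(length(first))
  newlab[as.integer(names(first))[ord]] <- seq_along(ord)
  out <- matrix(0L, nr, nc)
  out[idx] <- newlab[memb]
  out
}

# ordered boundary contours (1-based x, y) per label, via EBImage::ocontour
extract_contours <- function(lab) {
  img <- EBImage::Image(t(lab))
  oc <- EBImage::ocontour(img)
  lapply(oc, function(m) {
    m <- m + 1
    colnames(m) <- c("x", "y")
    m
  })
}

disk_kernel <- function(radius) {
  r <- ceiling(radius)
  side <- 2L * r + 1L
  k <- matrix(0, side, side)
  dx <- row(k) - r - 1L
  dy <- col(k) - r - 1L
  k[dx^2 + dy^2 <= radius^2] <- 1
  k
}

border_mask <- function(d) {
  m <- matrix(FALSE, d[1], d[2])
  m[1, ] <- TRUE; m[d[1], ] <- TRUE; m[, 1] <- TRUE; m[, d[2]] <- TRUE
  m
}
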