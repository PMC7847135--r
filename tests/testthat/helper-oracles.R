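# Independent oracles and fixture builders used across the suite.

# exhaustive all-pairs maximum distance (independent of the hull route)
brute_max_feret <- function(pts) {
  d <- as.matrix(stats::dist(pts))
  max(d)
}

# minimum caliper width by rotation scan: evaluate the projection width on a
# 0.01-degree grid, then refine around the best grid angle with optimize().
scan_min_feret <- function(pts, step_deg = 0.01) {
  th <- seq(0, pi, by = step_deg * pi / 180)
  px <- outer(pts[, 1], cos(th + pi / 2)) + outer(pts[, 2], sin(th + pi / 2))
  width_at <- function(a) {
    pr <- pts[, 1] * cos(a + pi / 2) + pts[, 2] * sin(a + pi / 2)
    max(pr) - min(pr)
  }
  w <- do.call(pmax, asplit(px, 1)) - do.call(pmin, asplit(px, 1))
  i <- which.min(w)
  lo <- th[max(1, i - 1)]; hi <- th[min(length(th), i + 1)]
  stats::optimize(width_at, c(lo, hi), tol = 1e-12)$objective
}

# direct rank-formula Kruskal-Wallis H (tie-corrected), independent of
# stats::kruskal.test
rank_formula_H <- function(groups) {
  x <- unlist(groups)
  n <- vapply(groups, length, integer(1))
  N <- length(x)
  r <- rank(x)
  Ri <- tapply(r, rep(seq_along(groups), n), sum)
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / n) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# all permutations of seq_len(n) (n <= 7)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# rasterize an ellipse (semi-axes a, b; angle in degrees, math convention
# with y down) into a logical matrix; returns the pixel set and frame
raster_ellipse <- function(a, b, angle_deg = 0, pad = 8) {
  side <- 2 * ceiling(a) + 2 * pad + 1
  cx <- cy <- (side + 1) / 2
  x <- rep(seq_len(side), each = side) - cx
  y <- rep(seq_len(side), times = side) - cy
  t0 <- -angle_deg * pi / 180
  u <- x * cos(t0) + y * sin(t0)
  v <- -x * sin(t0) + y * cos(t0)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  matrix(inside, side, side)  # [y, x]
}

# full-frame roi mask for a raw synthetic specimen
raw_roi_mask <- function(sp) {
  d <- dim(sp$image)
  matrix(spotmorph:::in_polygon(rep(seq_len(d[2]), each = d[1]),
                                rep(seq_len(d[1]), times = d[2]),
                                sp$roi$polygon), d[1], d[2])
}

# segment a raw-frame synthetic specimen (optionally without the despeckle
# pass, for noise-free renderings where there is nothing to despeckle)
segment_raw <- function(sp, clean = TRUE) {
  g <- stretch_levels(sp$image)
  roim <- raw_roi_mask(sp)
  thr <- minimum_auto_threshold(g, roim)
  m <- binarize_spots(g, thr, roim)
  if (clean) m <- clean_mask(m)
  label_spots(fill_holes(m))
}

# full standardized pipeline for one specimen, returning spot records
measure_specimen <- function(sp, ref_width = 400, central_band = 0.15) {
  g <- stretch_levels(sp$image)
  std <- standardize_geometry(g, sp$roi, ref_width = ref_width)
  thr <- minimum_auto_threshold(std$pixels, std$roi_mask)
  m <- fill_holes(clean_mask(binarize_spots(std$pixels, thr, std$roi_mask)))
  list(records = measure_spots(label_spots(m), std, central_band),
       std = std, Ta = sum(std$roi_mask))
}

# match segmented components to truth spots by nearest centroid
match_truth <- function(spots, truth) {
  vapply(seq_len(nrow(spots$components)), function(i) {
    which.min((truth$centroid_x - spots$components$centroid_x[i])^2 +
                (truth$centroid_y - spots$components$centroid_y[i])^2)
  }, integer(1))
}

# simulated feature tables for classifier tests: 3 informative variables
# separating 3 groups plus pure-noise columns
sim_features <- function(n_per_group = 30, n_noise = 5, sep = 2, seed = 1) {
  set.seed(seed)
  g <- rep(c("A", "B", "C"), each = n_per_group)
  mu <- list(A = c(0, 0, 0), B = c(sep, 0, sep), C = c(0, sep, -sep))
  inf <- do.call(rbind, lapply(g, function(gi) stats::rnorm(3, mu[[gi]], 1)))
  noise <- matrix(stats::rnorm(length(g) * n_noise), ncol = n_noise)
  out <- data.frame(inf, noise)
  names(out) <- c(paste0("inf", 1:3), paste0("noise", seq_len(n_noise)))
  out$group <- g
  out
}
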