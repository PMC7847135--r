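# minimal labeled_spots stub from a centroid table (numbering needs no
# contours)
stub_spots <- function(cx, cy) {
  structure(list(
    labels = matrix(0L, 1, 1),
    components = data.frame(label = seq_along(cx), pixel_count = 100L,
                            centroid_x = cx, centroid_y = cy),
    contours = NULL, Ta = 1000
  ), class = "labeled_spots")
}
frame1000 <- list(roi_mask = matrix(TRUE, 1500, 1000))

test_that("numbering follows the central-1/2, left-odd, right-even rule", {
  s <- stub_spots(c(500, 500, 100, 900, 110, 890),
                  c(200, 400, 150, 160, 300, 310))
  num <- classify_and_number(s, frame1000)
  expect_equal(num$number[match(1:6, num$label)], 1:6)
  expect_equal(num$cls[num$number %in% 1:2], rep("central", 2))
  expect_equal(num$side[num$number %in% c(3, 5)], rep("left", 2))
  expect_equal(num$side[num$number %in% c(4, 6)], rep("right", 2))
})

test_that("mirrored configurations swap parities, numbering otherwise identical", {
  cx <- c(500, 500, 100, 900, 110, 890)
  cy <- c(200, 400, 150, 160, 300, 310)
  n1 <- classify_and_number(stub_spots(cx, cy), frame1000)
  n2 <- classify_and_number(stub_spots(1001 - cx, cy), frame1000)
  m <- merge(n1, n2, by = "label")
  lat <- m$cls.x == "lateral"
  expect_equal(m$number.y[lat] - m$number.x[lat],
               ifelse(m$side.x[lat] == "left", 1, -1))
  expect_equal(m$number.y[!lat], m$number.x[!lat])
})

test_that("equal-y lateral ties resolve by increasing x", {
  s <- stub_spots(c(500, 500, 100, 140), c(200, 400, 300, 300))
  num <- classify_and_number(s, frame1000)
  expect_equal(num$number[num$label == 3], 3L)
  expect_equal(num$number[num$label == 4], 5L)
})

test_that("central-spot anomalies raise QC conditions", {
  s3 <- stub_spots(c(490, 500, 510), c(100, 300, 500))
  expect_error(classify_and_number(s3, frame1000), "ambiguous central spots")
  s0 <- stub_spots(c(100, 900), c(100, 100))
  expect_warning(classify_and_number(s0, frame1000), "no central spots")
})

test_that("spot metrics relativize by Ta as defined", {
  sq <- rbind(c(0, 0), c(30, 0), c(30, 1), c(0, 1))
  m <- spot_metrics(area_px = 50, contour = sq, Ta = 1000)
  expect_equal(m$Ra, 5)
  m2 <- suppressWarnings(
    spot_metrics(area_px = 100, contour = rbind(c(0, 0), c(30, 0)), Ta = 900))
  expect_equal(m2$MaxFd, 1)     # 30 / sqrt(900)
  expect_equal(m2$Fa, 0)
})

test_that("a rasterized circle is nearly round (Ar >= 0.95)", {
  disk <- raster_ellipse(20, 20)
  roi <- matrix(TRUE, nrow(disk), ncol(disk))
  spots <- label_spots(spot_mask(disk, roi))
  m <- spot_metrics(spots$components$pixel_count[1], spots$contours[[1]],
                    Ta = sum(roi))
  expect_gte(m$Ar, 0.95)
})

test_that("metrics are stable under re-rasterized rotation of an ellipse", {
  # apex-localization limits the Feret-angle precision of a digitized
  # ellipse to about sqrt(2) * b / a^(3/2) radians (sub-pixel localization
  # of the contact points on an apex of curvature radius b^2/a)
  a <- 150; b <- 60
  base <- NULL
  fa_tol <- sqrt(2) * b / a^1.5 * 180 / pi
  for (ang in c(0, 17, 45, 73, 120)) {
    px <- raster_ellipse(a, b, ang)
    roi <- matrix(TRUE, nrow(px), ncol(px))
    spots <- label_spots(spot_mask(px, roi))
    m <- spot_metrics(spots$components$pixel_count[1], spots$contours[[1]],
                      Ta = sum(roi))
    if (is.null(base)) { base <- m; next }
    expect_lt(abs(m$MaxFd - base$MaxFd) / base$MaxFd, 0.01)
    expect_lt(abs(m$MinFd - base$MinFd) / base$MinFd, 0.01)
    expect_lt(abs(m$Ar - base$Ar) / base$Ar, 0.01)
    dd <- (m$Fa - base$Fa - ang) %% 180
    expect_lt(min(dd, 180 - dd), 2 * fa_tol)
  }
})

test_that("feature aggregation reproduces the worked arithmetic", {
  rec <- data.frame(
    number = 1:6, cls = c("central", "central", rep("lateral", 4)),
    side = c("center", "center", "left", "right", "left", "right"),
    area_px = 1, Ra = c(2, 3, 1, 1, 1, 1),
    centroid_x = c(50, 50, 10, 90, 12, 88), centroid_y = c(20, 40, 15, 16, 30, 31),
    MaxFd = 1, MinFd = 0.5, Fa = 45, Fa_folded = 45, Ar = 0.5)
  specs <- list(
    list(specimen_id = "a", group = "G1", records = rec, Ta = 1000),
    list(specimen_id = "b", group = "G2", records = rec, Ta = 1000))
  tab <- build_feature_table(specs)
  expect_equal(tab$total_Ra, c(9, 9))
  expect_equal(tab$mean_Ra_central, c(2.5, 2.5))
  expect_equal(tab$mean_Ra_lateral, c(1, 1))
  expect_equal(tab$central_lateral_ratio, c(2.5, 2.5))
  expect_equal(tab$n_central, c(2L, 2L))
  # identical configurations: zero Procrustes scatter, equal distances
  expect_equal(tab$sum_central_lateral_dist[1], tab$sum_central_lateral_dist[2])
  expect_error(build_feature_table(list()), "no specimens")
  expect_error(build_feature_table(specs[c(1, 1)]), "duplicated specimen_id")
})

test_that("total_Ra equals the exact sum of per-spot Ra", {
  arch <- default_archetypes()$H1
  sp <- generate_specimen(arch, seed = 3)
  res <- measure_specimen(sp)
  tab <- build_feature_table(list(list(specimen_id = "x", group = "H1",
                                       records = res$records, Ta = res$Ta),
                                  list(specimen_id = "y", group = "H1",
                                       records = res$records, Ta = res$Ta)))
  expect_equal(tab$total_Ra[1], sum(res$records$Ra))
})

test_that("gpa removes similarity transforms to numerical precision", {
  set.seed(1)
  cfg <- matrix(stats::rnorm(28), 14, 2)
  th <- 57 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cfg2 <- sweep(3 * cfg %*% t(R), 2, c(5, -2), "+")
  g <- gpa(list(cfg, cfg2))
  expect_lt(sqrt(mean((g$aligned[[1]] - g$aligned[[2]])^2)), 1e-8)
})

test_that("gpa consensus equals a duplicated configuration", {
  set.seed(2)
  cfg <- matrix(stats::rnorm(20), 10, 2)
  g <- gpa(list(cfg, cfg, cfg))
  norm <- sweep(cfg, 2, colMeans(cfg))
  norm <- norm / sqrt(sum(norm^2))
  # consensus matches up to rotation; align and compare
  r <- spotmorph:::rotate_onto(g$mean_shape, norm)
  expect_lt(sqrt(mean((r - norm)^2)), 1e-10)
})

test_that("gpa recovers the true shape from noisy copies", {
  set.seed(4)
  truth <- matrix(stats::rnorm(28), 14, 2)
  truth <- sweep(truth, 2, colMeans(truth))
  truth <- truth / sqrt(sum(truth^2))
  noisy <- lapply(1:50, function(i) truth + matrix(stats::rnorm(28, 0, 0.01), 14, 2))
  g <- gpa(noisy)
  cons <- spotmorph:::rotate_onto(g$mean_shape, truth)
  expect_lt(sqrt(mean((cons - truth)^2)), 0.005)
})

test_that("gpa agrees with an established two-configuration Procrustes fit", {
  skip_if_not_installed("vegan")
  set.seed(6)
  x <- matrix(stats::rnorm(24), 12, 2)
  y <- x %*% matrix(c(cos(0.4), sin(0.4), -sin(0.4), cos(0.4)), 2, 2) * 2 +
    matrix(stats::rnorm(24, 0, 0.05), 12, 2)
  g <- gpa(list(x, y))
  v <- vegan::procrustes(g$aligned[[1]], g$aligned[[2]], scale = TRUE)
  # our alignment should leave essentially no removable rotation
  expect_lt(abs(acos(min(1, v$rotation[1, 1]))), 0.02)
})

test_that("gpa rejects mismatched landmark counts", {
  expect_error(gpa(list(matrix(0, 5, 2), matrix(0, 4, 2))), "mismatched")
})

test_that("central-lateral distances sum over all pairs", {
  pts <- rbind(c(0, 0), c(3, 4), c(0, 5))
  cls <- c("central", "lateral", "lateral")
  expect_equal(sum_central_lateral_distances(pts, cls), 10)
  same <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_equal(sum_central_lateral_distances(same, cls), 0)
  expect_message(
    na <- sum_central_lateral_distances(pts, rep("lateral", 3)), "no central")
  expect_true(is.na(na))
  # left-right symmetric configuration: mirrored pairs contribute equally
  sym <- rbind(c(0, 0), c(-2, 3), c(2, 3))
  d1 <- sqrt(sum((sym[1, ] - sym[2, ])^2))
  d2 <- sqrt(sum((sym[1, ] - sym[3, ])^2))
  expect_equal(d1, d2)
  expect_equal(sum_central_lateral_distances(sym, cls), d1 + d2)
})
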