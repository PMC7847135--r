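#' Classify and number spots
#'
#' Applies the numbering convention: the two central spots are 1 and 2
#' (anterior first); spots on the edge of the abdomen are numbered
#' consecutively with odd numbers on the left and even numbers on the right,
#' each side anterior to posterior. A spot is central when its centroid lies
#' within `central_band` of the body width around the vertical midline of
#' the ROI bounding box. Ties in y are broken by increasing x.
#'
#' @param spots a `labeled_spots` object (see [label_spots()]).
#' @param frame the `std_image` the spots were segmented from (supplies the
#'   midline and body width), or a list with `roi_mask`.
#' @param central_band half-width of the central band as a fraction of body
#'   width.
#' @return data.frame: label, number, cls ("central"/"lateral"), side
#'   ("left"/"right"/"center"), centroid_x, centroid_y; ordered by number.
#' @export
classify_and_number <- function(spots, frame, central_band = 0.15) {
  stopifnot(inherits(spots, "labeled_spots"))
  cols <- which(apply(frame$roi_mask, 2, any))
  midline <- (min(cols) + max(cols)) / 2
  body_width <- max(cols) - min(cols) + 1
  comp <- spots$components
  dx <- comp$centroid_x - midline
  central <- abs(dx) < central_band * body_width
  if (sum(central) > 2L) stop("ambiguous central spots: ", sum(central),
                              " candidates in the central band")
  if (sum(central) == 0L)
    warning("no central spots found; central means will be missing")
  out <- data.frame(label = comp$label, number = NA_integer_,
                    cls = ifelse(central, "central", "lateral"),
                    side = "center",
                    centroid_x = comp$centroid_x, centroid_y = comp$centroid_y,
                    stringsAsFactors = FALSE)
  ord_c <- which(central)[order(comp$centroid_y[central], comp$centroid_x[central])]
  out$number[ord_c] <- seq_along(ord_c)
  left <- !central & dx < 0
  right <- !central & dx >= 0
  ord_l <- which(left)[order(comp$centroid_y[left], comp$centroid_x[left])]
  ord_r <- which(right)[order(comp$centroid_y[right], comp$centroid_x[right])]
  out$number[ord_l] <- 3L + 2L * (seq_along(ord_l) - 1L)
  out$number[ord_r] <- 4L + 2L * (seq_along(ord_r) - 1L)
  out$side[left] <- "left"
  out$side[right] <- "right"
  out[order(out$number), ]
}

#' Per-spot shape metrics
#'
#' Relativized measurements of one spot: relative area Ra as a percentage of
#' the total abdomen area Ta, Feret diameters relative to sqrt(Ta), the
#' Feret angle and its folded version, and the aspect ratio.
#'
#' @param area_px spot area in pixels.
#' @param contour ordered (x, y) boundary points of the spot.
#' @param Ta total abdomen area in pixels.
#' @return list: Ra (percent), MaxFd, MinFd (relative lengths), Fa (degrees,
#'   [0, 180)), Fa_folded (degrees, [0, 90]), Ar (MinFd/MaxFd).
#' @export
spot_metrics <- function(area_px, contour, Ta) {
  stopifnot(Ta > 0)
  mf <- max_feret(contour)
  mn <- min_feret(contour)
  list(Ra = 100 * area_px / Ta,
       MaxFd = mf$length / sqrt(Ta),
       MinFd = mn / sqrt(Ta),
       Fa = mf$angle,
       Fa_folded = fold_angle(mf$angle),
       Ar = if (mf$length > 0) mn / mf$length else NA_real_)
}

#' Measure all spots of one specimen
#'
#' Numbers the spots and computes the full per-spot record.
#'
#' @inheritParams classify_and_number
#' @return data.frame of spot records ordered by number: number, cls, side,
#'   area_px, Ra, centroid_x, centroid_y, MaxFd, MinFd, Fa, Fa_folded, Ar.
#' @export
measure_spots <- function(spots, frame, central_band = 0.15) {
  num <- classify_and_number(spots, frame, central_band)
  comp <- spots$components
  recs <- lapply(seq_len(nrow(num)), function(i) {
    lab <- num$label[i]
    m <- spot_metrics(comp$pixel_count[comp$label == lab],
                      spots$contours[[as.character(lab)]], spots$Ta)
    data.frame(number = num$number[i], cls = num$cls[i], side = num$side[i],
               area_px = comp$pixel_count[comp$label == lab],
               Ra = m$Ra, centroid_x = num$centroid_x[i],
               centroid_y = num$centroid_y[i],
               MaxFd = m$MaxFd, MinFd = m$MinFd, Fa = m$Fa,
               Fa_folded = m$Fa_folded, Ar = m$Ar,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Generalized Procrustes analysis of centroid configurations
#'
#' Removes translation (centroids to the origin), size (unit centroid size)
#' and rotation (iterative orthogonal alignment to the evolving mean, no
#' reflection) from a set of landmark configurations. Iterates until the
#' mean shape changes by less than `tol` RMS.
#'
#' @param configs list of k x 2 point matrices with identical point counts
#'   and consistent point numbering.
#' @param tol convergence tolerance on the consensus (RMS).
#' @param max_iter iteration cap.
#' @return list: `aligned` (list of k x 2 matrices, unit centroid size),
#'   `mean_shape`, `iterations`.
#' @export
gpa <- function(configs, tol = 1e-8, max_iter = 200L) {
  if (length(configs) < 2L) stop("need at least 2 configurations")
  ks <- vapply(configs, nrow, integer(1))
  if (length(unique(ks)) != 1L) {
    bad <- which(ks != as.integer(names(sort(table(ks), decreasing = TRUE))[1]))
    stop("mismatched point counts in configurations: ",
         paste(if (is.null(names(configs))) bad else names(configs)[bad],
               collapse = ", "))
  }
  norm1 <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    cs <- sqrt(sum(x^2))
    if (cs == 0) stop("degenerate configuration: zero centroid size")
    x / cs
  }
  aligned <- lapply(configs, norm1)
  mean_shape <- aligned[[1]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(aligned, rotate_onto, target = mean_shape)
    new_mean <- norm1(Reduce(`+`, aligned) / length(aligned))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  aligned <- lapply(aligned, rotate_onto, target = mean_shape)
  list(aligned = aligned, mean_shape = mean_shape, iterations = it)
}

# optimal rotation (no reflection) of centered config x onto target
rotate_onto <- function(x, target) {
  m <- crossprod(x, target)
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  r <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  x %*% r
}

#' Sum of central-to-lateral centroid distances
#'
#' Sum over all (central, lateral) spot pairs of the Euclidean distance
#' between their centroids, in the frame of `points` (for Procrustes-aligned
#' configurations this is the unit-centroid-size frame).
#'
#' @param points k x 2 matrix of spot centroids.
#' @param cls character vector ("central"/"lateral") aligned with rows.
#' @return numeric sum; NA (with a message) when no central point exists.
#' @export
sum_central_lateral_distances <- function(points, cls) {
  ci <- which(cls == "central")
  li <- which(cls == "lateral")
  if (length(ci) == 0L) {
    message("no central points: central-lateral distance is missing")
    return(NA_real_)
  }
  if (length(li) == 0L) return(NA_real_)
  s <- 0
  for (i in ci)
    s <- s + sum(sqrt((points[li, 1] - points[i, 1])^2 +
                        (points[li, 2] - points[i, 2])^2))
  s
}

#' Build the per-specimen feature table
#'
#' Aggregates per-spot records into one feature vector per specimen: total
#' relative area, class means of Ra, MaxFd and Ar, class means of the folded
#' Feret angle, the central/lateral area ratio, and the summed
#' central-lateral centroid distance computed after a generalized Procrustes
#' alignment of the centroid configurations. Specimens whose spot-number
#' signature differs from the majority are excluded from the Procrustes step
#' only (distance recorded as NA); their other features are kept.
#'
#' @param specimens list; each element a list with `specimen_id`, `group`,
#'   `records` (data.frame from [measure_spots()]) and `Ta`.
#' @return data.frame, one row per specimen, with a `units` attribute.
#' @export
build_feature_table <- function(specimens) {
  if (length(specimens) == 0L) stop("no specimens: refusing to build an empty table")
  ids <- vapply(specimens, function(s) s$specimen_id, character(1))
  if (anyDuplicated(ids)) stop("duplicated specimen_id: ",
                               ids[duplicated(ids)][1])
  rows <- lapply(specimens, function(s) {
    r <- s$records
    ctr <- r[r$cls == "central", ]
    lat <- r[r$cls == "lateral", ]
    mc <- function(x) if (nrow(ctr)) mean(x) else NA_real_
    data.frame(
      specimen_id = s$specimen_id, group = s$group, Ta = s$Ta,
      total_Ra = sum(r$Ra),
      mean_Ra_central = mc(ctr$Ra),
      mean_Ra_lateral = mean(lat$Ra),
      central_lateral_ratio = mc(ctr$Ra) / mean(lat$Ra),
      mean_MaxFd_central = mc(ctr$MaxFd),
      mean_MaxFd_lateral = mean(lat$MaxFd),
      mean_Ar_central = mc(ctr$Ar),
      mean_Ar_lateral = mean(lat$Ar),
      mean_Fa_central = mc(ctr$Fa_folded),
      mean_Fa_lateral = mean(lat$Fa_folded),
      sum_central_lateral_dist = NA_real_,
      n_central = nrow(ctr), n_lateral = nrow(lat),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  # Procrustes-registered central-lateral distances on the majority signature
  sigs <- vapply(specimens, function(s)
    paste(sort(s$records$number), collapse = ","), character(1))
  major <- names(sort(table(sigs), decreasing = TRUE))[1]
  in_gpa <- sigs == major
  if (sum(in_gpa) >= 2L) {
    configs <- lapply(specimens[in_gpa], function(s) {
      r <- s$records[order(s$records$number), ]
      as.matrix(r[, c("centroid_x", "centroid_y")])
    })
    g <- gpa(configs)
    cls_ref <- specimens[in_gpa][[1]]$records[
      order(specimens[in_gpa][[1]]$records$number), "cls"]
    d <- vapply(g$aligned, sum_central_lateral_distances, numeric(1),
                cls = cls_ref)
    tab$sum_central_lateral_dist[in_gpa] <- d
  }
  if (any(!in_gpa))
    message(sum(!in_gpa), " specimen(s) excluded from the Procrustes step ",
            "(spot-number signature differs from the majority): ",
            paste(ids[!in_gpa], collapse = ", "))
  attr(tab, "units") <- feature_units()
  attr(tab, "gpa_excluded") <- ids[!in_gpa]
  tab
}

feature_units <- function() {
  c(specimen_id = "id", group = "label", Ta = "px^2",
    total_Ra = "% of Ta", mean_Ra_central = "% of Ta",
    mean_Ra_lateral = "% of Ta", central_lateral_ratio = "dimensionless",
    mean_MaxFd_central = "px / sqrt(Ta)", mean_MaxFd_lateral = "px / sqrt(Ta)",
    mean_Ar_central = "dimensionless", mean_Ar_lateral = "dimensionless",
    mean_Fa_central = "degrees [0,90]", mean_Fa_lateral = "degrees [0,90]",
    sum_central_lateral_dist = "unit centroid-size frame",
    n_central = "count", n_lateral = "count")
}

#' Numeric feature columns used by the classifiers
#' @return character vector of column names.
#' @export
feature_columns <- function() {
  c("total_Ra", "mean_Ra_central", "mean_Ra_lateral", "central_lateral_ratio",
    "mean_MaxFd_central", "mean_MaxFd_lateral", "mean_Ar_central",
    "mean_Ar_lateral", "mean_Fa_central", "mean_Fa_lateral",
    "sum_central_lateral_dist")
}
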