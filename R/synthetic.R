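#' Haplogroup archetype
#'
#' Generative parameters for one haplogroup's dorsal spot pattern: a dark
#' elliptical abdomen bearing 2 central light spots on the midline and
#' `n_lateral_pairs` pairs of light spots along the connexivum (the abdominal
#' margin). Spot sizes are expressed as area weights that are rescaled so
#' the expected total relative spot area matches `target_total_Ra`.
#'
#' @param name group label.
#' @param target_total_Ra expected total spot area as percent of abdomen
#'   area.
#' @param central_share fraction of total spot area carried by the two
#'   central spots.
#' @param central_ar,lateral_ar aspect ratio (minor/major) of central and
#'   lateral spot ellipses.
#' @param orientation_mean_by_pair,orientation_sd_by_pair folded Feret-angle
#'   means and sds (degrees, 0-90) per lateral pair, anterior to posterior.
#' @param central_orientation mean folded orientation of the central spots.
#' @param n_lateral_pairs number of lateral spot pairs.
#' @param abdomen_axes c(width, height) of the abdomen ellipse in pixels.
#' @param body_intensity,spot_intensity,background_intensity mean 8-bit
#'   intensities of abdomen, spots and background.
#' @param intensity_sd per-pixel Gaussian intensity noise sd.
#' @param speckle_density fraction of ROI pixels hit by salt-and-pepper
#'   speckle.
#' @param position_jitter_sd centroid jitter sd as a fraction of body width.
#' @param size_jitter_sd lognormal sd of the per-spot area multiplier
#'   (mean 1).
#' @param pose_rotation_sd sd (degrees) of the specimen's rotation in the
#'   photograph.
#' @param pose_scale_range range of the specimen's imaging scale.
#' @param fusion_probability probability of deliberately fusing one lateral
#'   spot pair with its neighbour (QC-stress cases).
#' @return a `haplogroup_archetype` list.
#' @export
haplogroup_archetype <- function(name,
                                 target_total_Ra,
                                 central_share = 0.3,
                                 central_ar = 0.75,
                                 lateral_ar = 0.55,
                                 orientation_mean_by_pair = rep(65, 6),
                                 orientation_sd_by_pair = rep(14, 6),
                                 central_orientation = 80,
                                 n_lateral_pairs = 6L,
                                 abdomen_axes = c(300, 430),
                                 body_intensity = 55,
                                 spot_intensity = 190,
                                 background_intensity = 215,
                                 intensity_sd = 4,
                                 speckle_density = 0.005,
                                 position_jitter_sd = 0.012,
                                 size_jitter_sd = 0.10,
                                 pose_rotation_sd = 8,
                                 pose_scale_range = c(0.85, 1.15),
                                 fusion_probability = 0) {
  stopifnot(target_total_Ra > 0, target_total_Ra < 100,
            central_share > 0, central_share < 1,
            n_lateral_pairs >= 1L,
            length(orientation_mean_by_pair) == n_lateral_pairs,
            length(orientation_sd_by_pair) == n_lateral_pairs,
            central_ar > 0, central_ar <= 1, lateral_ar > 0, lateral_ar <= 1,
            fusion_probability >= 0, fusion_probability <= 1)
  structure(as.list(environment()), class = "haplogroup_archetype")
}

#' Default haplogroup archetypes
#'
#' The three generative archetypes emulate the published contrasts between
#' the haplogroups: H2 has the largest total relative spot area (15.6%) with
#' central and lateral spots contributing about equally (large, rounder
#' central spots); H3 the smallest (8.7%), lateral-dominant with elongated
#' lateral spots; H1 sits between (11%), lateral-dominant, with its three
#' anterior lateral pairs tilted forward (folded orientation near 30 degrees
#' with low spread).
#'
#' @return named list of three [haplogroup_archetype()] values (H1, H2, H3).
#' @export
default_archetypes <- function() {
  list(
    H1 = haplogroup_archetype(
      "H1", target_total_Ra = 11, central_share = 0.30,
      central_ar = 0.75, lateral_ar = 0.55,
      orientation_mean_by_pair = c(28, 30, 33, 60, 65, 70),
      orientation_sd_by_pair = c(8, 8, 8, 14, 14, 14)),
    H2 = haplogroup_archetype(
      "H2", target_total_Ra = 15.6, central_share = 0.52,
      central_ar = 0.85, lateral_ar = 0.60,
      orientation_mean_by_pair = c(60, 62, 65, 66, 68, 70),
      orientation_sd_by_pair = rep(16, 6)),
    H3 = haplogroup_archetype(
      "H3", target_total_Ra = 8.7, central_share = 0.25,
      central_ar = 0.70, lateral_ar = 0.35,
      orientation_mean_by_pair = c(58, 60, 63, 65, 68, 70),
      orientation_sd_by_pair = rep(16, 6))
  )
}

# canonical spot layout for an archetype: centers (fractions of the unit
# abdomen box), per-spot class/side/pair, area weights
archetype_layout <- function(arch) {
  np <- arch$n_lateral_pairs
  yl <- seq(0.18, 0.88, length.out = np)
  half_w <- function(yf) 0.5 * sqrt(pmax(1 - (2 * yf - 1)^2, 0))
  inset <- 0.72
  lat_w <- (1 - arch$central_share) / (2 * np)
  rows <- list(
    data.frame(cls = "central", side = "center", pair = 0L,
               xf = 0.5, yf = c(0.36, 0.56),
               weight = arch$central_share / 2, ar = arch$central_ar,
               orientation_mean = arch$central_orientation,
               orientation_sd = 10)
  )
  for (i in seq_len(np)) {
    hw <- half_w(yl[i]) * inset
    rows[[length(rows) + 1L]] <- data.frame(
      cls = "lateral", side = c("left", "right"), pair = i,
      xf = c(0.5 - hw, 0.5 + hw), yf = yl[i],
      weight = lat_w, ar = arch$lateral_ar,
      orientation_mean = arch$orientation_mean_by_pair[i],
      orientation_sd = arch$orientation_sd_by_pair[i])
  }
  do.call(rbind, rows)
}

#' Generate one synthetic specimen
#'
#' Renders a dark elliptical abdomen on a light background with light
#' elliptical spots at jittered canonical positions, sampled orientations
#' and sizes rescaled so the expected total relative spot area matches the
#' archetype target; applies a random imaging pose (rotation, scale), adds
#' Gaussian intensity noise and salt-and-pepper speckle, and emits the exact
#' pre-noise ground truth. Deterministic given `seed`.
#'
#' @param arch a [haplogroup_archetype()].
#' @param seed integer seed.
#' @param pose optional list(rotation, scale) overriding the sampled pose
#'   (degrees; dimensionless factor).
#' @param max_tries resampling attempts when spots overlap.
#' @return a `synthetic_specimen` list: `image` (matrix, 0-255), `roi`
#'   ([abdomen_roi()]), `truth_mask` (logical matrix, pre-noise), `truth_spots`
#'   (data.frame: number, cls, side, area_px, centroid_x, centroid_y,
#'   orientation = folded canonical Feret angle), `group`, `seed`, `pose`.
#' @export
generate_specimen <- function(arch, seed, pose = NULL, max_tries = 100L) {
  stopifnot(inherits(arch, "haplogroup_archetype"))
  set.seed(as.integer(seed))
  W <- arch$abdomen_axes[1]; Hgt <- arch$abdomen_axes[2]
  if (is.null(pose)) {
    pose <- list(rotation = stats::rnorm(1, 0, arch$pose_rotation_sd),
                 scale = stats::runif(1, arch$pose_scale_range[1],
                                      arch$pose_scale_range[2]))
  }
  lay <- archetype_layout(arch)
  abd_area <- pi / 4 * W * Hgt
  base_area <- lay$weight * arch$target_total_Ra / 100 * abd_area

  # sample spot geometry in canonical abdomen coordinates (origin at center)
  for (try in seq_len(max_tries)) {
    mult <- exp(stats::rnorm(nrow(lay), 0, arch$size_jitter_sd) -
                  arch$size_jitter_sd^2 / 2)
    area <- base_area * mult
    ar <- pmin(pmax(lay$ar * exp(stats::rnorm(nrow(lay), 0, 0.05)), 0.05), 0.95)
    maj <- sqrt(4 * area / (pi * ar))     # full major axis length
    mnr <- maj * ar
    fold <- stats::rnorm(nrow(lay), lay$orientation_mean, lay$orientation_sd)
    fold <- pmin(pmax(fold, 2), 88)
    fa <- ifelse(lay$side == "left", 180 - fold, fold)   # mirror the left side
    cx <- (lay$xf - 0.5 + stats::rnorm(nrow(lay), 0, arch$position_jitter_sd)) * W
    cy <- (lay$yf - 0.5 + stats::rnorm(nrow(lay), 0, arch$position_jitter_sd)) * Hgt
    sep <- TRUE
    for (i in seq_len(nrow(lay) - 1L)) {
      dd <- sqrt((cx[-(1:i)] - cx[i])^2 + (cy[-(1:i)] - cy[i])^2)
      if (any(dd < 0.55 * (maj[i] + maj[-(1:i)]))) { sep <- FALSE; break }
    }
    if (sep) break
    if (try == max_tries) stop("could not place non-overlapping spots after ",
                               max_tries, " attempts")
  }

  # pose transform canonical -> image
  phi <- pose$rotation * pi / 180
  s <- pose$scale
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  corners <- cbind(c(-W, W, W, -W) / 2, c(-Hgt, -Hgt, Hgt, Hgt) / 2)
  cor_t <- s * t(R %*% t(corners))
  margin <- 14
  xr <- range(cor_t[, 1]); yr <- range(cor_t[, 2])
  cw <- ceiling(xr[2] - xr[1] + 2 * margin)
  ch <- ceiling(yr[2] - yr[1] + 2 * margin)
  ctr <- c(margin - xr[1] + 1, margin - yr[1] + 1)  # canonical origin in image

  # canonical coordinates of every canvas pixel (inverse pose)
  xo <- rep(seq_len(cw), each = ch)
  yo <- rep(seq_len(ch), times = cw)
  q <- cbind(xo - ctr[1], yo - ctr[2]) / s
  pcan <- t(t(R) %*% t(q))            # R^-1 = t(R)
  ux <- pcan[, 1]; uy <- pcan[, 2]

  abd <- (ux / (W / 2))^2 + (uy / (Hgt / 2))^2 <= 1
  spot <- logical(length(ux))
  spot_id <- integer(length(ux))
  for (i in seq_len(nrow(lay))) {
    a <- -fa[i] * pi / 180             # image y points down
    dx <- ux - cx[i]; dy <- uy - cy[i]
    u <- dx * cos(a) + dy * sin(a)
    v <- -dx * sin(a) + dy * cos(a)
    inside <- (u / (maj[i] / 2))^2 + (v / (mnr[i] / 2))^2 <= 1
    spot_id[inside & abd & !spot] <- i
    spot <- spot | (inside & abd)
  }

  img <- matrix(0, ch, cw)
  nbg <- sum(!abd)
  img[cbind(yo, xo)[!abd, ]] <- stats::rnorm(nbg, arch$background_intensity, arch$intensity_sd)
  body <- abd & !spot
  img[cbind(yo, xo)[body, ]] <- stats::rnorm(sum(body), arch$body_intensity, arch$intensity_sd)
  img[cbind(yo, xo)[spot, ]] <- stats::rnorm(sum(spot), arch$spot_intensity, arch$intensity_sd)

  truth_mask <- matrix(FALSE, ch, cw)
  truth_mask[cbind(yo, xo)[spot, ]] <- TRUE

  # speckle within the abdomen
  if (arch$speckle_density > 0) {
    roi_lin <- which(abd)
    nsp <- round(arch$speckle_density * length(roi_lin))
    if (nsp > 0) {
      hit <- sample(roi_lin, nsp)
      salt <- sample(c(TRUE, FALSE), nsp, replace = TRUE)
      img[cbind(yo, xo)[hit, ]] <- ifelse(salt, 255, 0)
    }
  }
  img <- round(pmin(pmax(img, 0), 255))

  # truth spot table (image coordinates; numbering per the pipeline convention)
  ts <- lapply(seq_len(nrow(lay)), function(i) {
    lin <- spot_id == i
    if (!any(lin)) return(NULL)
    data.frame(cls = lay$cls[i], side = lay$side[i], pair = lay$pair[i],
               area_px = sum(lin),
               centroid_x = mean(xo[lin]), centroid_y = mean(yo[lin]),
               orientation = fold[i], Fa_canonical = fa[i] %% 180,
               major_axis = maj[i], minor_axis = mnr[i], ar = ar[i],
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, ts)
  truth <- number_truth(truth)

  # ROI annotation: abdomen outline polygon + landmarks, pose-transformed
  tpt <- function(pc) as.numeric(s * R %*% pc + ctr)
  th <- seq(0, 2 * pi, length.out = 97L)[-97L]
  poly <- t(vapply(th, function(t0) tpt(c(W / 2 * cos(t0), Hgt / 2 * sin(t0))),
                   numeric(2)))
  li <- tpt(c(-W / 2, 0)); ri <- tpt(c(W / 2, 0)); po <- tpt(c(0, Hgt / 2))
  if (li[1] > ri[1]) { tmp <- li; li <- ri; ri <- tmp }
  roi <- abdomen_roi(polygon = poly, left_insertion = li,
                     right_insertion = ri, posterior = po)

  structure(list(image = img, roi = roi, truth_mask = truth_mask,
                 truth_spots = truth, group = arch$name,
                 seed = as.integer(seed), pose = pose,
                 abdomen_area_px = sum(abd)),
            class = "synthetic_specimen")
}

# assign spot numbers to the truth table with the central-1/2,
# left-odd/right-even anterior-to-posterior convention
number_truth <- function(truth) {
  truth$number <- NA_integer_
  ctr <- which(truth$cls == "central")
  truth$number[ctr[order(truth$centroid_y[ctr], truth$centroid_x[ctr])]] <-
    seq_along(ctr)
  l <- which(truth$side == "left")
  r <- which(truth$side == "right")
  truth$number[l[order(truth$centroid_y[l], truth$centroid_x[l])]] <-
    3L + 2L * (seq_along(l) - 1L)
  truth$number[r[order(truth$centroid_y[r], truth$centroid_x[r])]] <-
    4L + 2L * (seq_along(r) - 1L)
  truth[order(truth$number), ]
}

#' Generate a full synthetic dataset
#'
#' Per-specimen seeds are derived reproducibly from `master_seed`. With
#' `dir` the generator writes everything the pipeline consumes: PNG images,
#' per-image ROI JSON, a ground-truth CSV and a labels CSV.
#'
#' @param archetypes list of [haplogroup_archetype()] (default
#'   [default_archetypes()]).
#' @param n_per_group integer vector, specimens per archetype.
#' @param master_seed integer master seed.
#' @param dir optional output directory.
#' @param force overwrite an existing non-empty `dir`.
#' @return invisibly, a list: `specimens` (list of `synthetic_specimen`),
#'   `labels` (data.frame specimen_id, group), `truth` (data.frame).
#' @export
generate_dataset <- function(archetypes = default_archetypes(),
                             n_per_group = c(39L, 23L, 39L),
                             master_seed = 1L, dir = NULL, force = FALSE) {
  stopifnot(length(n_per_group) == length(archetypes), all(n_per_group >= 1L))
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
      stop("output directory ", dir, " is not empty (use force = TRUE)")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, sum(n_per_group))
  specimens <- list(); labels <- list(); truth <- list()
  idx <- 0L
  for (a in seq_along(archetypes)) {
    arch <- archetypes[[a]]
    for (i in seq_len(n_per_group[a])) {
      idx <- idx + 1L
      id <- sprintf("%s_%03d", arch$name, i)
      sp <- generate_specimen(arch, seeds[idx])
      specimens[[id]] <- sp
      labels[[idx]] <- data.frame(specimen_id = id, group = arch$name,
                                  stringsAsFactors = FALSE)
      tr <- sp$truth_spots
      tr$specimen_id <- id
      truth[[idx]] <- tr
      if (!is.null(dir)) {
        write_image(sp$image, file.path(dir, paste0(id, ".png")))
        write_roi(sp$roi, file.path(dir, paste0(id, ".json")))
      }
    }
  }
  labels <- do.call(rbind, labels)
  truth <- do.call(rbind, truth)
  if (!is.null(dir)) {
    utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(list(specimens = specimens, labels = labels, truth = truth))
}
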