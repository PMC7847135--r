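#' Accumulate a spot-frequency heat map
#'
#' Superimposes the aligned binary spot masks of all specimens of one group:
#' each cell holds the fraction of specimens with a spot pixel there, so high
#' values mark the most shared parts of the pattern.
#'
#' @param masks list of `spot_mask` objects or logical matrices sharing the
#'   canonical frame dimensions.
#' @param group group label carried in the result.
#' @return a `spot_heatmap` list: `grid` (fractions in [0, 1]), `n`, `group`.
#' @export
accumulate_heatmap <- function(masks, group = NA_character_) {
  if (length(masks) == 0L) stop("no masks to accumulate")
  grids <- lapply(masks, function(m) {
    if (inherits(m, "spot_mask")) m$grid else m
  })
  d <- dim(grids[[1]])
  for (i in seq_along(grids)) {
    if (!all(dim(grids[[i]]) == d))
      stop("mask ", i, " dimensions ", paste(dim(grids[[i]]), collapse = "x"),
           " differ from ", paste(d, collapse = "x"))
  }
  acc <- Reduce(`+`, lapply(grids, function(g) g * 1))
  structure(list(grid = acc / length(grids), n = length(grids), group = group),
            class = "spot_heatmap")
}

#' Render a heat map to a false-color PNG
#'
#' Writes the frequency grid as a false-color image with a vertical colorbar
#' legend on the right. Deterministic for a fixed palette: re-rendering the
#' same input produces a byte-identical file.
#'
#' @param hm a `spot_heatmap`.
#' @param path output PNG path.
#' @param palette vector of colors from low to high; default a perceptually
#'   uniform sequential palette.
#' @return the path, invisibly.
#' @export
render_heatmap <- function(hm, path,
                           palette = grDevices::hcl.colors(256, "viridis")) {
  stopifnot(inherits(hm, "spot_heatmap"))
  g <- hm$grid
  idx <- pmin(pmax(floor(g * length(palette)) + 1, 1), length(palette))
  rgbm <- grDevices::col2rgb(palette) / 255
  h <- nrow(g); w <- ncol(g)
  img <- array(0, dim = c(h, w + 24L, 3L))
  for (ch in 1:3) img[, seq_len(w), ch] <- matrix(rgbm[ch, idx], h, w)
  # colorbar legend: 16 px wide, 8 px gap, top = 1, bottom = 0
  bar_idx <- pmin(pmax(ceiling((h - seq_len(h) + 1) / h * length(palette)), 1),
                  length(palette))
  for (ch in 1:3) {
    img[, w + seq_len(8L), ch] <- 1
    img[, w + 8L + seq_len(16L), ch] <- matrix(rgbm[ch, bar_idx], h, 16L)
  }
  png::writePNG(img, path, dpi = NULL)
  invisible(path)
}

#' @rdname accumulate_heatmap
#' @param x a `spot_heatmap`.
#' @param ... ignored.
#' @export
print.spot_heatmap <- function(x, ...) {
  cat("spot-frequency heat map: group", x$group, "- n =", x$n,
      "-", paste(dim(x$grid), collapse = " x "),
      "- max frequency", round(max(x$grid), 3), "\n")
  invisible(x)
}
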