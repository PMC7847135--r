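#' Read a specimen photograph
#'
#' Reads a PNG or TIFF image and returns it on the 0-255 intensity scale:
#' a matrix for grayscale input, a height x width x channels array otherwise.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix or 3-d array, values in [0, 255].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expected PNG or TIFF)")
  )
  img <- img * 255
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  img
}

#' Write a grayscale image as PNG
#'
#' @param pixels numeric matrix on the 0-255 scale.
#' @param path output file path.
#' @param bits 8 or 16; 16-bit is used for label grids.
#' @export
write_image <- function(pixels, path, bits = 8L) {
  maxval <- 2^bits - 1
  m <- pmin(pmax(round(pixels), 0), maxval) / maxval
  png::writePNG(m, path, dpi = NULL)
  invisible(path)
}

#' Read an abdomen ROI annotation
#'
#' The annotation stands in for the manual abdomen clipping of the original
#' protocol. JSON schema (0-based pixel coordinates, origin at the top-left
#' pixel, x rightward, y downward):
#' \preformatted{
#' {"polygon": [[x,y], ...], "left_insertion": [x,y],
#'  "right_insertion": [x,y], "posterior": [x,y]}
#' }
#' `polygon` outlines the abdomen (>= 3 vertices, simple); the insertion
#' points sit at the thorax-abdomen insertion angles and `posterior` at the
#' abdomen tip. Internally coordinates are 1-based.
#'
#' @param path JSON file path.
#' @return an `abdomen_roi` object.
#' @export
read_roi <- function(path) {
  j <- jsonlite::fromJSON(path)
  abdomen_roi(
    polygon = as.matrix(j$polygon) + 1,
    left_insertion = unlist(j$left_insertion) + 1,
    right_insertion = unlist(j$right_insertion) + 1,
    posterior = unlist(j$posterior) + 1
  )
}

#' @rdname read_roi
#' @param roi an `abdomen_roi` object.
#' @export
write_roi <- function(roi, path) {
  j <- list(
    polygon = unname(roi$polygon) - 1,
    left_insertion = unname(roi$left_insertion) - 1,
    right_insertion = unname(roi$right_insertion) - 1,
    posterior = unname(roi$posterior) - 1
  )
  jsonlite::write_json(j, path, digits = NA)
  invisible(path)
}

#' Construct an abdomen ROI
#'
#' @param polygon n x 2 matrix of (x, y) vertices, 1-based pixel coordinates.
#' @param left_insertion,right_insertion,posterior (x, y) landmark points.
#' @return an `abdomen_roi` list.
#' @export
abdomen_roi <- function(polygon, left_insertion, right_insertion, posterior) {
  polygon <- as_points(polygon)
  if (nrow(polygon) < 3L) stop("ROI polygon needs at least 3 vertices")
  if (left_insertion[1] >= right_insertion[1])
    stop("left_insertion must lie left of right_insertion in source orientation")
  structure(list(
    polygon = polygon,
    left_insertion = as.numeric(left_insertion),
    right_insertion = as.numeric(right_insertion),
    posterior = as.numeric(posterior)
  ), class = "abdomen_roi")
}
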