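#' Axis-aligned bounding box
#'
#' Boxes use the half-open pixel convention: a pixel center (x, y) lies inside
#' the box iff `x0 <= x < x0 + width` and `y0 <= y < y0 + height`.
#' Coordinates are continuous (float) and 0-based.
#'
#' @param x0,y0 Top-left corner (pixels).
#' @param width,height Box extent (pixels, must be positive).
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(x0, y0, width, height) {
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop_input("bounding_box: width and height must be positive")
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0),
                 width = as.numeric(width), height = as.numeric(height)),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box (%.2f, %.2f) %.2f x %.2f>\n",
              x$x0, x$y0, x$width, x$height))
  invisible(x)
}

box_area <- function(b) b$width * b$height

#' Intersection over union of two boxes
#'
#' `area(a intersect b) / area(a union b)`; symmetric, in `[0, 1]`, and equal
#' to 1 iff the boxes are identical. Ratio of the standard detection-quality
#' measure: values of at least 0.5 are conventionally counted as correct
#' detections.
#'
#' @param a,b `bounding_box` objects.
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a$x0 + a$width, b$x0 + b$width) - max(a$x0, b$x0))
  iy <- max(0, min(a$y0 + a$height, b$y0 + b$height) - max(a$y0, b$y0))
  inter <- ix * iy
  inter / (box_area(a) + box_area(b) - inter)
}

#' 68-point facial landmark set
#'
#' An ordered 68 x 2 matrix of (x, y) landmark coordinates in frame pixel
#' coordinates (continuous, 0-based). Index semantics follow the standard
#' 68-point layout (0-based): 0-16 jaw, 17-26 brows, 27-35 nose, 36-47 eyes,
#' 48-67 mouth.
#'
#' @param points A 68 x 2 numeric matrix (columns x, y).
#' @return An object of class `shape68` (a matrix).
#' @export
shape68 <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 68 || ncol(points) != 2)
    stop_format("shape68: expected a 68 x 2 coordinate matrix, got ",
                nrow(points), " x ", ncol(points))
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y"))
  class(points) <- c("shape68", "matrix", "array")
  points
}

as_shape68 <- function(m) shape68(unclass(m))

#' @export
print.shape68 <- function(x, ...) {
  b <- shape_bbox(x)
  cat(sprintf("<shape68: 68 landmarks, bbox (%.1f, %.1f) %.1f x %.1f>\n",
              b$x0, b$y0, b$width, b$height))
  invisible(x)
}

#' Tight axis-aligned bounding box of a landmark set
#' @param shape A `shape68`.
#' @return A `bounding_box`.
#' @export
shape_bbox <- function(shape) {
  rx <- range(shape[, 1]); ry <- range(shape[, 2])
  bounding_box(rx[1], ry[1], max(rx[2] - rx[1], 1e-12),
               max(ry[2] - ry[1], 1e-12))
}

#' Inter-ocular distance of a landmark set
#'
#' Euclidean distance between the outer eye corners (0-based landmark indices
#' 36 and 45), the scale normalizer used throughout for landmark errors.
#'
#' @param shape A `shape68`.
#' @return Positive scalar (pixels).
#' @export
inter_ocular <- function(shape) {
  sqrt(sum((shape[37, ] - shape[46, ])^2))
}

#' Expand a landmark bounding box into a detector-style face box
#'
#' The generator and tracker share this convention: the tight landmark box
#' expanded by 2.5% of its width on each side and 10% of its height above the
#' brows (faces extend above the topmost landmark).
#'
#' @param shape A `shape68`.
#' @return A `bounding_box` containing `shape_bbox(shape)`.
#' @export
shape_face_box <- function(shape) {
  b <- shape_bbox(shape)
  bounding_box(b$x0 - 0.025 * b$width, b$y0 - 0.10 * b$height,
               b$width * 1.05, b$height * 1.10)
}

# Centered square box with side max(width, height) * pad, same center.
square_box <- function(b, pad = 1) {
  s <- max(b$width, b$height) * pad
  cx <- b$x0 + b$width / 2; cy <- b$y0 + b$height / 2
  bounding_box(cx - s / 2, cy - s / 2, s, s)
}
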