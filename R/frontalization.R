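# Face frontalization: piecewise affine warp of a detected face into a
# canonical frontal frame over a Delaunay triangulation of the 68 landmarks.
# The triangulation is computed ONCE on the reference shape and shared by
# every frame (a common triangulation of detected and reference landmarks),
# so fixed ROIs stay anatomically registered while the face moves.

#' Canonical frontal coordinate frame
#'
#' Scales the model mean shape to fill 80% of the target frame, centers it,
#' and computes the Delaunay triangulation of the reference landmarks with
#' deterministic ordering (triangles sorted on their vertex index triples).
#' The per-pixel triangle membership and barycentric coordinates are
#' precomputed here and reused by every [frontalize()] call.
#'
#' @param shape_model A `thermoface_shape_model`, or directly a `shape68` /
#'   68 x 2 matrix to use as frontal reference.
#' @param size (width, height) of the canonical frame in pixels.
#' @return An object of class `canonical_frame` with fields
#'   `reference_shape`, `size`, `triangles` (n x 3, 1-based vertex indices).
#' @export
make_canonical_frame <- function(shape_model, size = c(256, 256)) {
  mean_shape <- if (inherits(shape_model, "thermoface_shape_model"))
    shape_model$mean_shape else unclass(shape_model)
  wd <- size[1]; ht <- size[2]
  rx <- range(mean_shape[, 1]); ry <- range(mean_shape[, 2])
  s <- 0.8 * min((wd - 1) / (rx[2] - rx[1]), (ht - 1) / (ry[2] - ry[1]))
  ctr <- c(mean(rx), mean(ry))
  ref <- sweep(mean_shape, 2, ctr) * s
  ref[, 1] <- ref[, 1] + (wd - 1) / 2
  ref[, 2] <- ref[, 2] + (ht - 1) / 2
  tri <- delaunay_triangles(ref)
  cf <- structure(list(reference_shape = shape68(ref),
                       size = c(width = as.integer(wd),
                                height = as.integer(ht)),
                       triangles = tri,
                       cache = new.env(parent = emptyenv())),
                  class = "canonical_frame")
  cf$cache$warp_map <- build_warp_map(cf)
  cf
}

#' @export
print.canonical_frame <- function(x, ...) {
  cat(sprintf("<canonical_frame %d x %d, %d triangles>\n",
              x$size[1], x$size[2], nrow(x$triangles)))
  invisible(x)
}

# Delaunay triangulation of an n x 2 point set, rows sorted canonically.
delaunay_triangles <- function(pts) {
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  tri <- t(vapply(tl, function(d) sort(d$ptNum), integer(3)))
  tri[order(tri[, 1], tri[, 2], tri[, 3]), , drop = FALSE]
}

# Precompute, for every canonical pixel inside the reference hull, its
# triangle id and barycentric coordinates. Shared-edge ties resolve to the
# first triangle in canonical order.
build_warp_map <- function(canonical) {
  ref <- unclass(canonical$reference_shape)
  tri <- canonical$triangles
  wd <- canonical$size[1]; ht <- canonical$size[2]
  tri_id <- integer(0); px <- integer(0); py <- integer(0)
  wts <- matrix(0, 0, 3)
  assigned <- matrix(FALSE, ht, wd)
  tol <- 1e-9
  for (k in seq_len(nrow(tri))) {
    v <- ref[tri[k, ], , drop = FALSE]
    x0 <- max(0L, floor(min(v[, 1]))); x1 <- min(wd - 1L, ceiling(max(v[, 1])))
    y0 <- max(0L, floor(min(v[, 2]))); y1 <- min(ht - 1L, ceiling(max(v[, 2])))
    if (x1 < x0 || y1 < y0) next
    gx <- rep(x0:x1, each = y1 - y0 + 1L)
    gy <- rep.int(y0:y1, x1 - x0 + 1L)
    free <- !assigned[cbind(gy + 1L, gx + 1L)]
    if (!any(free)) next
    gx <- gx[free]; gy <- gy[free]
    den <- (v[2, 2] - v[3, 2]) * (v[1, 1] - v[3, 1]) +
      (v[3, 1] - v[2, 1]) * (v[1, 2] - v[3, 2])
    if (abs(den) < 1e-12) next
    w1 <- ((v[2, 2] - v[3, 2]) * (gx - v[3, 1]) +
             (v[3, 1] - v[2, 1]) * (gy - v[3, 2])) / den
    w2 <- ((v[3, 2] - v[1, 2]) * (gx - v[3, 1]) +
             (v[1, 1] - v[3, 1]) * (gy - v[3, 2])) / den
    w3 <- 1 - w1 - w2
    inside <- w1 >= -tol & w2 >= -tol & w3 >= -tol
    if (!any(inside)) next
    gx <- gx[inside]; gy <- gy[inside]
    assigned[cbind(gy + 1L, gx + 1L)] <- TRUE
    tri_id <- c(tri_id, rep.int(k, length(gx)))
    px <- c(px, gx); py <- c(py, gy)
    wts <- rbind(wts, cbind(w1[inside], w2[inside], w3[inside]))
  }
  list(px = px, py = py, tri = tri_id, w = wts,
       lin = py + 1L + px * ht)   # linear index into ht x wd image
}

#' The unique affine map sending a source triangle onto a destination triangle
#'
#' @param src,dst 3 x 2 matrices of triangle vertices (rows correspond).
#' @return A 2 x 3 coefficient matrix `M`; the map is
#'   `(x, y) -> M %*% c(x, y, 1)`.
#' @export
affine_from_triangle <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  A <- cbind(src, 1)
  if (abs(det(A)) < 1e-9)
    stop_geometry("affine_from_triangle: degenerate source triangle")
  t(solve(A, dst))
}

# Map points given in canonical coordinates through the piecewise affine
# transform defined by (reference triangulation -> detected shape).
# Used for vertex-exactness checks and ROI transfer back into the frame.
piecewise_map_points <- function(canonical, detected_shape, pts) {
  ref <- unclass(canonical$reference_shape)
  det_s <- unclass(detected_shape)
  tri <- canonical$triangles
  out <- matrix(NA_real_, nrow(pts), 2)
  tol <- 1e-9
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    for (k in seq_len(nrow(tri))) {
      v <- ref[tri[k, ], , drop = FALSE]
      den <- (v[2, 2] - v[3, 2]) * (v[1, 1] - v[3, 1]) +
        (v[3, 1] - v[2, 1]) * (v[1, 2] - v[3, 2])
      if (abs(den) < 1e-12) next
      w1 <- ((v[2, 2] - v[3, 2]) * (p[1] - v[3, 1]) +
               (v[3, 1] - v[2, 1]) * (p[2] - v[3, 2])) / den
      w2 <- ((v[3, 2] - v[1, 2]) * (p[1] - v[3, 1]) +
               (v[1, 1] - v[3, 1]) * (p[2] - v[3, 2])) / den
      w3 <- 1 - w1 - w2
      if (w1 >= -tol && w2 >= -tol && w3 >= -tol) {
        d <- det_s[tri[k, ], , drop = FALSE]
        out[i, ] <- w1 * d[1, ] + w2 * d[2, ] + w3 * d[3, ]
        break
      }
    }
  }
  out
}

#' Warp a face into the canonical frontal frame
#'
#' Backward piecewise-affine warping: every canonical pixel inside the
#' reference hull is mapped through the inverse per-triangle affine transform
#' into the source frame and bilinearly interpolated. Pixels whose source
#' coordinates fall outside the frame are masked out. Self-occluded regions
#' are still warped (no inpainting): their validity must be judged downstream
#' via the mask and ROI valid fractions.
#'
#' @param frame A `thermal_frame` (or plain pixel matrix).
#' @param detected_shape A `shape68` in frame coordinates.
#' @param canonical A `canonical_frame`.
#' @return An object of class `frontalized_face`: list(image, mask) both of
#'   the canonical size; mask is FALSE everywhere outside the reference hull.
#' @export
frontalize <- function(frame, detected_shape, canonical) {
  pixels <- if (inherits(frame, "thermal_frame")) frame$pixels else
    as.matrix(frame)
  det_s <- unclass(detected_shape)
  if (max(apply(det_s, 2, stats::sd)) < 1e-12)
    stop_geometry("frontalize: degenerate shape")
  wm <- canonical$cache$warp_map
  tri <- canonical$triangles
  v1 <- det_s[tri[wm$tri, 1], , drop = FALSE]
  v2 <- det_s[tri[wm$tri, 2], , drop = FALSE]
  v3 <- det_s[tri[wm$tri, 3], , drop = FALSE]
  sx <- wm$w[, 1] * v1[, 1] + wm$w[, 2] * v2[, 1] + wm$w[, 3] * v3[, 1]
  sy <- wm$w[, 1] * v1[, 2] + wm$w[, 2] * v2[, 2] + wm$w[, 3] * v3[, 2]
  smp <- bilinear_sample(pixels, sx, sy)
  wd <- canonical$size[1]; ht <- canonical$size[2]
  img <- matrix(0, ht, wd)
  msk <- matrix(FALSE, ht, wd)
  img[wm$lin] <- smp$values
  msk[wm$lin] <- smp$inside
  structure(list(image = img, mask = msk, canonical_size = canonical$size),
            class = "frontalized_face")
}

#' @export
print.frontalized_face <- function(x, ...) {
  cat(sprintf("<frontalized_face %d x %d, %.1f%% valid>\n",
              nrow(x$image), ncol(x$image), 100 * mean(x$mask)))
  invisible(x)
}

#' Region-of-interest specification in the canonical frame
#'
#' Either an explicit polygon in canonical coordinates or a landmark-anchored
#' definition: the convex hull of the anchor landmarks (optionally offset),
#' dilated by a radius in canonical pixels. Landmark-anchored ROIs are
#' resolved against a `canonical_frame` by [default_rois()] /
#' [resolve_roi()].
#'
#' @param name ROI name.
#' @param polygon n x 2 matrix of canonical (x, y) vertices (>= 3, positive
#'   area), or NULL for a landmark-anchored ROI.
#' @param landmarks 0-based landmark indices anchoring the ROI.
#' @param dilation Dilation radius, canonical pixels.
#' @param offset Optional (dx, dy) shift of the anchors, canonical pixels.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, polygon = NULL, landmarks = NULL, dilation = 0,
                     offset = c(0, 0)) {
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (nrow(polygon) < 3) stop_input("roi_spec: polygon needs >= 3 vertices")
    if (abs(polygon_area(polygon)) < 1e-9)
      stop_input("roi_spec: polygon has no area")
  }
  structure(list(name = name, polygon = polygon, landmarks = landmarks,
                 dilation = as.numeric(dilation), offset = as.numeric(offset)),
            class = "roi_spec")
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(n, seq_len(n - 1))
  sum(p[j, 1] * p[, 2] - p[, 1] * p[j, 2]) / 2
}

#' Resolve a landmark-anchored ROI into an explicit canonical polygon
#' @param roi A `roi_spec`.
#' @param canonical A `canonical_frame`.
#' @return The `roi_spec` with `polygon` filled in.
#' @export
resolve_roi <- function(roi, canonical) {
  if (!is.null(roi$polygon)) return(roi)
  if (is.null(roi$landmarks)) stop_input("resolve_roi: no polygon or anchors")
  ref <- unclass(canonical$reference_shape)
  pts <- ref[roi$landmarks + 1L, , drop = FALSE]
  pts[, 1] <- pts[, 1] + roi$offset[1]
  pts[, 2] <- pts[, 2] + roi$offset[2]
  # dilate: take the hull of octagonal offsets around each anchor
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  cloud <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i)
    cbind(pts[i, 1] + roi$dilation * cos(ang),
          pts[i, 2] + roi$dilation * sin(ang))))
  hull <- cloud[grDevices::chull(cloud), , drop = FALSE]
  roi$polygon <- hull
  roi
}

#' Default analysis ROIs in the canonical frame
#'
#' Ships "nostrils" (nose-base landmarks 31-35 dilated by 4% of the reference
#' inter-ocular distance), plus "periorbital" (eye landmarks 36-47, 6% IOD
#' dilation) and "forehead" (brow landmarks 17-26 shifted up by 45% IOD, 8%
#' IOD dilation) convenience regions.
#'
#' @param canonical A `canonical_frame`.
#' @return Named list of resolved `roi_spec` objects.
#' @export
default_rois <- function(canonical) {
  iod <- inter_ocular(canonical$reference_shape)
  rois <- list(
    nostrils = roi_spec("nostrils", landmarks = 31:35, dilation = 0.04 * iod),
    periorbital = roi_spec("periorbital", landmarks = 36:47,
                           dilation = 0.06 * iod),
    forehead = roi_spec("forehead", landmarks = 17:26,
                        dilation = 0.08 * iod, offset = c(0, -0.45 * iod)))
  lapply(rois, resolve_roi, canonical = canonical)
}

#' Read an ROI registry from YAML
#'
#' The registry maps ROI names to either `landmarks` (0-based indices) with
#' `dilation` (canonical pixels) and optional `offset`, or an explicit
#' `polygon` (list of `[x, y]` canonical coordinates).
#'
#' @param path YAML file path.
#' @param canonical A `canonical_frame` used to resolve landmark-anchored
#'   entries.
#' @return Named list of resolved `roi_spec` objects.
#' @export
read_rois <- function(path, canonical) {
  reg <- yaml::read_yaml(path)
  out <- lapply(names(reg), function(nm) {
    e <- reg[[nm]]
    if (!is.null(e$polygon)) {
      roi_spec(nm, polygon = do.call(rbind, e$polygon))
    } else {
      resolve_roi(roi_spec(nm, landmarks = unlist(e$landmarks),
                           dilation = e$dilation %||% 0,
                           offset = unlist(e$offset %||% c(0, 0))),
                  canonical)
    }
  })
  stats::setNames(out, names(reg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Even-odd point-in-polygon test, vectorized over points.
points_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

roi_pixel_indices <- function(roi, ht, wd) {
  if (is.null(roi$polygon)) stop_input("extract_roi: unresolved ROI")
  b <- roi$polygon
  x0 <- max(0L, floor(min(b[, 1]))); x1 <- min(wd - 1L, ceiling(max(b[, 1])))
  y0 <- max(0L, floor(min(b[, 2]))); y1 <- min(ht - 1L, ceiling(max(b[, 2])))
  gx <- rep(x0:x1, each = y1 - y0 + 1L)
  gy <- rep.int(y0:y1, x1 - x0 + 1L)
  keep <- points_in_polygon(gx, gy, b)
  (gy + 1L + gx * ht)[keep]
}

#' Mean value of a canonical-frame ROI
#'
#' Averages the frontalized image over the pixels inside the ROI polygon that
#' are also valid under the warp mask. If no polygon pixel is valid the mean
#' is undefined and returned as `NA`.
#'
#' @param face A `frontalized_face`.
#' @param roi A resolved `roi_spec`.
#' @param calibration Optional list(gain, offset) to convert intensities to
#'   Kelvin.
#' @return List with `mean_value` (intensity or Kelvin; `NA` if undefined)
#'   and `valid_fraction` (masked-in fraction of the polygon pixels).
#' @export
extract_roi <- function(face, roi, calibration = NULL) {
  ht <- nrow(face$image); wd <- ncol(face$image)
  idx <- roi_pixel_indices(roi, ht, wd)
  if (length(idx) == 0) return(list(mean_value = NA_real_, valid_fraction = 0))
  ok <- face$mask[idx]
  vf <- mean(ok)
  if (!any(ok)) return(list(mean_value = NA_real_, valid_fraction = 0))
  m <- mean(face$image[idx][ok])
  if (!is.null(calibration)) m <- calibration$gain * m + calibration$offset
  list(mean_value = m, valid_fraction = vf)
}
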