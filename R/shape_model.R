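#' Similarity pose
#'
#' A 2-D similarity transform `q -> scale * R(rotation) * q + translation`,
#' the global pose component of any shape instance.
#'
#' @param scale Positive scalar.
#' @param rotation Radians (counter-clockwise in the x-right / y-down image
#'   frame appears clockwise on screen).
#' @param translation Length-2 numeric (x, y) in pixels.
#' @return An object of class `similarity_pose`.
#' @export
similarity_pose <- function(scale = 1, rotation = 0, translation = c(0, 0)) {
  if (scale <= 0) stop_input("similarity_pose: scale must be positive")
  structure(list(scale = as.numeric(scale), rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "similarity_pose")
}

#' Apply a similarity pose to a point set
#' @param points An n x 2 matrix (or `shape68`).
#' @param pose A `similarity_pose`.
#' @return Transformed points, same class as input where possible.
#' @export
apply_pose <- function(points, pose) {
  R <- matrix(c(cos(pose$rotation), sin(pose$rotation),
                -sin(pose$rotation), cos(pose$rotation)), 2, 2)
  out <- pose$scale * unclass(points) %*% t(R)
  out[, 1] <- out[, 1] + pose$translation[1]
  out[, 2] <- out[, 2] + pose$translation[2]
  if (inherits(points, "shape68")) shape68(out) else out
}

#' Invert a similarity pose
#' @param pose A `similarity_pose`.
#' @return The inverse `similarity_pose`; applying both is the identity.
#' @export
pose_inverse <- function(pose) {
  s <- 1 / pose$scale; r <- -pose$rotation
  R <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
  t_inv <- -s * as.vector(R %*% pose$translation)
  similarity_pose(s, r, t_inv)
}

#' Optimal similarity alignment of one shape onto a reference
#'
#' Closed-form least-squares Procrustes fit: returns the similarity transform
#' minimizing the summed squared distances between the transformed shape and
#' the reference (rotation via the complex cross-covariance; reflections are
#' excluded), together with the transformed shape.
#'
#' @param shape,reference `shape68` objects (or n x 2 matrices with matching n).
#' @return List with `aligned` (transformed shape), `pose` (the
#'   `similarity_pose` mapping `shape` onto `reference`) and `residual`
#'   (summed squared distance after alignment).
#' @export
procrustes_align <- function(shape, reference) {
  x <- unclass(shape); r <- unclass(reference)
  if (nrow(x) != nrow(r)) stop_input("procrustes_align: point count mismatch")
  if (max(apply(x, 2, stats::sd)) < 1e-12)
    stop_input("procrustes_align: degenerate shape (all points coincident)")
  cx <- colMeans(x); cr <- colMeans(r)
  zx <- complex(real = x[, 1] - cx[1], imaginary = x[, 2] - cx[2])
  zr <- complex(real = r[, 1] - cr[1], imaginary = r[, 2] - cr[2])
  a <- sum(Conj(zx) * zr) / sum(Conj(zx) * zx)   # scale * exp(i rotation)
  s <- Mod(a); th <- Arg(a)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_vec <- cr - s * as.vector(R %*% cx)
  pose <- similarity_pose(s, th, t_vec)
  aligned <- apply_pose(shape, pose)
  res <- sum((unclass(aligned) - r)^2)
  list(aligned = if (inherits(shape, "shape68")) shape68(aligned) else aligned,
       pose = pose, residual = res)
}

# Normalize a point set to zero centroid and unit centroid size
# (sqrt of summed squared distances to centroid).
normalize_shape <- function(x) {
  x <- unclass(x)
  x <- sweep(x, 2, colMeans(x))
  s <- sqrt(sum(x^2))
  if (s < 1e-12) stop_input("normalize_shape: degenerate shape")
  x / s
}

#' Build a 68-point statistical shape model
#'
#' Generalized Procrustes alignment of the training shapes (iterated
#' similarity alignment to the evolving mean, mean re-normalized to unit
#' centroid size, until the mean moves by less than 1e-7 or 100 iterations),
#' then PCA of the aligned, mean-centered coordinate vectors. The retained
#' component count `k` is the smallest number of components reaching
#' `variance_retained` of the total variance. Decoding parameters through the
#' PCA basis guarantees plausible landmark configurations (the model's
#' "PCA layer").
#'
#' @param shapes List of `shape68` (at least 3).
#' @param variance_retained Fraction of variance to retain (default 0.98).
#' @param max_components Optional hard cap on `k`.
#' @return An object of class `thermoface_shape_model` with fields
#'   `mean_shape` (68 x 2, unit centroid size, zero centroid), `components`
#'   (136 x k orthonormal), `eigenvalues` (length k, non-increasing), `k`.
#' @export
build_shape_model <- function(shapes, variance_retained = 0.98,
                              max_components = Inf) {
  if (length(shapes) < 3) stop_training("build_shape_model: need >= 3 shapes")
  xs <- lapply(shapes, function(s) normalize_shape(unclass(s)))
  mean_shape <- xs[[1]]
  for (iter in seq_len(100)) {
    aligned <- lapply(xs, function(x)
      unclass(procrustes_align(x, mean_shape)$aligned))
    new_mean <- normalize_shape(Reduce(`+`, aligned) / length(aligned))
    delta <- max(abs(new_mean - mean_shape))
    mean_shape <- new_mean
    if (delta < 1e-7) break
  }
  aligned <- lapply(xs, function(x)
    unclass(procrustes_align(x, mean_shape)$aligned))
  X <- do.call(rbind, lapply(aligned, as.vector))   # n x 136, (x1..x68,y1..y68)
  mu <- as.vector(mean_shape)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  ev <- sv$d^2 / max(1, nrow(X) - 1)
  total <- sum(ev)
  if (total < 1e-20) {
    k <- 0L
  } else {
    cum <- cumsum(ev) / total
    k <- which(cum >= variance_retained - 1e-12)[1]
    # drop numerically-zero modes
    k <- min(k, sum(ev > 1e-12 * ev[1]), max_components)
    k <- as.integer(max(k, 0L))
  }
  comps <- if (k > 0) sv$v[, seq_len(k), drop = FALSE] else
    matrix(0, 136, 0)
  structure(list(mean_shape = matrix(mu, 68, 2,
                                     dimnames = list(NULL, c("x", "y"))),
                 components = comps,
                 eigenvalues = if (k > 0) ev[seq_len(k)] else numeric(0),
                 k = k, n_train = length(shapes)),
            class = "thermoface_shape_model")
}

#' @export
print.thermoface_shape_model <- function(x, ...) {
  cat(sprintf("<shape model: k = %d components, %d training shapes>\n",
              x$k, x$n_train))
  invisible(x)
}

#' Shape parameters (PCA coefficients + similarity pose)
#' @param b Numeric vector of PCA coefficients (length = model `k`).
#' @param pose A `similarity_pose` mapping model space into the image.
#' @return An object of class `shape_params`.
#' @export
shape_params <- function(b, pose = similarity_pose()) {
  structure(list(b = as.numeric(b), pose = pose), class = "shape_params")
}

#' Generate landmark positions from shape-model parameters
#'
#' `shape = pose o (mean_shape + sum_i b_i component_i)`, with each `b_i`
#' clamped to plus/minus 3 standard deviations (`3 sqrt(eigenvalue_i)`)
#' before synthesis, the standard plausibility constraint.
#'
#' @param model A `thermoface_shape_model`.
#' @param params A `shape_params` with `length(b) == model$k`.
#' @return A `shape68` in image coordinates.
#' @export
decode_params <- function(model, params) {
  b <- params$b
  if (length(b) != model$k)
    stop_input("decode_params: expected ", model$k, " coefficients, got ",
               length(b))
  if (model$k > 0) {
    lim <- 3 * sqrt(pmax(model$eigenvalues, 0))
    b <- pmin(pmax(b, -lim), lim)
    v <- as.vector(model$mean_shape) + as.vector(model$components %*% b)
  } else v <- as.vector(model$mean_shape)
  shape68(apply_pose(matrix(v, 68, 2), params$pose))
}

#' Project a landmark set onto the shape model
#'
#' Procrustes-aligns the shape to the model mean and projects the residual
#' onto the PCA basis; no clamping is applied on encode. The returned pose
#' maps model space into the image (the inverse of the alignment pose), so
#' `decode_params(model, encode_shape(model, s))` reproduces `s` for shapes
#' in the model span.
#'
#' @param model A `thermoface_shape_model`.
#' @param shape A `shape68`.
#' @return A `shape_params`.
#' @export
encode_shape <- function(model, shape) {
  al <- procrustes_align(shape, shape68(model$mean_shape))
  d <- as.vector(unclass(al$aligned)) - as.vector(model$mean_shape)
  b <- if (model$k > 0) as.vector(crossprod(model$components, d)) else numeric(0)
  shape_params(b, pose_inverse(al$pose))
}

#' Serialize a shape model to JSON
#' @param model A `thermoface_shape_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shape_model <- function(model, path) {
  obj <- list(mean_shape = as.vector(model$mean_shape),
              components = as.vector(model$components),
              eigenvalues = model$eigenvalues, k = model$k,
              n_train = model$n_train)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a shape model written by [write_shape_model()]
#' @param path JSON path.
#' @return A `thermoface_shape_model`.
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean_shape = matrix(obj$mean_shape, 68, 2,
                                     dimnames = list(NULL, c("x", "y"))),
                 components = matrix(obj$components, 136, obj$k),
                 eigenvalues = as.numeric(obj$eigenvalues),
                 k = as.integer(obj$k), n_train = obj$n_train),
            class = "thermoface_shape_model")
}
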