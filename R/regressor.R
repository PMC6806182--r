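# PCA-constrained cascaded shape regression.
#
# The architectural idea: a regressor predicts pose + PCA shape coefficients
# and every prediction is decoded through the statistical shape model (the
# "PCA layer"), so outputs are always plausible landmark configurations.
# The regressor family here is multi-cell HOG features + cascaded ridge
# regression: desk-scale trainable and fully deterministic.

regressor_crop_box <- function(box, pad = 1.15) square_box(box, pad)

# Map image-frame points into the crop pixel frame of box_patch().
crop_coords <- function(pts, sq, window) {
  u <- (pts[, 1] - sq$x0 + 0.5) * window / sq$width - 0.5
  v <- (pts[, 2] - sq$y0 + 0.5) * window / sq$height - 0.5
  cbind(u, v)
}

crop_to_image <- function(pts, sq, window) {
  x <- (pts[, 1] + 0.5) * sq$width / window + sq$x0 - 0.5
  y <- (pts[, 2] + 0.5) * sq$height / window + sq$y0 - 0.5
  cbind(x, y)
}

# Linear pose parameters (a, b, tx, ty) of a similarity_pose.
pose_to_q <- function(pose) {
  c(pose$scale * cos(pose$rotation) - 1, pose$scale * sin(pose$rotation),
    pose$translation[1], pose$translation[2])
}

regressor_target <- function(sm, shape_crop) {
  par <- encode_shape(sm, shape_crop)
  c(pose_to_q(par$pose), par$b)
}

regressor_decode <- function(sm, t_vec) {
  q <- t_vec[1:4]
  bs <- if (sm$k > 0) t_vec[5:(4 + sm$k)] else numeric(0)
  shape68(aam_shape_from_params(sm, q, bs))
}

ridge_fit <- function(X, Y, lambda) {
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  W <- solve(crossprod(Xc) + diag(lambda, ncol(X)), crossprod(Xc, Yc))
  list(W = W, mx = mx, my = my)
}

ridge_predict <- function(fit, x) {
  as.vector(fit$my + crossprod(fit$W, x - fit$mx))
}

#' Train the PCA-constrained cascaded shape regressor
#'
#' Each cascade stage crops the current face box, resizes it to `crop_size`,
#' extracts multi-cell HOG features and ridge-regresses pose + shape-model
#' coefficients; predictions decode through [decode_params()]-style clamping
#' so every output lies in the model's plausibility region. Training jitters
#' the boxes by up to 10% in position and scale so the regressor tolerates
#' imperfect detections.
#'
#' @param frames List of `annotated_frame` with shapes and face boxes
#'   (>= 50).
#' @param shape_model A prebuilt `thermoface_shape_model` (NULL = build from
#'   the training shapes at 98% retained variance).
#' @param crop_size Square crop side in pixels fed to HOG.
#' @param n_stages Cascade stages (default 3).
#' @param n_jitter Jittered boxes per training frame.
#' @param lambda Ridge regularization.
#' @param seed Integer seed for the jitter.
#' @return An object of class `shape_regressor`.
#' @export
train_shape_regressor <- function(frames, shape_model = NULL, crop_size = 96L,
                                  n_stages = 4L, n_jitter = 8L, lambda = 5,
                                  seed = 1L) {
  if (length(frames) < 50)
    stop_training("train_shape_regressor: need >= 50 annotated frames")
  if (is.null(shape_model))
    shape_model <- build_shape_model(lapply(frames, `[[`, "shape"), 0.98,
                                     max_components = 12L)
  spec <- hog_spec(cell = 8L, block = 2L, n_orientations = 9L,
                   window = as.integer(crop_size))
  with_seed(seed, {
    # jittered initial boxes per sample
    samples <- list()
    for (af in frames) {
      fb <- af$face_box
      for (j in seq_len(n_jitter)) {
        sc <- stats::runif(1, 0.9, 1.1)
        dx <- stats::runif(1, -0.1, 0.1) * fb$width
        dy <- stats::runif(1, -0.1, 0.1) * fb$height
        jb <- bounding_box(fb$x0 + dx + fb$width * (1 - sc) / 2,
                           fb$y0 + dy + fb$height * (1 - sc) / 2,
                           fb$width * sc, fb$height * sc)
        samples[[length(samples) + 1L]] <-
          list(pixels = af$frame$pixels, shape = af$shape, box = jb)
      }
    }
    stages <- vector("list", n_stages)
    boxes <- lapply(samples, `[[`, "box")
    for (st in seq_len(n_stages)) {
      X <- t(vapply(seq_along(samples), function(i) {
        sq <- regressor_crop_box(boxes[[i]])
        compute_hog(box_patch(samples[[i]]$pixels, sq, spec$window), spec)
      }, numeric(hog_descriptor_length(spec))))
      Y <- t(vapply(seq_along(samples), function(i) {
        sq <- regressor_crop_box(boxes[[i]])
        sc <- crop_coords(unclass(samples[[i]]$shape), sq, spec$window)
        regressor_target(shape_model, shape68(sc))
      }, numeric(4 + shape_model$k)))
      fit <- ridge_fit(X, Y, lambda)
      stages[[st]] <- fit
      if (st < n_stages) {
        boxes <- lapply(seq_along(samples), function(i) {
          sq <- regressor_crop_box(boxes[[i]])
          pred <- ridge_predict(fit, X[i, ])
          sh_c <- regressor_decode(shape_model, pred)
          sh <- shape68(crop_to_image(unclass(sh_c), sq, spec$window))
          shape_face_box(sh)
        })
      }
    }
    structure(list(shape_model = shape_model, hog = spec,
                   crop_size = as.integer(crop_size), stages = stages,
                   n_stages = as.integer(n_stages)),
              class = "shape_regressor")
  })
}

#' @export
print.shape_regressor <- function(x, ...) {
  cat(sprintf("<shape_regressor: %d stages, %d-px crop, k = %d>\n",
              x$n_stages, x$crop_size, x$shape_model$k))
  invisible(x)
}

#' Fit landmarks with the cascaded shape regressor
#'
#' One deterministic forward pass per cascade stage. The reported cost is the
#' mean per-point disagreement between the last two cascade stages divided by
#' the predicted inter-ocular distance: a self-consistency confidence proxy
#' that is small on faces and large on background.
#'
#' @param frame A `thermal_frame` (or pixel matrix).
#' @param init_box A `bounding_box` overlapping the image.
#' @param regressor A `shape_regressor`.
#' @return A [fit_result()].
#' @export
fit_regressor <- function(frame, init_box, regressor) {
  pixels <- if (inherits(frame, "thermal_frame")) frame$pixels else
    as.matrix(frame)
  if (init_box$x0 > ncol(pixels) || init_box$y0 > nrow(pixels) ||
      init_box$x0 + init_box$width < 0 || init_box$y0 + init_box$height < 0)
    stop_input("fit_regressor: init_box does not overlap the image")
  sm <- regressor$shape_model
  spec <- regressor$hog
  box <- init_box
  prev_shape <- NULL
  shape <- NULL
  for (st in seq_len(regressor$n_stages)) {
    sq <- regressor_crop_box(box)
    feats <- compute_hog(box_patch(pixels, sq, spec$window), spec)
    pred <- ridge_predict(regressor$stages[[st]], feats)
    sh_c <- regressor_decode(sm, pred)
    prev_shape <- shape
    shape <- shape68(crop_to_image(unclass(sh_c), sq, spec$window))
    box <- shape_face_box(shape)
  }
  cost <- if (is.null(prev_shape)) 0 else
    mean(sqrt(rowSums((unclass(shape) - unclass(prev_shape))^2))) /
      inter_ocular(shape)
  fit_result(shape, TRUE, regressor$n_stages, cost)
}

#' Normalized root-mean-square landmark error
#'
#' RMSE over the 68 point distances divided by the inter-ocular distance of
#' the ground truth (outer eye corners, landmarks 36 and 45), the scale-free
#' landmark accuracy measure.
#'
#' @param predicted,truth `shape68` objects.
#' @return Non-negative scalar.
#' @export
nrmse <- function(predicted, truth) {
  io <- inter_ocular(truth)
  if (io <= 0) stop_input("nrmse: zero inter-ocular distance")
  sqrt(mean(rowSums((unclass(predicted) - unclass(truth))^2))) / io
}
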