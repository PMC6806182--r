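# Feature-based Active Appearance Models.
#
# Two presets mirror the classic precision/speed trade-off: a high-quality
# model (reference diagonal 150 px, 36-channel dense gradient-orientation
# features, 3 pyramid levels, simultaneous shape+appearance Gauss-Newton
# updates) and a fast model (diagonal 70 px, raw intensity features, 2
# levels, project-out updates). Appearance lives in the mean-shape reference
# frame; images are warped into it by the shared piecewise-affine machinery.

#' Landmark fitting result
#' @param shape Fitted `shape68` (frame coordinates).
#' @param converged Logical.
#' @param n_iterations Iterations consumed.
#' @param final_cost Mean squared appearance residual (fitter-specific scale).
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(shape, converged, n_iterations, final_cost) {
  structure(list(shape = shape, converged = isTRUE(converged),
                 n_iterations = as.integer(n_iterations),
                 final_cost = as.numeric(final_cost)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s after %d iterations, cost %.4g>\n",
              if (x$converged) "converged" else "not converged",
              x$n_iterations, x$final_cost))
  invisible(x)
}

# Reference frame whose scaled mean shape has the requested bbox diagonal.
aam_reference_frame <- function(mean_shape, diagonal, margin = 0.15) {
  rx <- range(mean_shape[, 1]); ry <- range(mean_shape[, 2])
  bw <- rx[2] - rx[1]; bh <- ry[2] - ry[1]
  s <- diagonal / sqrt(bw^2 + bh^2)
  wd <- ceiling(bw * s * (1 + 2 * margin)); ht <- ceiling(bh * s * (1 + 2 * margin))
  ref <- sweep(mean_shape, 2, c(mean(rx), mean(ry))) * s
  ref[, 1] <- ref[, 1] + (wd - 1) / 2
  ref[, 2] <- ref[, 2] + (ht - 1) / 2
  cf <- structure(list(reference_shape = shape68(ref),
                       size = c(width = as.integer(wd),
                                height = as.integer(ht)),
                       triangles = delaunay_triangles(ref),
                       cache = new.env(parent = emptyenv())),
                  class = "canonical_frame")
  cf$cache$warp_map <- build_warp_map(cf)
  # dense barycentric transfer matrix: src = Wmat %*% vertex_coords
  wm <- cf$cache$warp_map
  Wmat <- matrix(0, length(wm$px), 68)
  tri <- cf$triangles
  for (j in 1:3) {
    idx <- cbind(seq_along(wm$px), tri[wm$tri, j])
    Wmat[idx] <- Wmat[idx] + wm$w[, j]
  }
  cf$cache$Wmat <- Wmat
  cf
}

# Multi-channel feature maps of an image. kind "intensity": the image itself.
# kind "dense_sift": 9 unsigned orientation maps (soft-binned, magnitude
# weighted, box-pooled) sampled at 4 spatial offsets per pixel by the warp =
# 36 channels, L2-normalized per pixel at sampling time.
aam_feature_maps <- function(pixels, kind) {
  if (kind == "intensity") {
    g <- image_gradients(pixels)
    return(list(maps = list(pixels), gx = list(g$gx), gy = list(g$gy),
                offsets = matrix(0, 1, 2), normalize = FALSE))
  }
  nb <- 9L
  g <- image_gradients(pixels)
  mag <- sqrt(g$gx^2 + g$gy^2)
  ang <- (atan2(g$gy, g$gx) * 180 / pi) %% 180
  t <- ang / 20
  b0 <- floor(t); w1 <- t - b0
  b0 <- ((b0 %% nb) + nb) %% nb
  maps <- vector("list", nb)
  for (o in 0:(nb - 1L)) {
    m <- mag * ((b0 == o) * (1 - w1) + (((b0 + 1) %% nb) == o) * w1)
    maps[[o + 1L]] <- box_blur(m, 9L)
  }
  gx <- lapply(maps, function(m) image_gradients(m)$gx)
  gy <- lapply(maps, function(m) image_gradients(m)$gy)
  offs <- rbind(c(-3, -3), c(-3, 3), c(3, -3), c(3, 3))
  list(maps = maps, gx = gx, gy = gy, offsets = offs, normalize = TRUE)
}

# Sample feature maps (and optionally their gradients) at continuous source
# coordinates. Returns f [npix x nch]; with gradients also Fx, Fy.
aam_sample_features <- function(fm, sx, sy, gradients = FALSE) {
  nmap <- length(fm$maps); noff <- nrow(fm$offsets)
  nch <- nmap * noff
  n <- length(sx)
  f <- matrix(0, n, nch)
  Fx <- if (gradients) matrix(0, n, nch) else NULL
  Fy <- if (gradients) matrix(0, n, nch) else NULL
  dim_hw <- dim(fm$maps[[1]])
  ch <- 0L
  for (k in seq_len(noff)) {
    prep <- bilinear_prep(dim_hw, sx + fm$offsets[k, 1],
                          sy + fm$offsets[k, 2])
    for (o in seq_len(nmap)) {
      ch <- ch + 1L
      f[, ch] <- bilinear_apply(fm$maps[[o]], prep)
      if (gradients) {
        Fx[, ch] <- bilinear_apply(fm$gx[[o]], prep)
        Fy[, ch] <- bilinear_apply(fm$gy[[o]], prep)
      }
    }
  }
  if (fm$normalize) {
    nrm <- sqrt(rowSums(f^2)) + 1e-6
    f <- f / nrm
    if (gradients) { Fx <- Fx / nrm; Fy <- Fy / nrm }
  } else {
    mu <- mean(f); sd_ <- stats::sd(as.vector(f)) + 1e-9
    f <- (f - mu) / sd_
    if (gradients) { Fx <- Fx / sd_; Fy <- Fy / sd_ }
  }
  list(f = f, Fx = Fx, Fy = Fy)
}

aam_presets <- function(preset) {
  switch(preset,
    high_quality = list(diagonal = 150, feature_kind = "dense_sift",
                        n_levels = 3L, var_shape = 0.98, var_app = 0.98,
                        max_shape = 12L, max_app = 16L),
    fast = list(diagonal = 70, feature_kind = "intensity", n_levels = 2L,
                var_shape = 0.90, var_app = 0.90,
                max_shape = 5L, max_app = 8L),
    stop_input("train_aam: unknown preset"))
}

#' Train an Active Appearance Model
#'
#' Builds the statistical shape model from the annotated shapes, then, per
#' pyramid level, warps every training image into the mean-shape reference
#' frame, extracts features and builds the PCA appearance model. The
#' `high_quality` preset maximizes precision; `fast` drastically reduces the
#' parameter set and resolution for speed at a known precision cost.
#'
#' @param frames List of `annotated_frame` with ground-truth shapes (>= 20).
#' @param preset "high_quality" or "fast".
#' @param calibrate_failure Fit a subset of training frames after training to
#'   calibrate the failure-cost threshold (99th percentile of correct-fit
#'   costs).
#' @return An object of class `aam_model`.
#' @export
train_aam <- function(frames, preset = c("high_quality", "fast"),
                      calibrate_failure = TRUE) {
  preset <- match.arg(preset)
  if (length(frames) < 20) stop_training("train_aam: need >= 20 frames")
  cfg <- aam_presets(preset)
  shapes <- lapply(frames, `[[`, "shape")
  sm <- build_shape_model(shapes, cfg$var_shape, max_components = cfg$max_shape)
  levels <- vector("list", cfg$n_levels)
  for (lv in seq_len(cfg$n_levels)) {
    l <- lv - 1L
    ref <- aam_reference_frame(sm$mean_shape, cfg$diagonal / 2^l)
    wm <- ref$cache$warp_map
    feats <- vapply(frames, function(af) {
      img <- af$frame$pixels
      sh <- unclass(af$shape)
      if (l > 0) for (i in seq_len(l)) img <- pyr_down(img)
      sh <- sh / 2^l
      fm <- aam_feature_maps(img, cfg$feature_kind)
      src <- ref$cache$Wmat %*% sh
      as.vector(aam_sample_features(fm, src[, 1], src[, 2])$f)
    }, numeric(length(wm$px) *
                 (if (cfg$feature_kind == "dense_sift") 36L else 1L)))
    X <- t(feats)
    a0 <- colMeans(X)
    Xc <- sweep(X, 2, a0)
    sv <- svd(Xc, nu = 0)
    ev <- sv$d^2 / max(1, nrow(X) - 1)
    tot <- sum(ev)
    k <- if (tot < 1e-20) 0L else
      min(which(cumsum(ev) / tot >= cfg$var_app - 1e-12)[1],
          sum(ev > 1e-12 * ev[1]), cfg$max_app)
    A <- if (k > 0) sv$v[, seq_len(k), drop = FALSE] else
      matrix(0, ncol(X), 0)
    levels[[lv]] <- list(level = l, ref = ref, a0 = a0, A = A,
                         app_eigenvalues = if (k > 0) ev[seq_len(k)] else
                           numeric(0))
  }
  model <- structure(list(shape_model = sm, feature_kind = cfg$feature_kind,
                          diagonal = cfg$diagonal, n_levels = cfg$n_levels,
                          preset = preset, levels = levels,
                          failure_cost_threshold = Inf),
                     class = "aam_model")
  if (calibrate_failure) {
    idx <- unique(round(seq(1, length(frames), length.out = min(8,
                                                                length(frames)))))
    costs <- vapply(frames[idx], function(af)
      fit_aam(af$frame, af$face_box, model)$final_cost, numeric(1))
    model$failure_cost_threshold <- stats::quantile(costs, 0.99,
                                                    names = FALSE) * 2
  }
  model
}

#' @export
print.aam_model <- function(x, ...) {
  cat(sprintf("<aam_model (%s): diagonal %g px, %s features, %d levels, k_shape = %d>\n",
              x$preset, x$diagonal, x$feature_kind, x$n_levels,
              x$shape_model$k))
  invisible(x)
}

#' Model size in stored coefficients (shape + appearance bases)
#' @param model An `aam_model`.
#' @return Integer coefficient count.
#' @export
aam_model_size <- function(model) {
  sum(vapply(model$levels, function(lv)
    length(lv$a0) + length(lv$A), numeric(1))) +
    length(model$shape_model$components)
}

# Shape synthesized from (q = c(a, b, tx, ty), bs): S_q (mean + P bs) + t.
aam_shape_from_params <- function(sm, q, bs) {
  v <- as.vector(sm$mean_shape)
  if (sm$k > 0) {
    lim <- 3 * sqrt(pmax(sm$eigenvalues, 0))
    bs <- pmin(pmax(bs, -lim), lim)
    v <- v + as.vector(sm$components %*% bs)
  }
  m <- matrix(v, 68, 2)
  x <- (1 + q[1]) * m[, 1] - q[2] * m[, 2] + q[3]
  y <- q[2] * m[, 1] + (1 + q[1]) * m[, 2] + q[4]
  cbind(x, y)
}

# Per-vertex Jacobians of the synthesized shape w.r.t. (q, bs):
# list(DVx, DVy) each 68 x (4 + k).
aam_shape_jacobian <- function(sm, q, bs) {
  v <- as.vector(sm$mean_shape)
  if (sm$k > 0) {
    lim <- 3 * sqrt(pmax(sm$eigenvalues, 0))
    bs <- pmin(pmax(bs, -lim), lim)
    v <- v + as.vector(sm$components %*% bs)
  }
  m <- matrix(v, 68, 2)
  k <- sm$k
  DVx <- matrix(0, 68, 4 + k); DVy <- matrix(0, 68, 4 + k)
  DVx[, 1] <- m[, 1]; DVy[, 1] <- m[, 2]
  DVx[, 2] <- -m[, 2]; DVy[, 2] <- m[, 1]
  DVx[, 3] <- 1; DVy[, 4] <- 1
  if (k > 0) {
    Px <- sm$components[1:68, , drop = FALSE]
    Py <- sm$components[69:136, , drop = FALSE]
    DVx[, 5:(4 + k)] <- (1 + q[1]) * Px - q[2] * Py
    DVy[, 5:(4 + k)] <- q[2] * Px + (1 + q[1]) * Py
  }
  list(DVx = DVx, DVy = DVy)
}

#' Fit an Active Appearance Model to a frame
#'
#' The mean shape is scaled and translated into the initialization box, then
#' Gauss-Newton iterations refine the pose and shape (and, for the
#' high-quality preset, appearance) parameters per pyramid level from coarse
#' to fine, with backtracking step halving so the appearance cost never
#' increases at an accepted step. Iteration stops when the parameter-update
#' norm drops below 1e-4 or `max_iters` is reached.
#'
#' @param frame A `thermal_frame` (or pixel matrix).
#' @param init_box A `bounding_box` overlapping the image (typically a
#'   detector output or the previous frame's shape box).
#' @param model An `aam_model`.
#' @param max_iters Maximum Gauss-Newton iterations per pyramid level.
#' @return A [fit_result()].
#' @export
fit_aam <- function(frame, init_box, model, max_iters = 50) {
  pixels <- if (inherits(frame, "thermal_frame")) frame$pixels else
    as.matrix(frame)
  img_box <- bounding_box(0, 0, ncol(pixels), nrow(pixels))
  if (iou(init_box, img_box) <= 0 &&
      (init_box$x0 > ncol(pixels) || init_box$y0 > nrow(pixels) ||
       init_box$x0 + init_box$width < 0 || init_box$y0 + init_box$height < 0))
    stop_input("fit_aam: init_box does not overlap the image")
  sm <- model$shape_model
  mb <- shape_bbox(shape68(sm$mean_shape))
  s0 <- min(init_box$width / (1.05 * mb$width),
            init_box$height / (1.10 * mb$height))
  ctr <- c(init_box$x0 + init_box$width / 2,
           init_box$y0 + init_box$height / 2)
  mctr <- c(mb$x0 + mb$width / 2, mb$y0 + mb$height / 2)
  q <- c(s0 - 1, 0, ctr[1] - s0 * mctr[1], ctr[2] - s0 * mctr[2])
  bs <- numeric(sm$k)
  lam <- NULL
  total_iters <- 0L
  converged <- FALSE
  final_cost <- NA_real_
  simultaneous <- model$feature_kind == "dense_sift"
  for (lv in rev(seq_len(model$n_levels))) {   # coarse -> fine
    lev <- model$levels[[lv]]
    l <- lev$level
    img <- pixels
    if (l > 0) for (i in seq_len(l)) img <- pyr_down(img)
    fm <- aam_feature_maps(img, model$feature_kind)
    Wmat <- lev$ref$cache$Wmat
    A <- lev$A
    k_app <- ncol(A)
    eval_cost <- function(q_, bs_) {
      sh <- aam_shape_from_params(sm, q_, bs_) / 2^l
      src <- Wmat %*% sh
      f <- aam_sample_features(fm, src[, 1], src[, 2])$f
      r <- as.vector(f) - lev$a0
      # appearance-optimal residual: A is orthonormal, so the projected
      # residual energy is |r|^2 - |A^T r|^2
      if (k_app > 0) (sum(r^2) - sum(crossprod(A, r)^2)) / length(r) else
        mean(r^2)
    }
    cost <- eval_cost(q, bs)
    for (it in seq_len(max_iters)) {
      total_iters <- total_iters + 1L
      sh <- aam_shape_from_params(sm, q, bs) / 2^l
      src <- Wmat %*% sh
      sf <- aam_sample_features(fm, src[, 1], src[, 2], gradients = TRUE)
      fvec <- as.vector(sf$f)
      jac <- aam_shape_jacobian(sm, q, bs)
      dSx <- (Wmat %*% jac$DVx) / 2^l   # npix x np
      dSy <- (Wmat %*% jac$DVy) / 2^l
      np <- ncol(dSx)
      nch <- ncol(sf$f)
      J <- matrix(0, length(fvec), np)
      for (j in seq_len(np))
        J[, j] <- as.vector(sf$Fx * dSx[, j] + sf$Fy * dSy[, j])
      r <- fvec - lev$a0
      # Joint (shape, appearance) normal equations, reduced by a Schur
      # complement on the appearance block (A orthonormal): both the
      # simultaneous and the project-out update solve
      #   (J'J - (J'A)(J'A)') dq = -(J'r - (J'A)(A'r))
      # with r the current residual (appearance-corrected for simultaneous).
      if (simultaneous && k_app > 0) {
        if (is.null(lam) || length(lam) != k_app)
          lam <- as.vector(crossprod(A, r))
        r_cur <- as.vector(r - A %*% lam)
      } else r_cur <- r
      JtJ <- crossprod(J)
      Jtr <- as.vector(crossprod(J, r_cur))
      if (k_app > 0) {
        JtA <- crossprod(J, A)
        alpha <- as.vector(crossprod(A, r_cur))
        S <- JtJ - tcrossprod(JtA)
        rhs <- Jtr - as.vector(JtA %*% alpha)
      } else { S <- JtJ; rhs <- Jtr }
      dq <- tryCatch(as.vector(-solve(S + diag(1e-8, np), rhs)),
                     error = function(e) NULL)
      if (is.null(dq)) break
      dlam <- if (simultaneous && k_app > 0)
        as.vector(crossprod(JtA, dq)) + alpha else NULL
      # backtracking: accept only non-increasing cost
      step <- 1
      accepted <- FALSE
      for (h in 1:5) {
        q_new <- q + step * dq[1:4]
        bs_new <- if (sm$k > 0) bs + step * dq[5:(4 + sm$k)] else bs
        cost_new <- eval_cost(q_new, bs_new)
        if (cost_new <= cost + 1e-12) {
          q <- q_new; bs <- bs_new; cost <- cost_new
          if (!is.null(dlam)) lam <- lam + step * dlam
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
      if (sqrt(sum((step * dq)^2)) < 1e-4) { converged <- TRUE; break }
    }
    final_cost <- cost
    lam <- NULL
  }
  shape <- shape68(aam_shape_from_params(sm, q, bs))
  fit_result(shape, converged, total_iters, final_cost)
}
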