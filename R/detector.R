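# Sliding-window HOG-SVM face detection with an image pyramid, hard-negative
# mining and greedy non-maximum suppression.

#' Detection result
#' @param box A `bounding_box` in frame coordinates.
#' @param score Linear SVM decision value.
#' @return An object of class `detection`.
#' @export
detection <- function(box, score) {
  structure(list(box = box, score = as.numeric(score)), class = "detection")
}

# Sample a square window from an arbitrary box, resampled to spec$window px.
box_patch <- function(pixels, box, window) {
  sq <- square_box(box)
  xs <- sq$x0 + (seq_len(window) - 0.5) * sq$width / window - 0.5
  ys <- sq$y0 + (seq_len(window) - 0.5) * sq$height / window - 0.5
  prep <- bilinear_prep(dim(pixels), rep(xs, each = window),
                        rep.int(ys, window))
  matrix(bilinear_apply(pixels, prep), window, window)
}

#' Train the sliding-window face detector
#'
#' Positives are the face boxes of the training frames, resampled to the HOG
#' window; initial negatives are random background windows; a linear SVM is
#' fit, and each hard-negative round runs the current detector over the
#' background frames and appends its false positives to the negative set.
#' Finally the score threshold is calibrated on held-out background frames to
#' a fixed false-positive budget.
#'
#' @param faces List of `annotated_frame` with `face_box` (>= 20).
#' @param backgrounds List of face-free `thermal_frame` (>= 20).
#' @param spec A [hog_spec()].
#' @param n_hard_negative_rounds Mining rounds (default 2).
#' @param n_initial_negatives Random negative windows drawn per background.
#' @param scales Image pyramid scale factors (window side multipliers).
#' @param nms_iou Non-maximum suppression overlap threshold.
#' @param cost SVM regularization constant.
#' @param calibration_backgrounds Held-out backgrounds for threshold
#'   calibration (defaults to the training backgrounds, with a warning-free
#'   fallback documented in the vignette).
#' @param fp_budget Calibrated false-positive budget, detections per
#'   background frame (default 0.1 = one per ten frames).
#' @param seed Integer seed controlling negative sampling.
#' @return An object of class `detector_model`.
#' @export
train_detector <- function(faces, backgrounds, spec = hog_spec(),
                           n_hard_negative_rounds = 2,
                           n_initial_negatives = 8,
                           scales = 1.2^(0:4), nms_iou = 0.3, cost = 1,
                           calibration_backgrounds = NULL, fp_budget = 0.1,
                           seed = 1L) {
  if (length(faces) < 20 || length(backgrounds) < 20)
    stop_training("train_detector: need >= 20 positives and >= 20 backgrounds")
  win <- spec$window
  with_seed(seed, {
    pos <- t(vapply(faces, function(af)
      compute_hog(box_patch(af$frame$pixels, af$face_box, win), spec),
      numeric(hog_descriptor_length(spec))))
    neg <- list()
    for (bg in backgrounds) {
      h <- nrow(bg$pixels); w <- ncol(bg$pixels)
      for (j in seq_len(n_initial_negatives)) {
        side <- stats::runif(1, win, min(h, w))
        bx <- bounding_box(stats::runif(1, 0, w - side),
                           stats::runif(1, 0, h - side), side, side)
        neg[[length(neg) + 1L]] <- compute_hog(box_patch(bg$pixels, bx, win),
                                               spec)
      }
    }
    neg <- do.call(rbind, neg)
    fit_svm <- function(P, N) {
      X <- rbind(P, N)
      y <- factor(c(rep("face", nrow(P)), rep("bg", nrow(N))),
                  levels = c("face", "bg"))
      m <- e1071::svm(X, y, kernel = "linear", scale = FALSE, cost = cost)
      w_vec <- as.vector(t(m$coefs) %*% m$SV)
      b <- -m$rho
      # e1071 orients the decision value toward the first factor level seen
      # in the data; enforce "face" positive.
      if (m$labels[1] != 1) { w_vec <- -w_vec; b <- -b }
      pred <- X %*% w_vec + b
      if (mean(pred[y == "face"]) < mean(pred[y == "bg"])) {
        w_vec <- -w_vec; b <- -b
      }
      list(w = w_vec, b = b)
    }
    sv <- fit_svm(pos, neg)
    model <- structure(list(hog = spec, weights = sv$w, bias = sv$b,
                            scales = scales, score_threshold = 0,
                            nms_iou = nms_iou),
                       class = "detector_model")
    for (round in seq_len(n_hard_negative_rounds)) {
      hard <- list()
      for (bg in backgrounds) {
        dets <- detect_faces(bg, model, threshold = 0)
        for (d in dets)
          hard[[length(hard) + 1L]] <-
            compute_hog(box_patch(bg$pixels, d$box, win), spec)
      }
      if (length(hard) == 0) break
      neg <- rbind(neg, do.call(rbind, hard))
      sv <- fit_svm(pos, neg)
      model$weights <- sv$w
      model$bias <- sv$b
    }
    calib <- if (is.null(calibration_backgrounds)) backgrounds else
      calibration_backgrounds
    scores <- unlist(lapply(calib, function(bg)
      vapply(detect_faces(bg, model, threshold = -Inf), `[[`, numeric(1),
             "score")))
    allowed <- floor(fp_budget * length(calib))
    thr <- if (length(scores) <= allowed) 0 else {
      s <- sort(scores, decreasing = TRUE)
      s[allowed + 1] + 1e-9
    }
    model$score_threshold <- max(thr, 0)
    model
  })
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model: %d-px window, %d features, threshold %.3f>\n",
              x$hog$window, length(x$weights), x$score_threshold))
  invisible(x)
}

#' Serialize a detector model to JSON
#' @param model A `detector_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detector <- function(model, path) {
  obj <- list(hog = unclass(model$hog), weights = model$weights,
              bias = model$bias, scales = model$scales,
              score_threshold = model$score_threshold,
              nms_iou = model$nms_iou)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a detector model written by [write_detector()]
#' @param path JSON path.
#' @return A `detector_model`.
#' @export
read_detector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(hog = do.call(hog_spec, obj$hog),
                 weights = as.numeric(obj$weights),
                 bias = as.numeric(obj$bias),
                 scales = as.numeric(obj$scales),
                 score_threshold = as.numeric(obj$score_threshold),
                 nms_iou = as.numeric(obj$nms_iou)),
            class = "detector_model")
}

#' Detect faces in a frame
#'
#' Slides the HOG window with stride equal to the cell size over every
#' pyramid scale, keeps windows scoring at or above the threshold, maps the
#' boxes back to frame coordinates and applies non-maximum suppression.
#'
#' @param frame A `thermal_frame` (or pixel matrix).
#' @param model A `detector_model`.
#' @param threshold Score threshold (default: the model's calibrated one).
#' @return List of `detection`, sorted by descending score (possibly empty).
#' @export
detect_faces <- function(frame, model, threshold = NULL) {
  pixels <- if (inherits(frame, "thermal_frame")) frame$pixels else
    as.matrix(frame)
  if (is.null(threshold)) threshold <- model$score_threshold
  spec <- model$hog
  win <- spec$window; cell <- spec$cell
  wc <- win %/% cell; bw <- wc - spec$block + 1L
  dets <- list()
  for (s in model$scales) {
    nh <- floor(nrow(pixels) / s); nw <- floor(ncol(pixels) / s)
    if (nh < win || nw < win) next
    img <- if (s == 1) pixels else bilinear_resize(pixels, nh, nw)
    blocks <- hog_block_normalize(hog_cell_histograms(img, spec), spec)
    nby <- dim(blocks)[1]; nbx <- dim(blocks)[2]
    for (bj in seq_len(nbx - bw + 1L)) {
      for (bi in seq_len(nby - bw + 1L)) {
        d <- hog_window_descriptor(blocks, spec, bi, bj)
        sc <- sum(d * model$weights) + model$bias
        if (sc >= threshold) {
          x0 <- (bj - 1L) * cell * s
          y0 <- (bi - 1L) * cell * s
          dets[[length(dets) + 1L]] <-
            detection(bounding_box(x0, y0, win * s, win * s), sc)
        }
      }
    }
  }
  nms(dets, model$nms_iou)
}

#' Greedy non-maximum suppression
#'
#' Keeps detections in order of descending score, suppressing any box whose
#' IoU with an already-kept box exceeds `nms_iou`. Score ties break toward
#' the smaller (y0, x0) corner, so the result is independent of input order.
#'
#' @param detections List of `detection`.
#' @param nms_iou Overlap threshold in (0, 1).
#' @return Filtered list, score-descending.
#' @export
nms <- function(detections, nms_iou = 0.3) {
  if (length(detections) <= 1) return(detections)
  sc <- vapply(detections, `[[`, numeric(1), "score")
  y0 <- vapply(detections, function(d) d$box$y0, numeric(1))
  x0 <- vapply(detections, function(d) d$box$x0, numeric(1))
  ord <- order(-sc, y0, x0)
  kept <- list()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) if (iou(detections[[i]]$box, k$box) > nms_iou) {
      ok <- FALSE; break
    }
    if (ok) kept[[length(kept) + 1L]] <- detections[[i]]
  }
  kept
}
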