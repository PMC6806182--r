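# Analysis heads: contactless respiratory signal extraction from the nostril
# ROI of frontalized faces, and four-class emotion recognition from HOG
# features of the landmark-cropped face with a random forest.

#' Crop a face to its landmark bounding box plus a margin
#'
#' The landmark box is expanded by `margin * width` on the left and right and
#' `margin * height` on the top and bottom, so the outer face contour is well
#' within the crop. Out-of-frame area is zero-padded, making the output size
#' depend only on the landmarks, not the frame borders.
#'
#' @param frame A `thermal_frame` (or pixel matrix).
#' @param shape A `shape68`.
#' @param margin Expansion fraction per side (default 0.10).
#' @return List with `pixels` (the crop) and `box` (the expanded
#'   `bounding_box` in frame coordinates).
#' @export
crop_with_margin <- function(frame, shape, margin = 0.10) {
  pixels <- if (inherits(frame, "thermal_frame")) frame$pixels else
    as.matrix(frame)
  b <- shape_bbox(shape)
  eb <- bounding_box(b$x0 - margin * b$width, b$y0 - margin * b$height,
                     b$width * (1 + 2 * margin), b$height * (1 + 2 * margin))
  wd <- max(2L, as.integer(round(eb$width)))
  ht <- max(2L, as.integer(round(eb$height)))
  xs <- eb$x0 + (seq_len(wd) - 0.5) * eb$width / wd - 0.5
  ys <- eb$y0 + (seq_len(ht) - 0.5) * eb$height / ht - 0.5
  g <- expand.grid(y = ys, x = xs)
  smp <- bilinear_sample(pixels, g$x, g$y)
  v <- smp$values
  v[!smp$inside] <- 0
  list(pixels = matrix(v, ht, wd), box = eb)
}

#' Emotion-recognition feature vector of a face crop
#'
#' The crop is bilinearly resized to `crop_size` x `crop_size` and described
#' by HOG. Output length is fixed by the HOG spec (8100 for a 128-px crop
#' with 8-px cells, 2x2 blocks and 9 bins).
#'
#' @param crop Pixel matrix (any size).
#' @param hog A [hog_spec()] whose `window` equals the resize target.
#' @return Numeric feature vector.
#' @export
extract_emotion_features <- function(crop, hog = hog_spec(window = 128L)) {
  resized <- bilinear_resize(as.matrix(crop), hog$window, hog$window)
  compute_hog(resized, hog)
}

#' Train the four-class emotion classifier
#'
#' HOG features from margin-expanded landmark crops feed a seeded random
#' forest (1000 trees by default). All four classes must be present with at
#' least 10 samples each.
#'
#' @param frames List of `annotated_frame` with `shape` and `emotion`.
#' @param n_trees Number of trees.
#' @param crop_size HOG resize target (pixels).
#' @param margin Crop margin fraction.
#' @param seed Integer seed (forest growth is deterministic given it).
#' @return An object of class `emotion_model`.
#' @export
train_emotion <- function(frames, n_trees = 1000L, crop_size = 128L,
                          margin = 0.10, seed = 1L) {
  classes <- emotion_classes()
  labels <- vapply(frames, `[[`, character(1), "emotion")
  if (!all(classes %in% labels))
    stop_training("train_emotion: all four classes must be present")
  if (min(table(factor(labels, levels = classes))) < 10)
    stop_training("train_emotion: need >= 10 samples per class")
  spec <- hog_spec(cell = 8L, block = 2L, n_orientations = 9L,
                   window = as.integer(crop_size))
  X <- t(vapply(frames, function(af)
    extract_emotion_features(crop_with_margin(af$frame, af$shape,
                                              margin)$pixels, spec),
    numeric(hog_descriptor_length(spec))))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- factor(labels, levels = classes)
  forest <- ranger::ranger(x = X, y = y, num.trees = as.integer(n_trees),
                           probability = TRUE, seed = as.integer(seed),
                           num.threads = 1L)
  structure(list(classes = classes, n_trees = as.integer(n_trees),
                 hog = spec, crop_size = as.integer(crop_size),
                 margin = margin, forest = forest, seed = as.integer(seed)),
            class = "emotion_model")
}

#' @export
print.emotion_model <- function(x, ...) {
  cat(sprintf("<emotion_model: %d trees, %d-px crop, classes %s>\n",
              x$n_trees, x$crop_size, paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Classify the emotion of a face
#'
#' Crops the face around the given landmarks, extracts HOG features and
#' returns the forest's vote shares as class probabilities. The label is the
#' argmax; ties break toward the earlier class in the declared order.
#'
#' @param model An `emotion_model`.
#' @param frame A `thermal_frame`.
#' @param shape A `shape68` (ground-truth or tracked landmarks).
#' @return List with `label` and `probabilities` (named, sums to 1).
#' @export
classify_emotion <- function(model, frame, shape) {
  if (is.null(model$forest)) stop_input("classify_emotion: untrained model")
  f <- extract_emotion_features(crop_with_margin(frame, shape,
                                                 model$margin)$pixels,
                                model$hog)
  x <- matrix(f, 1, dimnames = list(NULL, paste0("f", seq_along(f))))
  p <- stats::predict(model$forest, data = as.data.frame(x),
                      num.threads = 1L)$predictions[1, ]
  p <- p[model$classes]
  label <- model$classes[which.max(p)]
  list(label = label, probabilities = p)
}

#' Respiratory signal from a sequence of frontalized faces
#'
#' Per frame, the mean nostril-ROI value is extracted; samples whose ROI
#' valid fraction falls below 0.5 are flagged invalid and linearly
#' interpolated from their neighbours (flags preserved) so the series stays
#' uniformly sampled for spectral analysis.
#'
#' @param faces List of `frontalized_face`.
#' @param roi A resolved `roi_spec` (e.g. `default_rois(cf)$nostrils`).
#' @param frame_rate Frames per second.
#' @param calibration Optional list(gain, offset) for Kelvin output.
#' @return An object of class `resp_signal`: list(values, times, frame_rate,
#'   valid).
#' @export
respiratory_signal <- function(faces, roi, frame_rate, calibration = NULL) {
  if (length(faces) < 1) stop_input("respiratory_signal: no faces")
  vals <- numeric(length(faces)); valid <- logical(length(faces))
  for (i in seq_along(faces)) {
    r <- extract_roi(faces[[i]], roi, calibration)
    vals[i] <- r$mean_value
    valid[i] <- is.finite(r$mean_value) && r$valid_fraction >= 0.5
  }
  if (!any(valid))
    stop(errorCondition("respiratory_signal: all samples invalid",
                        class = c("thermoface_signal_error",
                                  "thermoface_error")))
  if (any(!valid)) {
    idx <- which(valid)
    vals <- stats::approx(idx, vals[idx], xout = seq_along(vals),
                          rule = 2)$y
  }
  structure(list(values = vals,
                 times = (seq_along(vals) - 1) / frame_rate,
                 frame_rate = frame_rate, valid = valid),
            class = "resp_signal")
}

#' @export
print.resp_signal <- function(x, ...) {
  cat(sprintf("<resp_signal: %d samples at %g Hz (%.1f s), %d invalid>\n",
              length(x$values), x$frame_rate,
              length(x$values) / x$frame_rate, sum(!x$valid)))
  invisible(x)
}

#' Estimate the respiratory rate from a nostril-temperature signal
#'
#' Linear detrend, Hann window, zero-padded periodogram; the rate is 60 times
#' the peak frequency inside the physiological band. If the spectral peak is
#' not prominent (below 3 times the median band power) the estimate is
#' refused and `NA` returned. This estimator goes beyond plain signal
#' extraction and is documented as an extension in the methods vignette.
#'
#' @param signal A `resp_signal` covering at least 30 s.
#' @param band `c(min_hz, max_hz)` search band (default 0.1-1.0 Hz, i.e.
#'   6-60 breaths/min).
#' @param pad_factor Zero-padding multiple for finer frequency resolution.
#' @return Breaths per minute, or `NA` if no prominent peak.
#' @export
estimate_rate <- function(signal, band = c(0.1, 1.0), pad_factor = 4L) {
  n <- length(signal$values)
  if (n / signal$frame_rate < 30)
    stop_input("estimate_rate: need at least 30 s of signal")
  t <- signal$times
  v <- stats::residuals(stats::lm(signal$values ~ t))
  if (stats::sd(v) < 1e-12 * (1 + stats::sd(signal$values)))
    return(NA_real_)   # flat signal: no oscillation to rate
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  vw <- v * w
  nfft <- pad_factor * 2^ceiling(log2(n))
  sp <- Mod(stats::fft(c(vw, numeric(nfft - n))))^2
  freqs <- (seq_len(nfft) - 1) * signal$frame_rate / nfft
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) return(NA_real_)
  pb <- sp[in_band]; fb <- freqs[in_band]
  pk <- which.max(pb)
  if (pb[pk] < 3 * stats::median(pb)) return(NA_real_)
  60 * fb[pk]
}

#' Detect apnoea (breathing-pause) segments in a respiratory signal
#'
#' Sliding-window (stride 1 s) standard deviation; windows whose deviation
#' falls below `k` times the global signal deviation are merged into maximal
#' segments, and segments shorter than 5 s are discarded. An operational
#' version of the visual flat-segment reading of such signals, documented as
#' an extension.
#'
#' @param signal A `resp_signal` at least two windows long.
#' @param window_s Window length, seconds.
#' @param k Fraction of the global standard deviation acting as flatness
#'   threshold.
#' @return data.frame with columns `start_s`, `end_s` (possibly 0 rows),
#'   disjoint and sorted.
#' @export
detect_apnoea <- function(signal, window_s = 10, k = 0.25) {
  fr <- signal$frame_rate
  n <- length(signal$values)
  dur <- n / fr
  if (dur < 2 * window_s)
    stop_input("detect_apnoea: signal shorter than two windows")
  t <- signal$times
  v <- stats::residuals(stats::lm(signal$values ~ t))
  g_sd <- stats::sd(v)
  starts <- seq(0, dur - window_s, by = 1)
  flat <- vapply(starts, function(s0) {
    idx <- t >= s0 & t < s0 + window_s
    stats::sd(v[idx]) <= k * g_sd   # <=: an all-flat signal is all-apnoea
  }, logical(1))
  if (!any(flat)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  segs <- list()
  i <- 1
  while (i <= length(flat)) {
    if (flat[i]) {
      j <- i
      while (j < length(flat) && flat[j + 1]) j <- j + 1
      segs[[length(segs) + 1L]] <- c(starts[i], starts[j] + window_s)
      i <- j + 1
    } else i <- i + 1
  }
  out <- do.call(rbind, segs)
  out <- data.frame(start_s = out[, 1], end_s = pmin(out[, 2], dur))
  out[out$end_s - out$start_s >= 5, , drop = FALSE]
}

#' Jaccard overlap of two time intervals
#' @param a,b Length-2 numeric `c(start, end)`.
#' @return Intersection over union of the intervals, in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- max(a[2], b[2]) - min(a[1], b[1])
  if (uni <= 0) return(0)
  inter / uni
}
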