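# Synthetic thermal-face generator.
#
# Emulates the statistical structure of annotated thermal face databases:
# a face markedly warmer than the background, 68 semantically indexed
# landmarks, per-frame rigid head motion, nostril-temperature oscillation
# synchronized with breathing, and emotion-dependent landmark deformation.
# Appearance is built from anisotropic Gaussian kernels anchored on the
# (deformed) landmark template, so expression changes move both geometry and
# texture, and the nostril warmth follows the nostril landmarks.

# Base 68-point frontal template, canonical units: x right, y down,
# face half-height ~1, centered near the nose. Inter-ocular distance 0.96.
template_base_points <- function() {
  pts <- matrix(NA_real_, 68, 2)
  phi <- pi * (0:16) / 16
  pts[1:17, ] <- cbind(-0.78 * cos(phi), -0.15 + 1.05 * sin(phi))    # jaw
  browx <- seq(-0.58, -0.12, length.out = 5)
  browy <- c(-0.50, -0.555, -0.575, -0.555, -0.50)
  pts[18:22, ] <- cbind(browx, browy)                                 # brow L
  pts[23:27, ] <- cbind(rev(-browx), rev(browy))                      # brow R
  pts[28:31, ] <- cbind(0, c(-0.40, -0.225, -0.05, 0.12))             # bridge
  pts[32:36, ] <- cbind(c(-0.16, -0.08, 0, 0.08, 0.16),
                        c(0.20, 0.225, 0.24, 0.225, 0.20))            # nose base
  eye <- cbind(c(-0.48, -0.40, -0.28, -0.20, -0.28, -0.40),
               c(-0.35, -0.395, -0.395, -0.35, -0.305, -0.305))
  pts[37:42, ] <- eye                                                 # eye L
  pts[43:48, ] <- cbind(-eye[c(4, 3, 2, 1, 6, 5), 1],
                        eye[c(4, 3, 2, 1, 6, 5), 2])                  # eye R
  pts[49:60, ] <- cbind(c(-0.28, -0.18, -0.07, 0, 0.07, 0.18, 0.28,
                          0.18, 0.07, 0, -0.07, -0.18),
                        c(0.50, 0.44, 0.41, 0.42, 0.41, 0.44, 0.50,
                          0.58, 0.62, 0.63, 0.62, 0.58))              # mouth out
  pts[61:68, ] <- cbind(c(-0.22, -0.08, 0, 0.08, 0.22, 0.08, 0, -0.08),
                        c(0.50, 0.47, 0.48, 0.47, 0.50, 0.55, 0.56, 0.55))
  pts
}

#' Canonical identity template
#'
#' Returns a frontal 68-point template in canonical coordinates (face
#' half-height ~1, y down) together with the appearance parameters of the
#' thermal texture: warm periorbital and inner-canthus regions, a warm
#' nostril band under the nose base, a cooler nose tip and hair line. The
#' identity seed perturbs the landmark template by a smooth displacement
#' field bounded by 3% of the inter-ocular distance per point.
#'
#' @param identity_seed Integer; same seed gives the identical template.
#' @return List with `points` (68 x 2 canonical landmarks) and `appearance`
#'   (kernel weights/scales used by [render_face()]).
#' @export
canonical_template <- function(identity_seed = 1L) {
  base <- template_base_points()
  iod <- sqrt(sum((base[37, ] - base[46, ])^2))
  pts <- with_seed(identity_seed, {
    # smooth low-frequency displacement field, per-point norm <= 3% IOD
    coef <- matrix(stats::rnorm(12), 3, 4)  # 3 harmonics x (ax, bx, ay, by)
    freq <- matrix(stats::runif(12, 0.8, 2.6), 3, 4)
    phase <- matrix(stats::runif(12, 0, 2 * pi), 3, 4)
    amp_frac <- stats::runif(1, 0.5, 1)
    dx <- dy <- numeric(68)
    for (j in 1:3) {
      dx <- dx + coef[j, 1] * sin(freq[j, 1] * base[, 1] +
                                  freq[j, 2] * base[, 2] + phase[j, 1])
      dy <- dy + coef[j, 3] * sin(freq[j, 3] * base[, 1] +
                                  freq[j, 4] * base[, 2] + phase[j, 3])
    }
    nrm <- sqrt(dx^2 + dy^2)
    target <- 0.03 * iod * amp_frac
    sc <- target / max(nrm, 1e-12)
    base + cbind(dx, dy) * sc
  })
  appearance <- list(
    base = 0.55,
    eye_w = 0.30, eye_floor = 0.045, canthus_w = 0.45, canthus_sigma = 0.05,
    nostril_w = 0.45, nostril_floor = 0.05,
    tip_w = -0.35, tip_sigma = 0.07,
    brow_w = -0.20, brow_floor = 0.035,
    mouth_w = 0.25, mouth_floor = 0.045,
    hair_w = -0.40, hair_v = -0.70, hair_edge = 0.06,
    ellipse = c(rx = 0.82, ry = 1.08, cy = 0.02, edge = 0.04))
  list(points = pts, appearance = appearance, iod = iod)
}

#' Emotion-dependent landmark deformation
#'
#' Applied to the canonical template before the pose transform. Class
#' displacements are 12% of the inter-ocular distance (well above the 10%
#' separability floor): happy raises and spreads the mouth corners, surprised
#' raises the brows and opens the mouth, sad lowers the mouth corners and
#' raises the inner brows; neutral is the identity.
#'
#' @param points 68 x 2 canonical landmarks.
#' @param emotion One of "neutral", "happy", "sad", "surprised".
#' @param iod Inter-ocular distance of `points` (computed if missing).
#' @return Deformed 68 x 2 matrix.
#' @export
emotion_deform <- function(points, emotion = "neutral", iod = NULL) {
  emotion <- match.arg(emotion, emotion_classes())
  if (is.null(iod)) iod <- sqrt(sum((points[37, ] - points[46, ])^2))
  d <- 0.12 * iod
  p <- points
  if (emotion == "happy") {
    p[49, ] <- p[49, ] + c(-d, -d)      # mouth corners up and outward
    p[55, ] <- p[55, ] + c(d, -d)
    p[c(61, 65), 2] <- p[c(61, 65), 2] - 0.6 * d
    p[50:54, 2] <- p[50:54, 2] - d / 3
  } else if (emotion == "surprised") {
    p[18:27, 2] <- p[18:27, 2] - d      # brows raised
    p[56:60, 2] <- p[56:60, 2] + d      # lower lip drops: aperture grows
    p[66:68, 2] <- p[66:68, 2] + 0.8 * d
  } else if (emotion == "sad") {
    p[c(49, 55), 2] <- p[c(49, 55), 2] + d        # mouth corners down
    p[c(21, 22, 23, 24), 2] <- p[c(21, 22, 23, 24), 2] - 0.7 * d  # inner brows
  }
  p
}

#' The fixed emotion label set
#' @return Character vector of the four class labels, in canonical order.
#' @export
emotion_classes <- function() c("neutral", "happy", "sad", "surprised")

#' Synthesis parameters for one face
#'
#' @param center (x, y) face center in image pixels (NULL = image center).
#' @param scale Face half-height in pixels.
#' @param rotation In-plane rotation, radians.
#' @param shear_x Horizontal shear (out-of-plane rotation surrogate),
#'   absolute value at most 0.3.
#' @param emotion One of [emotion_classes()].
#' @param identity_seed Integer identity selector.
#' @param ambient_level,face_level Background / face intensity (intensity
#'   units; `face_level` must exceed `ambient_level`).
#' @return An object of class `face_params`.
#' @export
face_params <- function(center = NULL, scale = 45, rotation = 0, shear_x = 0,
                        emotion = "neutral", identity_seed = 1L,
                        ambient_level = 1500, face_level = 3500) {
  if (abs(shear_x) > 0.3) stop_input("face_params: |shear_x| must be <= 0.3")
  if (face_level <= ambient_level)
    stop_input("face_params: face_level must exceed ambient_level")
  structure(list(center = center, scale = as.numeric(scale),
                 rotation = as.numeric(rotation), shear_x = as.numeric(shear_x),
                 emotion = match.arg(emotion, emotion_classes()),
                 identity_seed = as.integer(identity_seed),
                 ambient_level = as.numeric(ambient_level),
                 face_level = as.numeric(face_level)),
            class = "face_params")
}

# Anisotropic Gaussian kernel parameters from a landmark subset: center =
# centroid, covariance = point covariance inflated and floored.
aniso_kernel <- function(pts, floor_sigma, weight, inflate = 1.3) {
  ctr <- colMeans(pts)
  if (nrow(pts) > 1) {
    C <- stats::cov(pts) * inflate + diag(floor_sigma^2, 2)
  } else C <- diag(floor_sigma^2, 2)
  list(center = ctr, inv = solve(C), weight = weight)
}

# Build the kernel list for a deformed template (canonical coordinates).
appearance_kernels <- function(pts, app, breath = 0) {
  k <- list(
    aniso_kernel(pts[37:42, , drop = FALSE], app$eye_floor, app$eye_w),
    aniso_kernel(pts[43:48, , drop = FALSE], app$eye_floor, app$eye_w),
    aniso_kernel(pts[40, , drop = FALSE], app$canthus_sigma, app$canthus_w),
    aniso_kernel(pts[43, , drop = FALSE], app$canthus_sigma, app$canthus_w),
    aniso_kernel(pts[32:36, , drop = FALSE], app$nostril_floor,
                 app$nostril_w + breath),
    aniso_kernel(pts[31, , drop = FALSE], app$tip_sigma, app$tip_w),
    aniso_kernel(pts[18:22, , drop = FALSE], app$brow_floor, app$brow_w),
    aniso_kernel(pts[23:27, , drop = FALSE], app$brow_floor, app$brow_w),
    aniso_kernel(pts[49:60, , drop = FALSE], app$mouth_floor, app$mouth_w))
  k
}

# Evaluate the thermal texture factor at canonical coordinates (u, v) given
# deformed landmarks; returns values in [0.05, 1.45] times the face mask.
appearance_eval <- function(u, v, pts, app, breath = 0) {
  el <- app$ellipse
  r <- sqrt((u / el["rx"])^2 + ((v + el["cy"]) / el["ry"])^2)
  mask <- 1 / (1 + exp((r - 1) / el["edge"]))
  val <- rep(app$base, length(u))
  live <- mask > 0.002
  if (any(live)) {
    ul <- u[live]; vl <- v[live]
    acc <- numeric(length(ul))
    for (k in appearance_kernels(pts, app, breath)) {
      du <- ul - k$center[1]; dv <- vl - k$center[2]
      q <- k$inv[1, 1] * du^2 + 2 * k$inv[1, 2] * du * dv + k$inv[2, 2] * dv^2
      acc <- acc + k$weight * exp(-0.5 * q)
    }
    acc <- acc + app$hair_w / (1 + exp((vl - app$hair_v) / app$hair_edge))
    val[live] <- val[live] + acc
  }
  pmin(pmax(val, 0.05), 1.45) * mask
}

# Forward pose matrix: canonical -> image offsets (before adding center).
pose_matrix <- function(scale, rotation, shear_x) {
  R <- matrix(c(cos(rotation), sin(rotation),
                -sin(rotation), cos(rotation)), 2, 2)
  S <- matrix(c(1, 0, shear_x, 1), 2, 2)
  scale * R %*% S
}

#' Render one synthetic thermal face
#'
#' Applies the similarity + shear transform to the (identity-perturbed,
#' emotion-deformed) canonical template, rasterizes the landmark-anchored
#' thermal texture with additive Gaussian noise, and returns the frame with
#' the exact transformed landmarks and a detector-style face box.
#'
#' @param params A [face_params()].
#' @param image_size (height, width) in pixels.
#' @param noise_sigma Additive Gaussian noise standard deviation (intensity
#'   units). `face_level - ambient_level` must be at least `5 * noise_sigma`
#'   so faces stay thermally salient.
#' @param breath Instantaneous breathing modulation, as a fraction of the
#'   face-to-ambient contrast added to the nostril-band weight.
#' @param seed Optional integer; if given, rendering is reproducible on its
#'   own (otherwise the current RNG stream is consumed).
#' @return An `annotated_frame`: list(frame, shape, face_box, emotion).
#' @export
render_face <- function(params, image_size = c(160, 160), noise_sigma = 20,
                        breath = 0, seed = NULL) {
  if (params$scale <= 0) stop_input("render_face: scale must be positive")
  if (params$face_level - params$ambient_level < 5 * noise_sigma)
    stop_input("render_face: face/ambient contrast below 5 x noise_sigma")
  if (!is.null(seed)) return(with_seed(seed,
    render_face(params, image_size, noise_sigma, breath, seed = NULL)))
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  center <- if (is.null(params$center)) c((w - 1) / 2, (h - 1) / 2) else
    as.numeric(params$center)
  tpl <- canonical_template(params$identity_seed)
  pts <- emotion_deform(tpl$points, params$emotion, tpl$iod)
  A <- pose_matrix(params$scale, params$rotation, params$shear_x)
  lm <- sweep(pts %*% t(A), 2, -center)  # add center
  Ainv <- solve(A)
  xs <- rep(seq_len(w) - 1, each = h) - center[1]
  ys <- rep.int(seq_len(h) - 1, w) - center[2]
  uc <- Ainv[1, 1] * xs + Ainv[1, 2] * ys
  vc <- Ainv[2, 1] * xs + Ainv[2, 2] * ys
  tex <- appearance_eval(uc, vc, pts, tpl$appearance, breath)
  contrast <- params$face_level - params$ambient_level
  pix <- params$ambient_level + contrast * tex +
    stats::rnorm(h * w, sd = noise_sigma)
  pix <- matrix(pmax(pix, 0), h, w)
  shape <- shape68(lm)
  annotated_frame(thermal_frame(pix), shape = shape,
                  face_box = shape_face_box(shape),
                  emotion = params$emotion)
}

#' Annotated frame container
#'
#' Bundles a frame with whatever annotations exist for it: a 68-point
#' landmark shape, a face box and/or an emotion label. When both shape and
#' box are given they must refer to the same face (their boxes must
#' overlap).
#'
#' @param frame A `thermal_frame`.
#' @param shape Optional `shape68`.
#' @param face_box Optional `bounding_box`.
#' @param emotion Optional label from [emotion_classes()].
#' @return An object of class `annotated_frame`.
#' @export
annotated_frame <- function(frame, shape = NULL, face_box = NULL,
                            emotion = NULL) {
  if (!inherits(frame, "thermal_frame"))
    stop_input("annotated_frame: frame must be a thermal_frame")
  if (!is.null(shape) && !is.null(face_box) &&
      iou(shape_bbox(shape), face_box) <= 0)
    stop_input("annotated_frame: shape and face_box do not overlap")
  if (!is.null(emotion)) emotion <- match.arg(emotion, emotion_classes())
  structure(list(frame = frame, shape = shape, face_box = face_box,
                 emotion = emotion), class = "annotated_frame")
}

#' @export
print.annotated_frame <- function(x, ...) {
  cat(sprintf("<annotated_frame %d x %d%s%s>\n", nrow(x$frame$pixels),
              ncol(x$frame$pixels),
              if (!is.null(x$shape)) ", 68 landmarks" else "",
              if (!is.null(x$emotion)) paste0(", ", x$emotion) else ""))
  invisible(x)
}

#' Sequence synthesis configuration
#'
#' @param n_frames Number of frames.
#' @param frame_rate Frames per second (default 8, typical of low-cost LWIR
#'   cores and ample for the respiratory band).
#' @param breathing_rate Breaths per minute, in (4, 60).
#' @param breathing_amplitude Nostril modulation amplitude in intensity units.
#' @param apnoea_windows List of `c(start_s, end_s)` pauses (modulation frozen
#'   at zero inside them); must lie inside the recording.
#' @param motion_profile "none", "slow" (bounded sinusoidal translation and
#'   rotation) or "complex" (smooth random walk over translation, rotation up
#'   to 25 degrees and shear up to 0.28).
#' @param noise_sigma Additive noise standard deviation (intensity units).
#' @param seed Integer; all randomness in the sequence derives from it.
#' @param image_size (height, width) pixels.
#' @return An object of class `sequence_config`.
#' @export
sequence_config <- function(n_frames = 480, frame_rate = 8,
                            breathing_rate = 15, breathing_amplitude = 300,
                            apnoea_windows = list(), motion_profile = "none",
                            noise_sigma = 20, seed = 1L,
                            image_size = c(160, 160)) {
  motion_profile <- match.arg(motion_profile, c("none", "slow", "complex"))
  if (breathing_rate <= 4 || breathing_rate >= 60)
    stop_input("sequence_config: breathing_rate must be in (4, 60)")
  dur <- n_frames / frame_rate
  for (wnd in apnoea_windows)
    if (wnd[1] < 0 || wnd[2] > dur || wnd[1] >= wnd[2])
      stop_input("sequence_config: apnoea window outside recording")
  structure(list(n_frames = as.integer(n_frames),
                 frame_rate = as.numeric(frame_rate),
                 breathing_rate = as.numeric(breathing_rate),
                 breathing_amplitude = as.numeric(breathing_amplitude),
                 apnoea_windows = apnoea_windows,
                 motion_profile = motion_profile,
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed),
                 image_size = as.integer(image_size)),
            class = "sequence_config")
}

# Smooth bounded random walk, length n, |x| <= bound, zero-mean-ish.
smooth_walk <- function(n, bound, smooth_n) {
  smooth_n <- min(smooth_n, max(1L, n %/% 2L))
  x <- cumsum(stats::rnorm(n))
  if (smooth_n > 1) x <- stats::filter(x, rep(1 / smooth_n, smooth_n),
                                       sides = 2)
  x <- as.numeric(x)
  x[is.na(x)] <- 0
  x <- x - mean(x)
  m <- max(abs(x), 1e-12)
  x / m * bound
}

#' Generate a synthetic thermal video with breathing and head motion
#'
#' Per frame, the nostril-band intensity of the canonical template is
#' modulated by `A sin(2 pi f t)` with `f = breathing_rate / 60`, frozen at
#' zero inside apnoea windows. Head motion follows `motion_profile`. All
#' randomness (motion and pixel noise) derives from `config$seed`, so equal
#' configurations reproduce bit-identical sequences.
#'
#' @param config A [sequence_config()].
#' @param params A [face_params()] for the subject.
#' @return List of `annotated_frame`; attribute `ground_truth` holds a
#'   data.frame with per-frame time, programmed breathing modulation
#'   (intensity units) and pose.
#' @export
generate_sequence <- function(config, params = face_params()) {
  with_seed(config$seed, {
    n <- config$n_frames; fr <- config$frame_rate
    h <- config$image_size[1]; w <- config$image_size[2]
    t <- (seq_len(n) - 1) / fr
    center0 <- if (is.null(params$center)) c((w - 1) / 2, (h - 1) / 2) else
      params$center
    mp <- config$motion_profile
    if (mp == "none") {
      dx <- dy <- rot <- shr <- numeric(n)
    } else if (mp == "slow") {
      dx <- 0.08 * w * sin(2 * pi * t / 17)
      dy <- 0.06 * h * sin(2 * pi * t / 23 + 1)
      rot <- (8 * pi / 180) * sin(2 * pi * t / 19 + 2)
      shr <- 0.10 * sin(2 * pi * t / 29)
    } else {
      sm <- max(3L, as.integer(2 * fr))
      dx <- smooth_walk(n, 0.12 * w, sm)
      dy <- smooth_walk(n, 0.10 * h, sm)
      rot <- smooth_walk(n, 25 * pi / 180, sm)
      shr <- smooth_walk(n, 0.28, sm)
    }
    f_hz <- config$breathing_rate / 60
    breath <- config$breathing_amplitude * sin(2 * pi * f_hz * t)
    for (wnd in config$apnoea_windows)
      breath[t >= wnd[1] & t < wnd[2]] <- 0
    contrast <- params$face_level - params$ambient_level
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      pi_ <- params
      pi_$center <- center0 + c(dx[i], dy[i])
      pi_$rotation <- params$rotation + rot[i]
      pi_$shear_x <- max(-0.3, min(0.3, params$shear_x + shr[i]))
      af <- render_face(pi_, image_size = c(h, w),
                        noise_sigma = config$noise_sigma,
                        breath = breath[i] / contrast)
      af$frame$timestamp <- t[i]
      af$frame$frame_index <- i - 1L
      frames[[i]] <- af
    }
    attr(frames, "ground_truth") <- data.frame(
      time_s = t, breath = breath, dx = dx, dy = dy,
      rotation = rot, shear = shr)
    frames
  })
}

#' Generate a balanced labeled face dataset plus background frames
#'
#' Faces vary in identity, pose and scale with balanced emotion classes;
#' background frames contain warm non-face distractor blobs for hard-negative
#' mining.
#'
#' @param n_per_class Faces per emotion class (>= 1).
#' @param n_background Face-free background frames.
#' @param seed Integer master seed.
#' @param image_size (height, width) pixels.
#' @param noise_sigma Additive noise standard deviation.
#' @return List with `faces` (list of `annotated_frame`, length
#'   `4 * n_per_class`) and `backgrounds` (list of `thermal_frame`).
#' @export
generate_dataset <- function(n_per_class, n_background, seed = 1L,
                             image_size = c(160, 160), noise_sigma = 20) {
  if (n_per_class < 1) stop_input("generate_dataset: n_per_class must be >= 1")
  with_seed(seed, {
    h <- image_size[1]; w <- image_size[2]
    faces <- list()
    for (cls in emotion_classes()) {
      for (i in seq_len(n_per_class)) {
        sc <- stats::runif(1, 0.23, 0.33) * min(h, w)
        cx <- stats::runif(1, 1.1 * sc, w - 1 - 1.1 * sc)
        cy <- stats::runif(1, 1.2 * sc, h - 1 - 1.2 * sc)
        p <- face_params(center = c(cx, cy), scale = sc,
                         rotation = stats::runif(1, -0.45, 0.45),
                         shear_x = stats::runif(1, -0.28, 0.28),
                         emotion = cls,
                         identity_seed = sample.int(1e6, 1))
        faces[[length(faces) + 1L]] <- render_face(p, image_size = c(h, w),
                                                   noise_sigma = noise_sigma)
      }
    }
    backgrounds <- lapply(seq_len(n_background), function(i) {
      pix <- matrix(1500 + stats::rnorm(h * w, sd = noise_sigma), h, w)
      nb <- sample(3:7, 1)
      xs <- rep(seq_len(w) - 1, each = h); ys <- rep.int(seq_len(h) - 1, w)
      for (b in seq_len(nb)) {
        ctr <- c(stats::runif(1, 0, w - 1), stats::runif(1, 0, h - 1))
        sx <- stats::runif(1, 5, 30); sy <- stats::runif(1, 5, 30)
        th <- stats::runif(1, 0, pi)
        du <- (xs - ctr[1]) * cos(th) + (ys - ctr[2]) * sin(th)
        dv <- -(xs - ctr[1]) * sin(th) + (ys - ctr[2]) * cos(th)
        amp <- stats::runif(1, 400, 2000)
        pix <- pix + amp * exp(-0.5 * ((du / sx)^2 + (dv / sy)^2))
      }
      thermal_frame(matrix(pmax(pix, 0), h, w), frame_index = i - 1L)
    })
    list(faces = faces, backgrounds = backgrounds)
  })
}
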