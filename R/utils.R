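# Internal numeric helpers shared across modules.
#
# Coordinate convention (package-wide): x = column, y = row, origin at the
# top-left pixel CENTER, 0-based.  A pixel matrix `m` stores the value of the
# pixel at (x, y) in m[y + 1, x + 1].

# Bilinear interpolation of `pixels` at continuous 0-based coordinates.
# Returns list(values, inside): `inside` is TRUE where the sample point lies
# within the image support [0, w-1] x [0, h-1]; outside samples return
# `fill` (default 0).  Coordinates on the boundary are clamped.
bilinear_sample <- function(pixels, x, y, fill = 0) {
  h <- nrow(pixels); w <- ncol(pixels)
  inside <- x >= 0 & x <= (w - 1) & y >= 0 & y <= (h - 1)
  xc <- pmin(pmax(x, 0), w - 1)
  yc <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(xc); y0 <- floor(yc)
  x0 <- pmin(x0, w - 2); y0 <- pmin(y0, h - 2)
  fx <- xc - x0; fy <- yc - y0
  i00 <- y0 + 1 + x0 * h
  v <- (1 - fx) * (1 - fy) * pixels[i00] +
    fx * (1 - fy) * pixels[i00 + h] +
    (1 - fx) * fy * pixels[i00 + 1] +
    fx * fy * pixels[i00 + h + 1]
  v[!inside] <- fill
  list(values = v, inside = inside)
}

# Precompute bilinear interpolation indices and weights for a fixed set of
# sample coordinates, so many maps can be sampled at the same positions
# without redoing the index arithmetic (see bilinear_apply).
bilinear_prep <- function(dim_hw, x, y) {
  h <- dim_hw[1]; w <- dim_hw[2]
  inside <- x >= 0 & x <= (w - 1) & y >= 0 & y <= (h - 1)
  xc <- pmin(pmax(x, 0), w - 1)
  yc <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(xc); y0 <- floor(yc)
  x0 <- pmin(x0, w - 2); y0 <- pmin(y0, h - 2)
  fx <- xc - x0; fy <- yc - y0
  i00 <- as.integer(y0 + 1 + x0 * h)
  list(i00 = i00, h = h,
       w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
       w01 = (1 - fx) * fy, w11 = fx * fy, inside = inside)
}

bilinear_apply <- function(pixels, prep) {
  prep$w00 * pixels[prep$i00] + prep$w10 * pixels[prep$i00 + prep$h] +
    prep$w01 * pixels[prep$i00 + 1L] + prep$w11 * pixels[prep$i00 + prep$h + 1L]
}

# Bilinear resize to (new_h, new_w), sampling at aligned pixel centers.
bilinear_resize <- function(pixels, new_h, new_w) {
  h <- nrow(pixels); w <- ncol(pixels)
  if (new_h == h && new_w == w) return(pixels)
  sy <- h / new_h; sx <- w / new_w
  ys <- (seq_len(new_h) - 0.5) * sy - 0.5
  xs <- (seq_len(new_w) - 0.5) * sx - 0.5
  g <- expand.grid(y = ys, x = xs)
  # edge-replicating: boundary samples clamp rather than read fill values
  matrix(bilinear_apply(pixels, bilinear_prep(dim(pixels), g$x, g$y)),
         new_h, new_w)
}

# 2x decimation with a small anti-alias box filter (used by image pyramids).
pyr_down <- function(pixels) {
  h <- nrow(pixels); w <- ncol(pixels)
  # 2x2 box average then take every other sample
  h2 <- h %/% 2L; w2 <- w %/% 2L
  a <- pixels[seq_len(2L * h2), seq_len(2L * w2), drop = FALSE]
  (a[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2)] +
     a[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2)] +
     a[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2)] +
     a[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2)]) / 4
}

# Image gradients by centered finite differences with replicated borders.
# Returns list(gx, gy) of the same dimension as `pixels`.
image_gradients <- function(pixels) {
  h <- nrow(pixels); w <- ncol(pixels)
  left <- pixels[, c(1L, seq_len(w - 1L)), drop = FALSE]
  right <- pixels[, c(seq_len(w)[-1L], w), drop = FALSE]
  up <- pixels[c(1L, seq_len(h - 1L)), , drop = FALSE]
  down <- pixels[c(seq_len(h)[-1L], h), , drop = FALSE]
  list(gx = (right - left) / 2, gy = (down - up) / 2)
}

# Box blur with an odd kernel side (replicated borders), separable.
box_blur <- function(pixels, side) {
  if (side <= 1L) return(pixels)
  r <- (side - 1L) %/% 2L
  h <- nrow(pixels); w <- ncol(pixels)
  idx <- function(n, k) pmin(pmax(seq_len(n) + k, 1L), n)
  out <- matrix(0, h, w)
  for (k in -r:r) out <- out + pixels[idx(h, k), , drop = FALSE]
  out2 <- matrix(0, h, w)
  for (k in -r:r) out2 <- out2 + out[, idx(w, k), drop = FALSE]
  out2 / (side * side)
}

# Evaluate code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

stop_input <- function(...) stop(errorCondition(paste0(...),
  class = c("thermoface_input_error", "thermoface_error")))
stop_format <- function(...) stop(errorCondition(paste0(...),
  class = c("thermoface_format_error", "thermoface_error")))
stop_training <- function(...) stop(errorCondition(paste0(...),
  class = c("thermoface_training_error", "thermoface_error")))
stop_geometry <- function(...) stop(errorCondition(paste0(...),
  class = c("thermoface_geometry_error", "thermoface_error")))
stop_config <- function(...) stop(errorCondition(paste0(...),
  class = c("thermoface_config_error", "thermoface_error")))
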