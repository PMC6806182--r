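#' HOG descriptor specification
#'
#' Histogram-of-oriented-gradients parameters for the detection window and the
#' emotion features. Defaults are the de-facto standard: 8-px cells, 2x2-cell
#' blocks, 9 unsigned orientation bins, 64-px square window.
#'
#' @param cell Pixels per cell side.
#' @param block Cells per block side.
#' @param n_orientations Number of orientation bins.
#' @param window Square detection-window side in pixels (divisible by `cell`).
#' @param signed If FALSE (default) orientations are folded to 0-180 degrees.
#' @return An object of class `hog_spec`.
#' @export
hog_spec <- function(cell = 8L, block = 2L, n_orientations = 9L,
                     window = 64L, signed = FALSE) {
  cell <- as.integer(cell); block <- as.integer(block)
  n_orientations <- as.integer(n_orientations); window <- as.integer(window)
  if (window %% cell != 0L)
    stop_input("hog_spec: window must be divisible by cell")
  structure(list(cell = cell, block = block, n_orientations = n_orientations,
                 window = window, signed = isTRUE(signed)),
            class = "hog_spec")
}

#' Descriptor length implied by a HOG specification
#'
#' `((window/cell - block + 1)^2) * block^2 * n_orientations`.
#' @param spec A `hog_spec`.
#' @return Integer descriptor length.
#' @export
hog_descriptor_length <- function(spec) {
  nb <- spec$window %/% spec$cell - spec$block + 1L
  as.integer(nb * nb * spec$block^2 * spec$n_orientations)
}

# Per-cell orientation histograms over an image whose cell grid is anchored at
# pixel (0, 0). Gradients are centered finite differences with replicated
# borders; each pixel votes its gradient magnitude into the two orientation
# bins adjacent to its gradient angle (linear interpolation), within the cell
# containing the pixel (no spatial interpolation across cells).
# Returns array [n_cells_y, n_cells_x, n_orientations].
hog_cell_histograms <- function(pixels, spec) {
  cell <- spec$cell; nb <- spec$n_orientations
  h <- nrow(pixels); w <- ncol(pixels)
  ncy <- h %/% cell; ncx <- w %/% cell
  if (ncy < 1L || ncx < 1L) stop_input("hog: image smaller than one cell")
  g <- image_gradients(pixels)
  hh <- ncy * cell; ww <- ncx * cell
  gx <- g$gx[seq_len(hh), seq_len(ww), drop = FALSE]
  gy <- g$gy[seq_len(hh), seq_len(ww), drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  period <- if (spec$signed) 360 else 180
  ang <- (atan2(gy, gx) * 180 / pi) %% period
  binw <- period / nb
  # bin centers at i * binw (i = 0..nb-1): a 0-degree gradient votes wholly
  # into bin 0
  t <- ang / binw
  b0 <- floor(t)
  w1 <- t - b0
  b0 <- ((b0 %% nb) + nb) %% nb          # bin indices 0..nb-1
  b1 <- (b0 + 1) %% nb
  # cell aggregation as two thin 0/1 matrix products per orientation bin
  Sy <- matrix(0, ncy, hh); Sy[cbind((seq_len(hh) - 1L) %/% cell + 1L,
                                     seq_len(hh))] <- 1
  Sx <- matrix(0, ww, ncx); Sx[cbind(seq_len(ww),
                                     (seq_len(ww) - 1L) %/% cell + 1L)] <- 1
  out <- array(0, dim = c(ncy, ncx, nb))
  for (o in 0:(nb - 1L)) {
    w_o <- mag * ((b0 == o) * (1 - w1) + (b1 == o) * w1)
    out[, , o + 1L] <- Sy %*% w_o %*% Sx
  }
  out
}

# L2-Hys block normalization over the cell-histogram array: for every
# block-position (i, j) the block x block cell histograms are concatenated
# (cells in column-major order, bins fastest... see order below), normalized
# v / sqrt(|v|^2 + eps^2), clipped at 0.2 and renormalized.
# Returns array [n_block_y, n_block_x, block^2 * n_orientations].
# Concatenation order within a block: cell (down then right), each cell's
# n_orientations bins contiguous.
hog_block_normalize <- function(cells, spec, eps = 1e-6) {
  blk <- spec$block; nb <- spec$n_orientations
  ncy <- dim(cells)[1]; ncx <- dim(cells)[2]
  nby <- ncy - blk + 1L; nbx <- ncx - blk + 1L
  if (nby < 1L || nbx < 1L) stop_input("hog: fewer cells than one block")
  blen <- blk * blk * nb
  out <- array(0, dim = c(nby, nbx, blen))
  pos <- 0L
  for (cj in seq_len(blk)) for (ci in seq_len(blk)) {
    sl <- cells[ci:(ci + nby - 1L), cj:(cj + nbx - 1L), , drop = FALSE]
    out[, , (pos * nb + 1L):(pos * nb + nb)] <- sl
    pos <- pos + 1L
  }
  flat <- matrix(out, nby * nbx, blen)
  nrm <- sqrt(rowSums(flat^2) + eps^2)
  flat <- flat / nrm
  flat[flat > 0.2] <- 0.2
  nrm2 <- sqrt(rowSums(flat^2) + eps^2)
  flat <- flat / nrm2
  array(flat, dim = c(nby, nbx, blen))
}

# Gather the window descriptor at block offset (bi, bj) (1-based block grid):
# blocks traversed down then right, block vectors concatenated.
hog_window_descriptor <- function(blocks, spec, bi, bj) {
  wc <- spec$window %/% spec$cell
  bw <- wc - spec$block + 1L
  sl <- blocks[bi:(bi + bw - 1L), bj:(bj + bw - 1L), , drop = FALSE]
  # blocks traversed down then right, each block's components contiguous
  as.vector(aperm(sl, c(3, 1, 2)))
}

#' Compute the HOG descriptor of a window-sized patch
#'
#' Gradients by centered finite differences (replicated borders), orientation
#' votes linearly interpolated between adjacent bins, L2-Hys block
#' normalization. A constant patch yields the all-zero descriptor.
#'
#' @param patch Numeric matrix of size `spec$window x spec$window`.
#' @param spec A `hog_spec`.
#' @return Numeric vector of length [hog_descriptor_length()].
#' @export
compute_hog <- function(patch, spec = hog_spec()) {
  patch <- as.matrix(patch)
  if (nrow(patch) != spec$window || ncol(patch) != spec$window)
    stop_input("compute_hog: patch must be ", spec$window, " x ", spec$window)
  cells <- hog_cell_histograms(patch, spec)
  blocks <- hog_block_normalize(cells, spec)
  hog_window_descriptor(blocks, spec, 1L, 1L)
}
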