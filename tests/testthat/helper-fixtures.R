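# Shared fixtures, built lazily once per test run. Unit tests use a small
# synthetic corpus; the acceptance suite builds its own full-size corpus in
# helper-acceptance.R.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_dataset <- function() fixture("dataset", function() {
  generate_dataset(15, 40, seed = 11)
})

fx_detector <- function() fixture("detector", function() {
  ds <- fx_dataset()
  train_detector(ds$faces, ds$backgrounds, n_hard_negative_rounds = 1,
                 seed = 3)
})

fx_regressor <- function() fixture("regressor", function() {
  train_shape_regressor(fx_dataset()$faces, seed = 5)
})

fx_canonical <- function() fixture("canonical", function() {
  make_canonical_frame(fx_regressor()$shape_model, c(128, 128))
})

fx_aam_fast <- function() fixture("aam_fast", function() {
  train_aam(fx_dataset()$faces[1:30], "fast")
})

fx_aam_hq <- function() fixture("aam_hq", function() {
  train_aam(fx_dataset()$faces[1:24], "high_quality",
            calibrate_failure = FALSE)
})

fx_testfaces <- function() fixture("testfaces", function() {
  generate_dataset(3, 5, seed = 77)
})

# Independent brute-force HOG oracle: per-pixel loops, no vectorization,
# mirroring the documented definition (centered differences with replicated
# borders, two-bin linear orientation votes, L2-Hys block normalization).
oracle_hog <- function(patch, spec) {
  h <- nrow(patch); w <- ncol(patch)
  cell <- spec$cell; nb <- spec$n_orientations; blk <- spec$block
  ncy <- h %/% cell; ncx <- w %/% cell
  hist <- array(0, c(ncy, ncx, nb))
  period <- if (spec$signed) 360 else 180
  binw <- period / nb
  for (r in 1:(ncy * cell)) for (c in 1:(ncx * cell)) {
    cl <- if (c == 1) 1 else c - 1
    cr <- if (c == w) w else c + 1
    ru <- if (r == 1) 1 else r - 1
    rd <- if (r == h) h else r + 1
    gx <- (patch[r, cr] - patch[r, cl]) / 2
    gy <- (patch[rd, c] - patch[ru, c]) / 2
    mag <- sqrt(gx^2 + gy^2)
    ang <- (atan2(gy, gx) * 180 / pi) %% period
    t <- ang / binw
    b0 <- floor(t); frac <- t - b0
    b0 <- b0 %% nb
    cy <- (r - 1) %/% cell + 1; cx <- (c - 1) %/% cell + 1
    hist[cy, cx, b0 + 1] <- hist[cy, cx, b0 + 1] + (1 - frac) * mag
    hist[cy, cx, (b0 + 1) %% nb + 1] <- hist[cy, cx, (b0 + 1) %% nb + 1] +
      frac * mag
  }
  wc <- spec$window %/% cell
  bw <- wc - blk + 1
  eps <- 1e-6
  desc <- numeric(0)
  for (bj in 1:bw) for (bi in 1:bw) {   # blocks: down, then right
    v <- c()
    for (cj in bj:(bj + blk - 1)) for (ci in bi:(bi + blk - 1))
      v <- c(v, hist[ci, cj, ])
    v <- v / sqrt(sum(v^2) + eps^2)
    v[v > 0.2] <- 0.2
    v <- v / sqrt(sum(v^2) + eps^2)
    desc <- c(desc, v)
  }
  desc
}
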