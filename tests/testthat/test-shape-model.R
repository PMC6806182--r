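ref_shape <- function() shape68(canonical_template(4)$points * 40 + 80)

test_that("iou matches closed-form box arithmetic and its invariants", {
  a <- bounding_box(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, bounding_box(20, 20, 5, 5)), 0)
  b <- bounding_box(5, 5, 10, 10)
  expect_equal(iou(a, b), 25 / 175)
  withr::with_seed(9, {
    for (i in 1:25) {
      x <- bounding_box(runif(1, -5, 5), runif(1, -5, 5),
                        runif(1, 0.5, 10), runif(1, 0.5, 10))
      y <- bounding_box(runif(1, -5, 5), runif(1, -5, 5),
                        runif(1, 0.5, 10), runif(1, 0.5, 10))
      v <- iou(x, y)
      expect_equal(v, iou(y, x))
      expect_gte(v, 0); expect_lte(v, 1)
      ident <- isTRUE(all.equal(unlist(x), unlist(y)))
      expect_equal(v == 1, ident)
    }
  })
})

test_that("procrustes alignment recovers known similarity transforms", {
  s <- ref_shape()
  al <- procrustes_align(s, s)
  expect_equal(al$pose$scale, 1, tolerance = 1e-9)
  expect_equal(al$pose$rotation, 0, tolerance = 1e-9)
  expect_equal(al$pose$translation, c(0, 0), tolerance = 1e-8)
  expect_lt(al$residual, 1e-12)
  # shape built by rotating/scaling the reference: inverse pose recovered
  rot <- apply_pose(s, similarity_pose(2, pi / 2, c(0, 0)))
  al2 <- procrustes_align(rot, s)
  expect_equal(al2$pose$scale, 0.5, tolerance = 1e-9)
  expect_equal(al2$pose$rotation, -pi / 2, tolerance = 1e-9)
  expect_lt(al2$residual, 1e-9)
  # pure translation
  tr <- shape68(unclass(s) + rep(c(5, -3), each = 68))
  al3 <- procrustes_align(tr, s)
  expect_equal(al3$pose$scale, 1, tolerance = 1e-9)
  expect_equal(al3$pose$rotation, 0, tolerance = 1e-9)
  expect_equal(al3$pose$translation, c(-5, 3), tolerance = 1e-8)
  expect_error(procrustes_align(shape68(matrix(1, 68, 2)), s),
               class = "thermoface_input_error")
})

test_that("procrustes agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  s <- ref_shape()
  t <- apply_pose(shape68(canonical_template(9)$points * 40 + 80),
                  similarity_pose(1.3, 0.4, c(12, -7)))
  ours <- procrustes_align(t, s)
  ref <- vegan::procrustes(unclass(s), unclass(t), scale = TRUE,
                           symmetric = FALSE)
  # vegan reports Yrot relative to the centered target
  ours_centered <- sweep(unclass(ours$aligned), 2, colMeans(unclass(s)))
  expect_lt(sum((ours_centered - ref$Yrot)^2), 1e-6)
  expect_equal(ours$residual, sum(stats::residuals(ref)^2),
               tolerance = 1e-6)
})

test_that("degenerate and near-zero-variance training sets collapse to k = 0", {
  s <- ref_shape()
  m <- build_shape_model(rep(list(s), 10))
  expect_equal(m$k, 0L)
  # mean equals the shape up to similarity normalization
  al <- procrustes_align(s, shape68(m$mean_shape))
  expect_lt(al$residual, 1e-12)
  expect_error(build_shape_model(list(s, s)),
               class = "thermoface_training_error")
})

test_that("a single deformation direction yields a single aligned component", {
  base <- unclass(ref_shape())
  # direction orthogonal to the similarity modes: bend the jaw only
  d <- matrix(0, 68, 2)
  d[1:17, 2] <- sin(seq(0, pi, length.out = 17)) * 4
  d <- d - rep(colMeans(d), each = 68)
  shapes <- lapply(c(-1, 0, 1), function(t) shape68(base + t * d))
  m <- build_shape_model(shapes, variance_retained = 0.98)
  expect_equal(m$k, 1L)
  # the component aligns with the (normalized-frame) deformation direction
  a0 <- unclass(procrustes_align(shapes[[1]], shape68(m$mean_shape))$aligned)
  a2 <- unclass(procrustes_align(shapes[[3]], shape68(m$mean_shape))$aligned)
  dd <- as.vector(a2 - a0)
  cosine <- abs(sum(dd * m$components[, 1])) / sqrt(sum(dd^2))
  expect_gte(cosine, 0.999)
})

test_that("encode/decode are mutually inverse on the model span", {
  shapes <- lapply(1:12, function(i)
    shape68(canonical_template(i)$points * 50 + 100))
  m <- build_shape_model(shapes, variance_retained = 1)
  for (i in c(1, 5, 9)) {
    rec <- decode_params(m, encode_shape(m, shapes[[i]]))
    expect_lt(max(abs(unclass(rec) - unclass(shapes[[i]]))), 1e-6)
  }
  # b = 0 with identity pose reproduces the mean exactly
  expect_equal(unclass(decode_params(m, shape_params(numeric(m$k)))),
               m$mean_shape, tolerance = 1e-12, ignore_attr = TRUE)
  # transformed mean encodes to b ~ 0 with the transform as pose
  pose <- similarity_pose(35, 0.3, c(90, 110))
  t <- apply_pose(shape68(m$mean_shape), pose)
  par <- encode_shape(m, t)
  expect_lt(sqrt(sum(par$b^2)), 1e-6)
  expect_equal(par$pose$scale, pose$scale, tolerance = 1e-6)
  expect_equal(par$pose$rotation, pose$rotation, tolerance = 1e-6)
  # encode is translation-invariant up to pose
  par2 <- encode_shape(m, shape68(unclass(t) + rep(c(11, -4), each = 68)))
  expect_lt(sqrt(sum((par$b - par2$b)^2)), 1e-9)
})

test_that("decode clamps coefficients at three standard deviations", {
  shapes <- lapply(1:12, function(i)
    shape68(canonical_template(i)$points * 50 + 100))
  m <- build_shape_model(shapes, variance_retained = 1)
  b_hot <- numeric(m$k); b_hot[1] <- 10 * sqrt(m$eigenvalues[1])
  b_lim <- numeric(m$k); b_lim[1] <- 3 * sqrt(m$eigenvalues[1])
  expect_equal(unclass(decode_params(m, shape_params(b_hot))),
               unclass(decode_params(m, shape_params(b_lim))))
  expect_error(decode_params(m, shape_params(numeric(m$k + 1))),
               class = "thermoface_input_error")
})

test_that("out-of-span reconstruction error equals the orthogonal residue", {
  shapes <- lapply(1:12, function(i)
    shape68(canonical_template(i)$points * 50 + 100))
  m <- build_shape_model(shapes, variance_retained = 1)
  probe <- shape68(canonical_template(400)$points * 50 + 100)
  # work in the aligned (model) frame: decode with identity pose
  a <- as.vector(unclass(procrustes_align(probe,
                                          shape68(m$mean_shape))$aligned))
  b <- encode_shape(m, probe)$b
  rec <- decode_params(m, shape_params(b))   # identity pose, clamp applied
  impl_err <- sum((as.vector(unclass(rec)) - a)^2)
  # brute-force oracle: clamped projection onto the basis
  bc <- pmin(pmax(b, -3 * sqrt(m$eigenvalues)), 3 * sqrt(m$eigenvalues))
  proj <- as.vector(m$mean_shape) + as.vector(m$components %*% bc)
  expect_equal(impl_err, sum((a - proj)^2), tolerance = 1e-10)
})

test_that("models from disjoint halves of a large corpus agree", {
  shapes <- lapply(1:60, function(i)
    shape68(canonical_template(i)$points * 50 + 100))
  m1 <- build_shape_model(shapes[1:30])
  m2 <- build_shape_model(shapes[31:60])
  al <- procrustes_align(shape68(m2$mean_shape), shape68(m1$mean_shape))
  d <- sqrt(mean(rowSums((unclass(al$aligned) - m1$mean_shape)^2)))
  expect_lt(d / inter_ocular(shape68(m1$mean_shape)), 0.01)
})

test_that("shape models serialize to JSON losslessly", {
  td <- withr::local_tempdir()
  shapes <- lapply(1:8, function(i)
    shape68(canonical_template(i)$points * 50 + 100))
  m <- build_shape_model(shapes)
  f <- file.path(td, "model.json")
  write_shape_model(m, f)
  m2 <- read_shape_model(f)
  expect_equal(m2$mean_shape, m$mean_shape)
  expect_equal(m2$components, m$components)
  expect_equal(m2$eigenvalues, m$eigenvalues)
})
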