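test_that("the canonical frame is deterministic and tiles the hull", {
  cf <- fx_canonical()
  ref <- unclass(cf$reference_shape)
  expect_true(all(ref[, 1] >= 0 & ref[, 1] < cf$size[1]))
  expect_true(all(ref[, 2] >= 0 & ref[, 2] < cf$size[2]))
  expect_setequal(sort(unique(as.vector(cf$triangles))), 1:68)
  # triangle areas sum to the convex-hull area (shoelace both ways)
  tri_area <- sum(apply(cf$triangles, 1, function(t) {
    v <- ref[t, ]
    abs((v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
          (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])) / 2
  }))
  hull <- ref[grDevices::chull(ref), ]
  expect_equal(tri_area, abs(thermoface:::polygon_area(hull)),
               tolerance = 1e-6)
  cf2 <- make_canonical_frame(fx_regressor()$shape_model, c(128, 128))
  expect_identical(cf2$triangles, cf$triangles)
  expect_equal(unclass(cf2$reference_shape), unclass(cf$reference_shape))
})

test_that("affine_from_triangle solves the three-point system exactly", {
  src <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(affine_from_triangle(src, src),
               rbind(c(1, 0, 0), c(0, 1, 0)), tolerance = 1e-12)
  expect_equal(affine_from_triangle(src, src + rep(c(5, -2), each = 3)),
               rbind(c(1, 0, 5), c(0, 1, -2)), tolerance = 1e-12)
  rot90 <- cbind(-src[, 2], src[, 1])
  expect_equal(affine_from_triangle(src, rot90),
               rbind(c(0, -1, 0), c(1, 0, 0)), tolerance = 1e-12)
  expect_error(affine_from_triangle(rbind(c(0, 0), c(1, 1), c(2, 2)), src),
               class = "thermoface_geometry_error")
})

test_that("warping with the reference shape is the identity inside the hull", {
  cf <- fx_canonical()
  img <- matrix(stats::runif(128 * 128, 0, 4000), 128, 128)
  ff <- frontalize(img, cf$reference_shape, cf)
  expect_lte(max(abs(ff$image[ff$mask] - img[ff$mask])), 1e-6)
  # mask is false outside the reference hull (allowing boundary pixels):
  # every masked-in pixel lies within the hull dilated by one pixel
  ref <- unclass(cf$reference_shape)
  hull <- ref[grDevices::chull(ref), ]
  ctr <- colMeans(hull)
  hull_dil <- t(apply(hull, 1, function(v)
    ctr + (v - ctr) * (1 + 1.5 / sqrt(sum((v - ctr)^2)))))
  xs <- rep(0:127, each = 128); ys <- rep.int(0:127, 128)
  on <- ff$mask[cbind(ys + 1, xs + 1)]
  expect_true(all(thermoface:::points_in_polygon(xs[on], ys[on], hull_dil)))
})

test_that("every landmark maps exactly onto its reference point", {
  cf <- fx_canonical()
  af <- render_face(face_params(rotation = 0.2, shear_x = 0.1), seed = 3)
  mapped <- thermoface:::piecewise_map_points(cf, af$shape,
                                              unclass(cf$reference_shape))
  expect_lt(max(abs(mapped - unclass(af$shape))), 1e-6)
})

test_that("the barycentric warp equals the per-pixel affine oracle", {
  cf <- fx_canonical()
  af <- render_face(face_params(rotation = 0.25, shear_x = -0.12), seed = 9)
  ff <- frontalize(af$frame, af$shape, cf)
  wm <- cf$cache$warp_map
  ref <- unclass(cf$reference_shape)
  det_s <- unclass(af$shape)
  # oracle: solve each triangle's affine map independently and apply it
  withr::with_seed(1, idx <- sample(length(wm$px), 400))
  for (i in idx) {
    tr <- cf$triangles[wm$tri[i], ]
    M <- affine_from_triangle(ref[tr, ], det_s[tr, ])
    src <- M %*% c(wm$px[i], wm$py[i], 1)
    bary_src <- c(wm$w[i, ] %*% det_s[tr, ])
    expect_lt(max(abs(src - bary_src)), 1e-9)
  }
})

test_that("rotated faces frontalize to the frontal rendering", {
  cf <- fx_canonical()
  p0 <- face_params(rotation = 0, identity_seed = 2)
  p15 <- face_params(rotation = 15 * pi / 180, identity_seed = 2)
  a0 <- render_face(p0, noise_sigma = 5, seed = 21)
  a15 <- render_face(p15, noise_sigma = 5, seed = 22)
  f0 <- frontalize(a0$frame, a0$shape, cf)
  f15 <- frontalize(a15$frame, a15$shape, cf)
  m <- f0$mask & f15$mask
  expect_gte(stats::cor(f0$image[m], f15$image[m]), 0.95)
})

test_that("default ROIs sit anatomically and inside the hull", {
  cf <- fx_canonical()
  rois <- default_rois(cf)
  expect_named(rois, c("nostrils", "periorbital", "forehead"))
  ref <- unclass(cf$reference_shape)
  no <- rois$nostrils$polygon
  expect_gt(abs(thermoface:::polygon_area(no)), 0)
  centroid <- colMeans(no)
  expect_gt(centroid[2], ref[31, 2])   # below the nose tip (landmark 30)
  expect_lt(centroid[2], ref[52, 2])   # above the upper lip (landmark 51)
  hull <- ref[grDevices::chull(ref), ]
  for (r in rois[c("nostrils", "periorbital")])
    expect_true(all(thermoface:::points_in_polygon(r$polygon[, 1],
                                                   r$polygon[, 2], hull)))
})

test_that("ROI registries load from YAML in both dialects", {
  cf <- fx_canonical()
  td <- withr::local_tempdir()
  f <- file.path(td, "rois.yaml")
  writeLines(c("nose_band:",
               "  landmarks: [31, 32, 33, 34, 35]",
               "  dilation: 3.5",
               "patch:",
               "  polygon:",
               "    - [10, 10]",
               "    - [40, 10]",
               "    - [25, 40]"), f)
  rois <- read_rois(f, cf)
  expect_named(rois, c("nose_band", "patch"))
  expect_gt(abs(thermoface:::polygon_area(rois$nose_band$polygon)), 0)
  expect_equal(nrow(rois$patch$polygon), 3)
  # anchored definition matches the equivalent in-code spec
  direct <- resolve_roi(roi_spec("nose_band", landmarks = 31:35,
                                 dilation = 3.5), cf)
  expect_equal(rois$nose_band$polygon, direct$polygon)
})

test_that("annotated frames validate the shape/box relationship", {
  af <- render_face(face_params(), seed = 31)
  ok <- annotated_frame(af$frame, shape = af$shape,
                        face_box = af$face_box, emotion = "neutral")
  expect_s3_class(ok, "annotated_frame")
  far <- bounding_box(1000, 1000, 10, 10)
  expect_error(annotated_frame(af$frame, shape = af$shape, face_box = far),
               class = "thermoface_input_error")
})

test_that("ROI extraction averages only masked-in polygon pixels", {
  cf <- fx_canonical()
  roi <- default_rois(cf)$nostrils
  ff <- structure(list(image = matrix(42, 128, 128),
                       mask = matrix(TRUE, 128, 128)),
                  class = "frontalized_face")
  r <- extract_roi(ff, roi)
  expect_equal(r$mean_value, 42)
  expect_equal(r$valid_fraction, 1)
  # calibration is affine on the mean
  r2 <- extract_roi(ff, roi, calibration = list(gain = 0.03, offset = 270))
  expect_equal(r2$mean_value, 0.03 * 42 + 270)
  # fully-masked-out ROI is undefined
  ff$mask[] <- FALSE
  r3 <- extract_roi(ff, roi)
  expect_true(is.na(r3$mean_value))
  expect_equal(r3$valid_fraction, 0)
  # half/half split averages by pixel count
  idx <- thermoface:::roi_pixel_indices(roi, 128, 128)
  img <- matrix(10, 128, 128)
  img[idx[seq_len(floor(length(idx) / 2))]] <- 20
  ff2 <- structure(list(image = img, mask = matrix(TRUE, 128, 128)),
                   class = "frontalized_face")
  frac <- floor(length(idx) / 2) / length(idx)
  expect_equal(extract_roi(ff2, roi)$mean_value, 20 * frac + 10 * (1 - frac))
})
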