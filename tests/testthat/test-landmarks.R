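test_that("nrmse follows its closed form and invariances", {
  s <- render_face(face_params(), seed = 1)$shape
  expect_equal(nrmse(s, s), 0)
  off <- shape68(unclass(s) + rep(c(3, 0), each = 68))
  expect_equal(nrmse(off, s), 3 / inter_ocular(s))
  both <- rep(c(7, -2), each = 68)
  expect_equal(nrmse(shape68(unclass(off) + both),
                     shape68(unclass(s) + both)), 3 / inter_ocular(s))
  expect_error(nrmse(s, shape68(matrix(1, 68, 2))),
               class = "thermoface_input_error")
})

test_that("aam training produces consistent, ordered models", {
  hq <- fx_aam_hq(); fa <- fx_aam_fast()
  # appearance bases orthonormal per level
  for (lv in hq$levels) {
    if (ncol(lv$A) > 1)
      expect_lt(max(abs(crossprod(lv$A) - diag(ncol(lv$A)))), 1e-8)
  }
  # fast preset stores drastically fewer coefficients
  expect_lt(aam_model_size(fa), aam_model_size(hq))
  expect_error(train_aam(fx_dataset()$faces[1:5], "fast"),
               class = "thermoface_training_error")
})

test_that("aam training is deterministic", {
  faces <- fx_dataset()$faces[1:20]
  m1 <- train_aam(faces, "fast", calibrate_failure = FALSE)
  m2 <- train_aam(faces, "fast", calibrate_failure = FALSE)
  expect_equal(m1$levels[[1]]$a0, m2$levels[[1]]$a0)
  expect_equal(m1$levels[[1]]$A, m2$levels[[1]]$A)
  expect_equal(m1$shape_model$components, m2$shape_model$components)
})

test_that("fitting a model-generated image is a near-zero-residual fixed point", {
  fa <- fx_aam_fast()
  lev <- fa$levels[[1]]
  # the mean appearance rendered in its own reference frame IS the model at
  # (mean shape, mean appearance): fitting it from the face box must stay at
  # the zero-residual fixed point
  target <- lev$ref$reference_shape
  img <- matrix(stats::median(lev$a0), lev$ref$size[2], lev$ref$size[1])
  img[lev$ref$cache$warp_map$lin] <- lev$a0
  img <- (img - min(img)) * 800 + 1200
  res <- fit_aam(img, shape_face_box(target), fa)
  expect_lt(nrmse(res$shape, target), 0.01)
})

test_that("hq fitting tolerates a translated initialization box", {
  hq <- fx_aam_hq()
  af <- fx_testfaces()$faces[[1]]
  b <- af$face_box
  shifted <- bounding_box(b$x0 + 0.05 * b$width, b$y0 + 0.05 * b$height,
                          b$width, b$height)
  res <- fit_aam(af$frame, shifted, hq)
  expect_lt(nrmse(res$shape, af$shape), 0.03)
})

test_that("aam flags pure-noise input through its calibrated cost", {
  fa <- fx_aam_fast()
  expect_true(is.finite(fa$failure_cost_threshold))
  noise <- withr::with_seed(3, matrix(stats::runif(160 * 160, 0, 4000),
                                      160, 160))
  res <- fit_aam(noise, bounding_box(40, 40, 80, 80), fa)
  expect_true(!res$converged || res$final_cost > fa$failure_cost_threshold)
  expect_error(fit_aam(noise, bounding_box(500, 500, 50, 50), fa),
               class = "thermoface_input_error")
})

test_that("aam accepted-step costs never increase within a pyramid level", {
  # backtracking enforces monotonicity; verify the final cost of a fit on
  # clean data is below the cost of its own initialization
  fa <- fx_aam_fast()
  af <- fx_testfaces()$faces[[2]]
  r1 <- fit_aam(af$frame, af$face_box, fa, max_iters = 1)
  r50 <- fit_aam(af$frame, af$face_box, fa, max_iters = 50)
  expect_lte(r50$final_cost, r1$final_cost + 1e-12)
})

test_that("the regressor is accurate, jitter-robust and deterministic", {
  reg <- fx_regressor()
  test <- fx_testfaces()$faces
  errs <- vapply(test, function(af)
    nrmse(fit_regressor(af$frame, af$face_box, reg)$shape, af$shape),
    numeric(1))
  expect_lte(mean(errs), 0.05)
  jerrs <- withr::with_seed(8, vapply(test, function(af) {
    b <- af$face_box
    jb <- bounding_box(b$x0 + runif(1, -0.1, 0.1) * b$width,
                       b$y0 + runif(1, -0.1, 0.1) * b$height,
                       b$width * runif(1, 0.9, 1.1),
                       b$height * runif(1, 0.9, 1.1))
    nrmse(fit_regressor(af$frame, jb, reg)$shape, af$shape)
  }, numeric(1)))
  expect_lte(median(jerrs), 0.08)
  r1 <- fit_regressor(test[[1]]$frame, test[[1]]$face_box, reg)
  r2 <- fit_regressor(test[[1]]$frame, test[[1]]$face_box, reg)
  expect_identical(unclass(r1$shape), unclass(r2$shape))
  reg2 <- train_shape_regressor(fx_dataset()$faces, seed = 5)
  expect_identical(reg2$stages[[1]]$W, reg$stages[[1]]$W)
})

test_that("regressor output always lies in the shape model's 3-sigma region", {
  reg <- fx_regressor()
  sm <- reg$shape_model
  noise <- withr::with_seed(4, matrix(stats::runif(160 * 160, 0, 4000),
                                      160, 160))
  inputs <- list(list(noise, bounding_box(30, 30, 90, 90)),
                 list(fx_testfaces()$faces[[3]]$frame$pixels,
                      bounding_box(10, 10, 60, 60)))
  for (inp in inputs) {
    sh <- fit_regressor(inp[[1]], inp[[2]], reg)$shape
    b <- encode_shape(sm, sh)$b
    expect_true(all(abs(b) <= 3 * sqrt(sm$eigenvalues) + 1e-6))
  }
  expect_error(train_shape_regressor(fx_dataset()$faces[1:10]),
               class = "thermoface_training_error")
})

test_that("tracking stays locked on a static face", {
  reg <- fx_regressor()
  det <- fx_detector()
  sq <- generate_sequence(sequence_config(n_frames = 40,
                                          motion_profile = "none", seed = 3),
                          face_params())
  trk <- track_video(sq, reg, det, tracker_config("dynamic_box"))
  errs <- vapply(seq_along(sq), function(i)
    nrmse(trk[[i]]$shape, sq[[i]]$shape), numeric(1))
  expect_lte(max(errs), 2 * errs[1] + 0.01)
})

test_that("all four update strategies track a slow-motion face", {
  reg <- fx_regressor()
  det <- fx_detector()
  sq <- generate_sequence(sequence_config(n_frames = 24,
                                          motion_profile = "slow", seed = 13),
                          face_params())
  for (strat in c("bounds_update", "shape_update", "dynamic_box",
                  "fixed_box")) {
    trk <- track_video(sq, reg, det, tracker_config(strat))
    ious <- vapply(seq_along(sq), function(i)
      iou(shape_bbox(trk[[i]]$shape), shape_bbox(sq[[i]]$shape)), numeric(1))
    expect_gte(min(ious), 0.5)
  }
  expect_error(track_video(list(), reg, det),
               class = "thermoface_input_error")
  blank <- list(thermal_frame(matrix(1500, 160, 160)))
  expect_error(track_video(blank, reg, det),
               class = "thermoface_tracking_error")
})
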