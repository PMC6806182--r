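synthetic_signal <- function(values, frame_rate) {
  structure(list(values = values,
                 times = (seq_along(values) - 1) / frame_rate,
                 frame_rate = frame_rate,
                 valid = rep(TRUE, length(values))),
            class = "resp_signal")
}

test_that("crop_with_margin expands the landmark box arithmetically", {
  # landmark box (10, 20)-(110, 220): width 100, height 200; 10% margin
  # expands 10 px left/right and 20 px top/bottom -> (0, 0)-(120, 240)
  pts <- cbind(seq(10, 110, length.out = 68), seq(20, 220, length.out = 68))
  s <- shape68(pts)
  big <- matrix(0, 400, 400)
  cr <- crop_with_margin(big, s, margin = 0.10)
  expect_equal(c(cr$box$x0, cr$box$y0), c(0, 0))
  expect_equal(c(cr$box$width, cr$box$height), c(120, 240))
  expect_equal(dim(cr$pixels), c(240L, 120L))
  cr0 <- crop_with_margin(big, s, margin = 0)
  expect_equal(c(cr0$box$width, cr0$box$height), c(100, 200))
  # near-corner crop keeps its dimensions, padding with zeros
  af <- render_face(face_params(center = c(20, 20), scale = 40), seed = 2)
  crc <- crop_with_margin(af$frame, af$shape, margin = 0.10)
  expect_equal(dim(crc$pixels),
               c(as.integer(round(crc$box$height)),
                 as.integer(round(crc$box$width))))
  expect_true(any(crc$pixels == 0))
})

test_that("emotion features have fixed length and affine-intensity invariance", {
  spec <- hog_spec(window = 128L)
  crop <- render_face(face_params(), seed = 3)$frame$pixels
  f1 <- extract_emotion_features(crop, spec)
  expect_length(f1, 8100L)   # (16-1)^2 * 4 * 9
  expect_identical(f1, extract_emotion_features(crop, spec))
  f2 <- extract_emotion_features(crop * 1.7 + 250, spec)
  expect_equal(f2, f1, tolerance = 1e-9)
  expect_equal(max(abs(extract_emotion_features(matrix(5, 40, 40), spec))), 0)
})

test_that("emotion training demands balanced classes and memorizes them", {
  ds <- fx_dataset()
  labs <- vapply(ds$faces, `[[`, character(1), "emotion")
  three <- ds$faces[labs != "sad"]
  expect_error(train_emotion(three), class = "thermoface_training_error")
  em <- train_emotion(ds$faces, n_trees = 300, seed = 7)
  preds <- vapply(ds$faces[seq(1, 60, by = 3)], function(af)
    classify_emotion(em, af$frame, af$shape)$label, character(1))
  acc <- mean(preds == labs[seq(1, 60, by = 3)])
  expect_gte(acc, 0.95)
  p <- classify_emotion(em, ds$faces[[1]]$frame, ds$faces[[1]]$shape)
  expect_equal(sum(p$probabilities), 1, tolerance = 1e-9)
  expect_true(all(p$probabilities >= 0 & p$probabilities <= 1))
  # seeded forests reproduce their predictions
  em2 <- train_emotion(ds$faces, n_trees = 300, seed = 7)
  p2 <- classify_emotion(em2, ds$faces[[1]]$frame, ds$faces[[1]]$shape)
  expect_identical(p$probabilities, p2$probabilities)
})

test_that("respiratory signals interpolate invalid samples but keep flags", {
  cf <- fx_canonical()
  roi <- default_rois(cf)$nostrils
  sq <- generate_sequence(sequence_config(n_frames = 20,
                                          motion_profile = "none", seed = 4),
                          face_params())
  faces <- lapply(sq, function(af) frontalize(af$frame, af$shape, cf))
  # occlude 10% of frames by masking their ROI out
  for (i in c(5, 13)) faces[[i]]$mask[] <- FALSE
  sig <- respiratory_signal(faces, roi, 8)
  expect_length(sig$values, 20)
  expect_equal(which(!sig$valid), c(5L, 13L))
  expect_true(all(is.finite(sig$values)))
  # constant-temperature input gives a flat signal
  flat <- lapply(1:15, function(i)
    structure(list(image = matrix(3000, 64, 64),
                   mask = matrix(TRUE, 64, 64)), class = "frontalized_face"))
  roi_small <- roi_spec("c", polygon = rbind(c(10, 10), c(30, 10), c(20, 30)))
  sflat <- respiratory_signal(flat, roi_small, 8)
  expect_equal(stats::sd(sflat$values), 0)
  for (f in faces) f$mask[] <- FALSE
  all_bad <- lapply(faces, function(f) { f$mask[] <- FALSE; f })
  expect_error(respiratory_signal(all_bad, roi, 8),
               class = "thermoface_signal_error")
})

test_that("rate estimation recovers pure sinusoids to within a bin", {
  t <- (0:599) / 10
  s <- synthetic_signal(sin(2 * pi * 0.25 * t), 10)
  expect_equal(estimate_rate(s), 15, tolerance = 60 * 10 / 4096 + 1e-9)
  s2 <- synthetic_signal(sin(2 * pi * 0.4 * t), 10)
  expect_equal(estimate_rate(s2), 24, tolerance = 60 * 10 / 4096 + 1e-9)
  # constant signal has no prominent peak
  expect_true(is.na(estimate_rate(synthetic_signal(rep(5, 600), 10))))
  expect_error(estimate_rate(synthetic_signal(rep(5, 100), 10)),
               class = "thermoface_input_error")
})

test_that("apnoea detection finds programmed flat segments", {
  fr <- 8
  t <- (0:719) / fr   # 90 s
  v <- sin(2 * pi * 0.25 * t)
  v[t >= 60 & t < 75] <- 0
  v <- v + withr::with_seed(2, stats::rnorm(length(v), sd = 0.02))
  segs <- detect_apnoea(synthetic_signal(v, fr))
  expect_equal(nrow(segs), 1)
  expect_gte(interval_jaccard(c(segs$start_s, segs$end_s), c(60, 75)), 0.6)
  # continuous breathing: nothing detected
  segs2 <- detect_apnoea(synthetic_signal(sin(2 * pi * 0.25 * t), fr))
  expect_equal(nrow(segs2), 0)
  # constant signal: one segment spanning (almost) everything
  segs3 <- detect_apnoea(synthetic_signal(rep(3, 720), fr))
  expect_equal(nrow(segs3), 1)
  expect_lte(segs3$start_s, 1)
  expect_gte(segs3$end_s, 89)
  # segments disjoint and sorted by construction
  v2 <- sin(2 * pi * 0.25 * t)
  v2[t < 12] <- 0; v2[t >= 50 & t < 62] <- 0
  segs4 <- detect_apnoea(synthetic_signal(v2, fr))
  expect_true(all(diff(as.vector(t(as.matrix(segs4)))) > 0))
})
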