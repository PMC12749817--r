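train_small <- function(spec, seeds = c(101, 102), slices_per = 8,
                        type = "qda") {
  sl <- list()
  for (s in seeds) {
    tr <- build_label_volume(spec, seed = s)
    vv <- render_oct(tr, spec, seed = s + 1)
    sl <- c(sl, training_slices_from_phantom(tr, vv, slices_per))
  }
  train_classifier(sl, type = type, voxel_um = spec$voxel_um, seed = 7)
}

test_that("noiseless two-intensity phantom is learned and segmented exactly", {
  spec <- noiseless_spec("mixed", fibroblast_density = 0)  # cancer vs matrix
  clf <- train_small(spec)
  expect_equal(clf$training$train_accuracy, 1.0)
  truth <- build_label_volume(spec, seed = 55)
  vol <- render_oct(truth, spec, seed = 56)
  labs <- segment_volume(vol, clf)
  expect_identical(labs$data, truth$label_volume$data)
})

test_that("crop_roi slices the stated ROI and validates bounds", {
  spec <- noiseless_spec("none", lat = 64, depth = 64, ct = 16)
  truth <- build_label_volume(spec, seed = 1)
  vol <- render_oct(truth, spec, seed = 1)
  # full-volume ROI is the identity
  full <- crop_roi(vol, c(0, 0, 0), c(64, 64, 64))
  expect_identical(full$data, vol$data)
  # lateral ROI from a larger field: shape (z, 48, 48), values unchanged
  roi <- crop_roi(vol, c(0, 8, 8), c(64, 48, 48))
  expect_equal(dim(roi$data), c(64, 48, 48))
  expect_identical(roi$data, vol$data[, 9:56, 9:56])
  # label volumes crop to label volumes
  lroi <- crop_roi(truth$label_volume, c(0, 8, 8), c(64, 48, 48))
  expect_s3_class(lroi, "label_volume")
  expect_error(crop_roi(vol, c(0, -1, 0), c(64, 48, 48)), "non-negative")
  expect_error(crop_roi(vol, c(0, 32, 32), c(64, 48, 48)), "out of bounds")
})

test_that("single-class training labels are rejected", {
  img <- matrix(100L, 20, 20)
  expect_error(train_classifier(list(list(image = img,
                                          labels = matrix(1L, 20, 20)))),
               "single class")
})

test_that("classifier reaches Dice >= 0.9 on a default-noise phantom", {
  spec <- small_spec("mixed")
  clf <- train_small(spec)
  truth <- build_label_volume(spec, seed = 60)
  vol <- render_oct(truth, spec, seed = 61)
  labs <- segment_volume(vol, clf)
  expect_gte(dice_score(labs$data == 1, truth$label_volume$data == 1), 0.9)
})

test_that("voxel-size mismatch is rejected", {
  spec <- small_spec("none")
  clf <- train_small(spec)
  truth <- build_label_volume(small_spec("none", voxel_um = 2, lat = 96,
                                         depth = 128, ct = 32), seed = 1)
  vol <- render_oct(truth, small_spec("none", voxel_um = 2, lat = 96,
                                      depth = 128, ct = 32), seed = 2)
  expect_error(segment_volume(vol, clf), "voxel size mismatch")
})

test_that("constant volume yields a flagged single-class segmentation", {
  spec <- small_spec("none")
  clf <- train_small(spec)
  flat <- oct_volume(array(5000L, c(16, 16, 16)), voxel_um = 1)
  expect_message(labs <- segment_volume(flat, clf), "single class")
  expect_length(unique(as.integer(labs$data)), 1)
})

test_that("otsu threshold separates a two-delta histogram and hits truth", {
  spec <- noiseless_spec("none")
  truth <- build_label_volume(spec, seed = 3)
  vol <- render_oct(truth, spec, seed = 3)
  thr <- otsu_threshold(vol)
  lo <- spec$class_mean_intensity[["matrix"]]
  hi <- spec$class_mean_intensity[["cancer"]]
  expect_gte(thr, lo); expect_lt(thr, hi)  # mask is intensity > threshold
  expect_identical(otsu_baseline(vol), truth$label_volume$data == 1L)
})

test_that("otsu fails on constant input and inverts on inverted contrast", {
  expect_error(otsu_threshold(oct_volume(array(42L, c(8, 8, 8)))), "constant")
  # inverted contrast: cancer darker than surroundings -> mask selects the
  # background, the documented global-threshold failure mode
  spec <- noiseless_spec("none",
                         class_mean_intensity = c(medium = 60000, cancer = 2000,
                                                  stromal = 50000, matrix = 55000))
  truth <- build_label_volume(spec, seed = 3)
  vol <- render_oct(truth, spec, seed = 3)
  mask <- otsu_baseline(vol)
  cancer <- truth$label_volume$data == 1L
  expect_lt(dice_score(mask, cancer), 0.1)
  expect_gt(dice_score(!mask, cancer), 0.99)
})

test_that("under depth attenuation the classifier beats the otsu baseline", {
  spec <- small_spec("mixed")  # default attenuation 0.004/um
  clf <- train_small(spec)
  truth <- build_label_volume(spec, seed = 71)
  vol <- render_oct(truth, spec, seed = 72)
  cancer <- truth$label_volume$data == 1L
  d_clf <- dice_score(segment_volume(vol, clf)$data == 1, cancer)
  d_otsu <- dice_score(otsu_baseline(vol), cancer)
  expect_gt(d_clf, d_otsu)
})

test_that("classifier Dice is monotone non-decreasing in SNR", {
  # speckle contrast 1/sqrt(k): k = 2 (high contrast) .. 16 (low)
  shapes <- c(2, 4, 16)
  mean_dice <- vapply(shapes, function(k) {
    spec <- small_spec("mixed", speckle_shape = k)
    clf <- train_small(spec, slices_per = 6)
    mean(vapply(81:85, function(s) {
      truth <- build_label_volume(spec, seed = s)
      vol <- render_oct(truth, spec, seed = s + 100)
      dice_score(segment_volume(vol, clf)$data == 1,
                 truth$label_volume$data == 1)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_dice) >= 0))
})

test_that("clean_mask removes sub-resolution specks and keeps real objects", {
  m <- array(FALSE, c(20, 20, 20))
  m[3:4, 3:4, 3:4] <- TRUE            # 8 um^3 speck
  m[8:17, 8:17, 8:17] <- TRUE         # 1000 um^3 object
  out <- clean_mask(m, min_object_um3 = 27, voxel_um = 1)
  expect_false(any(out[3:4, 3:4, 3:4]))
  expect_true(all(out[8:17, 8:17, 8:17]))
  empty <- array(FALSE, c(8, 8, 8))
  expect_identical(clean_mask(empty), empty)
})

test_that("classifier JSON serialization round-trips predictions exactly", {
  spec <- small_spec("mixed")
  clf <- train_small(spec, slices_per = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, path)
  clf2 <- read_classifier(path)
  truth <- build_label_volume(spec, seed = 90)
  vol <- render_oct(truth, spec, seed = 91)
  expect_identical(segment_volume(vol, clf2)$data,
                   segment_volume(vol, clf)$data)
})

test_that("feature_spec validates its contract", {
  expect_error(feature_spec(smoothing_scales_um = c(2, 1)), "increasing")
  expect_error(feature_spec(smoothing_scales_um = c(-1, 2)), "positive")
  expect_error(feature_spec(texture_window_um = 0), "positive")
})

test_that("C++ discriminant assignment matches the reference scores", {
  set.seed(42)
  X <- matrix(rnorm(500 * 4), 500, 4)
  y <- sample(c(1L, 2L, 3L), 500, replace = TRUE)
  X[y == 2, 1] <- X[y == 2, 1] + 2
  X[y == 3, 2] <- X[y == 3, 2] - 2
  for (type in c("lda", "qda")) {
    fit <- octinvasion:::gd_fit(X, y, type = type)
    ref <- fit$classes[max.col(octinvasion:::gd_scores(fit, X),
                               ties.method = "first")]
    expect_identical(octinvasion:::gd_predict(fit, X), ref)
  }
})
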