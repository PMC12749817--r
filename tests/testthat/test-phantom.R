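test_that("no-infiltration phantom has zero invasion truth", {
  truth <- build_label_volume(small_spec("none"), seed = 1)
  expect_equal(truth$true_depth_of_invasion_um, 0)
  expect_equal(truth$true_iccr_volume_um3, 0)
  expect_equal(truth$true_invasion_fraction, 0)
  expect_equal(truth$true_baseline_z_um, 16)
})

test_that("cohesive slab without bumps has baseline at the slab bottom", {
  spec <- small_spec("cohesive", finger_count = 0, ct = 20)
  truth <- build_label_volume(spec, seed = 3)
  expect_equal(truth$true_baseline_z_um, 20)
  expect_equal(truth$true_iccr_volume_um3, 0)
})

test_that("island voxel counts match the discrete-sphere enumeration oracle", {
  for (r in c(4, 6)) {
    expected <- bf_sphere_count(r)  # voxel centres inside radius r
    spec <- small_spec("island", lat = 56, depth = 80, ct = 12,
                       island_radius_um = c(mean = r, sd = 0))
    truth <- build_label_volume(spec, seed = 11)
    expect_length(truth$per_island_volumes_um3, 3)
    expect_equal(truth$per_island_volumes_um3, rep(expected, 3))
  }
})

test_that("programmed truth equals brute-force recomputation from the labels", {
  for (pattern in c("none", "cohesive", "finger", "island", "mixed")) {
    truth <- build_label_volume(small_spec(pattern), seed = 5)
    bf <- bf_truth_from_labels(truth$label_volume, truth$true_baseline_z_um)
    expect_identical(truth$true_iccr_volume_um3, bf$iccr)
    expect_identical(truth$true_depth_of_invasion_um, bf$doi)
    expect_identical(truth$true_invasion_fraction,
                     if (bf$total > 0) bf$iccr / bf$total else 0)
  }
})

test_that("build and render are bit-deterministic given (spec, seed)", {
  spec <- small_spec("mixed")
  t1 <- build_label_volume(spec, seed = 9)
  t2 <- build_label_volume(spec, seed = 9)
  expect_identical(t1$label_volume$data, t2$label_volume$data)
  v1 <- render_oct(t1, spec, seed = 10)
  v2 <- render_oct(t2, spec, seed = 10)
  expect_identical(v1$data, v2$data)
  expect_false(identical(v1$data, render_oct(t1, spec, seed = 11)$data))
})

test_that("increasing island count never decreases ICCR volume (shared prefix)", {
  specs <- lapply(1:4, function(k) small_spec("island", island_count = k))
  truths <- lapply(specs, build_label_volume, seed = 21)
  iccr <- vapply(truths, `[[`, 0, "true_iccr_volume_um3")
  expect_true(all(diff(iccr) >= 0))
  # islands are drawn sequentially: the first k islands are shared
  expect_equal(truths[[4]]$per_island_volumes_um3[1:2],
               truths[[2]]$per_island_volumes_um3)
})

test_that("geometry violations are rejected, not clipped", {
  expect_error(small_spec("finger", finger_depth_um = 60, depth = 64, ct = 16),
               "geometry violation")
  expect_error(small_spec("island", island_depth_range_um = c(40, 80)),
               "geometry violation")
  expect_error(small_spec("finger", finger_radius_um = 1), "2 voxels")
})

test_that("islands keep >= 2 voxel clearance from the slab and fingers", {
  for (seed in 1:5) {
    truth <- build_label_volume(small_spec("mixed"), seed = seed)
    lab <- truth$label_volume$data
    d <- dim(lab)
    cancer <- lab == 1L
    # components of the cancer mask: everything except detached islands must
    # be one 26-connected mass; islands must not touch it
    part <- partition_cancer(cancer, truth$true_baseline_z_um, 1)
    detached <- part$invasive_mask & !part$connected_to_original
    if (any(detached)) {
      # grow the contiguous mass by one voxel; still disjoint from islands
      mass <- cancer & !detached
      shift_any <- function(m) {
        out <- array(FALSE, d)
        for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                       c(0,0,1), c(0,0,-1))) {
          src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
          dst <- src
          for (ax in 1:3) {
            if (s[ax] == 1) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax]-1) }
            if (s[ax] == -1) { dst[[ax]] <- 1:(d[ax]-1); src[[ax]] <- 2:d[ax] }
          }
          out[dst[[1]], dst[[2]], dst[[3]]] <-
            out[dst[[1]], dst[[2]], dst[[3]]] | m[src[[1]], src[[2]], src[[3]]]
        }
        out
      }
      grown <- shift_any(mass) | mass
      expect_false(any(grown & detached))
    }
  }
})

test_that("noiseless rendering is the exact class-mean identity", {
  spec <- noiseless_spec("none")
  truth <- build_label_volume(spec, seed = 2)
  vol <- render_oct(truth, spec, seed = 2)
  cancer <- truth$label_volume$data == 1L
  expect_true(all(vol$data[cancer] == spec$class_mean_intensity[["cancer"]]))
  matrixv <- truth$label_volume$data == 3L
  expect_true(all(vol$data[matrixv] == spec$class_mean_intensity[["matrix"]]))
})

test_that("attenuation-only rendering follows the closed form within quantization", {
  mu <- 0.01
  spec <- noiseless_spec("none", attenuation_per_um = mu)
  truth <- build_label_volume(spec, seed = 2)
  vol <- render_oct(truth, spec, seed = 2)
  cancer <- truth$label_volume$data == 1L
  z <- (slice.index(vol$data, 1) - 1)  # depth um at 1 um voxels
  expected <- round(spec$class_mean_intensity[["cancer"]] * exp(-mu * z[cancer]))
  expect_true(all(abs(vol$data[cancer] - expected) <= 1))
})

test_that("extract_slice returns the expected planes and validates indices", {
  spec <- noiseless_spec("none", ct = 16)
  truth <- build_label_volume(spec, seed = 1)
  lv <- truth$label_volume
  xz <- extract_slice(lv, "XZ", 5)
  expect_equal(dim(xz), c(64, 48))
  expect_true(all(xz[1:16, ] == 1))       # top rows cancer
  expect_true(all(xz[17:64, ] %in% c(2, 3)))  # below: stroma
  xy <- extract_slice(lv, "XY", 8)
  expect_true(all(xy == 1))               # inside the slab: all cancer
  # stacking all XY slices reproduces the volume
  stack <- simplify2array(lapply(seq_len(64), function(z)
    extract_slice(lv, "XY", z)))
  expect_equal(aperm(stack, c(3, 1, 2)), lv$data, ignore_attr = TRUE)
  expect_error(extract_slice(lv, "XY", 0), "out of range")
  expect_error(extract_slice(lv, "XZ", 49), "out of range")
})
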