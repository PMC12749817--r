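truth_partition <- function(truth) {
  partition_cancer(truth$label_volume$data == 1L, truth$true_baseline_z_um,
                   truth$label_volume$voxel_um)
}

slab_mask_local <- function(d, ct) {
  m <- array(FALSE, d)
  m[seq_len(ct), , ] <- TRUE
  m
}

test_that("ICCR volume: slab zero, island oracle count, exact conservation", {
  p <- truth_partition(build_label_volume(small_spec("none"), seed = 1))
  expect_equal(iccr_volume(p)$v_iccr_um3, 0)

  spec <- small_spec("island", island_count = 1,
                     island_radius_um = c(mean = 5, sd = 0))
  truth <- build_label_volume(spec, seed = 8)
  p <- truth_partition(truth)
  expect_equal(iccr_volume(p)$v_iccr_um3, bf_sphere_count(5))

  for (pattern in c("cohesive", "finger", "mixed")) {
    p <- truth_partition(build_label_volume(small_spec(pattern), seed = 3))
    v <- iccr_volume(p)
    expect_identical(v$v_total_um3 - v$v_original_um3 - v$v_iccr_um3, 0)
  }
})

test_that("flat-front HIF area equals the lateral ROI area to machine precision", {
  for (d in list(c(30, 16, 16), c(30, 20, 40))) {
    p <- partition_cancer(slab_mask_local(d, 10), 10, 1)
    hm <- hif_height_map(p)
    expect_true(all(hm == 10))
    expect_equal(hif_surface_area(hm), d[2] * d[3], tolerance = 1e-12)
  }
  # and at non-unit voxel size
  p <- partition_cancer(slab_mask_local(c(30, 16, 16), 10), 20, 2)
  expect_equal(hif_surface_area(hif_height_map(p)), (16 * 2) * (16 * 2),
               tolerance = 1e-12)
})

test_that("sinusoidal front area matches fine-grid quadrature within 1%", {
  A <- 20; lambda <- 100; L <- 200
  xs <- (seq_len(L) - 0.5)  # column centres, 1 um spacing
  hm <- matrix(rep(100 + A * sin(2 * pi * xs / lambda), each = L), L, L)
  area <- hif_surface_area(hm, voxel_um = 1)
  oracle <- bf_surface_area_quadrature(
    f = NULL,
    fx = function(x, y) A * 2 * pi / lambda * cos(2 * pi * x / lambda),
    fy = function(x, y) 0 * x,
    Lx = L, Ly = L, h = 0.1)
  expect_lt(abs(area - oracle) / oracle, 0.01)
})

test_that("HIF area is monotone in amplitude and never below the flat area", {
  L <- 100
  xs <- seq_len(L) - 0.5
  areas <- vapply(c(0, 5, 10, 20), function(A) {
    hm <- matrix(rep(50 + A * sin(2 * pi * xs / 100), each = L), L, L)
    hif_surface_area(hm, voxel_um = 1)
  }, 0)
  expect_true(all(diff(areas) > 0))
  expect_equal(areas[1], L * L, tolerance = 1e-12)
  # random rough height maps: always >= projected area, equality iff flat
  for (seed in 1:5) {
    set.seed(seed)
    hm <- matrix(runif(30 * 30, 20, 60), 30, 30)
    expect_gt(hif_surface_area(hm, voxel_um = 1), 900)
  }
})

test_that("detached islands do not contribute to the HIF surface", {
  d <- c(50, 20, 20)
  base <- slab_mask_local(d, 12)
  with_island <- base
  with_island[30:36, 8:14, 8:14] <- TRUE   # detached block below the front
  p0 <- partition_cancer(base, 12, 1)
  p1 <- partition_cancer(with_island, 12, 1)
  expect_identical(hif_height_map(p1), hif_height_map(p0))
  expect_equal(hif_surface_area(hif_height_map(p1)),
               hif_surface_area(hif_height_map(p0)))
  # but a connected finger deepens the front
  with_finger <- base
  with_finger[13:30, 8:10, 8:10] <- TRUE
  p2 <- partition_cancer(with_finger, 12, 1)
  expect_gt(hif_surface_area(hif_height_map(p2)),
            hif_surface_area(hif_height_map(p0)))
})

test_that("mass invasion index: anchors, arithmetic, printed form, errors", {
  # no infiltration -> 0
  p <- truth_partition(build_label_volume(small_spec("none"), seed = 1))
  expect_equal(mass_invasion_index(p), 0)
  expect_equal(mass_invasion_index(p, form = "printed"), 1)

  # v_iccr = 2000, v_total = 10000 -> 0.2 (constructed partition)
  m <- array(FALSE, c(40, 20, 20))
  m[1:20, , ] <- TRUE            # 8000 um^3 above the plane
  m[21:25, , ] <- TRUE           # 2000 um^3 below
  p <- partition_cancer(m, 20, 1)
  expect_equal(iccr_volume(p)$v_iccr_um3, 2000)
  expect_equal(iccr_volume(p)$v_total_um3, 10000)
  expect_equal(mass_invasion_index(p), 0.2)
  expect_equal(mass_invasion_index(p, form = "printed"), 0.8)

  # all cancer below the baseline -> 1
  deep <- array(FALSE, c(40, 10, 10))
  deep[25:30, , ] <- TRUE
  p <- partition_cancer(deep, 10, 1)
  expect_equal(mass_invasion_index(p), 1)

  empty <- partition_cancer(array(FALSE, c(10, 10, 10)), 5, 1)
  expect_error(mass_invasion_index(empty), "v_total = 0")
})

test_that("depth of invasion: slab zero, programmed finger depth, islands count", {
  p <- truth_partition(build_label_volume(small_spec("none"), seed = 1))
  expect_equal(depth_of_invasion_3d(p), 0)

  # finger tip at programmed depth: ct 16 + finger_depth 18 -> DOI 18
  spec <- noiseless_spec("finger")
  truth <- build_label_volume(spec, seed = 4)
  p <- truth_partition(truth)
  expect_equal(depth_of_invasion_3d(p), truth$true_depth_of_invasion_um)
  expect_equal(depth_of_invasion_3d(p), 18)

  # detached islands count toward the depth
  spec <- small_spec("island")
  truth <- build_label_volume(spec, seed = 4)
  expect_equal(depth_of_invasion_3d(truth_partition(truth)),
               truth$true_depth_of_invasion_um)
})

test_that("invasion_metrics collects a consistent one-row table", {
  truth <- build_label_volume(small_spec("mixed"), seed = 12)
  met <- invasion_metrics(truth_partition(truth))
  expect_equal(nrow(met), 1)
  expect_identical(met$v_total_um3, met$v_original_um3 + met$v_iccr_um3)
  expect_equal(met$mass_invasion_index, met$v_iccr_um3 / met$v_total_um3)
  expect_gte(met$hif_area_um2, 48 * 48)
})

test_that("section metrics reproduce the published anchor values", {
  # no infiltration -> index 0 in every field
  truth <- build_label_volume(small_spec("none"), seed = 1)
  sl <- extract_slice(truth$label_volume, "XZ", 10)
  sm <- section_metrics(sl, n_fields = 5, seed = 2)
  expect_equal(sm$invasion_index, rep(0, nrow(sm)))
  expect_equal(sm$depth_of_invasion_um, rep(0, nrow(sm)))

  # original layer fully consumed -> baseline 0, index 1
  consumed <- matrix(0L, 40, 48)
  consumed[25:32, 5:44] <- 1L
  expect_message(sm <- section_metrics(consumed, n_fields = 3, seed = 2),
                 "complete infiltration")
  expect_equal(sm$invasion_index, rep(1, nrow(sm)))

  # equal original and invasive areas in one field -> 0.5
  half <- matrix(0L, 60, 50)
  half[1:25, ] <- 1L         # 50 x 25 original block per field width
  half[26:50, ] <- 1L        # 50 x 25 invasive
  sm <- section_metrics(half, n_fields = 1, field_width_um = 50,
                        baseline_z_um = 25, seed = 1)
  expect_equal(sm$invasion_index, 0.5)
  expect_equal(sm$depth_of_invasion_um, 25)
})

test_that("fields without cancer are skipped with a message", {
  sl <- matrix(0L, 30, 60)
  sl[1:10, 1:20] <- 1L  # cancer only on the left third
  expect_message(sm <- section_metrics(sl, n_fields = 3, field_width_um = 20,
                                       seed = 5),
                 "skipped")
  expect_true(nrow(sm) < 3)
  expect_error(section_metrics(matrix(0L, 10, 10)), "no cancer")
})

test_that("mass index equals the 2-D invasion index on laterally uniform phantoms", {
  # build an x-z profile and extrude it along y
  profile <- matrix(0L, 48, 32)
  profile[1:12, ] <- 1L
  profile[13:20, 10:14] <- 1L   # a finger
  profile[30:34, 20:26] <- 1L   # an island
  arr <- array(0L, c(48, 32, 32))
  for (y in 1:32) arr[, y, ] <- profile
  lv <- label_volume(arr, voxel_um = 1)
  p <- partition_cancer(lv$data == 1L, 12, 1)
  mii <- mass_invasion_index(p)
  sm <- section_metrics(profile, n_fields = 1, field_width_um = 32,
                        baseline_z_um = 12, seed = 1)
  expect_equal(sm$invasion_index, mii)
})
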