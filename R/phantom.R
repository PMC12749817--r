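# Synthetic OCT phantom generator for organotypic cancer models.
#
# The phantom emulates the imaging situation of a scaffold-based 3D oral
# cancer model: a bright, granular cancer cell slab at the top (air-facing)
# surface, a weak-signal collagen stromal layer below it with sparse
# spindle-shaped fibroblasts, and programmed invasion structures (a cohesive
# bulging front, finger-like extensions contiguous with the slab, and/or
# detached islands). Rendering applies exponential depth attenuation,
# multiplicative mean-one Gamma speckle, an anisotropic Gaussian PSF and
# additive read noise, then quantizes to the instrument's 16-bit range.

CLASS_CODES <- c(medium = 0L, cancer = 1L, stromal = 2L, matrix = 3L)

#' Phantom specification
#'
#' All generator parameters with defaults matching the imaging geometry of
#' the modelled instrument: 500 x 500 um lateral ROI, 1 um isotropic voxels,
#' 300--600 um depth range, 3 um lateral / 0.86 um axial optical resolution,
#' 16-bit intensity range.
#'
#' @param lateral_size_um lateral ROI extent, `c(y, x)` in micrometres.
#' @param depth_um scan depth in micrometres (300--600 typical).
#' @param voxel_um isotropic voxel size; all structure sizes are rounded onto
#'   this grid.
#' @param cancer_thickness_um thickness of the seeded cancer slab; its bottom
#'   face is the programmed baseline plane.
#' @param stroma_thickness_um stromal layer thickness; default fills the
#'   remaining depth.
#' @param invasion_pattern one of `"none"`, `"cohesive"` (smooth bulging
#'   front), `"finger"` (capsules contiguous with the slab), `"island"`
#'   (detached ellipsoids), `"mixed"` (fingers + islands).
#' @param finger_count,finger_depth_um,finger_radius_um finger parameters;
#'   for the cohesive pattern these control bump count, maximum bump
#'   amplitude and bump footprint (support radius `3 * finger_radius_um`).
#' @param island_count number of detached islands.
#' @param island_radius_um `c(mean, sd)` of the island radius distribution.
#' @param island_depth_range_um depth of island centres below the baseline,
#'   `c(min, max)`.
#' @param fibroblast_density spindle fibroblasts per mm^3 of stroma.
#' @param fibroblast_axis_um spindle semi-axes `c(major, minor, minor)`.
#' @param class_mean_intensity named mean backscatter intensity per class
#'   (0--65535) before attenuation: bright granular cancer, moderately bright
#'   fibroblasts, weak matrix, near-dark medium.
#' @param speckle_shape Gamma shape k (mean fixed at 1); speckle contrast is
#'   `1/sqrt(k)`. Use `Inf` to disable speckle.
#' @param read_noise_sd additive Gaussian detector noise (intensity counts).
#' @param attenuation_per_um signal decay rate with depth (um^-1).
#' @param psf_lateral_fwhm_um,psf_axial_fwhm_um Gaussian PSF full widths at
#'   half maximum; defaults match 3 um lateral / 0.86 um axial resolution.
#' @param seed default RNG seed used when an operation is called without one.
#' @return a validated `phantom_spec` object.
#' @export
phantom_spec <- function(lateral_size_um = c(500, 500),
                         depth_um = 400,
                         voxel_um = 1,
                         cancer_thickness_um = 100,
                         stroma_thickness_um = NULL,
                         invasion_pattern = c("mixed", "none", "cohesive",
                                              "finger", "island"),
                         finger_count = 6,
                         finger_depth_um = 80,
                         finger_radius_um = 12,
                         island_count = 5,
                         island_radius_um = c(mean = 12, sd = 2.5),
                         island_depth_range_um = c(20, 120),
                         fibroblast_density = 2000,
                         fibroblast_axis_um = c(10, 3, 3),
                         class_mean_intensity = c(medium = 1500, cancer = 30000,
                                                  stromal = 18000, matrix = 5000),
                         speckle_shape = 4,
                         read_noise_sd = 300,
                         attenuation_per_um = 0.004,
                         psf_lateral_fwhm_um = 3.0,
                         psf_axial_fwhm_um = 0.86,
                         seed = 1L) {
  invasion_pattern <- match.arg(invasion_pattern)
  stroma_thickness_um <- stroma_thickness_um %||%
    (depth_um - cancer_thickness_um)
  # tolerate list-valued fields (e.g. specs parsed from JSON)
  lateral_size_um <- unlist(lateral_size_um)
  island_radius_um <- unlist(island_radius_um)
  island_depth_range_um <- unlist(island_depth_range_um)
  fibroblast_axis_um <- unlist(fibroblast_axis_um)
  class_mean_intensity <- unlist(class_mean_intensity)
  spec <- structure(list(
    lateral_size_um = rep(lateral_size_um, length.out = 2),
    depth_um = depth_um, voxel_um = voxel_um,
    cancer_thickness_um = cancer_thickness_um,
    stroma_thickness_um = stroma_thickness_um,
    invasion_pattern = invasion_pattern,
    finger_count = finger_count, finger_depth_um = finger_depth_um,
    finger_radius_um = finger_radius_um,
    island_count = island_count,
    island_radius_um = rep(island_radius_um, length.out = 2),
    island_depth_range_um = island_depth_range_um,
    fibroblast_density = fibroblast_density,
    fibroblast_axis_um = rep(fibroblast_axis_um, length.out = 3),
    class_mean_intensity = class_mean_intensity,
    speckle_shape = speckle_shape, read_noise_sd = read_noise_sd,
    attenuation_per_um = attenuation_per_um,
    psf_lateral_fwhm_um = psf_lateral_fwhm_um,
    psf_axial_fwhm_um = psf_axial_fwhm_um,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# stroma clearance kept below the deepest programmed structure, in um
STROMA_MARGIN_UM <- 5

validate_phantom_spec <- function(spec) {
  s <- spec
  if (s$voxel_um <= 0) stop_("voxel_um must be positive")
  if (any(s$lateral_size_um < 8 * s$voxel_um) || s$depth_um < 8 * s$voxel_um)
    stop_("phantom must be at least 8 voxels in every dimension")
  if (s$cancer_thickness_um <= 0)
    stop_("cancer_thickness_um must be positive")
  ci <- s$class_mean_intensity
  if (!all(c("medium", "cancer", "stromal", "matrix") %in% names(ci)))
    stop_("class_mean_intensity must name medium, cancer, stromal, matrix")
  if (any(ci < 0 | ci > 65535))
    stop_("class mean intensities must lie within [0, 65535]")
  if (s$speckle_shape < 1) stop_("speckle_shape must be >= 1 (or Inf)")
  if (s$attenuation_per_um < 0) stop_("attenuation_per_um must be >= 0")
  uses_fingers <- s$invasion_pattern %in% c("finger", "mixed", "cohesive")
  uses_islands <- s$invasion_pattern %in% c("island", "mixed")
  max_invasion <- 0
  if (uses_fingers) {
    if (s$invasion_pattern != "cohesive" && s$finger_radius_um < 2 * s$voxel_um)
      stop_("finger_radius_um must be >= 2 voxels")
    max_invasion <- max(max_invasion, s$finger_depth_um)
  }
  if (uses_islands) {
    if (s$island_radius_um[1] < 2 * s$voxel_um)
      stop_("island_radius_um mean must be >= 2 voxels")
    r_hi <- s$island_radius_um[1] + 3 * s$island_radius_um[2]
    max_invasion <- max(max_invasion, s$island_depth_range_um[2] + r_hi)
  }
  if (s$cancer_thickness_um + max_invasion + STROMA_MARGIN_UM > s$depth_um)
    stop_("geometry violation: cancer slab (%g um) + maximum invasion depth (%g um) + stroma margin (%g um) exceed the %g um volume depth",
          s$cancer_thickness_um, max_invasion, STROMA_MARGIN_UM, s$depth_um)
  invisible(spec)
}

spec_dims <- function(spec) {
  c(round(spec$depth_um / spec$voxel_um),
    round(spec$lateral_size_um[1] / spec$voxel_um),
    round(spec$lateral_size_um[2] / spec$voxel_um))
}

# Paint an ellipsoid (semi-axes in voxels, optionally rotated by theta about
# z) into `lab` with class `code`, restricted to voxels currently in
# `overwrite` classes. Coordinates are 0-based voxel indices of the centre.
paint_ellipsoid <- function(lab, d, zc, yc, xc, az, ay, ax, code,
                            overwrite, theta = 0) {
  rmax <- max(az, ay, ax)
  z0 <- max(0L, floor(zc - rmax)); z1 <- min(d[1] - 1L, ceiling(zc + rmax))
  y0 <- max(0L, floor(yc - rmax)); y1 <- min(d[2] - 1L, ceiling(yc + rmax))
  x0 <- max(0L, floor(xc - rmax)); x1 <- min(d[3] - 1L, ceiling(xc + rmax))
  if (z1 < z0 || y1 < y0 || x1 < x0) return(lab)
  zz <- (z0:z1) - zc; yy <- (y0:y1) - yc; xx <- (x0:x1) - xc
  bz <- length(zz); by <- length(yy); bx <- length(xx)
  # rotate lateral coordinates by -theta (major axis along rotated x)
  ct <- cos(theta); st <- sin(theta)
  Xr <- outer(yy * -st, xx * ct, `+`)   # by x bx
  Yr <- outer(yy * ct, xx * st, `+`)
  lat <- (Xr / ax)^2 + (Yr / ay)^2      # by x bx
  q <- array(rep((zz / az)^2, times = by * bx), c(bz, by, bx)) +
    array(rep(as.vector(lat), each = bz), c(bz, by, bx))
  sub <- lab[(z0:z1) + 1L, (y0:y1) + 1L, (x0:x1) + 1L, drop = FALSE]
  sel <- q <= 1 & array(sub %in% overwrite, dim(sub))
  sub[sel] <- code
  lab[(z0:z1) + 1L, (y0:y1) + 1L, (x0:x1) + 1L] <- sub
  lab
}

#' Build a phantom label volume with programmed ground truth
#'
#' Constructs the label volume (top cancer slab, invasion structures,
#' fibroblast-populated stroma) and computes all truth quantities by exact
#' voxel enumeration on the emitted volume. Deterministic given
#' `(spec, seed)`; random draws occur in a fixed documented order
#' (fibroblasts, then fingers/front bumps, then islands, sequentially), so
#' phantoms differing only in `island_count` share their first islands.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed (defaults to `spec$seed`).
#' @return a `programmed_truth` object: `label_volume`,
#'   `true_baseline_z_um`, `true_depth_of_invasion_um`,
#'   `true_iccr_volume_um3`, `true_invasion_fraction`,
#'   `per_island_volumes_um3`, plus the spec and seed used.
#' @export
build_label_volume <- function(spec, seed = spec$seed) {
  validate_phantom_spec(spec)
  vx <- spec$voxel_um
  d <- spec_dims(spec)
  ct_vox <- round(spec$cancer_thickness_um / vx)
  st_vox <- min(d[1] - ct_vox, round(spec$stroma_thickness_um / vx))
  lab <- array(CLASS_CODES[["medium"]], d)
  lab[seq_len(ct_vox), , ] <- CLASS_CODES[["cancer"]]
  if (st_vox > 0)
    lab[ct_vox + seq_len(st_vox), , ] <- CLASS_CODES[["matrix"]]

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  # 1. fibroblasts in the stroma (never overwrite cancer)
  stroma_mm3 <- (st_vox * prod(d[2:3]) * vx^3) * 1e-9
  n_fib <- round(spec$fibroblast_density * stroma_mm3)
  ax_f <- spec$fibroblast_axis_um / vx
  if (n_fib > 0 && st_vox > 0) {
    for (i in seq_len(n_fib)) {
      zc <- runif(1, ct_vox + ax_f[3], ct_vox + st_vox - 1 - ax_f[3])
      yc <- runif(1, 0, d[2] - 1)
      xc <- runif(1, 0, d[3] - 1)
      theta <- runif(1, 0, pi)
      lab <- paint_ellipsoid(lab, d, zc, yc, xc, ax_f[3], ax_f[2], ax_f[1],
                             CLASS_CODES[["stromal"]],
                             CLASS_CODES[["matrix"]], theta)
    }
  }

  finger_info <- list()
  if (spec$invasion_pattern %in% c("finger", "mixed") && spec$finger_count > 0) {
    r <- spec$finger_radius_um / vx
    fd <- round(spec$finger_depth_um / vx)
    for (i in seq_len(spec$finger_count)) {
      # snapped to the grid so the capsule tip reaches exactly ct + fd
      yc <- round(runif(1, r + 1, d[2] - r - 2))
      xc <- round(runif(1, r + 1, d[3] - r - 2))
      # capsule: cylinder from the slab bottom with a hemispherical tip
      tip_z <- ct_vox + fd - 1 - r   # sphere centre
      z0 <- ct_vox; z1 <- min(d[1] - 1L, ct_vox + fd - 1L)
      zz <- z0:z1
      y0 <- max(0L, floor(yc - r)); y1 <- min(d[2] - 1L, ceiling(yc + r))
      x0 <- max(0L, floor(xc - r)); x1 <- min(d[3] - 1L, ceiling(xc + r))
      lat <- outer(((y0:y1) - yc)^2, ((x0:x1) - xc)^2, `+`)  # squared lateral dist
      for (z in zz) {
        if (z <= tip_z) keep <- lat <= r^2
        else keep <- lat <= max(r^2 - (z - tip_z)^2, -1)
        if (!any(keep)) next
        sl <- lab[z + 1L, (y0:y1) + 1L, (x0:x1) + 1L]
        sl[keep & sl %in% c(CLASS_CODES[["matrix"]], CLASS_CODES[["stromal"]],
                            CLASS_CODES[["medium"]])] <- CLASS_CODES[["cancer"]]
        lab[z + 1L, (y0:y1) + 1L, (x0:x1) + 1L] <- sl
      }
      finger_info[[i]] <- list(yc = yc, xc = xc, r = r,
                               zmax = ct_vox + fd - 1)
    }
  }

  if (spec$invasion_pattern == "cohesive" && spec$finger_count > 0) {
    # smooth bulging front: compactly-supported cos^2 bumps added to the slab
    R <- 3 * spec$finger_radius_um / vx
    bump <- matrix(0, d[2], d[3])
    yi <- 0:(d[2] - 1); xi <- 0:(d[3] - 1)
    for (i in seq_len(spec$finger_count)) {
      yc <- runif(1, 0, d[2] - 1)
      xc <- runif(1, 0, d[3] - 1)
      amp <- runif(1, 0.5, 1) * spec$finger_depth_um / vx
      rr <- sqrt(outer((yi - yc)^2, (xi - xc)^2, `+`))
      contrib <- ifelse(rr < R, amp * cos(pi * rr / (2 * R))^2, 0)
      bump <- pmax(bump, contrib)
    }
    extra <- pmin(round(bump), d[1] - ct_vox - 1L)
    for (y in seq_len(d[2]))
      for (x in seq_len(d[3]))
        if (extra[y, x] > 0)
          lab[ct_vox + seq_len(extra[y, x]), y, x] <- CLASS_CODES[["cancer"]]
  }

  per_island <- numeric(0)
  if (spec$invasion_pattern %in% c("island", "mixed") && spec$island_count > 0) {
    clearance <- 2  # voxels between island surface and slab/fingers/islands
    placed <- list()
    lo <- spec$island_depth_range_um[1] / vx
    hi <- spec$island_depth_range_um[2] / vx
    for (i in seq_len(spec$island_count)) {
      ok <- FALSE
      for (attempt in 1:200) {
        r <- rnorm(1, spec$island_radius_um[1], spec$island_radius_um[2]) / vx
        r <- max(r, 2)
        d_lo <- max(lo, r + clearance)
        if (d_lo > hi)
          stop_("island %d cannot satisfy slab clearance within island_depth_range_um", i)
        dep <- runif(1, d_lo, hi)
        # snap island centres to the voxel grid so island voxel counts equal
        # the exact discrete-sphere enumeration for a given radius
        zc <- round(ct_vox + dep)
        yc <- round(runif(1, r + 1, d[2] - r - 2))
        xc <- round(runif(1, r + 1, d[3] - r - 2))
        if (zc + r + clearance > d[1] - 1)
          stop_("geometry violation: island %d extends beyond the volume depth", i)
        clear <- TRUE
        for (fg in finger_info) {
          lat_gap <- sqrt((yc - fg$yc)^2 + (xc - fg$xc)^2) - fg$r - r
          if (lat_gap < clearance && (zc - r) < fg$zmax + clearance) {
            clear <- FALSE; break
          }
        }
        if (clear) for (pl in placed) {
          gap <- sqrt((zc - pl$zc)^2 + (yc - pl$yc)^2 + (xc - pl$xc)^2) -
            pl$r - r
          if (gap < clearance) { clear <- FALSE; break }
        }
        if (clear) { ok <- TRUE; break }
      }
      if (!ok) stop_("could not place island %d without overlap after 200 attempts", i)
      before <- sum(lab == CLASS_CODES[["cancer"]])
      lab <- paint_ellipsoid(lab, d, zc, yc, xc, r, r, r,
                             CLASS_CODES[["cancer"]],
                             c(CLASS_CODES[["matrix"]], CLASS_CODES[["stromal"]],
                               CLASS_CODES[["medium"]]))
      per_island <- c(per_island, (sum(lab == CLASS_CODES[["cancer"]]) - before) * vx^3)
      placed[[length(placed) + 1L]] <- list(zc = zc, yc = yc, xc = xc, r = r)
    }
  }

  lv <- label_volume(lab, voxel_um = vx)
  truth_from_labels(lv, baseline_z_um = ct_vox * vx,
                    per_island_volumes_um3 = per_island,
                    spec = spec, seed = seed)
}

# Exact truth bookkeeping by voxel enumeration on a label volume.
truth_from_labels <- function(lv, baseline_z_um, per_island_volumes_um3,
                              spec, seed) {
  vx <- lv$voxel_um
  d <- dim(lv$data)
  cancer <- lv$data == CLASS_CODES[["cancer"]]
  z_top_um <- z_index_array(d) * vx       # depth of each voxel's top face
  n_iccr <- sum(cancer & z_top_um >= baseline_z_um)
  n_total <- sum(cancer)
  doi <- if (n_total > 0) {
    max(0, max(z_top_um[cancer]) + vx - baseline_z_um)
  } else 0
  structure(list(
    label_volume = lv,
    true_baseline_z_um = baseline_z_um,
    true_depth_of_invasion_um = doi,
    true_iccr_volume_um3 = n_iccr * vx^3,
    true_invasion_fraction = if (n_total > 0) n_iccr / n_total else 0,
    per_island_volumes_um3 = per_island_volumes_um3,
    spec = spec, seed = seed), class = "programmed_truth")
}

#' @export
print.programmed_truth <- function(x, ...) {
  cat(sprintf("<programmed_truth> pattern %s | baseline %g um | DOI %g um | V_ICCR %g um^3 (fraction %.3f) | %d islands\n",
              x$spec$invasion_pattern, x$true_baseline_z_um,
              x$true_depth_of_invasion_um, x$true_iccr_volume_um3,
              x$true_invasion_fraction, length(x$per_island_volumes_um3)))
  invisible(x)
}

#' Render a label volume into an OCT-like intensity volume
#'
#' Per voxel: class mean intensity, exponential depth attenuation
#' `exp(-mu * z_um)`, multiplicative Gamma(k, mean 1) speckle, anisotropic
#' Gaussian PSF blur (stated FWHMs), additive Gaussian read noise, clamping
#' to \[0, 65535\] and integer quantization. Deterministic given
#' `(spec, seed)`; speckle is drawn before read noise from a single stream.
#'
#' @param truth a `programmed_truth` from [build_label_volume()] (or any
#'   object with a `$label_volume`).
#' @param spec the [phantom_spec()] controlling optics and noise.
#' @param seed integer RNG seed (defaults to `spec$seed`).
#' @return an [oct_volume()].
#' @export
render_oct <- function(truth, spec, seed = spec$seed) {
  lv <- if (inherits(truth, "label_volume")) truth else truth$label_volume
  d <- dim(lv$data)
  vx <- lv$voxel_um
  means <- spec$class_mean_intensity[c("medium", "cancer", "stromal", "matrix")]
  img <- array(means[as.integer(lv$data) + 1L], d)
  if (spec$attenuation_per_um > 0)
    img <- img * exp(-spec$attenuation_per_um * z_index_array(d) * vx)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  if (is.finite(spec$speckle_shape)) {
    k <- spec$speckle_shape
    img <- img * rgamma(length(img), shape = k, rate = k)
  }
  sig_ax <- spec$psf_axial_fwhm_um / (2 * sqrt(2 * log(2))) / vx
  sig_lat <- spec$psf_lateral_fwhm_um / (2 * sqrt(2 * log(2))) / vx
  kz <- gaussian_kernel(sig_ax)
  kl <- gaussian_kernel(sig_lat)
  if (length(kz) > 1 || length(kl) > 1)
    img <- conv_separable(img, list(kz, kl, kl))
  if (spec$read_noise_sd > 0)
    img <- img + rnorm(length(img), 0, spec$read_noise_sd)
  img <- round(pmin(pmax(img, 0), 65535))
  storage.mode(img) <- "integer"
  oct_volume(img, voxel_um = vx,
             provenance = sprintf("octinvasion phantom (pattern=%s, seed=%d)",
                                  spec$invasion_pattern, as.integer(seed)))
}

#' Extract a 2-D slice from a volume
#'
#' `"XY"` returns the lateral plane at depth index `index`; `"XZ"` the
#' cross-sectional plane (rows = depth, columns = x) at lateral index
#' `index`, matching the instrument's cross-sectional scans.
#'
#' @param volume an [oct_volume()], [label_volume()] or 3-D array.
#' @param axis `"XY"` or `"XZ"`.
#' @param index 1-based plane index.
#' @return a matrix with attributes `voxel_um` and `axis`.
#' @export
extract_slice <- function(volume, axis = c("XY", "XZ"), index) {
  axis <- match.arg(axis)
  arr <- if (is.list(volume)) volume$data else volume
  d <- assert_dims3(arr)
  vx <- if (is.list(volume)) volume$voxel_um else 1
  lim <- if (axis == "XY") d[1] else d[2]
  if (index < 1 || index > lim || index != round(index))
    stop_("slice index %s out of range [1, %d]", format(index), lim)
  sl <- if (axis == "XY") arr[index, , ] else arr[, index, ]
  structure(sl, voxel_um = vx, axis = axis)
}
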