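# Invasion metrics: volumetric (ICCR volume, mass invasion index, depth of
# invasion), planimetric (hypothetical-invasion-front surface area), and the
# 2-D histomorphometric section metrics (depth of invasion, invasion index
# over random high-power fields).

#' Volumes of the cancer partition
#'
#' Exact voxel counts times the voxel volume. The ICCR volume is the
#' subtraction-based volumetric invasion parameter:
#' `v_iccr = v_total - v_original`, an identity that holds exactly on every
#' partition by construction.
#'
#' @param partition a `region_partition` from [partition_cancer()].
#' @return list with `v_total_um3`, `v_original_um3`, `v_iccr_um3`.
#' @export
iccr_volume <- function(partition) {
  vx3 <- partition$voxel_um^3
  list(v_total_um3 = sum(partition$cancer_mask) * vx3,
       v_original_um3 = sum(partition$original_mask) * vx3,
       v_iccr_um3 = sum(partition$invasive_mask) * vx3)
}

#' Height map of the hypothetical invasion front (HIF)
#'
#' The HIF is realized as a single-valued lower-envelope height field: for
#' each lateral column, the bottom face depth of the deepest cancer voxel
#' that is part of the contiguous cancer mass (original region or invasive
#' voxels connected to it). Detached islands are excluded by construction.
#' Columns containing no contiguous cancer (stromal layer exposed to the
#' surface) get height 0.
#'
#' @param partition a `region_partition`; must contain an original region.
#' @return numeric (ny, nx) matrix of front depths in micrometres, with
#'   attribute `voxel_um`.
#' @export
hif_height_map <- function(partition) {
  if (!any(partition$original_mask))
    stop_("no original region: cannot construct the invasion front")
  eligible <- partition$original_mask | partition$connected_to_original
  d <- dim(eligible)
  deepest <- column_deepest_cpp(as.logical(eligible), as.integer(d))
  hm <- (deepest + 1L) * partition$voxel_um  # bottom face depth; -1 -> 0
  structure(hm, voxel_um = partition$voxel_um)
}

#' Surface area of a height field
#'
#' Triangulates the height field with two triangles per lateral cell.
#' Columns sample the surface at cell centres `(i - 1/2) * voxel_um`; edge
#' values are replicated half a voxel outward so the node grid spans exactly
#' the lateral ROI and a flat front over an Lx x Ly ROI has area exactly
#' `Lx * Ly`. A convoluted front is therefore never smaller than its flat
#' projection.
#'
#' @param height_map numeric (ny, nx) matrix of depths (um), e.g. from
#'   [hif_height_map()].
#' @param voxel_um lateral sample spacing (um); defaults to the matrix's
#'   `voxel_um` attribute.
#' @return surface area in um^2.
#' @export
hif_surface_area <- function(height_map, voxel_um = attr(height_map, "voxel_um")) {
  if (is.null(voxel_um)) stop_("voxel_um not given and not an attribute")
  h <- voxel_um
  ny <- nrow(height_map); nx <- ncol(height_map)
  # node grid: replicate border columns/rows half a voxel outward
  Z <- rbind(height_map[1, , drop = FALSE], height_map,
             height_map[ny, , drop = FALSE])
  Z <- cbind(Z[, 1, drop = FALSE], Z, Z[, nx, drop = FALSE])
  yc <- c(0, (seq_len(ny) - 0.5) * h, ny * h)
  xc <- c(0, (seq_len(nx) - 0.5) * h, nx * h)
  ii <- seq_len(ny + 1L)  # cell row index over the node grid
  jj <- seq_len(nx + 1L)
  dy <- diff(yc)  # per cell-row heights
  dx <- diff(xc)
  z00 <- Z[ii, jj, drop = FALSE]
  z10 <- Z[ii + 1L, jj, drop = FALSE]
  z01 <- Z[ii, jj + 1L, drop = FALSE]
  z11 <- Z[ii + 1L, jj + 1L, drop = FALSE]
  DY <- matrix(dy, ny + 1L, nx + 1L)
  DX <- matrix(dx, ny + 1L, nx + 1L, byrow = TRUE)
  # triangle (00, 10, 01): edges (DY, z10-z00) x (DX, z01-z00)
  a1 <- 0.5 * sqrt((DY * (z01 - z00))^2 + (DX * (z10 - z00))^2 + (DY * DX)^2)
  # triangle (11, 01, 10)
  a2 <- 0.5 * sqrt((DY * (z10 - z11))^2 + (DX * (z01 - z11))^2 + (DY * DX)^2)
  sum(a1) + sum(a2)
}

#' Mass invasion index
#'
#' The volumetric counterpart of the 2-D invasion index. The default
#' `"invasive_fraction"` form returns `v_iccr / v_total`, sharing the 2-D
#' index's anchors: 0 = no infiltration, 1 = complete infiltration (original
#' layer fully consumed). `form = "printed"` returns the literal published
#' formula `1 - v_iccr / v_total`, whose anchors are reversed.
#'
#' @param partition a `region_partition` with at least one cancer voxel.
#' @param form `"invasive_fraction"` (default) or `"printed"`.
#' @return scalar in \[0, 1\].
#' @export
mass_invasion_index <- function(partition,
                                form = c("invasive_fraction", "printed")) {
  form <- match.arg(form)
  vols <- iccr_volume(partition)
  if (vols$v_total_um3 <= 0)
    stop_("mass invasion index undefined: no cancer voxels (v_total = 0)")
  frac <- vols$v_iccr_um3 / vols$v_total_um3
  if (form == "printed") 1 - frac else frac
}

#' Depth of invasion (3-D)
#'
#' Maximum vertical distance from the baseline plane (the bottom of the
#' original cancer cell region) to the invasion front: the bottom-face depth
#' of the deepest cancer voxel minus the baseline, floored at 0. Detached
#' islands count.
#'
#' @param partition a `region_partition`.
#' @return depth in micrometres (>= 0).
#' @export
depth_of_invasion_3d <- function(partition) {
  if (!any(partition$cancer_mask)) return(0)
  d <- dim(partition$cancer_mask)
  deepest <- column_deepest_cpp(as.logical(partition$cancer_mask),
                                as.integer(d))
  max(0, (max(deepest) + 1) * partition$voxel_um - partition$baseline_z_um)
}

#' All 3-D invasion metrics of a partition
#'
#' Convenience wrapper collecting `v_total`, `v_original`, `v_iccr`, the HIF
#' surface area, the mass invasion index and the depth of invasion into a
#' one-row data.frame matching the metrics-table column contract.
#'
#' @param partition a `region_partition`.
#' @param mass_index_form passed to [mass_invasion_index()].
#' @return one-row data.frame.
#' @export
invasion_metrics <- function(partition,
                             mass_index_form = c("invasive_fraction", "printed")) {
  vols <- iccr_volume(partition)
  data.frame(v_total_um3 = vols$v_total_um3,
             v_original_um3 = vols$v_original_um3,
             v_iccr_um3 = vols$v_iccr_um3,
             hif_area_um2 = hif_surface_area(hif_height_map(partition)),
             mass_invasion_index = mass_invasion_index(partition,
                                                       mass_index_form),
             depth_of_invasion_um = depth_of_invasion_3d(partition))
}

#' 2-D histomorphometric metrics over random section fields
#'
#' Emulates the histological protocol: within one cross-sectional (X-Z)
#' label image, a number of random, non-overlapping lateral fields is
#' selected (seeded draw) and, per field, the depth of invasion and the
#' invasion index `1 - area(original) / area(total cancer)` are computed
#' with the same baseline/depth conventions as the 3-D metrics. Fields
#' containing no cancer are skipped with a message. If the section has no
#' cancer at the top surface (original layer fully consumed) the baseline is
#' 0 and the index is 1 by the published anchor convention.
#'
#' @param label_slice integer matrix (rows = z from the top, cols = x):
#'   class codes, cancer = 1; logical matrices are taken as cancer masks.
#' @param n_fields number of random fields (default 5).
#' @param field_width_um lateral field width; default one fifth of the
#'   section width.
#' @param voxel_um pixel size (um); defaults to the slice's `voxel_um`
#'   attribute, else 1.
#' @param seed RNG seed for field placement.
#' @param baseline_z_um optional externally known baseline; estimated from
#'   the slice when NULL.
#' @return data.frame with one row per retained field: `field`, `x0_um`,
#'   `x1_um`, `depth_of_invasion_um`, `invasion_index`; the baseline is
#'   attached as attribute `baseline_z_um`.
#' @export
section_metrics <- function(label_slice, n_fields = 5, field_width_um = NULL,
                            voxel_um = NULL, seed = 1L,
                            baseline_z_um = NULL) {
  vx <- voxel_um %||% attr(label_slice, "voxel_um") %||% 1
  cancer <- if (is.logical(label_slice)) label_slice else label_slice == 1L
  if (!any(cancer)) stop_("no cancer present in the section")
  nz <- nrow(cancer); nx <- ncol(cancer)
  if (is.null(baseline_z_um)) {
    mask3 <- array(cancer, c(nz, 1L, nx))
    baseline_z_um <- tryCatch(estimate_baseline(mask3, vx),
                              error = function(e) {
                                message("section_metrics: no original region at the top surface; baseline set to 0 (complete infiltration convention)")
                                0
                              })
  }
  w_vox <- if (is.null(field_width_um)) {
    max(1L, nx %/% n_fields)  # default: fields tile the section width
  } else {
    max(1L, round(field_width_um / vx))
  }
  w_vox <- min(w_vox, nx)
  origins <- place_fields(nx, w_vox, n_fields, seed)
  above <- matrix(rep((0:(nz - 1)) * vx < baseline_z_um, nx), nz, nx)
  rows <- lapply(seq_along(origins), function(i) {
    x0 <- origins[i]
    cols <- x0:(x0 + w_vox - 1L)
    fc <- cancer[, cols, drop = FALSE]
    if (!any(fc)) {
      message(sprintf("section_metrics: field %d contains no cancer; skipped", i))
      return(NULL)
    }
    n_total <- sum(fc)
    n_orig <- sum(fc & above[, cols, drop = FALSE])
    zmax <- max(which(rowSums(fc) > 0))  # deepest cancer row (1-based)
    data.frame(field = i,
               x0_um = (x0 - 1L) * vx,
               x1_um = (x0 - 1L + w_vox) * vx,
               depth_of_invasion_um = max(0, zmax * vx - baseline_z_um),
               invasion_index = 1 - n_orig / n_total)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop_("all fields were empty of cancer")
  attr(out, "baseline_z_um") <- baseline_z_um
  out
}

# Seeded draw of n non-overlapping field origins (1-based) over nx columns.
# Random non-overlapping placement is attempted by rejection; if the section
# cannot host n disjoint random fields, fields fall back to an even tiling.
place_fields <- function(nx, w_vox, n_fields, seed) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  if (n_fields * w_vox > nx) {
    n_slots <- max(1L, nx %/% w_vox)
    if (n_fields > n_slots)
      stop_("cannot place %d non-overlapping fields of %d px in a %d px section",
            n_fields, w_vox, nx)
  }
  placed <- integer(0)
  for (attempt in seq_len(200L * n_fields)) {
    if (length(placed) == n_fields) break
    cand <- sample.int(nx - w_vox + 1L, 1L)
    if (all(abs(cand - placed) >= w_vox)) placed <- c(placed, cand)
  }
  if (length(placed) < n_fields) {
    # even tiling fallback (deterministic)
    placed <- 1L + (seq_len(n_fields) - 1L) * ((nx - w_vox) %/%
                                                 max(1L, n_fields - 1L))
  }
  placed
}
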