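# Partition of the cancer mask into the original cancer cell region and the
# invasive cancer cell region (ICCR), baseline-plane estimation, and 3-D
# object enumeration (the "3D object counter" analog).
#
# Depth conventions: voxel z (0-based) spans depths [z, z+1) * voxel_um; the
# baseline is a horizontal plane at depth baseline_z_um. A voxel belongs to
# the original region iff its top face lies above the plane
# (z * voxel_um < baseline), i.e. invasive voxels lie entirely below it.
# The original region is defined geometrically (cancer above the plane), not
# as a connected component, so fingers that remain connected to the slab
# still count as invasive below the plane and volume conservation
# v_original + v_iccr = v_total holds exactly by construction.

#' Estimate the baseline plane from a cancer mask
#'
#' For every lateral column whose top-surface voxel is cancer, the bottom of
#' the contiguous-from-top cancer run is recorded; the baseline is the mode
#' of these per-column bottoms (ties broken toward the smaller depth). If the
#' mode is supported by fewer than 5% of eligible columns the median is used
#' instead (heavily convoluted front). Errors when no cancer is present in
#' the top 10% of the depth range ("no original region").
#'
#' @param cancer_mask logical (z, y, x) array.
#' @param voxel_um voxel size (um).
#' @return baseline depth in micrometres.
#' @export
estimate_baseline <- function(cancer_mask, voxel_um = 1) {
  d <- assert_dims3(cancer_mask, "cancer mask")
  if (!any(cancer_mask)) stop_("no original region: cancer mask is empty")
  top_band <- max(1L, floor(d[1] * 0.10))
  if (!any(cancer_mask[seq_len(top_band), , ]))
    stop_("no original region: no cancer voxels in the top 10%% of the depth range")
  runs <- column_top_run_cpp(as.logical(cancer_mask), as.integer(d))
  runs <- runs[runs > 0L]
  if (!length(runs))
    stop_("no original region: no lateral column has top-surface cancer")
  tab <- tabulate(runs, nbins = d[1])
  mode_run <- which.max(tab)  # which.max takes the first max: smaller depth
  if (tab[mode_run] < 0.05 * length(runs))
    mode_run <- median(runs)
  mode_run * voxel_um
}

#' Partition the cancer mask at the baseline plane
#'
#' Splits cancer voxels into the original region (above the plane) and the
#' invasive region (below it), and flags every invasive voxel that has a
#' 26-connected path through cancer voxels back to the original region
#' (fingers: connected; detached islands: not).
#'
#' @param cancer_mask logical (z, y, x) array.
#' @param baseline_z_um baseline plane depth (um), within the volume depth.
#' @param voxel_um voxel size (um).
#' @return a `region_partition`: `cancer_mask`, `original_mask`,
#'   `invasive_mask`, `connected_to_original` (logical array, TRUE only on
#'   invasive voxels reachable from the original region), `baseline_z_um`,
#'   `voxel_um`.
#' @export
partition_cancer <- function(cancer_mask, baseline_z_um, voxel_um = 1) {
  d <- assert_dims3(cancer_mask, "cancer mask")
  if (baseline_z_um < 0 || baseline_z_um > d[1] * voxel_um)
    stop_("baseline %g um lies outside the volume depth [0, %g]",
          baseline_z_um, d[1] * voxel_um)
  cancer_mask <- array(as.logical(cancer_mask), d)
  above <- z_index_array(d) * voxel_um < baseline_z_um
  original <- cancer_mask & above
  invasive <- cancer_mask & !above
  reach <- array(flood_reachable_cpp(as.logical(cancer_mask),
                                     as.logical(original),
                                     as.integer(d), 26L), d)
  structure(list(cancer_mask = cancer_mask,
                 original_mask = original,
                 invasive_mask = invasive,
                 connected_to_original = reach & invasive,
                 baseline_z_um = baseline_z_um,
                 voxel_um = voxel_um),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  vx3 <- x$voxel_um^3
  cat(sprintf("<region_partition> baseline %g um | V_total %g | V_original %g | V_ICCR %g um^3 (%g connected)\n",
              x$baseline_z_um, sum(x$cancer_mask) * vx3,
              sum(x$original_mask) * vx3, sum(x$invasive_mask) * vx3,
              sum(x$connected_to_original) * vx3))
  invisible(x)
}

#' Enumerate 3-D objects in a binary mask
#'
#' Connected-component labeling with per-object voxel count, volume,
#' bounding box and centroid -- the voxel-counting "3D object counter"
#' analog. Object ids are dense from 1 in scan order.
#'
#' @param mask logical (z, y, x) array.
#' @param voxel_um voxel size (um).
#' @param connectivity 26 (default; diagonal contacts join) or 6.
#' @return data.frame with columns `id`, `voxel_count`, `volume_um3`,
#'   `z/y/x min/max` (1-based voxel indices) and centroid coordinates (um).
#' @export
label_components <- function(mask, voxel_um = 1, connectivity = 26) {
  d <- assert_dims3(mask, "mask")
  empty <- data.frame(id = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0),
                      zmin = integer(0), zmax = integer(0),
                      ymin = integer(0), ymax = integer(0),
                      xmin = integer(0), xmax = integer(0),
                      centroid_z_um = numeric(0), centroid_y_um = numeric(0),
                      centroid_x_um = numeric(0))
  if (!any(mask)) return(empty)
  labs <- label_components_cpp(as.logical(mask), as.integer(d),
                               as.integer(connectivity))
  idx <- which(labs > 0L)
  lab_i <- labs[idx]
  z <- (idx - 1L) %% d[1]
  y <- ((idx - 1L) %/% d[1]) %% d[2]
  x <- (idx - 1L) %/% (d[1] * d[2])
  n <- tabulate(lab_i)
  lab_f <- factor(lab_i, levels = seq_along(n))  # numeric level order
  agg <- function(v, f) as.vector(tapply(v, lab_f, f))
  data.frame(id = seq_along(n),
             voxel_count = n,
             volume_um3 = n * voxel_um^3,
             zmin = agg(z, min) + 1L, zmax = agg(z, max) + 1L,
             ymin = agg(y, min) + 1L, ymax = agg(y, max) + 1L,
             xmin = agg(x, min) + 1L, xmax = agg(x, max) + 1L,
             centroid_z_um = agg(z, mean) * voxel_um,
             centroid_y_um = agg(y, mean) * voxel_um,
             centroid_x_um = agg(x, mean) * voxel_um)
}

#' Object table for a partitioned cancer mask
#'
#' [label_components()] on the cancer mask plus a `touches_original` flag:
#' TRUE for objects containing at least one original-region voxel (the
#' contiguous cancer mass), FALSE for detached invasive islands. This
#' preserves the stricter "spatially separated clusters or islands" reading
#' of the ICCR alongside the subtraction-based volume.
#'
#' @param partition a `region_partition`.
#' @param connectivity 26 or 6.
#' @return the component data.frame with a `touches_original` column.
#' @export
component_table <- function(partition, connectivity = 26) {
  d <- dim(partition$cancer_mask)
  tab <- label_components(partition$cancer_mask, partition$voxel_um,
                          connectivity)
  if (!nrow(tab)) {
    tab$touches_original <- logical(0)
    return(tab)
  }
  labs <- label_components_cpp(as.logical(partition$cancer_mask),
                               as.integer(d), as.integer(connectivity))
  with_orig <- unique(labs[as.logical(partition$original_mask)])
  tab$touches_original <- tab$id %in% with_orig
  tab
}
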