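# Shared fixtures and independent oracles. Everything here is deliberately
# written by a different route than the package code it checks.

# -- small phantom specs used across tests ------------------------------------

small_spec <- function(pattern = "mixed", lat = 48, depth = 64, ct = 16, ...) {
  args <- list(lateral_size_um = c(lat, lat), depth_um = depth, voxel_um = 1,
               cancer_thickness_um = ct, invasion_pattern = pattern,
               finger_count = 3, finger_depth_um = 18, finger_radius_um = 4,
               island_count = 3, island_radius_um = c(mean = 4.5, sd = 0.8),
               island_depth_range_um = c(8, 28),
               fibroblast_density = 2000, fibroblast_axis_um = c(6, 2, 2))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# noiseless, blur-free rendering options
noiseless <- list(speckle_shape = Inf, read_noise_sd = 0,
                  attenuation_per_um = 0, psf_lateral_fwhm_um = 0,
                  psf_axial_fwhm_um = 0)

noiseless_spec <- function(pattern = "mixed", ...) {
  args <- noiseless
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(small_spec, c(list(pattern = pattern), args))
}

# acceptance-scale spec: 128 x 128 x 256 voxels, default noise/optics
accept_spec <- function(pattern) {
  phantom_spec(lateral_size_um = c(128, 128), depth_um = 256, voxel_um = 1,
               cancer_thickness_um = 60,
               invasion_pattern = pattern,
               finger_count = if (pattern == "cohesive") 3 else 4,
               finger_depth_um = if (pattern == "cohesive") 40 else 60,
               finger_radius_um = if (pattern == "cohesive") 8 else 10,
               island_count = 4, island_radius_um = c(mean = 10, sd = 2),
               island_depth_range_um = c(15, 100),
               fibroblast_density = 2000, fibroblast_axis_um = c(10, 3, 3))
}

# -- brute-force oracles ------------------------------------------------------

# voxel centres strictly inside a radius-r sphere centred on a voxel centre
bf_sphere_count <- function(r) {
  g <- expand.grid(z = -ceiling(r):ceiling(r), y = -ceiling(r):ceiling(r),
                   x = -ceiling(r):ceiling(r))
  sum(g$z^2 + g$y^2 + g$x^2 <= r^2)
}

# connected components via igraph over an explicitly built adjacency list
bf_components_igraph <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(integer(0))
  pos <- arrayInd(idx, d)
  id_of <- array(0L, d)
  id_of[idx] <- seq_along(idx)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2, as.numeric(offs[k, ]), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    to <- id_of[nb[ok, , drop = FALSE]]
    from <- seq_along(idx)[ok]
    keep <- to > 0L
    if (any(keep)) edges <- rbind(edges, cbind(from[keep], to[keep]))
  }
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  igraph::components(g)$membership
}

# literal O(n^2) union-find over all voxel pairs (tiny masks only)
bf_components_unionfind <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  pos <- arrayInd(idx, d)
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(idx)) for (j in seq_len(i - 1L)) {
    dd <- abs(pos[i, ] - pos[j, ])
    adjacent <- if (connectivity == 26) all(dd <= 1) else sum(dd) == 1
    if (adjacent) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_along(idx), find, 0L)
}

# canonical form of a component labeling: relabel by first occurrence
canonical_labels <- function(lab) {
  lab <- as.integer(lab)
  match(lab, unique(lab))
}

# fine-grid quadrature of the surface-area integral for z = f(x, y) over
# [0, Lx] x [0, Ly]: integral sqrt(1 + fx^2 + fy^2) dx dy (midpoint rule)
bf_surface_area_quadrature <- function(f, fx, fy, Lx, Ly, h = 0.1) {
  xs <- seq(h / 2, Lx - h / 2, by = h)
  ys <- seq(h / 2, Ly - h / 2, by = h)
  total <- 0
  for (y in ys)
    total <- total + sum(sqrt(1 + fx(xs, y)^2 + fy(xs, y)^2)) * h * h
  total
}

# Mann-Whitney U computed by pair counting (not midranks)
bf_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

# exact two-sided Mann-Whitney p by enumeration of group assignments,
# statistic computed by pair counting
bf_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  combos <- utils::combn(n, nx)
  u_obs <- bf_u_stat(x, y)
  u_all <- apply(combos, 2, function(ix) bf_u_stat(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# truth quantities recomputed from a label volume by an independent route
# (slice.index instead of the package's z index array)
bf_truth_from_labels <- function(lv, baseline) {
  cancer <- lv$data == 1L
  depth_top <- (slice.index(lv$data, 1) - 1) * lv$voxel_um
  list(iccr = sum(cancer & depth_top >= baseline) * lv$voxel_um^3,
       total = sum(cancer) * lv$voxel_um^3,
       doi = if (any(cancer)) max(0, max(depth_top[cancer]) + lv$voxel_um - baseline) else 0)
}

# deterministic seeded random mask
random_mask <- function(d, p, seed) {
  set.seed(seed)
  array(runif(prod(d)) < p, d)
}
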