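# Voxel segmentation: trainable Gaussian discriminant classifier over
# multi-scale intensity, local-variance texture and normalized-depth
# features, plus the global-threshold (Otsu) baseline it is compared
# against. The classifier stands in for a CNN trained on labeled
# cross-sectional (X-Z) images: features are computed strictly in-plane
# (z and x), so training on 2-D slices and inference on 3-D volumes use
# identical feature definitions. The interface is pluggable; any model
# mapping the same feature matrix to class posteriors can be substituted.

#' Crop a region of interest from a volume
#'
#' Removes surrounding culture medium/dish signal by restricting the volume
#' to a rectangular ROI. Coordinates are in micrometres on the (z, y, x)
#' axes; `origin_um = c(0, 0, 0)` is the top-surface corner. The ROI must
#' lie entirely inside the volume; values are unchanged.
#'
#' @param volume an [oct_volume()] (or [label_volume()]).
#' @param origin_um ROI origin `c(z, y, x)` in micrometres (top faces).
#' @param size_um ROI extent `c(z, y, x)` in micrometres.
#' @return a volume of the same class with the requested size.
#' @export
crop_roi <- function(volume, origin_um, size_um) {
  arr <- volume$data
  d <- assert_dims3(arr)
  vx <- volume$voxel_um
  origin_um <- rep(origin_um, length.out = 3)
  size_um <- rep(size_um, length.out = 3)
  if (any(origin_um < 0)) stop_("ROI origin must be non-negative")
  if (any(size_um <= 0)) stop_("ROI size must be positive")
  i0 <- round(origin_um / vx)
  n <- round(size_um / vx)
  if (any(i0 + n > d))
    stop_("ROI out of bounds: origin %s um + size %s um exceeds volume extent %s um",
          paste(origin_um, collapse = "x"), paste(size_um, collapse = "x"),
          paste(d * vx, collapse = "x"))
  out <- arr[i0[1] + seq_len(n[1]), i0[2] + seq_len(n[2]),
             i0[3] + seq_len(n[3]), drop = FALSE]
  if (inherits(volume, "label_volume")) label_volume(out, vx)
  else oct_volume(out, vx, provenance = volume$provenance)
}

#' Feature specification for voxel classification
#'
#' @param smoothing_scales_um Gaussian smoothing scales (sigma, um) applied
#'   to log-intensity; must be positive and strictly increasing.
#' @param texture_window_um edge length of the local-variance window (um).
#' @param include_depth add depth normalized to \[0, 1\] as a feature; this
#'   is what lets a linear classifier undo exponential depth attenuation of
#'   log-intensity (the depth-bias the learning-based approach addresses).
#' @return a `feature_spec` object.
#' @export
feature_spec <- function(smoothing_scales_um = c(1, 2, 4),
                         texture_window_um = 5,
                         include_depth = TRUE) {
  if (any(smoothing_scales_um <= 0) ||
      is.unsorted(smoothing_scales_um, strictly = TRUE))
    stop_("smoothing scales must be positive and strictly increasing")
  if (texture_window_um <= 0) stop_("texture window must be positive")
  structure(list(smoothing_scales_um = smoothing_scales_um,
                 texture_window_um = texture_window_um,
                 include_depth = isTRUE(include_depth)),
            class = "feature_spec")
}

# Feature matrix for a (z, y, x) intensity array. All smoothing is in-plane
# (z and x only) so 2-D X-Z training slices and 3-D volumes match.
compute_features <- function(arr, voxel_um, fspec) {
  d <- assert_dims3(arr, "intensity array")
  logi <- log1p(as.double(arr))
  dim(logi) <- d
  feats <- list(logI_raw = as.vector(logi))
  for (s in fspec$smoothing_scales_um) {
    k <- gaussian_kernel(s / voxel_um)
    feats[[sprintf("logI_s%g", s)]] <-
      as.vector(conv_separable(logi, list(k, NULL, k)))
  }
  w <- max(3L, round(fspec$texture_window_um / voxel_um))
  if (w %% 2L == 0L) w <- w + 1L
  box <- rep(1 / w, w)
  m1 <- conv_separable(logi, list(box, NULL, box))
  m2 <- conv_separable(logi^2, list(box, NULL, box))
  feats[["texture_var"]] <- pmax(as.vector(m2 - m1^2), 0)
  if (fspec$include_depth)
    feats[["depth"]] <- as.vector(z_index_array(d)) / max(d[1] - 1L, 1L)
  do.call(cbind, feats)
}

# wrap an X-Z slice (rows = z, cols = x) as a (z, 1, x) pseudo-volume
slice_as_volume <- function(sl) {
  array(as.double(sl), c(nrow(sl), 1L, ncol(sl)))
}

## ---- Gaussian discriminant (LDA / QDA) fit on voxel features ----
## Hand-rolled so the model is a plain parameter list (JSON-serializable for
## the CLI contract) and the class-balance convention is explicit: priors are
## uniform over observed classes, i.e. voxels are weighted inversely to class
## frequency, which keeps the dominant stroma from swamping the fit.

gd_fit <- function(X, y, type = c("qda", "lda"), ridge = 1e-6) {
  type <- match.arg(type)
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop_("training labels contain a single class (%s); need >= 2", classes[1])
  p <- ncol(X)
  means <- matrix(0, length(classes), p)
  covs <- vector("list", length(classes))
  pooled <- matrix(0, p, p)
  n_per <- integer(length(classes))
  for (i in seq_along(classes)) {
    Xi <- X[y == classes[i], , drop = FALSE]
    n_per[i] <- nrow(Xi)
    means[i, ] <- colMeans(Xi)
    ci <- crossprod(sweep(Xi, 2, means[i, ])) / max(nrow(Xi) - 1L, 1L)
    covs[[i]] <- ci
    pooled <- pooled + ci * (nrow(Xi) - 1L)
  }
  pooled <- pooled / max(sum(n_per) - length(classes), 1L)
  reg <- function(S) S + diag(ridge * mean(diag(S)) + 1e-12, p)
  if (type == "lda") covs <- rep(list(reg(pooled)), length(classes))
  else covs <- lapply(covs, reg)
  list(type = type, classes = classes, means = means, covs = covs,
       n_per_class = n_per, feature_names = colnames(X))
}

# class scores (log-posterior up to a constant, uniform priors)
gd_scores <- function(fit, X) {
  n <- nrow(X)
  scores <- matrix(0, n, length(fit$classes))
  for (i in seq_along(fit$classes)) {
    ch <- chol(fit$covs[[i]])
    Xc <- sweep(X, 2, fit$means[i, ])
    Z <- Xc %*% backsolve(ch, diag(ncol(X)))  # whitened residuals
    scores[, i] <- -0.5 * rowSums(Z^2) - sum(log(diag(ch)))
  }
  scores
}

gd_predict <- function(fit, X) {
  # single-pass C++ argmax (identical scores to gd_scores, which remains the
  # small-n reference implementation exercised in the tests)
  qs <- lapply(fit$covs, function(S) chol2inv(chol(S)))
  consts <- vapply(fit$covs,
                   function(S) -sum(log(diag(chol(S)))), 0)
  means <- lapply(seq_along(fit$classes), function(i) fit$means[i, ])
  fit$classes[gd_assign_cpp(X, means, qs, consts)]
}

#' Train a voxel classifier from labeled cross-sectional slices
#'
#' Mirrors the workflow of training a semantic-segmentation model on labeled
#' X-Z images: each slice contributes per-voxel features (in-plane
#' multi-scale log-intensity, local variance, normalized depth) and its label
#' image; a Gaussian discriminant (QDA by default) is fitted with uniform
#' class priors. A stratified voxel subsample keeps the fit desk-scale.
#'
#' @param slices list of labeled slices; each element is a list (or pair)
#'   with an intensity matrix (`image`, rows = z) and an integer label matrix
#'   (`labels`) of identical shape.
#' @param fspec a [feature_spec()].
#' @param type `"qda"` (class-specific covariance) or `"lda"` (pooled).
#' @param voxel_um voxel size of the training slices.
#' @param max_voxels_per_class stratified subsample cap per class.
#' @param seed RNG seed for the subsample (deterministic training).
#' @return a `voxel_classifier` with the fitted model and a training summary
#'   (slice count, voxels per class, training-set voxel accuracy).
#' @export
train_classifier <- function(slices, fspec = feature_spec(),
                             type = c("qda", "lda"), voxel_um = 1,
                             max_voxels_per_class = 20000, seed = 1L) {
  type <- match.arg(type)
  if (length(slices) < 1L) stop_("need at least one labeled slice")
  Xs <- list(); ys <- list()
  for (i in seq_along(slices)) {
    sl <- slices[[i]]
    img <- sl$image %||% sl[[1]]
    labs <- sl$labels %||% sl[[2]]
    if (!identical(dim(img), dim(labs)))
      stop_("slice %d: image and labels differ in shape", i)
    Xs[[i]] <- compute_features(slice_as_volume(img), voxel_um, fspec)
    ys[[i]] <- as.integer(labs)
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop_("training labels contain a single class (%d); need >= 2", classes[1])
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  keep <- unlist(lapply(classes, function(cl) {
    idx <- which(y == cl)
    if (length(idx) > max_voxels_per_class)
      sort(sample(idx, max_voxels_per_class))
    else idx
  }))
  fit <- gd_fit(X[keep, , drop = FALSE], y[keep], type = type)
  acc <- mean(gd_predict(fit, X[keep, , drop = FALSE]) == y[keep])
  structure(list(feature_spec = fspec, fit = fit, voxel_um = voxel_um,
                 training = list(n_slices = length(slices),
                                 n_voxels_per_class = fit$n_per_class,
                                 classes = classes,
                                 train_accuracy = acc)),
            class = "voxel_classifier")
}

#' @export
print.voxel_classifier <- function(x, ...) {
  cat(sprintf("<voxel_classifier> %s over %d features | %d slices | classes %s | train acc %.3f\n",
              toupper(x$fit$type), length(x$fit$feature_names),
              x$training$n_slices,
              paste(x$training$classes, collapse = ","),
              x$training$train_accuracy))
  invisible(x)
}

#' Segment an OCT volume with a trained voxel classifier
#'
#' Computes the same in-plane features used in training for every voxel and
#' assigns the highest-posterior class. Voxel size must match training.
#'
#' @param volume an [oct_volume()].
#' @param classifier a `voxel_classifier` from [train_classifier()].
#' @return a [label_volume()] covering every voxel.
#' @export
segment_volume <- function(volume, classifier) {
  if (!inherits(volume, "oct_volume")) stop_("expected an oct_volume")
  if (!isTRUE(all.equal(volume$voxel_um, classifier$voxel_um)))
    stop_("voxel size mismatch: volume %g um vs classifier trained at %g um",
          volume$voxel_um, classifier$voxel_um)
  X <- compute_features(volume$data, volume$voxel_um, classifier$feature_spec)
  pred <- gd_predict(classifier$fit, X)
  if (length(unique(pred)) == 1L)
    message("segment_volume: output contains a single class (", pred[1],
            "); the volume may be constant or out of the training domain")
  label_volume(array(as.integer(pred), dim(volume$data)),
               voxel_um = volume$voxel_um)
}

#' Otsu threshold of an intensity volume
#'
#' Global bimodal-separation threshold maximizing between-class variance of
#' the 16-bit histogram.
#'
#' @param volume an [oct_volume()] (or integer array).
#' @return the threshold intensity (scalar).
#' @export
otsu_threshold <- function(volume) {
  arr <- if (is.list(volume)) volume$data else volume
  v <- as.integer(arr)
  if (min(v) == max(v)) stop_("cannot threshold a constant volume")
  h <- as.numeric(tabulate(v + 1L, 65536L))
  n <- length(v)
  w <- cumsum(h)
  mu <- cumsum(h * (0:65535))
  mu_t <- mu[65536]
  valid <- w > 0 & w < n
  sigma_b <- rep(-Inf, 65536)
  sigma_b[valid] <- (mu_t * w[valid] - n * mu[valid])^2 /
    (as.numeric(w[valid]) * (n - w[valid]))
  which.max(sigma_b) - 1L  # threshold: mask is intensity > threshold
}

#' Threshold-based cancer mask (the conventional baseline)
#'
#' Binarizes the volume at the global Otsu threshold. Serves as the
#' conventional comparison point for the learned classifier: under depth
#' attenuation a single global threshold misses deep, dimmed cancer, which
#' is the depth-related bias the classifier's depth feature corrects. On a
#' volume with inverted contrast (cancer darker than background) the mask
#' selects the background instead -- a documented failure mode of global
#' thresholding.
#'
#' @param volume an [oct_volume()].
#' @return logical array: intensity above the Otsu threshold.
#' @export
otsu_baseline <- function(volume) {
  arr <- if (is.list(volume)) volume$data else volume
  thr <- otsu_threshold(volume)
  arr > thr
}

#' Remove small objects from a binary mask
#'
#' Deletes 26-connected components smaller than `min_object_um3`
#' (default 27 um^3, a 3-um cube at the lateral optical resolution: objects
#' below resolution are treated as noise).
#'
#' @param mask logical 3-D array.
#' @param min_object_um3 minimum retained object volume (um^3).
#' @param voxel_um voxel size (um).
#' @param connectivity 6 or 26.
#' @return the cleaned logical array.
#' @export
clean_mask <- function(mask, min_object_um3 = 27, voxel_um = 1,
                       connectivity = 26) {
  d <- assert_dims3(mask, "mask")
  if (!any(mask)) return(mask)
  labs <- label_components_cpp(as.logical(mask), as.integer(d),
                               as.integer(connectivity))
  sizes <- tabulate(labs)
  min_vox <- ceiling(min_object_um3 / voxel_um^3)
  drop <- which(sizes < min_vox)
  if (length(drop)) {
    out <- mask
    out[labs %in% drop] <- FALSE
    out
  } else mask
}

#' Serialize / restore a voxel classifier as JSON
#'
#' @param classifier a `voxel_classifier`.
#' @param path JSON file path.
#' @return `write_classifier` returns `path` invisibly; `read_classifier`
#'   the restored classifier.
#' @export
write_classifier <- function(classifier, path) {
  fit <- classifier$fit
  obj <- list(
    format = "octinvasion voxel_classifier v1",
    feature_spec = unclass(classifier$feature_spec),
    voxel_um = classifier$voxel_um,
    type = fit$type,
    classes = fit$classes,
    feature_names = fit$feature_names,
    means = fit$means,
    covs = lapply(fit$covs, identity),
    n_per_class = fit$n_per_class,
    training = classifier$training)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  fspec <- do.call(feature_spec, obj$feature_spec)
  covs <- obj$covs
  if (is.array(covs) && length(dim(covs)) == 3L) {
    # jsonlite simplifies the list of equal-shape matrices to a K x p x p array
    covs <- lapply(seq_len(dim(covs)[1]), function(k) covs[k, , ])
  } else {
    covs <- lapply(covs, as.matrix)
  }
  fit <- list(type = obj$type, classes = as.integer(obj$classes),
              means = as.matrix(obj$means),
              covs = covs,
              n_per_class = as.integer(obj$n_per_class),
              feature_names = obj$feature_names)
  structure(list(feature_spec = fspec, fit = fit, voxel_um = obj$voxel_um,
                 training = obj$training),
            class = "voxel_classifier")
}
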