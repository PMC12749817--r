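#' @useDynLib octinvasion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median pnorm pt rgamma rnorm runif sd var
#' @importFrom utils read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

assert_dims3 <- function(x, what = "volume") {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop_("%s must be a 3-D array (z, y, x)", what)
  invisible(d)
}

#' Sorensen-Dice overlap between two binary masks
#'
#' Utility used throughout the test-suite and vignettes to score a predicted
#' mask against ground truth: `2|A & B| / (|A| + |B|)`. Returns 1 when both
#' masks are empty (perfect agreement on "nothing there").
#'
#' @param a,b logical arrays of identical shape.
#' @return scalar in \[0, 1\].
#' @export
dice_score <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_("masks differ in shape")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# Gaussian kernel (unit sum) for a given sigma in voxel units; odd length.
gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable convolution of a 3-D array along selected axes (1 = z, 2 = y,
# 3 = x in the (z, y, x) storage convention), symmetric boundary.
conv_separable <- function(vol, kernels) {
  d <- assert_dims3(vol)
  v <- as.double(vol)
  for (axis in seq_along(kernels)) {
    k <- kernels[[axis]]
    if (is.null(k) || length(k) < 2) next
    v <- conv3d_axis_cpp(v, as.integer(d), as.double(k), axis - 1L)
  }
  array(v, d)
}

# 0-based z index grid (same shape as the volume) as a double array.
z_index_array <- function(d) {
  array(rep(0:(d[1] - 1L), times = d[2] * d[3]), d)
}
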