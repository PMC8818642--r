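# Shared numeric helpers: Gaussian FWHM conversion, separable Gaussian
# convolution, and 2D point rotation. All spatial units are nm unless a
# function says otherwise.

#' Convert a Gaussian standard deviation to its full width at half maximum
#'
#' FWHM = 2 * sqrt(2 * ln 2) * sigma, the standard readout for the width of a
#' Gaussian intensity or distance profile.
#'
#' @param sigma Gaussian standard deviation (any length unit).
#' @return FWHM in the same unit.
#' @export
#' @examples
#' sigma_to_fwhm(10) # 23.548
sigma_to_fwhm <- function(sigma) 2 * sqrt(2 * log(2)) * sigma

#' Convert a Gaussian FWHM to its standard deviation
#'
#' @param fwhm full width at half maximum.
#' @return sigma in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Normalized 1D Gaussian kernel sampled at integer offsets, truncated at
# `radius` (default 4 sigma).
gaussian_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  x <- -radius:radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2D Gaussian convolution with zero padding outside the image.
# Implemented as band-matrix products so the boundary handling is explicit:
# mass within `radius` of the edge is partially lost, everything else is
# conserved exactly.
gaussian_blur <- function(mat, sigma_px, radius = ceiling(4 * sigma_px)) {
  stopifnot(is.matrix(mat), sigma_px > 0)
  k <- gaussian_kernel_1d(sigma_px, radius)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    kv <- numeric(2 * n)
    idx <- seq_len(min(radius, n - 1) + 1)
    kv[idx] <- k[radius + idx]
    matrix(kv[d + 1], n, n)
  }
  band(nrow(mat)) %*% mat %*% band(ncol(mat))
}

# Rotate points by angle theta (radians, counter-clockwise) about the origin.
rotate_xy <- function(x, y, theta) {
  ct <- cos(theta)
  st <- sin(theta)
  cbind(x = ct * x - st * y, y = st * x + ct * y)
}

# Stage-tagged error helper used by the pipeline compositions.
stage_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
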