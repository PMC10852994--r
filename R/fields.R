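#' Convert a full-width-at-half-maximum to a Gaussian standard deviation
#'
#' Imaging-standard convention: \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})}.
#'
#' @param fwhm full width at half maximum, in pixels.
#' @return kernel standard deviation in pixels.
#' @export
fwhm_to_sigma <- function(fwhm) {
  stopifnot(fwhm >= 0)
  fwhm / (2 * sqrt(2 * log(2)))
}

# Normalised 1-D Gaussian kernel, truncated at 4 sigma. fwhm = 0 gives the
# identity kernel.
.gaussian_kernel <- function(fwhm) {
  sigma <- fwhm_to_sigma(fwhm)
  if (sigma == 0) return(1)
  rad <- as.integer(ceiling(4 * sigma))
  k <- dnorm(seq.int(-rad, rad), sd = sigma)
  k / sum(k)
}

.kernel_radius <- function(fwhm) (length(.gaussian_kernel(fwhm)) - 1L) %/% 2L

# Pointwise standard deviation of unit white noise after separable 2-D
# convolution with kernel k (full support): sqrt((sum k^2)^2) = sum(k^2).
.smoothed_white_sd <- function(k) sum(k^2)

.check_field <- function(field) {
  if (!is.matrix(field) || !is.numeric(field))
    stop("a scalar field must be a numeric matrix")
  if (any(dim(field) < 2L))
    stop("grid extents must be at least 2 pixels")
  if (!all(is.finite(field)))
    stop("scalar fields must be finite everywhere")
  invisible(field)
}

#' Smooth a scalar field with an isotropic Gaussian filter
#'
#' Discrete separable convolution with a normalised Gaussian kernel
#' truncated at four standard deviations. At the image edge the kernel
#' mass falling outside the grid is handled by `edge`:
#' `"renormalise"` divides by the local kernel mass (constants are
#' preserved exactly, the default), `"zero"` treats outside pixels as 0
#' (used internally for noise generated on a padded grid).
#'
#' @param field numeric matrix.
#' @param fwhm full width at half maximum of the kernel, in pixels;
#'   `fwhm = 0` returns the input unchanged.
#' @param edge `"renormalise"` or `"zero"`.
#' @return a numeric matrix of the same dimensions.
#' @export
gaussian_smooth <- function(field, fwhm, edge = c("renormalise", "zero")) {
  .check_field(field)
  edge <- match.arg(edge)
  k <- .gaussian_kernel(fwhm)
  if (length(k) == 1L) return(field)
  nr <- nrow(field); nc <- ncol(field)
  out <- cpp_smooth_stack(matrix(as.numeric(field), ncol = 1L), nr, nc, k, 0L)
  out <- matrix(out, nr, nc)
  if (edge == "renormalise") {
    mass <- cpp_smooth_stack(matrix(1, nr * nc, 1L), nr, nc, k, 0L)
    out <- out / matrix(mass, nr, nc)
  }
  out
}

#' @export
print.conjcr_field_stack <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("field stack: %d x %d grid, %d observations\n",
              g[1], g[2], ncol(x)))
  invisible(x)
}

# attach grid metadata to an npix x n stack
.as_stack <- function(x, grid) {
  attr(x, "grid") <- as.integer(grid)
  class(x) <- unique(c("conjcr_field_stack", oldClass(x), "matrix"))
  x
}

.stack_grid <- function(x) {
  g <- attr(x, "grid")
  if (is.null(g)) stop("observation stack carries no grid attribute")
  g
}
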