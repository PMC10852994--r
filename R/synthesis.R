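#' Specify a synthetic signal
#'
#' Three signal families are supported, mirroring the standard two-condition
#' simulation geometries for conjunction inference:
#' * `"circle"`: binary disks of radius `radius`, centred `separation` pixels
#'   apart in a Venn-diagram arrangement, scaled by `magnitude` and smoothed.
#' * `"square"`: axis-aligned binary squares of side `side`, likewise
#'   separated horizontally; their overlap produces boundary stretches shared
#'   by both conditions.
#' * `"ramp"`: condition 1 is a horizontal, condition 2 a vertical, linear
#'   ramp with slope `gradient` per pixel, passing through `level` at the
#'   grid centre. Ramps are analytic and are not smoothed (a linear field is
#'   invariant under interior Gaussian smoothing).
#'
#' Defaults give the high signal-to-noise setting: `magnitude = 3` before
#' smoothing with a 5-pixel FWHM kernel (circles/squares), ramp `level = 2`
#' with gradient 1/50. The low-SNR variant is obtained by dividing the
#' signal by 4 (see [generate_dataset()]).
#'
#' @param kind `"circle"`, `"square"` or `"ramp"`.
#' @param magnitude template height before smoothing (circles/squares).
#' @param fwhm smoothing kernel FWHM in pixels.
#' @param separation distance between template centres, in pixels.
#' @param radius circle radius in pixels.
#' @param side square side length in pixels.
#' @param level ramp value at the grid centre.
#' @param gradient ramp slope per pixel.
#' @return an object of class `conjcr_signal_spec`.
#' @export
signal_spec <- function(kind = c("circle", "square", "ramp"),
                        magnitude = 3, fwhm = 5,
                        separation = 20, radius = 28, side = 50,
                        level = 2, gradient = 1 / 50) {
  kind <- match.arg(kind)
  stopifnot(magnitude >= 0, fwhm >= 0, separation >= 0,
            radius > 0, side > 0)
  structure(list(kind = kind, magnitude = magnitude, fwhm = fwhm,
                 separation = separation, radius = radius, side = side,
                 level = level, gradient = gradient),
            class = "conjcr_signal_spec")
}

#' Specify the noise process
#'
#' White pixel noise (unit variance Gaussian, or scaled t for the
#' heavy-tailed option), optionally mixed across the two conditions to
#' induce a cross-condition correlation `rho` before smoothing, then
#' smoothed with an isotropic Gaussian filter. With `restandardise = TRUE`
#' (default) the smoothed fields are divided by the theoretical pointwise
#' standard deviation of the smoothed white field, so the marginal pixel
#' variance is exactly 1.
#'
#' Noise is generated on a grid padded by the kernel radius and cropped
#' after smoothing, so every retained pixel has full kernel support and
#' there are no edge-variance artefacts.
#'
#' @param fwhm smoothing FWHM in pixels.
#' @param rho cross-condition correlation in `[-1, 1]` (two conditions).
#' @param distribution `"gaussian"` or `"heavy_tailed"` (scaled Student-t
#'   white noise before smoothing).
#' @param df integer degrees of freedom for the heavy-tailed option (> 2).
#' @param restandardise force unit pointwise variance after smoothing.
#' @return an object of class `conjcr_noise_spec`.
#' @export
noise_spec <- function(fwhm = 3, rho = 0,
                       distribution = c("gaussian", "heavy_tailed"),
                       df = 3, restandardise = TRUE) {
  distribution <- match.arg(distribution)
  stopifnot(fwhm >= 0, abs(rho) <= 1)
  if (distribution == "heavy_tailed") {
    stopifnot(df > 2, df == round(df))
  }
  structure(list(fwhm = fwhm, rho = rho, distribution = distribution,
                 df = as.integer(df), restandardise = restandardise),
            class = "conjcr_noise_spec")
}

# Binary (or analytic ramp) template before magnitude scaling / smoothing.
# Coordinates are 0-based pixel centres; condition centres are offset by
# +/- separation/2 along the horizontal (column) axis.
.make_template <- function(spec, grid, which) {
  nr <- grid[1]; nc <- grid[2]
  cy <- (nr - 1) / 2
  cx <- (nc - 1) / 2 + (if (which == 1L) -1 else 1) * spec$separation / 2
  y <- matrix(seq_len(nr) - 1, nr, nc)
  x <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  tmpl <- switch(spec$kind,
    circle = (x - cx)^2 + (y - cy)^2 <= spec$radius^2,
    square = abs(x - cx) <= spec$side / 2 & abs(y - cy) <= spec$side / 2,
    ramp = NULL)
  if (spec$kind == "ramp") {
    coord <- if (which == 1L) x else y
    centre <- if (which == 1L) (nc - 1) / 2 else (nr - 1) / 2
    return(spec$level + spec$gradient * (coord - centre))
  }
  if (!any(tmpl))
    stop("signal template lies entirely outside the grid")
  tmpl * 1.0
}

#' Generate a synthetic signal field
#'
#' Builds the binary template for the requested condition, scales it by
#' `spec$magnitude` and smooths it with `spec$fwhm` (ramps are returned
#' analytically, unsmoothed). Set `smooth = FALSE` to inspect the
#' pre-smoothing template.
#'
#' @param spec a [signal_spec()].
#' @param grid integer vector `c(rows, cols)`; all extents must be >= 2.
#' @param which condition index (1 or 2).
#' @param smooth apply the Gaussian filter (default `TRUE`).
#' @return a numeric matrix.
#' @export
make_signal <- function(spec, grid = c(100L, 100L), which = 1L,
                        smooth = TRUE) {
  stopifnot(inherits(spec, "conjcr_signal_spec"),
            length(grid) == 2L, all(grid >= 2L), which %in% c(1L, 2L))
  tmpl <- .make_template(spec, grid, as.integer(which))
  if (spec$kind == "ramp") return(tmpl)
  field <- tmpl * spec$magnitude
  if (smooth) field <- gaussian_smooth(field, spec$fwhm) else field
}

# white stack (npix x n) for one condition from the package RNG
.white_stack <- function(npix, n, spec, seed) {
  z <- cpp_white_stack(npix, n, seed)
  if (spec$distribution == "heavy_tailed") {
    df <- spec$df
    chi <- cpp_white_stack(npix, n, derive_seed(seed, 101))^2
    if (df >= 2L) for (j in 2:df)
      chi <- chi + cpp_white_stack(npix, n, derive_seed(seed, 100 + j))^2
    # scaled t: unit pointwise variance requires df > 2
    z <- z / sqrt(chi / df) * sqrt((df - 2) / df)
  }
  z
}

#' Generate smoothed noise stacks
#'
#' Produces `M` stacks of `n` noise fields each, as `npix x n` matrices
#' (pixels in column-major order, one column per observation), following
#' the recipe in [noise_spec()]. Cross-condition correlation (`rho != 0`)
#' is defined for `M = 2`: the second white stack is replaced by
#' `rho * z1 + sqrt(1 - rho^2) * z2` before smoothing.
#'
#' @param n number of observations per condition (>= 2).
#' @param M number of conditions.
#' @param grid integer `c(rows, cols)`.
#' @param spec a [noise_spec()].
#' @param seed integer seed; `NULL` draws one from the session RNG.
#' @return a list of `M` stacks with a `grid` attribute.
#' @export
generate_noise <- function(n, M = 2L, grid = c(100L, 100L),
                           spec = noise_spec(), seed = NULL) {
  stopifnot(inherits(spec, "conjcr_noise_spec"), n >= 2L, M >= 1L,
            length(grid) == 2L, all(grid >= 2L))
  if (spec$rho != 0 && M != 2L)
    stop("cross-condition correlation is defined for M = 2 conditions")
  seed <- .resolve_seed(seed)
  k <- .gaussian_kernel(spec$fwhm)
  pad <- (length(k) - 1L) %/% 2L
  nr_pad <- grid[1] + 2L * pad
  nc_pad <- grid[2] + 2L * pad
  stacks <- lapply(seq_len(M), function(i)
    .white_stack(nr_pad * nc_pad, n, spec, derive_seed(seed, i)))
  if (spec$rho != 0)
    cpp_mix_inplace(stacks[[1]], stacks[[2]], spec$rho)
  stacks <- lapply(stacks, function(z) {
    if (pad > 0L) {
      z <- cpp_smooth_stack(z, nr_pad, nc_pad, k, pad)
      if (spec$restandardise) z <- z / .smoothed_white_sd(k)
    }
    .as_stack(z, grid)
  })
  stacks
}

#' Generate a synthetic dataset with its true excursion geometry
#'
#' Adds the true signal fields to the noise stacks (`Y_i = mu_i + eps_i`
#' per observation) and records the quantities needed for the inclusion
#' check: the true conjunction mask `{min_i mu_i >= c}` on the lattice and
#' the sub-pixel true boundary, extracted by linear interpolation of
#' `min_i mu_i - c` along lattice edges.
#'
#' @param signals list of `M` signal fields (numeric matrices on a common
#'   grid); divide a high-SNR signal by 4 for the low-SNR variant.
#' @param noise list of `M` noise stacks from [generate_noise()].
#' @param c excursion threshold.
#' @return a list with elements `y` (list of `npix x n` stacks), `signals`,
#'   `c`, `true_mask`, `true_boundary` (see [extract_zero_boundary()]) and
#'   `grid`.
#' @export
generate_dataset <- function(signals, noise, c) {
  stopifnot(is.list(signals), is.list(noise),
            length(signals) == length(noise))
  grid <- .stack_grid(noise[[1]])
  for (s in signals) {
    .check_field(s)
    if (!all(dim(s) == grid)) stop("signal and noise grids disagree")
  }
  y <- Map(function(mu, eps) .as_stack(eps + as.vector(mu), grid),
           signals, noise)
  gmin_true <- Reduce(pmin, signals) - c
  list(y = y, signals = signals, c = c,
       true_mask = gmin_true >= 0,
       true_boundary = extract_zero_boundary(gmin_true),
       grid = grid)
}
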