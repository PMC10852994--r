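#' Wald binomial confidence interval
#'
#' Normal-approximation interval `p_hat +/- z * sqrt(p_hat (1-p_hat)/trials)`,
#' clipped to `[0, 1]`.
#'
#' @param successes number of successes.
#' @param trials number of trials (> 0).
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lo, hi)`.
#' @export
binomial_ci <- function(successes, trials, level = 0.95) {
  stopifnot(trials > 0, successes >= 0, successes <= trials,
            level > 0, level < 1)
  p <- successes / trials
  z <- qnorm(1 - (1 - level) / 2)
  hw <- z * sqrt(p * (1 - p) / trials)
  c(lo = max(0, p - hw), hi = min(1, p + hw))
}

#' Check the nested-inclusion statement for one simulation instance
#'
#' The inclusion `upper CR inside true conjunction set inside lower CR`
#' is deemed to hold if, and only if:
#' 1. pixel nesting: every pixel of the upper mask lies in the true set
#'    and every true-set pixel lies in the lower mask; and
#' 2. at every sub-pixel point of the true boundary (extracted from
#'    `min_i mu_i - c` by edge interpolation), the interpolated statistic
#'    `tau_n^{-1} min g_hat` is `< a` (otherwise the upper region leaks
#'    outside the true set) and `>= -a` (otherwise the lower region fails
#'    to cover it). The boundary of the closed true set belongs to the
#'    set, hence the asymmetric strictness.
#'
#' @param truth list with `true_mask` and `true_boundary`, e.g. from
#'   [generate_dataset()].
#' @param result a `conjcr_inference` object (conjunction query).
#' @param a threshold constant; defaults to the result's quantile.
#' @return `TRUE` or `FALSE`.
#' @export
check_inclusion <- function(truth, result, a = result$boot$quantile_a) {
  stopifnot(inherits(result, "conjcr_inference"))
  if (!any(truth$true_mask)) stop("the true conjunction set is empty")
  crs <- result$crs
  if (any(crs$upper & !truth$true_mask)) return(FALSE)
  if (any(truth$true_mask & !crs$lower)) return(FALSE)
  if (nrow(truth$true_boundary) > 0L) {
    t_on_boundary <- interpolate_at_boundary(result$tstat, truth$true_boundary)
    if (any(t_on_boundary >= a)) return(FALSE)
    if (any(t_on_boundary < -a)) return(FALSE)
  }
  TRUE
}

#' Naive intersection of per-condition confidence regions
#'
#' Intersects the upper, point-estimate and lower masks of `M`
#' single-condition confidence-region triples pixelwise. This is **not** a
#' valid `(1-alpha)` procedure for the conjunction set — its asymptotic
#' coverage can fall anywhere in `[1 - M alpha, 1]` — and is provided only
#' as a comparator for the miscoverage demonstration.
#'
#' @param crs_list list of `conjcr_crs` (or `conjcr_inference`) objects on
#'   a common grid.
#' @return a `conjcr_crs` object (with `a = NA`).
#' @export
naive_intersection_crs <- function(crs_list) {
  crs_list <- lapply(crs_list, function(x)
    if (inherits(x, "conjcr_inference")) x$crs else x)
  d <- dim(crs_list[[1]]$upper)
  for (x in crs_list) {
    stopifnot(inherits(x, "conjcr_crs"))
    if (!all(dim(x$upper) == d)) stop("confidence regions must share a grid")
  }
  structure(list(
    upper = Reduce(`&`, lapply(crs_list, `[[`, "upper")),
    point_estimate = Reduce(`&`, lapply(crs_list, `[[`, "point_estimate")),
    lower = Reduce(`&`, lapply(crs_list, `[[`, "lower")),
    a = NA_real_, alpha = crs_list[[1]]$alpha,
    tau_n = crs_list[[1]]$tau_n, query = NULL),
    class = "conjcr_crs")
}

#' Configure a coverage simulation
#'
#' Simulation families:
#' * `1` — two smoothed circle signals; the sweep parameter is the circle
#'   separation in pixels (0 to 50 in the full study).
#' * `2` — two smoothed square signals with shared boundary stretches; the
#'   sweep parameter is the cross-condition noise correlation `rho`.
#' * `3` — horizontal and vertical linear ramps; the sweep parameter is the
#'   divisor `k` applied to the ramp gradients.
#'
#' `snr = "high"` uses signal magnitude 3 (ramp level 2) with threshold
#' `c = 2`; `snr = "low"` divides the signal by 4 and uses `c = 1/2`.
#' Defaults are desk-scale (500 instances, B = 1000); the full-scale study
#' uses 2500 instances and B = 5000.
#'
#' @param simulation 1, 2 or 3.
#' @param snr `"high"` or `"low"`.
#' @param n vector of per-condition sample sizes.
#' @param sweep vector of sweep values (separation / rho / k); defaults to
#'   a single value (20 / 0 / 1).
#' @param instances Monte-Carlo instances per cell.
#' @param B bootstrap realisations.
#' @param alpha tolerance level.
#' @param seed master seed.
#' @param boundary `"estimated"` or `"true"` bootstrap boundary.
#' @param grid image dimensions.
#' @param signal_fwhm,noise_fwhm smoothing FWHMs in pixels.
#' @param radius,side circle radius / square side in pixels.
#' @param multiplier bootstrap multiplier kind.
#' @param signal_scale extra multiplier applied to the signal and the
#'   threshold (1 = the stated SNR settings), for custom SNR sweeps.
#' @param threshold override the SNR-implied threshold `c`.
#' @param ci_level level of the binomial interval on the coverage.
#' @return an object of class `conjcr_sim_config`.
#' @export
sim_config <- function(simulation = 1L, snr = c("high", "low"),
                       n = 100L, sweep = NULL, instances = 500L,
                       B = 1000L, alpha = 0.05, seed = 1L,
                       boundary = c("estimated", "true"),
                       grid = c(100L, 100L),
                       signal_fwhm = 5, noise_fwhm = 3,
                       radius = 28, side = 50,
                       multiplier = "rademacher",
                       signal_scale = 1, threshold = NULL,
                       ci_level = 0.95) {
  snr <- match.arg(snr)
  boundary <- match.arg(boundary)
  stopifnot(simulation %in% 1:3, instances >= 1L, all(n >= 2L))
  if (is.null(sweep))
    sweep <- switch(simulation, 20, 0, 1)
  if (simulation == 2L && any(abs(sweep) > 1))
    stop("simulation 2 sweeps the noise correlation; values must be in [-1, 1]")
  if (is.null(threshold)) threshold <- if (snr == "high") 2 else 0.5
  structure(list(simulation = as.integer(simulation), snr = snr, n = n,
                 sweep = sweep, instances = as.integer(instances),
                 B = as.integer(B), alpha = alpha, seed = seed,
                 boundary = boundary, grid = as.integer(grid),
                 signal_fwhm = signal_fwhm, noise_fwhm = noise_fwhm,
                 radius = radius, side = side, multiplier = multiplier,
                 signal_scale = signal_scale, threshold = threshold,
                 ci_level = ci_level),
            class = "conjcr_sim_config")
}

# signals for one sweep value of a configured simulation
.sim_signals <- function(config, sweep_value) {
  snr_div <- if (config$snr == "low") 4 else 1
  scale <- config$signal_scale / snr_div
  spec <- switch(config$simulation,
    signal_spec("circle", magnitude = 3, fwhm = config$signal_fwhm,
                separation = sweep_value, radius = config$radius),
    signal_spec("square", magnitude = 3, fwhm = config$signal_fwhm,
                separation = 25, side = config$side),
    signal_spec("ramp", level = 2, gradient = (1 / 50) / sweep_value))
  lapply(1:2, function(i) make_signal(spec, config$grid, which = i) * scale)
}

#' Run a coverage simulation
#'
#' Loops over sweep values, sample sizes and Monte-Carlo instances. Each
#' instance draws fresh noise (from a per-instance sub-stream of the
#' master seed, so results do not depend on execution order), fits
#' intercept-only spatial linear models per condition, runs
#' [conjunction_inference()] and records [check_inclusion()]. Instances in
#' which the estimated conjunction set (or its lattice boundary) is empty
#' are tallied separately in the `empty` column and counted as failures.
#'
#' @param config a [sim_config()].
#' @param progress print a line per completed cell.
#' @return a data frame of class `conjcr_coverage` with one row per
#'   `(sweep, n)` cell: `successes`, `empty`, `coverage`, `ci_lo`, `ci_hi`.
#' @export
run_simulation <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "conjcr_sim_config"))
  threshold <- config$signal_scale * config$threshold
  rows <- list()
  cell <- 0L
  for (sw in config$sweep) {
    signals <- .sim_signals(config, sw)
    rho <- if (config$simulation == 2L) sw else 0
    nspec <- noise_spec(fwhm = config$noise_fwhm, rho = rho)
    for (n in config$n) {
      cell <- cell + 1L
      cell_seed <- derive_seed(config$seed, cell)
      ok <- 0L; empty <- 0L
      for (inst in seq_len(config$instances)) {
        inst_seed <- derive_seed(cell_seed, inst)
        noise <- generate_noise(n, 2L, config$grid, nspec,
                                seed = derive_seed(inst_seed, 1L))
        ds <- generate_dataset(signals, noise, threshold)
        fits <- lapply(ds$y, fit_spatial_lm)
        res <- tryCatch(
          conjunction_inference(
            fits, threshold, alpha = config$alpha, B = config$B,
            multiplier = config$multiplier,
            seed = derive_seed(inst_seed, 2L),
            boundary = config$boundary,
            true_fields = if (config$boundary == "true")
              lapply(ds$signals, function(s) s - threshold) else NULL),
          conjcr_inapplicable = function(e) e)
        if (inherits(res, "conjcr_inapplicable")) {
          empty <- empty + 1L
        } else if (check_inclusion(ds, res)) {
          ok <- ok + 1L
        }
      }
      ci <- binomial_ci(ok, config$instances, config$ci_level)
      rows[[cell]] <- data.frame(
        sweep = sw, n = n, instances = config$instances,
        successes = ok, empty = empty,
        coverage = ok / config$instances, ci_lo = ci[[1]], ci_hi = ci[[2]])
      if (progress)
        message(sprintf("sweep %.3g, n %d: coverage %.4f [%.4f, %.4f]",
                        sw, n, ok / config$instances, ci[[1]], ci[[2]]))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("conjcr_coverage", class(out))
  out
}
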