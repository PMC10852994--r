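#' Construct nested confidence-region masks
#'
#' Level sets of the t-statistic field `tau_n^{-1} min_i g_hat_i`:
#' `upper = {>= +a}`, `point = {min g_hat >= 0}`, `lower = {>= -a}`.
#' By construction `upper` is a subset of `point`, which is a subset of
#' `lower`, for any `a >= 0`.
#'
#' @param min_field minimum of the standardised fields (matrix).
#' @param tau_n CLT scaling, `n^{-1/2}` for `n` i.i.d. observations.
#' @param a non-negative quantile constant.
#' @param alpha tolerance recorded alongside (optional).
#' @param query a [query_spec()] recorded alongside (optional).
#' @return an object of class `conjcr_crs` with logical masks `upper`,
#'   `point_estimate`, `lower` and fields `a`, `alpha`, `tau_n`, `query`.
#' @export
construct_crs <- function(min_field, tau_n, a, alpha = NA_real_,
                          query = NULL) {
  if (a < 0) stop("'a' must be non-negative")
  tstat <- min_field / tau_n
  structure(list(upper = tstat >= a,
                 point_estimate = min_field >= 0,
                 lower = tstat >= -a,
                 a = a, alpha = alpha, tau_n = tau_n,
                 query = query),
            class = "conjcr_crs")
}

#' @export
print.conjcr_crs <- function(x, ...) {
  cat(sprintf(paste0("confidence regions (a = %.4g, alpha = %s): ",
                     "|upper| = %d <= |point| = %d <= |lower| = %d pixels\n"),
              x$a, format(x$alpha), sum(x$upper), sum(x$point_estimate),
              sum(x$lower)))
  invisible(x)
}

#' Specify a logical query over exceedance statements
#'
#' A query is a conjunction or disjunction of the `M` per-condition
#' statements "`mu_i` exceeds `c`", each optionally negated. Disjunctions
#' are evaluated through De Morgan's laws: the conjunction machinery runs
#' on sign-flipped standardised fields and the three output masks are
#' complemented, with upper and lower swapped.
#'
#' @param combine `"conjunction"` (default) or `"disjunction"`.
#' @param negate logical vector, one flag per condition (default none).
#' @return an object of class `conjcr_query`.
#' @export
query_spec <- function(combine = c("conjunction", "disjunction"),
                       negate = FALSE) {
  combine <- match.arg(combine)
  structure(list(combine = combine, negate = negate),
            class = "conjcr_query")
}

# classed condition: the method does not apply (empty estimate/boundary)
.stop_inapplicable <- function(msg) {
  stop(structure(class = c("conjcr_inapplicable", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# per-condition sign flips implied by a query for M conditions
.query_flips <- function(query, M) {
  negate <- rep_len(query$negate, M)
  xor(negate, query$combine == "disjunction")
}

#' Transform standardised fields for a logical query
#'
#' Negated conditions have their standardised field sign-flipped
#' (`{mu_i < c}` is the excursion set of `-g_i`); for a disjunction every
#' statement is additionally negated so that the conjunction machinery
#' computes the complement of the target set.
#'
#' @param fields list of `M` standardised fields.
#' @param query a [query_spec()].
#' @return list of transformed fields.
#' @export
logical_transform <- function(fields, query) {
  stopifnot(inherits(query, "conjcr_query"))
  flips <- .query_flips(query, length(fields))
  Map(function(f, fl) if (fl) -f else f, fields, flips)
}

# complement the three masks of a conjunction result and swap upper/lower
.complement_crs <- function(crs) {
  out <- crs
  out$upper <- !crs$lower
  out$lower <- !crs$upper
  out$point_estimate <- !crs$point_estimate
  out
}

#' End-to-end confidence regions for a logical combination of excursion sets
#'
#' Standardises each fitted condition at the threshold, applies the query
#' transform, extracts and partitions the sub-pixel boundary of the
#' minimum field, estimates the `(1-alpha)` quantile `a` of the boundary
#' supremum statistic by the wild t-bootstrap, and thresholds the
#' t-statistic field at `±a`. Deterministic given `seed`.
#'
#' @param fits list of `conjcr_fit` objects (all with the same grid and
#'   observation count; a single fit may be given for `M = 1`).
#' @param c excursion threshold; scalar, or length `M` for per-condition
#'   thresholds.
#' @param alpha tolerance level (default 0.05).
#' @param B number of bootstrap realisations (default 5000).
#' @param multiplier `"rademacher"` (default) or `"mammen"`.
#' @param seed integer seed for the multipliers; `NULL` draws one from the
#'   session RNG.
#' @param delta segment-assignment tolerance; default `tau_n`.
#' @param boundary `"estimated"` (default) calibrates on the boundary of
#'   the estimated conjunction set; `"true"` uses the boundary of
#'   `true_fields` (validation mode).
#' @param true_fields list of true standardised fields (required when
#'   `boundary = "true"`).
#' @param query a [query_spec()]; default plain conjunction.
#' @return an object of class `conjcr_inference`: list with `crs`
#'   (a [construct_crs()] object), `boot` (list with `h_samples`, `B`,
#'   `alpha`, `quantile_a`, `multiplier`, `seed`), `segments`, `tstat`
#'   (the statistic field on the query scale), `tau_n`, `query`.
#' @export
conjunction_inference <- function(fits, c, alpha = 0.05, B = 5000L,
                                  multiplier = c("rademacher", "mammen"),
                                  seed = NULL, delta = NULL,
                                  boundary = c("estimated", "true"),
                                  true_fields = NULL, query = query_spec()) {
  multiplier <- match.arg(multiplier)
  boundary <- match.arg(boundary)
  if (inherits(fits, "conjcr_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, alpha > 0, alpha < 1, B >= 1L)
  M <- length(fits)
  grid <- fits[[1]]$grid
  n <- fits[[1]]$n_obs
  for (f in fits) {
    stopifnot(inherits(f, "conjcr_fit"))
    if (!all(f$grid == grid)) stop("fits must share a grid")
    if (f$n_obs != n)
      stop("fits must share the observation count (one multiplier vector ",
           "is used across all conditions)")
  }
  thr <- rep_len(c, M)
  flips <- .query_flips(query, M)
  g <- lapply(seq_len(M), function(i) standardised_field(fits[[i]], thr[i]))
  g <- Map(function(f, fl) if (fl) -f else f, g, flips)
  gmin <- min_field(g)
  tau_n <- fits[[1]]$tau_n
  if (!any(gmin >= 0))
    .stop_inapplicable(
      "the estimated conjunction set is empty; the method is not applicable")
  if (is.null(delta)) delta <- tau_n
  if (boundary == "true") {
    if (is.null(true_fields))
      stop("boundary = \"true\" requires 'true_fields'")
    bfields <- Map(function(f, fl) if (fl) -f else f, true_fields, flips)
  } else {
    bfields <- g
  }
  bmin <- min_field(bfields)
  points <- extract_zero_boundary(bmin)
  if (nrow(points) == 0L)
    .stop_inapplicable(paste0(
      "the conjunction boundary is empty on the lattice; ",
      "the method is not applicable"))
  segments <- partition_boundary(points, bfields, delta)
  seed <- .resolve_seed(seed)
  h <- .bootstrap_h_samples(fits, segments, B, multiplier,
                            seed = derive_seed(seed, 8L), flip = flips)
  a <- estimate_quantile(h, alpha)
  crs <- construct_crs(gmin, tau_n, a, alpha = alpha, query = query)
  if (query$combine == "disjunction") crs <- .complement_crs(crs)
  structure(list(crs = crs,
                 boot = list(h_samples = h, B = B, alpha = alpha,
                             quantile_a = a, multiplier = multiplier,
                             seed = seed),
                 segments = segments, tstat = gmin / tau_n,
                 tau_n = tau_n, query = query, grid = grid),
            class = "conjcr_inference")
}

#' @export
print.conjcr_inference <- function(x, ...) {
  cat(sprintf("%s inference: a = %.4g (alpha = %.3g, B = %d, %s multipliers)\n",
              x$query$combine, x$crs$a, x$boot$alpha, x$boot$B,
              x$boot$multiplier))
  print(x$crs)
  invisible(x)
}

#' Re-threshold an inference result at a different tolerance
#'
#' Reuses the stored bootstrap sample, so no new randomness is involved;
#' a smaller `alpha` can only widen the gap between upper and lower masks.
#'
#' @param result a `conjcr_inference` object.
#' @param alpha new tolerance level.
#' @return a new `conjcr_inference` object.
#' @export
crs_at_alpha <- function(result, alpha) {
  stopifnot(inherits(result, "conjcr_inference"))
  a <- estimate_quantile(result$boot$h_samples, alpha)
  crs <- construct_crs(result$tstat * result$tau_n, result$tau_n, a,
                       alpha = alpha, query = result$query)
  if (result$query$combine == "disjunction") crs <- .complement_crs(crs)
  out <- result
  out$crs <- crs
  out$boot$alpha <- alpha
  out$boot$quantile_a <- a
  out
}
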