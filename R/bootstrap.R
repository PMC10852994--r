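#' Wild t-bootstrap field values along the boundary
#'
#' For one condition, the bootstrap analogue of the limiting error field
#' at a boundary point `s` is
#' \deqn{\tilde G(s) = n^{-1/2} \sum_l r_l R_l(s) / \hat\sigma_*(s),}
#' where `R_l` are the decorrelated residual fields interpolated to `s`,
#' `r_l` the multipliers, and `\hat\sigma_*` the standard deviation (with
#' the `1/(n-1)` convention) of the multiplied sample at `s` — the
#' t-standardisation that makes the statistic scale-free.
#'
#' @param fit a `conjcr_fit` for the condition.
#' @param multipliers length-`n` vector or `n x B` matrix from
#'   [draw_multipliers()].
#' @param points boundary points ([extract_zero_boundary()]).
#' @return a `P x B` matrix (a vector if `multipliers` is a vector).
#' @export
bootstrap_G <- function(fit, multipliers, points) {
  stopifnot(inherits(fit, "conjcr_fit"))
  r <- if (is.matrix(multipliers)) multipliers else cbind(multipliers)
  n <- fit$n_obs
  if (nrow(r) != n) stop("multiplier count must equal the observation count")
  if (nrow(points) == 0L) stop("no boundary points supplied")
  px <- .boundary_pixels(points, fit$grid[1])
  Rp <- .residuals_at(fit, px$p)
  Rq <- .residuals_at(fit, px$q)
  Rpts <- (1 - points$w) * Rp + points$w * Rq   # P x n
  m <- (Rpts %*% r) / n                          # P x B bootstrap means
  if (all(abs(r) == 1)) {
    s2 <- rowSums(Rpts^2)                        # multiplier signs drop out
  } else {
    s2 <- Rpts^2 %*% r^2
  }
  v <- (s2 - n * m^2) / (n - 1)
  if (any(v <= 0))
    stop("degenerate bootstrap standard deviation at a boundary point")
  G <- sqrt(n) * m / sqrt(v)
  if (is.matrix(multipliers)) G else as.vector(G)
}

#' One bootstrap realisation of the boundary supremum statistic
#'
#' \deqn{\tilde H = \max_{\phi} \sup_{s \in \partial_\phi \hat F_c}
#'   | \min_{i \in \phi} \tilde G_i(s) |,}
#' the maximum over non-empty boundary segments of the supremum of the
#' absolute pointwise minimum of the bootstrap fields of the conditions
#' attaining that segment. Empty segments are skipped; if the boundary has
#' no points at all the statistic is undefined (the method does not apply
#' when the estimated conjunction set is empty).
#'
#' @param G_values list of `M` matrices (`P x B`, or length-`P` vectors)
#'   of bootstrap field values at the boundary points.
#' @param segments a `conjcr_segments` partition of those points.
#' @return a length-`B` vector of non-negative statistics (scalar for
#'   vector input).
#' @export
bootstrap_H <- function(G_values, segments) {
  stopifnot(inherits(segments, "conjcr_segments"))
  vec_in <- !is.matrix(G_values[[1]])
  G <- lapply(G_values, function(g) if (is.matrix(g)) g else cbind(g))
  if (length(G) != segments$M)
    stop("need one set of bootstrap values per condition")
  active <- Filter(function(ix) length(ix) > 0L, segments$segments)
  if (length(active) == 0L)
    stop("all boundary segments are empty; the estimated conjunction set ",
         "has no boundary and the method is not applicable")
  B <- ncol(G[[1]])
  h <- rep(0, B)
  for (nm in names(active)) {
    ix <- active[[nm]]
    conds <- as.integer(strsplit(nm, ",", fixed = TRUE)[[1]])
    Gmin <- Reduce(pmin, lapply(conds, function(i) G[[i]][ix, , drop = FALSE]))
    h <- pmax(h, apply(abs(Gmin), 2L, max))
  }
  if (vec_in) h[1] else h
}

#' Empirical bootstrap quantile
#'
#' The `ceiling((1 - alpha) * B)`-th order statistic of the bootstrap
#' sample — the conservative (higher) order statistic rather than an
#' interpolated quantile.
#'
#' @param h numeric vector of bootstrap statistics.
#' @param alpha tolerance level in (0, 1).
#' @return scalar quantile.
#' @export
estimate_quantile <- function(h, alpha) {
  stopifnot(length(h) >= 1L, alpha > 0, alpha < 1)
  sort(h)[ceiling((1 - alpha) * length(h))]
}

# Full bootstrap pass shared by conjunction_inference(): returns the
# B-vector of H-tilde realisations.
.bootstrap_h_samples <- function(fits, segments, B, multiplier, seed,
                                 flip = NULL) {
  n <- fits[[1]]$n_obs
  r <- draw_multipliers(n, B, kind = multiplier, seed = seed)
  G <- lapply(seq_along(fits), function(i) {
    g <- bootstrap_G(fits[[i]], r, segments$points)
    if (!is.null(flip) && flip[i]) -g else g
  })
  bootstrap_H(G, segments)
}
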