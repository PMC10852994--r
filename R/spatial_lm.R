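#' Bundle the inputs of one condition's spatially varying linear model
#'
#' At every pixel `s` the `n` responses follow `Y(s) = X beta(s) + eps(s)`,
#' with a design matrix `X` common to all pixels and a contrast vector `L`
#' selecting the target function `mu(s) = L' beta(s)`. Several conditions
#' may share the same responses and design and differ only in their
#' contrast; fitting each such model yields identical residual fields.
#'
#' @param y `npix x n` response stack (pixels in column-major order, one
#'   column per observation), e.g. from [generate_dataset()]; a plain
#'   matrix needs `grid` supplied.
#' @param design `n x p` design matrix; default intercept-only.
#' @param contrast length-`p` contrast vector; default `1`.
#' @param grid integer `c(rows, cols)`; taken from `y`'s attribute if absent.
#' @param Sigma optional `n x n` plug-in error covariance (a consistent
#'   estimate, known up to the residual variance scale); default i.i.d.
#'   errors, i.e. ordinary least squares.
#' @return an object of class `conjcr_model`.
#' @export
condition_model <- function(y, design = NULL, contrast = NULL, grid = NULL,
                            Sigma = NULL) {
  if (is.null(grid)) grid <- .stack_grid(y)
  grid <- as.integer(grid)
  y <- as.matrix(y)
  n <- ncol(y)
  if (nrow(y) != prod(grid)) stop("stack rows must equal prod(grid)")
  if (is.null(design)) design <- matrix(1, n, 1L)
  design <- as.matrix(design)
  if (is.null(contrast)) contrast <- rep(1, ncol(design))
  if (nrow(design) != n) stop("design rows must match the observation count")
  if (length(contrast) != ncol(design))
    stop("contrast length must match the design column count")
  structure(list(y = y, design = design, contrast = as.numeric(contrast),
                 grid = grid, Sigma = Sigma),
            class = "conjcr_model")
}

#' Fit the spatially varying linear model at every pixel
#'
#' Computes, per pixel: the contrast estimate `mu_hat = L' beta_hat`, the
#' contrast standard error `se = sigma_hat * sqrt(L'(X'X)^{-1}L)` (after
#' whitening when a plug-in covariance is supplied), and the decorrelated
#' residuals used by the wild bootstrap. The residual variance uses the
#' unbiased `1/(n - p)` convention. The central-limit scaling is
#' `tau_n = n^{-1/2}`, and the standardisation field is
#' `sigma = se / tau_n`, so that `tau_n^{-1} g_hat` with
#' `g_hat = (mu_hat - c)/sigma` is the pixelwise t-statistic
#' `(mu_hat - c)/se`.
#'
#' @param model a [condition_model()], or an `npix x n` stack (intercept-only
#'   fit with unit contrast).
#' @param ... passed to [condition_model()] when `model` is a stack.
#' @return an object of class `conjcr_fit` with fields `mu_hat`, `se`,
#'   `sigma` (matrices), `tau_n`, `n_obs`, `grid`.
#' @export
fit_spatial_lm <- function(model, ...) {
  if (!inherits(model, "conjcr_model")) model <- condition_model(model, ...)
  X <- model$design
  Y <- model$y
  n <- ncol(Y); p <- ncol(X)
  if (n <= p) stop("need more observations than design columns (n > p)")
  if (!is.null(model$Sigma)) {
    # whiten responses and design by Sigma^{-1/2}, then proceed as OLS
    e <- eigen(model$Sigma, symmetric = TRUE)
    if (any(e$values <= 0)) stop("plug-in covariance must be positive definite")
    W <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
    X <- W %*% X
    Y <- Y %*% W   # rows are pixels: right-multiply by W' = W
  }
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  Q <- qr.Q(qrX)                       # n x p, orthonormal columns
  Rinv <- backsolve(qr.R(qrX), diag(p))
  C <- Y %*% Q                         # npix x p
  beta <- C %*% t(Rinv)                # npix x p
  rss <- cpp_row_resid_sumsq(Y, C, Q)
  sigma_ols <- sqrt(rss / (n - p))
  # degenerate when the residual scale is zero up to arithmetic noise
  # relative to the fitted scale
  degen <- rss <= 1e-20 * pmax(rowSums(C^2), rss, .Machine$double.xmin)
  if (any(degen))
    stop("zero residual variance at ", sum(degen),
         " pixel(s); the limiting error field would be degenerate there")
  L <- model$contrast
  cXXc <- sqrt(sum((crossprod(Rinv, L))^2))   # sqrt(L'(X'X)^{-1}L)
  tau_n <- 1 / sqrt(n)
  grid <- model$grid
  structure(list(
    mu_hat = matrix(as.vector(beta %*% L), grid[1], grid[2]),
    se = matrix(sigma_ols * cXXc, grid[1], grid[2]),
    sigma = matrix(sigma_ols * cXXc / tau_n, grid[1], grid[2]),
    tau_n = tau_n, n_obs = n, grid = grid,
    .Y = Y, .Q = Q, .C = C, .sigma_ols = sigma_ols, beta = beta
  ), class = "conjcr_fit")
}

#' @export
print.conjcr_fit <- function(x, ...) {
  cat(sprintf("spatial LM fit: %d x %d grid, n = %d, tau_n = %.4g\n",
              x$grid[1], x$grid[2], x$n_obs, x$tau_n))
  invisible(x)
}

# Decorrelated residuals at a subset of pixels (rows of the stack):
# R = (Y - X beta_hat) / sigma_ols, evaluated lazily for speed.
.residuals_at <- function(fit, pix) {
  E <- fit$.Y[pix, , drop = FALSE] -
    fit$.C[pix, , drop = FALSE] %*% t(fit$.Q)
  E / fit$.sigma_ols[pix]
}

#' Decorrelated residual fields of a fit
#'
#' Returns the full `npix x n` matrix of residuals whitened by the
#' estimated error covariance (under OLS, divided by the pixelwise
#' residual standard deviation).
#'
#' @param object a `conjcr_fit`.
#' @param ... unused.
#' @export
residuals.conjcr_fit <- function(object, ...) {
  .residuals_at(object, seq_len(nrow(object$.Y)))
}

#' Standardised excursion field
#'
#' `g_hat = (mu_hat - c) / sigma`, whose excursion set at level 0 equals
#' the excursion set of `mu_hat` at level `c`. `tau_n^{-1} g_hat` is the
#' pixelwise t-statistic used to threshold the confidence regions.
#'
#' @param fit a `conjcr_fit`.
#' @param c excursion threshold (same units as the response).
#' @return a numeric matrix.
#' @export
standardised_field <- function(fit, c) {
  stopifnot(inherits(fit, "conjcr_fit"))
  (fit$mu_hat - c) / fit$sigma
}
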