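#' Derive a reproducible sub-stream seed
#'
#' All randomness in conjCR flows through an explicit integer seed and a
#' self-contained, platform-independent generator (xoshiro256++ with a
#' splitmix64 scrambler). Sub-streams — one per simulation instance, per
#' noise condition, per bootstrap multiplier block — are derived by
#' scrambling `(seed, key)` pairs, so results are independent of execution
#' order and safe to parallelise.
#'
#' @param seed non-negative integer-valued scalar (< 2^53).
#' @param key non-negative integer-valued scalar identifying the sub-stream.
#' @return a non-negative integer-valued double < 2^53 usable as a seed.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(key), length(key) == 1L, key >= 0)
  cpp_derive_seed(as.numeric(seed), as.numeric(key))
}

.resolve_seed <- function(seed) {
  # NULL means "take one draw from R's session RNG", so that set.seed()
  # at the session level still makes package output reproducible.
  if (is.null(seed)) sample.int(.Machine$integer.max, 1L) else seed
}

#' Draw wild-bootstrap multipliers
#'
#' Rademacher multipliers take the values -1 and +1 with equal probability.
#' Mammen multipliers take \eqn{-(\sqrt5-1)/2} and \eqn{(\sqrt5+1)/2} with
#' probabilities \eqn{(\sqrt5+1)/(2\sqrt5)} and \eqn{(\sqrt5-1)/(2\sqrt5)};
#' they have mean 0, variance 1 and third moment 1, preserving skewness at
#' the cost of inflated kurtosis.
#'
#' One column of the returned matrix is the multiplier vector of one
#' bootstrap instance; within an instance the same vector is shared across
#' all study conditions, so the cross-condition dependence of the residual
#' fields is carried into the bootstrap fields.
#'
#' @param n number of observations (rows).
#' @param B number of bootstrap instances (columns).
#' @param kind `"rademacher"` (default) or `"mammen"`.
#' @param seed integer seed; `NULL` draws one from the session RNG.
#' @return an `n x B` numeric matrix.
#' @export
draw_multipliers <- function(n, B = 1L, kind = c("rademacher", "mammen"),
                             seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 1L, B >= 1L)
  seed <- .resolve_seed(seed)
  if (kind == "rademacher") cpp_rademacher(n, B, seed) else cpp_mammen(n, B, seed)
}
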