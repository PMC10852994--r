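# Independent oracles and small fixtures shared across the test files.
# Each oracle is written as directly as possible (loops, enumeration) and
# never calls the code path it is used to check.

# brute-force 2-D convolution with a truncated normalised Gaussian kernel,
# zero padding, per-pixel kernel-mass renormalisation
oracle_smooth <- function(field, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (sigma == 0) return(field)
  rad <- ceiling(4 * sigma)
  k1 <- dnorm(seq(-rad, rad), sd = sigma)
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  nr <- nrow(field); nc <- ncol(field)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0; mass <- 0
    for (dr in -rad:rad) for (dc in -rad:rad) {
      rr <- r + dr; ccc <- cc + dc
      if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc) {
        wgt <- K[dr + rad + 1, dc + rad + 1]
        acc <- acc + wgt * field[rr, ccc]
        mass <- mass + wgt
      }
    }
    out[r, cc] <- acc / mass
  }
  out
}

# exhaustive evaluation of the boundary supremum statistic: loop over every
# non-empty subset phi of conditions, collect the points labelled phi, take
# min over phi, abs, sup, then the max across subsets
oracle_H <- function(G_list, labels) {
  M <- length(G_list)
  P <- length(labels)
  best <- 0
  for (bits in 1:(2^M - 1)) {
    phi <- which(bitwAnd(bits, 2^(seq_len(M) - 1)) > 0)
    lab <- paste(phi, collapse = ",")
    ix <- which(labels == lab)
    if (length(ix) == 0) next
    for (p in ix) {
      v <- min(sapply(phi, function(i) G_list[[i]][p]))
      best <- max(best, abs(v))
    }
  }
  best
}

# directly coded single-condition confidence-region routine: sup |G~| over
# the whole boundary of one standardised field, no combinatorial partition.
# Uses the package fit and the published multiplier contract, but its own
# residual interpolation, studentisation, supremum and quantile code.
oracle_single_crs <- function(fit, c, alpha, B, seed) {
  g <- (fit$mu_hat - c) / fit$sigma
  bnd <- extract_zero_boundary(g)
  stopifnot(nrow(bnd) > 0)
  n <- fit$n_obs
  R_full <- residuals(fit)                       # npix x n
  nr <- fit$grid[1]
  lp <- (bnd$pc - 1L) * nr + bnd$pr
  lq <- (bnd$qc - 1L) * nr + bnd$qr
  Rpts <- (1 - bnd$w) * R_full[lp, , drop = FALSE] +
    bnd$w * R_full[lq, , drop = FALSE]
  r <- draw_multipliers(n, B, "rademacher", seed = derive_seed(seed, 8L))
  h <- numeric(B)
  for (b in seq_len(B)) {
    sup <- 0
    for (p in seq_len(nrow(bnd))) {
      x <- r[, b] * Rpts[p, ]
      Gv <- sqrt(n) * mean(x) / sd(x)
      sup <- max(sup, abs(Gv))
    }
    h[b] <- sup
  }
  a <- sort(h)[ceiling((1 - alpha) * B)]
  list(a = a, h = h,
       upper = g / fit$tau_n >= a,
       point = g >= 0,
       lower = g / fit$tau_n >= -a)
}

# small high-SNR two-circle dataset used by several suites
make_sim1_dataset <- function(n = 60, separation = 20, seed = 1,
                              grid = c(60L, 60L), radius = 18,
                              magnitude = 3, c = 2, rho = 0) {
  spec <- signal_spec("circle", magnitude = magnitude, separation = separation,
                      radius = radius)
  sig <- lapply(1:2, function(i) make_signal(spec, grid, which = i))
  noise <- generate_noise(n, 2L, grid, noise_spec(rho = rho), seed = seed)
  generate_dataset(sig, noise, c)
}

# bilinear interpolation of a field at continuous (row, col) positions
bilinear_at <- function(field, row, col) {
  r0 <- pmin(pmax(floor(row), 1), nrow(field) - 1)
  c0 <- pmin(pmax(floor(col), 1), ncol(field) - 1)
  fr <- row - r0; fc <- col - c0
  f00 <- field[cbind(r0, c0)]; f10 <- field[cbind(r0 + 1, c0)]
  f01 <- field[cbind(r0, c0 + 1)]; f11 <- field[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * f00 + fr * (1 - fc) * f10 +
    (1 - fr) * fc * f01 + fr * fc * f11
}
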