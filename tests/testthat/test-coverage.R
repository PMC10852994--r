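test_that("binomial_ci matches the closed form and clips", {
  ci <- binomial_ci(100, 100)
  expect_equal(unname(ci[2]), 1)
  ci2 <- binomial_ci(0.95 * 2500, 2500)
  hw <- 1.96 * sqrt(0.95 * 0.05 / 2500)
  expect_equal(unname(ci2[2] - ci2[1]) / 2, hw, tolerance = 1e-3)
  # symmetric in successes <-> failures about 0.5
  a <- binomial_ci(30, 100); b <- binomial_ci(70, 100)
  expect_equal(unname(a[1]), unname(1 - b[2]), tolerance = 1e-12)
  expect_error(binomial_ci(1, 0), "trials")
})

test_that("check_inclusion is exact in the zero-noise limit and fails at a = 0", {
  # The zero-noise limit is realised by noise that is identical at every
  # pixel with exact mean zero: mu_hat recovers the signal exactly, the
  # residual sd is spatially constant, and g_hat is proportional to the
  # true standardised field. (Exactly-zero noise is rejected by the fit:
  # the limiting field would be degenerate.)
  grid <- c(40L, 40L)
  spec <- signal_spec("circle", separation = 12, radius = 13)
  sig <- lapply(1:2, function(i) make_signal(spec, grid, which = i))
  set.seed(30)
  e <- rnorm(12); e <- e - mean(e)
  degenerate <- lapply(1:2, function(i) {
    z <- matrix(e, prod(grid), 12, byrow = TRUE)
    attr(z, "grid") <- grid
    z
  })
  ds <- generate_dataset(sig, degenerate, 2)
  fits <- lapply(ds$y, fit_spatial_lm)
  expect_equal(fits[[1]]$mu_hat, sig[[1]], tolerance = 1e-12)
  res <- conjunction_inference(fits, 2, B = 50, seed = 2)
  # the statistic vanishes on the true boundary: any positive a passes
  expect_true(check_inclusion(ds, res, a = 1e-8))
  expect_true(check_inclusion(ds, res, a = res$boot$quantile_a))
  # a = 0 fails (the boundary statistic is not strictly below 0)
  expect_false(check_inclusion(ds, res, a = 0))
  # a genuinely noisy instance fails at a = 0 too
  ds_noisy <- make_sim1_dataset(n = 40, seed = 13)
  fits_n <- lapply(ds_noisy$y, fit_spatial_lm)
  res_n <- conjunction_inference(fits_n, ds_noisy$c, B = 50, seed = 2)
  expect_false(check_inclusion(ds_noisy, res_n, a = 0))
  expect_error(check_inclusion(list(true_mask = matrix(FALSE, 2, 2),
                                    true_boundary = ds$true_boundary),
                               res),
               "empty")
})

test_that("check_inclusion agrees with a 10x supersampled oracle", {
  # the oracle evaluates the inclusion on a bilinearly refined lattice:
  # every refined point of the true set must have statistic > -a, every
  # refined point outside must not reach +a (up to the sub-pixel boundary
  # band that both representations localise by interpolation)
  oracle_inclusion <- function(ds, res, a, factor = 10) {
    grid <- dim(ds$true_mask)
    rows <- seq(1, grid[1], by = 1 / factor)
    cols <- seq(1, grid[2], by = 1 / factor)
    rc <- expand.grid(row = rows, col = cols)
    gtrue <- pmin(ds$signals[[1]], ds$signals[[2]]) - ds$c
    tvals <- bilinear_at(gtrue, rc$row, rc$col)
    svals <- bilinear_at(res$tstat, rc$row, rc$col)
    if (any(svals[tvals < 0] >= a)) return(FALSE)   # upper leaks outside
    if (any(svals[tvals >= 0] < -a)) return(FALSE)  # lower misses the set
    TRUE
  }
  failures_seen <- 0L
  for (s in 1:50) {
    ds <- make_sim1_dataset(n = 25, seed = 1000 + s, grid = c(40L, 40L),
                            radius = 13, separation = 12)
    fits <- lapply(ds$y, fit_spatial_lm)
    res <- conjunction_inference(fits, ds$c, B = 200, seed = 2000 + s)
    a <- res$boot$quantile_a
    got <- check_inclusion(ds, res, a)
    failures_seen <- failures_seen + !got
    expect_identical(got, oracle_inclusion(ds, res, a))
  }
  # both outcomes are exercised at these fixed seeds
  expect_gt(failures_seen, 0L)
  expect_lt(failures_seen, 50L)
})

test_that("run_simulation replays deterministically and reports coherent cells", {
  cfg1 <- sim_config(1, "high", n = 30, instances = 2, B = 50, seed = 42,
                     grid = c(40L, 40L), radius = 13, sweep = 12)
  r1 <- run_simulation(cfg1)
  r2 <- run_simulation(cfg1)
  expect_identical(r1$successes, r2$successes)
  expect_equal(r1$coverage, r1$successes / r1$instances)
  expect_true(all(r1$ci_lo <= r1$coverage & r1$coverage <= r1$ci_hi))
  # the zero-noise limit (coverage exactly 1) per instance: degenerate
  # pixel-identical noise with exact mean zero and several patterns
  grid <- c(40L, 40L)
  spec <- signal_spec("circle", separation = 12, radius = 13)
  sig <- lapply(1:2, function(i) make_signal(spec, grid, which = i))
  set.seed(55)
  hits <- vapply(1:5, function(k) {
    e <- rnorm(15); e <- e - mean(e)
    degenerate <- lapply(1:2, function(i) {
      z <- matrix(e, prod(grid), 15, byrow = TRUE)
      attr(z, "grid") <- grid
      z
    })
    ds <- generate_dataset(sig, degenerate, 2)
    fits <- lapply(ds$y, fit_spatial_lm)
    res <- conjunction_inference(fits, 2, B = 50, seed = k)
    check_inclusion(ds, res)
  }, logical(1))
  expect_true(all(hits))
})

test_that("simulation families 2 and 3 produce valid cells", {
  r2 <- run_simulation(sim_config(2, "high", n = 30, instances = 2, B = 50,
                                  seed = 3, sweep = -0.5, grid = c(60L, 60L),
                                  side = 30))
  expect_equal(r2$instances, 2L)
  r3 <- run_simulation(sim_config(3, "high", n = 30, instances = 2, B = 50,
                                  seed = 4, sweep = 1, grid = c(60L, 60L)))
  expect_equal(r3$instances, 2L)
  # true-boundary calibration mode produces a valid cell as well
  rt <- run_simulation(sim_config(1, "high", n = 30, instances = 2, B = 50,
                                  seed = 5, grid = c(40L, 40L), radius = 13,
                                  sweep = 12, boundary = "true"))
  expect_true(rt$coverage >= 0 && rt$coverage <= 1)
})

test_that("naive intersection reduces correctly in degenerate cases", {
  ds <- make_sim1_dataset(n = 40, seed = 17)
  fits <- lapply(ds$y, fit_spatial_lm)
  singles <- lapply(seq_along(fits), function(i)
    conjunction_inference(fits[[i]], ds$c, B = 100, seed = 50 + i))
  naive <- naive_intersection_crs(singles)
  # M = 1: identity
  one <- naive_intersection_crs(singles[1])
  expect_identical(one$upper, singles[[1]]$crs$upper)
  # intersected point estimates equal the conjunction point estimate
  conj <- conjunction_inference(fits, ds$c, B = 100, seed = 60)
  expect_identical(naive$point_estimate, conj$crs$point_estimate)
  # nesting of the intersected masks is preserved
  expect_true(all(naive$upper <= naive$point_estimate))
  expect_true(all(naive$point_estimate <= naive$lower))
})
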