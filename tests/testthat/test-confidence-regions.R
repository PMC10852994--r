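test_that("construct_crs thresholds and nests correctly", {
  f <- matrix(c(0.19, -0.3, 0, 0.5), 2, 2)
  tau <- 0.1
  crs <- construct_crs(f, tau, a = 2)
  # t-statistic 1.9 with a = 2: in lower, not in upper
  expect_true(crs$lower[1, 1]); expect_false(crs$upper[1, 1])
  expect_true(crs$point_estimate[1, 1])
  # a = 0 collapses the three masks
  crs0 <- construct_crs(f, tau, 0)
  expect_identical(crs0$upper, crs0$lower)
  expect_identical(crs0$upper, crs0$point_estimate)
  # monotone in a
  crs_small <- construct_crs(f, tau, 1)
  expect_true(all(crs$upper <= crs_small$upper))
  expect_true(all(crs_small$lower <= crs$lower))
  expect_error(construct_crs(f, tau, -1), "non-negative")
})

test_that("logical_transform flips signs per the query", {
  f1 <- matrix(1:4, 2, 2); f2 <- matrix(4:1, 2, 2)
  conj <- query_spec("conjunction", negate = c(FALSE, TRUE))
  out <- logical_transform(list(f1, f2), conj)
  expect_identical(out[[1]], f1)
  expect_identical(out[[2]], -f2)
  disj <- query_spec("disjunction", negate = c(FALSE, TRUE))
  out2 <- logical_transform(list(f1, f2), disj)
  expect_identical(out2[[1]], -f1)
  expect_identical(out2[[2]], f2)
})

test_that("conjunction inference returns nested, reproducible regions", {
  ds <- make_sim1_dataset(n = 80, seed = 21)
  fits <- lapply(ds$y, fit_spatial_lm)
  res <- conjunction_inference(fits, ds$c, alpha = 0.05, B = 400, seed = 3)
  crs <- res$crs
  expect_true(all(crs$upper <= crs$point_estimate))
  expect_true(all(crs$point_estimate <= crs$lower))
  expect_gte(res$boot$quantile_a, 0)
  expect_true(all(res$boot$h_samples >= 0))
  # point estimate equals the intersection of per-condition masks
  masks <- lapply(fits, function(f) excursion_mask(standardised_field(f, ds$c)))
  expect_identical(crs$point_estimate, masks[[1]] & masks[[2]])
  # deterministic replay
  res2 <- conjunction_inference(fits, ds$c, alpha = 0.05, B = 400, seed = 3)
  expect_identical(res$boot$h_samples, res2$boot$h_samples)
  expect_identical(res$crs$upper, res2$crs$upper)
  # alpha monotonicity via re-thresholding the same bootstrap sample
  res_loose <- crs_at_alpha(res, 0.2)
  expect_lte(res_loose$boot$quantile_a, res$boot$quantile_a)
  expect_true(all(res$crs$upper <= res_loose$crs$upper))
  expect_true(all(res_loose$crs$lower <= res$crs$lower))
})

test_that("empty estimates and boundaries are flagged as inapplicable", {
  ds <- make_sim1_dataset(n = 30, seed = 2)
  fits <- lapply(ds$y, fit_spatial_lm)
  expect_error(conjunction_inference(fits, c = 50, B = 10, seed = 1),
               class = "conjcr_inapplicable")
  # threshold below every value: full mask, no lattice boundary
  expect_error(conjunction_inference(fits, c = -50, B = 10, seed = 1),
               class = "conjcr_inapplicable")
  # mismatched observation counts are rejected (shared multipliers)
  ds2 <- make_sim1_dataset(n = 31, seed = 3)
  fits2 <- lapply(ds2$y, fit_spatial_lm)
  expect_error(conjunction_inference(list(fits[[1]], fits2[[2]]), 2,
                                     B = 10, seed = 1),
               "observation count")
})

test_that("disjunction CRs are De Morgan complements of conjunction CRs", {
  # zero-noise signals (tiny jitter keeps sample sd positive while leaving
  # no pixel exactly at the threshold)
  grid <- c(40L, 40L)
  spec <- signal_spec("circle", separation = 14, radius = 12)
  sig <- lapply(1:2, function(i) make_signal(spec, grid, which = i))
  set.seed(8)
  y <- lapply(sig, function(s) {
    z <- as.vector(s) + matrix(rnorm(prod(grid) * 20, sd = 1e-6), prod(grid))
    attr(z, "grid") <- grid
    z
  })
  fits <- lapply(y, fit_spatial_lm)
  disj <- conjunction_inference(fits, 2, B = 200, seed = 4,
                                query = query_spec("disjunction"))
  # point estimate: the pixelwise union of per-condition excursion masks
  union_mask <- (sig[[1]] > 2) | (sig[[2]] > 2)
  expect_identical(disj$crs$point_estimate, union_mask)
  # set algebra: complement of the conjunction run on negated fields,
  # with upper and lower swapped
  conj_neg <- conjunction_inference(fits, 2, B = 200, seed = 4,
                                    query = query_spec("conjunction",
                                                       negate = TRUE))
  expect_identical(disj$crs$upper, !conj_neg$crs$lower)
  expect_identical(disj$crs$lower, !conj_neg$crs$upper)
  expect_identical(disj$crs$point_estimate, !conj_neg$crs$point_estimate)
  # nesting still holds after complementation
  expect_true(all(disj$crs$upper <= disj$crs$point_estimate))
  expect_true(all(disj$crs$point_estimate <= disj$crs$lower))
  # union of a set with itself: single-field CRs are recovered
  disj_same <- conjunction_inference(list(fits[[1]], fits[[1]]), 2, B = 200,
                                     seed = 4,
                                     query = query_spec("disjunction"))
  single <- conjunction_inference(fits[[1]], 2, B = 200, seed = 4)
  expect_identical(disj_same$crs$point_estimate,
                   sig[[1]] > 2)
  expect_identical(disj_same$crs$point_estimate,
                   !(!single$crs$point_estimate))
})

test_that("per-condition thresholds shift the fields before standardising", {
  ds <- make_sim1_dataset(n = 50, seed = 12)
  fits <- lapply(ds$y, fit_spatial_lm)
  res_vec <- conjunction_inference(fits, c(2, 2), B = 100, seed = 6)
  res_scl <- conjunction_inference(fits, 2, B = 100, seed = 6)
  expect_identical(res_vec$crs$upper, res_scl$crs$upper)
  # different thresholds change the point estimate accordingly
  res_mix <- conjunction_inference(fits, c(2, 2.5), B = 100, seed = 6)
  m1 <- excursion_mask(standardised_field(fits[[1]], 2))
  m2 <- excursion_mask(standardised_field(fits[[2]], 2.5))
  expect_identical(res_mix$crs$point_estimate, m1 & m2)
})
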