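test_that("maxima detection: strict rise, non-rise, first-of-plateau, no endpoints", {
  expect_equal(detect_maxima(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_equal(detect_maxima(c(0, 2, 2, 0)), 2L)
  expect_equal(detect_maxima(c(3, 2, 1)), integer(0))
  expect_error(detect_maxima(c(1, 2)), "3 samples")
  expect_error(phase(c(3, 2, 1)), "fewer than 2 maxima")
  # endpoints never qualify even when largest
  expect_equal(detect_maxima(c(5, 1, 2, 1, 9)), 3L)
})

test_that("between-maxima phase interpolation matches the defining formula", {
  # maxima at positions 3 and 9 (6 steps apart): midpoint phase pi,
  # endpoints 0 and 2 pi
  x <- c(0, 1, 2, 1, 0, -1, 0, 1, 2, 1)
  ph <- phase(x)
  expect_equal(ph$maxima, c(3L, 9L))
  expect_equal(ph$phi[ph$index == 6], pi)
  expect_equal(ph$phi[ph$index == 3], 0)
  expect_equal(ph$phi[ph$index == 9], 2 * pi)

  # three maxima 6 steps apart: second cycle, m = 1
  y <- rep(c(2, 1, 0, -1, 0, 1), 3)[1:13]  # maxima at 1, 7, 13
  ph <- phase(y, maxima = c(1L, 7L, 13L))
  expect_equal(ph$phi[ph$index == 10], 3 * pi)

  # unequal inter-maximum intervals stay piecewise linear
  ph <- phase(c(0, 1, 0, 1, 0, 0, 1, 0), maxima = c(2L, 4L, 7L))
  expect_equal(ph$phi[ph$index == 3], pi)
  expect_equal(ph$phi[ph$index == 5], 2 * pi + 2 * pi / 3)
})

test_that("phase hits an exact multiple of 2 pi at every detected maximum and is non-decreasing", {
  set.seed(41)
  for (i in 1:20) {
    x <- stats::rnorm(60)
    ph <- phase(x)
    at_max <- ph$phi[match(ph$maxima, ph$index)]
    expect_equal(at_max, 2 * pi * (seq_along(ph$maxima) - 1L))
    expect_true(all(diff(ph$phi) >= 0))
  }
})

test_that("phase is invariant to positive affine rescaling of the values", {
  set.seed(43)
  x <- stats::rnorm(80)
  ph <- phase(x)
  ph2 <- phase(3.7 * x + 11)
  expect_identical(ph2$maxima, ph$maxima)
  expect_equal(ph2$phi, ph$phi)
})

test_that("phase-locking index reproduces analytic cases exactly", {
  idx <- 1:4
  # constant phase difference -> strict synchronization
  a <- phase_series(idx, c(0, 1, 2, 3))
  b <- phase_series(idx, c(1, 2, 3, 4))
  expect_equal(pli(a, b)$pli, 1, tolerance = 1e-12)
  expect_equal(pli(a, b)$n_points, 4L)
  # antipodal phasors cancel
  a <- phase_series(1:2, c(0, pi))
  b <- phase_series(1:2, c(0, 0))
  expect_equal(pli(a, b)$pli, 0, tolerance = 1e-12)
  # quarter-turn pair: |1 + i| / 2
  a <- phase_series(1:2, c(0, pi / 2))
  expect_equal(pli(a, b)$pli, sqrt(2) / 2, tolerance = 1e-12)
  # disjoint domains
  expect_error(pli(phase_series(1:3, 1:3), phase_series(7:9, 1:3)),
               "overlap")
})

test_that("pipeline PLI: self- and lagged synchronization are exact, incommensurate periods are not", {
  x <- rep(sin(2 * pi * (0:11) / 12), 2)
  expect_equal(pli_pipeline(x, x)$pli, 1, tolerance = 1e-12)

  lagged <- rep(sin(2 * pi * (0:11) / 12 + 1.1), 2)
  expect_equal(pli_pipeline(x, lagged)$pli, 1, tolerance = 1e-12)

  t <- 0:139
  a <- sin(2 * pi * t / 10)
  b <- sin(2 * pi * t / 7)
  res <- pli_pipeline(a, b)
  expect_lt(res$pli, 1)
  expect_gte(res$pli, 0)
})

test_that("PLI equals 1 iff the phase difference is constant modulo 2 pi", {
  set.seed(47)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    base <- cumsum(stats::runif(n, 0, 1))
    const <- phase_series(1:n, base + stats::runif(1, -10, 10) +
                            2 * pi * sample(-3:3, n, replace = TRUE))
    expect_equal(pli(phase_series(1:n, base), const)$pli, 1,
                 tolerance = 1e-12)
    jitter <- phase_series(1:n, base + stats::rnorm(n, 0, 0.5))
    p <- pli(phase_series(1:n, base), jitter)$pli
    expect_true(p >= 0 && p < 1)
  }
})

test_that("Spearman rank correlation handles monotone, antitone and tied-rank cases", {
  expect_equal(rank_correlation(1:4, 1:4)$rho, 1)
  expect_equal(rank_correlation(1:4, 4:1)$rho, -1)
  expect_equal(rank_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
  expect_error(rank_correlation(1:3, 1:4), "equal-length")
})
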