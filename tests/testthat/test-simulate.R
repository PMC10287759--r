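test_that("temperature generator produces the noiseless seasonal sinusoid", {
  spec <- sim_spec(n_years = 1, temp_noise_sd = 0, seed = 2)
  x <- generate_temperature(spec)
  mis <- 0:5
  expect_equal(x$value,
               14 + 6 * sin(2 * pi * mis / 6 - pi / 2))
  expect_equal(x$month, 5:10)
  expect_equal(x$year, rep(2001L, 6))

  flat <- sim_spec(n_years = 2, temp_amplitude = 0, temp_noise_sd = 0,
                   seed = 2)
  expect_equal(generate_temperature(flat)$value, rep(14, 12))

  a <- generate_temperature(sim_spec(seed = 7))
  b <- generate_temperature(sim_spec(seed = 7))
  expect_identical(a$value, b$value)
})

test_that("the forward model sits still at its trivial fixed point", {
  spec <- sim_spec(growth_mean = 0, growth_amplitude = 0,
                   growth_noise_sd = 0, f_const = 0, alpha = 0, seed = 1)
  sim <- forward_simulate(spec)
  expect_equal(sim$P$value, rep(10, 60))
  expect_equal(sim$Z$value, rep(2, 60))
})

test_that("inversion of simulated dynamics recovers the prescribed growth signal", {
  set.seed(71)
  for (i in 1:10) {
    spec <- random_viable_spec()
    sim <- forward_simulate(spec)
    G <- growth_rate(sim$P, sim$Z, spec$params)
    expect_equal(G$year, sim$G_true$year)
    expect_equal(G$month, sim$G_true$month)
    expect_lt(max(abs(G$value - sim$G_true$value) / abs(sim$G_true$value)),
              1e-10)
    f <- trophic_function(sim$P, sim$Z, spec$params)
    expect_lt(max(abs(f$value - sim$f_true$value)), 1e-10)
  }
})

test_that("the simulated temperature matches the standalone generator", {
  spec <- sim_spec(seed = 13)
  expect_identical(forward_simulate(spec)$temperature,
                   generate_temperature(spec))
})

test_that("noiseless zero-lag coupling yields perfect phase locking of G* and T", {
  spec <- sim_spec(temp_noise_sd = 0, growth_noise_sd = 0,
                   growth_phase_lag = 0, seed = 4)
  sim <- forward_simulate(spec)
  al <- align_series(sim$G_true, sim$temperature)
  expect_equal(pli_pipeline(al$a$value, al$b$value)$pli, 1,
               tolerance = 1e-12)
})

test_that("non-viable dynamics are rejected with the offending step", {
  # heavy grazing drives prey negative on the first step
  spec <- sim_spec(f_const = 1, Z0 = 5, seed = 1)
  expect_error(forward_simulate(spec), "year 2001, month 6")
  expect_error(sim_spec(missing_fraction = 0.5), "missing_fraction")
  expect_error(sim_spec(months_per_season = 2), "months_per_season")
  expect_error(sim_spec(P0 = 0), "P0")
})

test_that("missing-value injection flags the contracted count and spares sole observations", {
  spec <- sim_spec(seed = 5)
  sim <- forward_simulate(spec)
  expect_identical(inject_missing(sim$P, 0), sim$P)

  x <- inject_missing(sim$P, 0.1, seed = 3)
  expect_equal(sum(is.na(x$value)), 6L)  # 10% of 60 samples

  # at the cap, every calendar-month slice keeps an observation
  y <- inject_missing(sim$P, 0.2, seed = 3)
  kept <- tapply(!is.na(y$value), y$month, any)
  expect_true(all(kept))
})

test_that("injected gaps impute back close to the original series", {
  set.seed(81)
  for (i in 1:10) {
    sim <- forward_simulate(random_viable_spec())
    x <- inject_missing(sim$P, 0.05, seed = i)
    filled <- impute_seasonal(x)
    miss <- is.na(x$value)
    # error bounded by the local variation of each month slice
    for (j in which(miss)) {
      sel <- x$month == x$month[j]
      spread <- diff(range(sim$P$value[sel]))
      expect_lte(abs(filled$value[j] - sim$P$value[j]), spread + 1e-12)
    }
  }
})
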