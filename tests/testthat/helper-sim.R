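# shared fixtures: study-condition generator specs and small series builders

# phase-coupled study conditions: seasonal drive of G through the
# temperature phase, low noise
coupled_spec <- function(seed) sim_spec(seed = seed)

# null condition: no seasonal drive of G, irregular noise-driven maxima
uncoupled_spec <- function(seed) {
  sim_spec(seed = seed, growth_amplitude = 0, growth_noise_sd = 0.2)
}

# derived G vs temperature, aligned on common timestamps
g_vs_temp <- function(sim) {
  G <- growth_rate(sim$P, sim$Z, sim$spec$params)
  align_series(G, sim$temperature)
}

# a random viable simulation spec; rejection-samples specs whose
# trajectories hit non-positive abundances
random_viable_spec <- function() {
  repeat {
    spec <- sim_spec(
      n_years = sample(5:10, 1),
      months_per_season = sample(4:6, 1),
      growth_mean = stats::runif(1, 0.25, 0.45),
      growth_amplitude = stats::runif(1, 0, 0.15),
      growth_phase_lag = stats::runif(1, -pi, pi),
      growth_noise_sd = 0.02,
      f_const = stats::runif(1, 0.01, 0.05),
      alpha = stats::runif(1, 0, 1),
      beta = stats::runif(1, 0.05, 0.2),
      P0 = stats::runif(1, 5, 15),
      Z0 = stats::runif(1, 1, 3),
      seed = sample.int(2^30, 1))
    ok <- tryCatch({forward_simulate(spec); TRUE},
                   error = function(e) FALSE)
    if (ok) return(spec)
  }
}

# quick monitoring series on one or more May-start seasons
mk_series <- function(value, variable = "phytoplankton",
                      months_per_year = 6, first_year = 2001) {
  n <- length(value)
  stopifnot(n %% months_per_year == 0)
  yrs <- n %/% months_per_year
  monitoring_series(
    rep(first_year + seq_len(yrs) - 1L, each = months_per_year),
    rep(4L + seq_len(months_per_year), yrs),
    value, variable = variable)
}
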