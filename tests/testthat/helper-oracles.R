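# independent brute-force oracles and small fixtures shared across tests

# double-loop histogram oracle for score_fluence: per-bin sums of weights,
# normalized the same way but computed independently of the tallying code
brute_force_fluence <- function(energy, theta, weight, n_protons,
                                radius = 1) {
  lo <- seq(0, 170, by = 10)
  hi <- seq(10, 180, by = 10)
  area <- 2 * pi * radius^2 * (cospi(lo / 180) - cospi(hi / 180))
  values <- matrix(0, 18, 250)
  for (i in 1:18) {
    in_angle <- theta >= lo[i] & (theta < hi[i] | (i == 18 & theta == 180))
    for (j in 1:250) {
      sel <- in_angle & energy >= (j - 1) & energy < j
      values[i, j] <- sum(weight[sel]) / area[i] / n_protons
    }
  }
  values
}

# uniform random crossing set (unit weights unless stated)
random_crossings <- function(n, seed, weights = FALSE) {
  withr::with_seed(seed, {
    crossing_records(energy_MeV = runif(n, 0, 250),
                     theta_deg = runif(n, 0, 180),
                     weight = if (weights) runif(n, 0.1, 2) else 1)
  })
}

# flat angular source term (value in every bin), zero allowed
flat_term <- function(value, id = "phantom") {
  angular_source_term(id, rep(value, 18), allow_zero = TRUE)
}

# single phantom source at isocenter: geometry reduces to exact
# inverse-square
phantom_only <- function() {
  list(phantom = neutron_source_spec("phantom", 0, 1.0))
}

# analytic expected total H* summed over the sphere for a spectrum model:
# yield * sum_j P(E in bin j) * f(mid_j) * 1e-16, with its standard error
analytic_recovery <- function(model, yield_per_proton, n_protons, table) {
  p <- energy_bin_probabilities(model)
  f <- interpolate_coefficient(table, (1:250) - 0.5)
  mean_total <- yield_per_proton * sum(p * f) * 1e-16
  se <- sqrt(yield_per_proton * sum(p * f^2) / n_protons) * 1e-16
  list(mean = mean_total, se = se)
}

# total H* integrated over the sphere from a pipeline source term at 1 m
integrate_term <- function(term) {
  lo <- seq(0, 170, by = 10)
  hi <- seq(10, 180, by = 10)
  sum(term$values * 2 * pi * (cospi(lo / 180) - cospi(hi / 180)))
}
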