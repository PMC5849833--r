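#' Two-component neutron spectrum model
#'
#' Parametric stand-in for the neutron field emitted by a proton-struck
#' target, used to generate synthetic tally crossings. The energy
#' distribution is a mixture of an evaporation component — Maxwellian,
#' `p(E) proportional to E * exp(-E / T)` — and an intranuclear-cascade
#' component modeled as a normal distribution truncated to the scoring
#' range; both are truncated to `[0, 250)` MeV. The angular distribution
#' is forward-peaked with density proportional to `exp(kappa * cos
#' theta)` on the sphere (`kappa = 0` is isotropic), reflecting the
#' forward-peaked kinematics of cascade neutrons.
#'
#' These parameters are statistical fixtures for exercising the scoring
#' pipeline, not nuclear-physics claims.
#'
#' @param evaporation_temperature_MeV Maxwellian temperature T, MeV,
#'   `> 0`.
#' @param cascade_fraction Mixture weight of the cascade component, in
#'   `[0, 1]`.
#' @param cascade_mean_MeV,cascade_sd_MeV Mean and sd of the truncated
#'   normal cascade component, MeV.
#' @param angular_forwardness Concentration kappa, `>= 0`.
#' @return Object of class `"spectrum_model"`.
#' @export
spectrum_model <- function(evaporation_temperature_MeV = 2,
                           cascade_fraction = 0.3,
                           cascade_mean_MeV = 100,
                           cascade_sd_MeV = 40,
                           angular_forwardness = 2) {
  check_scalar(evaporation_temperature_MeV, "evaporation_temperature_MeV",
               positive = TRUE)
  check_unit_interval(cascade_fraction, "cascade_fraction")
  check_scalar(cascade_mean_MeV, "cascade_mean_MeV", positive = TRUE)
  check_scalar(cascade_sd_MeV, "cascade_sd_MeV", positive = TRUE)
  check_scalar(angular_forwardness, "angular_forwardness",
               nonnegative = TRUE)
  structure(list(evaporation_temperature_MeV = evaporation_temperature_MeV,
                 cascade_fraction = cascade_fraction,
                 cascade_mean_MeV = cascade_mean_MeV,
                 cascade_sd_MeV = cascade_sd_MeV,
                 angular_forwardness = angular_forwardness),
            class = "spectrum_model")
}

# Maxwellian E*exp(-E/T) is Gamma(shape = 2, scale = T); truncated by
# resampling the rare tail beyond e_max
sample_evaporation <- function(n, temperature, e_max = 250) {
  if (n == 0L) return(numeric())
  e <- stats::rgamma(n, shape = 2, scale = temperature)
  while (any(bad <- e >= e_max)) {
    e[bad] <- stats::rgamma(sum(bad), shape = 2, scale = temperature)
  }
  e
}

sample_cascade <- function(n, mean, sd, e_max = 250) {
  if (n == 0L) return(numeric())
  e <- stats::rnorm(n, mean, sd)
  while (any(bad <- e < 0 | e >= e_max)) {
    e[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  e
}

# inverse-CDF sample of cos(theta) with density prop. to exp(kappa * u)
# on [-1, 1]
sample_cos_theta <- function(n, kappa) {
  u <- stats::runif(n)
  if (kappa == 0) return(2 * u - 1)
  log(exp(-kappa) + u * (exp(kappa) - exp(-kappa))) / kappa
}

#' Generate synthetic crossing records
#'
#' Draws a Poisson number of neutron crossings (`n_protons *
#' yield_per_proton` expected) with i.i.d. energies and angles from a
#' [spectrum_model()], emulating a Monte Carlo tally export. All
#' randomness flows through the supplied seed; the global RNG state is
#' left untouched, and the same seed reproduces the records bitwise.
#'
#' @param model A [spectrum_model()].
#' @param n_protons Number of incident protons, `> 0`.
#' @param yield_per_proton Expected crossings per proton, `>= 0`.
#' @param seed Integer seed.
#' @return A [crossing_records()] data frame (unit weights).
#' @examples
#' cr <- generate_crossings(spectrum_model(), n_protons = 1000,
#'                          yield_per_proton = 0.1, seed = 1)
#' @export
generate_crossings <- function(model, n_protons, yield_per_proton, seed) {
  stopifnot(inherits(model, "spectrum_model"))
  check_scalar(n_protons, "n_protons", positive = TRUE)
  check_scalar(yield_per_proton, "yield_per_proton", nonnegative = TRUE)
  withr::with_seed(seed, {
    n <- stats::rpois(1, n_protons * yield_per_proton)
    n_cas <- stats::rbinom(1, n, model$cascade_fraction)
    energy <- c(
      sample_evaporation(n - n_cas, model$evaporation_temperature_MeV),
      sample_cascade(n_cas, model$cascade_mean_MeV, model$cascade_sd_MeV))
    # interleave deterministically: permute so component order is not
    # position-coded
    energy <- energy[sample.int(max(n, 1L), n)]
    theta <- acos(sample_cos_theta(n, model$angular_forwardness)) * 180 / pi
    crossing_records(energy, pmin(theta, 180), weight = 1)
  })
}

#' Analytic energy-bin probabilities of a spectrum model
#'
#' Probability that a sampled neutron energy falls in each of the 250
#' one-MeV scoring bins, from the closed-form mixture CDF (normalized
#' Maxwellian/Gamma and truncated-normal components). Used as the
#' independent oracle when checking that scoring and dose conversion
#' recover a known spectrum.
#'
#' @param model A [spectrum_model()].
#' @return Numeric vector of 250 probabilities summing to 1.
#' @export
energy_bin_probabilities <- function(model) {
  stopifnot(inherits(model, "spectrum_model"))
  edges <- 0:250
  tt <- model$evaporation_temperature_MeV
  # Gamma(2, T) CDF, conditioned on E < 250
  evap <- stats::pgamma(edges, shape = 2, scale = tt) /
    stats::pgamma(250, shape = 2, scale = tt)
  m <- model$cascade_mean_MeV
  s <- model$cascade_sd_MeV
  cas <- (stats::pnorm(edges, m, s) - stats::pnorm(0, m, s)) /
    (stats::pnorm(250, m, s) - stats::pnorm(0, m, s))
  cdf <- (1 - model$cascade_fraction) * evap + model$cascade_fraction * cas
  diff(cdf)
}

#' Generate a randomized synthetic vault
#'
#' Builds a valid rectangular concrete vault emulating a single-room
#' proton facility: four walls of randomized lateral half-extent (4-7 m)
#' and thickness (1-3 m), with `n_pois` points of interest placed 30 cm
#' outside the outer face of randomly chosen walls — the conventional
#' survey offset. Occupancy factors are drawn from the standard NCRP set
#' `{0.025, 0.0625, 0.25, 1}` and design goals from `{1, 5}` mSv/yr
#' (uncontrolled / controlled). The returned object also carries the
#' default three-source set, a placeholder beam normalization, the
#' 400 Gy/wk workload and the standard gantry-angle grid, so it can be
#' fed directly to [compliance_report()] or [run_assessment()].
#'
#' The geometry stands in for real architectural blueprints; it is
#' synthetic by construction and labeled as such.
#'
#' @param seed Integer seed (same seed, same vault).
#' @param n_pois Number of points of interest, `>= 1`.
#' @param protons_per_gray_at_isocenter Beam normalization carried in the
#'   config. The default 1e11 p/Gy is a round placeholder for exercising
#'   the pipeline, not a machine calibration.
#' @return A `vault_config` list (see [vault_config()]).
#' @export
generate_vault <- function(seed, n_pois = 8,
                           protons_per_gray_at_isocenter = 1e11) {
  if (!is.numeric(n_pois) || n_pois < 1) {
    stop("`n_pois` must be >= 1", call. = FALSE)
  }
  n_pois <- as.integer(n_pois)
  withr::with_seed(seed, {
    half_x <- stats::runif(1, 4, 7)   # room half-width along gantry axis
    half_y <- stats::runif(1, 4, 7)   # half-depth along beam axis
    half_z <- 2.5                     # half-height; walls span full height
    thick <- stats::runif(4, 1, 3)
    # walls at +/-x and +/-y; centers on the midplane of each wall
    walls <- list(
      barrier_slab("wall_east", c(half_x + thick[1] / 2, 0, 0), c(1, 0, 0),
                   c(0, half_y + max(thick), 0), c(0, 0, half_z), thick[1]),
      barrier_slab("wall_west", c(-half_x - thick[2] / 2, 0, 0),
                   c(-1, 0, 0),
                   c(0, half_y + max(thick), 0), c(0, 0, half_z), thick[2]),
      barrier_slab("wall_north", c(0, half_y + thick[3] / 2, 0), c(0, 1, 0),
                   c(half_x + max(thick), 0, 0), c(0, 0, half_z), thick[3]),
      barrier_slab("wall_south", c(0, -half_y - thick[4] / 2, 0),
                   c(0, -1, 0),
                   c(half_x + max(thick), 0, 0), c(0, 0, half_z), thick[4]))
    occ_set <- c(0.025, 0.0625, 0.25, 1)
    pois <- lapply(seq_len(n_pois), function(k) {
      wall_idx <- sample.int(4, 1)
      w <- walls[[wall_idx]]
      # outer face + 30 cm survey offset, random lateral placement kept
      # away from the rectangle edge so the ray from isocenter crosses
      # this wall
      lateral <- stats::runif(1, -0.6, 0.6)
      pos <- w$center_m + (w$thickness_m / 2 + 0.3) * w$normal +
        lateral * w$u_m
      goal <- sample(c(1, 5), 1)
      point_of_interest(
        id = sprintf("poi_%02d", k), position_m = pos,
        occupancy = sample(occ_set, 1),
        design_goal_mSv_per_yr = goal,
        area_class = if (goal == 5) "controlled" else "uncontrolled")
    })
    vault_config(
      geometry = vault_geometry(barriers = walls, pois = pois),
      sources = default_sources(),
      normalization = beam_normalization(protons_per_gray_at_isocenter),
      workload_Gy_per_wk = weekly_workload(),
      weeks_per_year = 50,
      gantry_angles_deg = c(0, 90, 180, 270))
  })
}
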