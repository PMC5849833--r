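#' Particle-crossing records
#'
#' A set of weighted neutron crossings of the scoring sphere, as exported by
#' a Monte Carlo tally or drawn from [generate_crossings()]. Each record
#' carries the neutron energy, the polar angle from the incident proton beam
#' axis at the source, and a statistical weight.
#'
#' @param energy_MeV Numeric vector of neutron energies in MeV; each must
#'   satisfy `0 <= E < 250` (the scoring grid spans 250 one-MeV bins).
#' @param theta_deg Numeric vector of polar angles in degrees, in
#'   `[0, 180]`, measured from the proton beam direction at the source.
#' @param weight Statistical weights, `>= 0`; recycled if length 1.
#' @return A `data.frame` of class `"crossing_records"` with columns
#'   `energy_MeV`, `theta_deg`, `weight`.
#' @examples
#' crossing_records(energy_MeV = c(5.5, 120), theta_deg = c(12, 3))
#' @seealso [score_fluence()], [generate_crossings()]
#' @export
crossing_records <- function(energy_MeV = numeric(), theta_deg = numeric(),
                             weight = 1) {
  energy_MeV <- as.numeric(energy_MeV)
  theta_deg <- as.numeric(theta_deg)
  n <- length(energy_MeV)
  if (length(theta_deg) != n) {
    stop("`energy_MeV` and `theta_deg` must have equal length", call. = FALSE)
  }
  weight <- rep_len(as.numeric(weight), n)
  bad <- which(!is.finite(energy_MeV) | energy_MeV < 0 | energy_MeV >= 250)
  if (length(bad)) {
    stop(sprintf(
      "record %d rejected: energy %g MeV outside [0, 250)",
      bad[1], energy_MeV[bad[1]]), call. = FALSE)
  }
  bad <- which(!is.finite(theta_deg) | theta_deg < 0 | theta_deg > 180)
  if (length(bad)) {
    stop(sprintf(
      "record %d rejected: polar angle %g deg outside [0, 180]",
      bad[1], theta_deg[bad[1]]), call. = FALSE)
  }
  if (any(!is.finite(weight) | weight < 0)) {
    stop("all weights must be finite and >= 0", call. = FALSE)
  }
  structure(
    data.frame(energy_MeV = energy_MeV, theta_deg = theta_deg,
               weight = weight),
    class = c("crossing_records", "data.frame"))
}

#' Tally crossings into an angular/energy fluence spectrum
#'
#' Bins weighted crossing records on a spherical scoring surface into 18
#' polar-angle bins (10 degrees each, `[0,10), ..., [170,180]`) by 250
#' energy bins (1 MeV each, up to 250 MeV), and normalizes each bin by the
#' spherical-zone area of its angle bin and by the number of incident
#' protons. The result is fluence in m^-2 per incident proton, the quantity
#' that multiplies a fluence-to-dose coefficient to give ambient dose
#' equivalent.
#'
#' The zone area of angle bin `[lo, hi)` at radius `r` is
#' `2 * pi * r^2 * (cos(lo) - cos(hi))`, so summing `value * area *
#' n_protons` over all bins recovers the total tallied weight exactly.
#'
#' @param crossings A [crossing_records()] object (or a data frame with the
#'   same columns, which is validated on entry).
#' @param n_protons Number of incident protons driving the tally; `> 0`.
#' @param radius Scoring sphere radius in meters (default 1 m, the
#'   normalization distance used for angular source terms).
#' @return An object of class `"fluence_spectrum"`: a list with `values`
#'   (18 x 250 matrix, m^-2 per proton), `n_protons`, and `radius`.
#' @examples
#' cr <- crossing_records(5.5, 12)
#' sp <- score_fluence(cr, n_protons = 1)
#' sp$values[2, 6]  # the [10,20) x [5,6) bin
#' @export
score_fluence <- function(crossings, n_protons, radius = 1) {
  check_scalar(n_protons, "n_protons", positive = TRUE)
  check_scalar(radius, "radius", positive = TRUE)
  if (!inherits(crossings, "crossing_records")) {
    crossings <- crossing_records(crossings$energy_MeV, crossings$theta_deg,
                                  if (is.null(crossings$weight)) 1
                                  else crossings$weight)
  }
  values <- matrix(0, nrow = N_ANGLE_BINS, ncol = N_ENERGY_BINS)
  if (nrow(crossings) > 0) {
    i <- angle_bin_index(crossings$theta_deg)
    j <- energy_bin_index(crossings$energy_MeV)
    tallied <- tapply(crossings$weight, list(factor(i, 1:N_ANGLE_BINS),
                                             factor(j, 1:N_ENERGY_BINS)),
                      sum, default = 0)
    values <- unname(as.matrix(tallied))
  }
  values <- values / zone_areas(radius) / n_protons
  structure(list(values = values, n_protons = n_protons, radius = radius),
            class = "fluence_spectrum")
}

#' @export
print.fluence_spectrum <- function(x, ...) {
  cat(sprintf(
    "<fluence_spectrum> 18 x 250 bins, %g incident protons, r = %g m\n",
    x$n_protons, x$radius))
  cat(sprintf("  total fluence: %.4g m^-2 per proton; %d nonzero bins\n",
              sum(x$values), sum(x$values > 0)))
  invisible(x)
}

#' Fluence-to-ambient-dose conversion coefficients
#'
#' An energy-indexed table of neutron fluence-to-H*(10) conversion
#' coefficients in pSv cm^2, of the kind tabulated in ICRP Publication 74
#' and its high-energy extensions. Coefficients are interpolated log-log
#' between grid points.
#'
#' @param energies_MeV Strictly increasing positive energy grid (MeV).
#' @param coefficients_pSv_cm2 Nonnegative coefficients at the grid points.
#' @return An object of class `"conversion_table"`.
#' @seealso [read_conversion_table()] for the packaged ICRP-74-style
#'   fixture, [interpolate_coefficient()].
#' @export
conversion_table <- function(energies_MeV, coefficients_pSv_cm2) {
  energies_MeV <- as.numeric(energies_MeV)
  coefficients_pSv_cm2 <- as.numeric(coefficients_pSv_cm2)
  if (length(energies_MeV) < 2L ||
      length(energies_MeV) != length(coefficients_pSv_cm2)) {
    stop("need >= 2 grid points with one coefficient each", call. = FALSE)
  }
  if (any(energies_MeV <= 0) || any(diff(energies_MeV) <= 0)) {
    stop("`energies_MeV` must be positive and strictly increasing",
         call. = FALSE)
  }
  if (any(coefficients_pSv_cm2 < 0)) {
    stop("coefficients must be >= 0", call. = FALSE)
  }
  structure(list(energies_MeV = energies_MeV,
                 coefficients_pSv_cm2 = coefficients_pSv_cm2),
            class = "conversion_table")
}

#' Read / write a conversion-coefficient table
#'
#' The on-disk format is a two-column CSV with header
#' `energy_MeV,coefficient_pSv_cm2`. With no argument,
#' `read_conversion_table()` loads the packaged ICRP-74-style neutron
#' H*(10) table (grid 1e-9 to 201 MeV; values above 20 MeV follow the
#' standard high-energy extension of the ICRP 74 coefficients).
#'
#' @param path CSV file path.
#' @return For `read_conversion_table()`, a [conversion_table()];
#'   `write_conversion_table()` returns `path` invisibly.
#' @examples
#' tab <- read_conversion_table()
#' interpolate_coefficient(tab, 2.5)
#' @export
read_conversion_table <- function(path = nv_extdata("icrp74_neutron_hstar10.csv")) {
  df <- utils::read.csv(path)
  need <- c("energy_MeV", "coefficient_pSv_cm2")
  if (!all(need %in% names(df))) {
    stop(sprintf("conversion table '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  conversion_table(df$energy_MeV, df$coefficient_pSv_cm2)
}

#' @rdname read_conversion_table
#' @param table A [conversion_table()].
#' @export
write_conversion_table <- function(table, path) {
  stopifnot(inherits(table, "conversion_table"))
  utils::write.csv(
    data.frame(energy_MeV = table$energies_MeV,
               coefficient_pSv_cm2 = table$coefficients_pSv_cm2),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate a fluence-to-dose coefficient
#'
#' Log-log interpolation of f(E) between bracketing grid points. Outside
#' the grid the policy is flat: below the lowest energy the lowest
#' coefficient is returned, above the highest the highest-energy
#' coefficient. Published coefficient grids are sparse and log-spaced, so
#' log-log interpolation is the field's standard rule.
#'
#' @param table A [conversion_table()].
#' @param energy_MeV Neutron energy (MeV), `> 0`; vectorized.
#' @return Coefficient(s) in pSv cm^2.
#' @export
interpolate_coefficient <- function(table, energy_MeV) {
  stopifnot(inherits(table, "conversion_table"))
  if (length(energy_MeV) == 0L) return(numeric())
  if (any(!is.finite(energy_MeV) | energy_MeV <= 0)) {
    stop("`energy_MeV` must be positive and finite", call. = FALSE)
  }
  e <- table$energies_MeV
  f <- table$coefficients_pSv_cm2
  # flat beyond the grid; rule = 2 clamps in log space which is exactly that
  out <- exp(stats::approx(log(e), log(pmax(f, .Machine$double.xmin)),
                           xout = log(energy_MeV), rule = 2)$y)
  # restore exact zeros if the table contains them
  out[out <= .Machine$double.xmin * 2] <- 0
  # grid points return their tabulated coefficient exactly
  hit <- match(energy_MeV, e)
  out[!is.na(hit)] <- f[hit[!is.na(hit)]]
  out
}

#' Convert a fluence spectrum to an angular source term
#'
#' For each polar-angle bin, multiplies the per-proton fluence in every
#' energy bin by the fluence-to-dose coefficient at the energy-bin midpoint
#' and sums over energy:
#' `H*(theta) = sum_E Phi(theta, E) * f(E_mid) * 1e-16`,
#' yielding ambient dose equivalent per incident proton in Sv m^2 at the
#' scoring radius (the 1e-16 factor converts pSv cm^2 to Sv m^2). The
#' spectrum must be scored at (or rescaled to) 1 m so the result matches
#' the 1 m normalization convention of angular source-term tables.
#'
#' @param spectrum A [score_fluence()] result with `radius == 1`.
#' @param table A [conversion_table()].
#' @param source_id Label for the resulting term (default `"custom"`).
#' @return An [angular_source_term()] with 18 values in Sv m^2 per proton.
#' @export
spectrum_to_source_term <- function(spectrum, table, source_id = "custom") {
  stopifnot(inherits(spectrum, "fluence_spectrum"),
            inherits(table, "conversion_table"))
  if (!isTRUE(all.equal(spectrum$radius, 1))) {
    stop("spectrum must be scored at radius 1 m (rescale before converting)",
         call. = FALSE)
  }
  if (!identical(dim(spectrum$values), c(N_ANGLE_BINS, N_ENERGY_BINS))) {
    stop("spectrum grid must be 18 angle bins x 250 energy bins",
         call. = FALSE)
  }
  f_mid <- interpolate_coefficient(table, seq_len(N_ENERGY_BINS) - 0.5)
  values <- as.numeric(spectrum$values %*% f_mid) * 1e-16
  angular_source_term(source_id, values, allow_zero = TRUE)
}

#' Write / read a fluence spectrum
#'
#' `write_fluence_spectrum()` serializes the full grid either as a long CSV
#' (`angle_bin`, `energy_bin`, `fluence_m2_per_proton`; 1-based bin
#' indices) or as a dense JSON object carrying the grid and its metadata;
#' the format follows the file extension. `read_fluence_spectrum()` inverts
#' either format.
#'
#' @param spectrum A `fluence_spectrum`.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path` (write) or a `fluence_spectrum` (read), invisibly/visibly.
#' @export
write_fluence_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "fluence_spectrum"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(n_protons = spectrum$n_protons, radius_m = spectrum$radius,
           values_m2_per_proton = spectrum$values),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    grid <- expand.grid(angle_bin = seq_len(N_ANGLE_BINS),
                        energy_bin = seq_len(N_ENERGY_BINS))
    utils::write.csv(
      data.frame(grid,
                 fluence_m2_per_proton = as.numeric(spectrum$values)),
      path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_fluence_spectrum
#' @export
read_fluence_spectrum <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    values <- matrix(as.numeric(x$values_m2_per_proton),
                     nrow = N_ANGLE_BINS, ncol = N_ENERGY_BINS)
    return(structure(list(values = values, n_protons = x$n_protons,
                          radius = x$radius_m), class = "fluence_spectrum"))
  }
  df <- utils::read.csv(path)
  values <- matrix(0, N_ANGLE_BINS, N_ENERGY_BINS)
  values[cbind(df$angle_bin, df$energy_bin)] <- df$fluence_m2_per_proton
  structure(list(values = values, n_protons = NA_real_, radius = 1),
            class = "fluence_spectrum")
}
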