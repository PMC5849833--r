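# internal helpers shared across modules

N_ANGLE_BINS <- 18L
N_ENERGY_BINS <- 250L
ANGLE_BIN_LO <- seq(0, 170, by = 10)
ANGLE_BIN_HI <- seq(10, 180, by = 10)
SOURCE_IDS <- c("cyclotron", "nozzle", "phantom")

# scalar numeric validators; `name` appears in the error message
check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  if (finite && !is.finite(x)) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

check_unit_interval <- function(x, name, open_lo = FALSE) {
  check_scalar(x, name)
  if (x > 1 || x < 0 || (open_lo && x == 0)) {
    stop(sprintf("`%s` must lie in %s0, 1] (got %g)", name,
                 if (open_lo) "(" else "[", x), call. = FALSE)
  }
  invisible(x)
}

check_point3 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 3L || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be a finite numeric vector of length 3", name),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

# index of the 10-degree polar-angle bin containing theta; theta = 180
# folds into the last bin (half-open [lo, hi) bins otherwise)
angle_bin_index <- function(theta) {
  pmin(floor(theta / 10) + 1L, N_ANGLE_BINS)
}

# index of the 1 MeV energy bin containing E in [0, 250)
energy_bin_index <- function(energy) {
  floor(energy) + 1L
}

# area (m^2) of each 10-degree spherical zone at the given radius
zone_areas <- function(radius = 1) {
  2 * pi * radius^2 * (cospi(ANGLE_BIN_LO / 180) - cospi(ANGLE_BIN_HI / 180))
}

# unit vector; errors on (near-)zero input
unit_vector <- function(v, name = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) {
    stop(sprintf("`%s` has zero length", name), call. = FALSE)
  }
  v / n
}

# angle in degrees between two 3-vectors
angle_between_deg <- function(a, b) {
  ca <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(min(1, max(-1, ca))) * 180 / pi
}

#' Path to a packaged example data file
#'
#' Convenience accessor for the plain-text fixtures shipped under
#' `inst/extdata`: the Mevion S250 angular source-term table, an
#' ICRP-74-style neutron H*(10) conversion-coefficient table, and a
#' synthetic concrete attenuation-length table used by the examples and
#' tests.
#'
#' @param file File name within the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @examples
#' nv_extdata()
#' nv_extdata("source_terms_mevion_s250.csv")
#' @export
nv_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "neutronvault")))
  }
  path <- system.file("extdata", file, package = "neutronvault")
  if (!nzchar(path)) {
    stop(sprintf("no packaged data file named '%s'", file), call. = FALSE)
  }
  path
}
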