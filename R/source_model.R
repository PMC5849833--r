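#' Angular neutron source term
#'
#' Ambient dose equivalent per incident proton at 1 m from a
#' neutron-producing target, binned in 18 ten-degree polar-angle intervals
#' measured from the incoming proton beam direction. Units are Sv m^2 per
#' proton: multiplying by 1/r^2 (r in meters) gives Sv per proton at
#' distance r.
#'
#' @param source_id Label; conventionally one of `"cyclotron"`, `"nozzle"`,
#'   `"phantom"`, but custom labels (e.g. a brass aperture term) are
#'   allowed.
#' @param values_Sv_m2_per_p 18 nonnegative values, one per 10-degree bin
#'   from `[0,10)` to `[170,180]`.
#' @param allow_zero Permit zero entries (a source term derived from a
#'   sparse tally can have empty bins); measured/packaged tables are
#'   strictly positive.
#' @return Object of class `"angular_source_term"`.
#' @seealso [read_source_terms()] for the packaged Mevion S250 table,
#'   [source_term_at_angle()].
#' @export
angular_source_term <- function(source_id, values_Sv_m2_per_p,
                                allow_zero = FALSE) {
  values <- as.numeric(values_Sv_m2_per_p)
  if (length(values) != N_ANGLE_BINS) {
    stop(sprintf("an angular source term has exactly %d bins (got %d)",
                 N_ANGLE_BINS, length(values)), call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0) ||
      (!allow_zero && any(values == 0))) {
    stop("source-term values must be finite and positive", call. = FALSE)
  }
  structure(list(source_id = as.character(source_id)[1], values = values),
            class = "angular_source_term")
}

#' @export
print.angular_source_term <- function(x, ...) {
  cat(sprintf("<angular_source_term> '%s': %.3g (forward) .. %.3g (backward) Sv m^2/p\n",
              x$source_id, x$values[1], x$values[N_ANGLE_BINS]))
  invisible(x)
}

#' Read / write angular source-term tables
#'
#' The on-disk format is a CSV with columns `angle_bin_lo`, `angle_bin_hi`
#' and one column per source (`nozzle`, `water_phantom`, `fe_target`),
#' values in Sv m^2 per proton normalized to 1 m. With no argument,
#' `read_source_terms()` loads the packaged Mevion S250 table obtained
#' from Monte Carlo simulation of the three in-room neutron sources: the
#' cyclotron iron target, the passive-scattering treatment nozzle, and a
#' 30 x 30 x 40 cm^3 water phantom at isocenter.
#'
#' @param path CSV file path.
#' @return A named list of three [angular_source_term()] objects with names
#'   `cyclotron`, `nozzle`, `phantom`.
#' @examples
#' terms <- read_source_terms()
#' source_term_at_angle(terms$cyclotron, 5)
#' @export
read_source_terms <- function(path = nv_extdata("source_terms_mevion_s250.csv")) {
  df <- utils::read.csv(path)
  need <- c("angle_bin_lo", "angle_bin_hi", "nozzle", "water_phantom",
            "fe_target")
  if (!all(need %in% names(df)) || nrow(df) != N_ANGLE_BINS) {
    stop(sprintf(
      "source-term table '%s' must have 18 rows and columns %s", path,
      paste(need, collapse = ", ")), call. = FALSE)
  }
  if (!all(df$angle_bin_lo == ANGLE_BIN_LO) ||
      !all(df$angle_bin_hi == ANGLE_BIN_HI)) {
    stop("angle bins must be 0-10, 10-20, ..., 170-180", call. = FALSE)
  }
  list(cyclotron = angular_source_term("cyclotron", df$fe_target),
       nozzle = angular_source_term("nozzle", df$nozzle),
       phantom = angular_source_term("phantom", df$water_phantom))
}

#' @rdname read_source_terms
#' @param terms Named list of the three [angular_source_term()] objects.
#' @export
write_source_terms <- function(terms, path) {
  stopifnot(all(SOURCE_IDS %in% names(terms)))
  df <- data.frame(angle_bin_lo = ANGLE_BIN_LO, angle_bin_hi = ANGLE_BIN_HI,
                   nozzle = terms$nozzle$values,
                   water_phantom = terms$phantom$values,
                   fe_target = terms$cyclotron$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up a source term at a polar angle
#'
#' Piecewise-constant lookup of the 10-degree bin containing `theta_deg`;
#' the tabulated terms are bin averages, so no interpolation is applied.
#' `theta = 180` folds into the last bin.
#'
#' @param term An [angular_source_term()].
#' @param theta_deg Polar angle in degrees, in `[0, 180]`; vectorized.
#' @return Source term value(s), Sv m^2 per proton at 1 m.
#' @export
source_term_at_angle <- function(term, theta_deg) {
  stopifnot(inherits(term, "angular_source_term"))
  if (any(!is.finite(theta_deg) | theta_deg < 0 | theta_deg > 180)) {
    stop("`theta_deg` must lie in [0, 180]", call. = FALSE)
  }
  term$values[angle_bin_index(theta_deg)]
}

#' Neutron source specification
#'
#' Position and beam-loss fraction of one of the three in-room neutron
#' sources. The cyclotron and nozzle sit upstream of isocenter on the beam
#' axis and rotate rigidly with the gantry; the phantom sits at isocenter.
#' The coordinate frame is right-handed with origin at isocenter, the
#' gantry rotation axis along +x (horizontal), and the default beam
#' reference axis +y (horizontal, the beam direction at gantry angle 0).
#'
#' @param source_id One of `"cyclotron"`, `"nozzle"`, `"phantom"`.
#' @param offset_from_isocenter_m Signed offset along the beam axis in
#'   meters; negative is upstream of isocenter. Must be 0 for the phantom.
#' @param loss_fraction Fraction of the beam lost (interacting) in this
#'   source, in `(0, 1]`. Conventional values: 0.1 cyclotron, 0.1 nozzle,
#'   1.0 phantom.
#' @param beam_axis_reference Unit beam direction at gantry angle 0.
#' @return Object of class `"neutron_source_spec"`.
#' @export
neutron_source_spec <- function(source_id,
                                offset_from_isocenter_m,
                                loss_fraction,
                                beam_axis_reference = c(0, 1, 0)) {
  source_id <- match.arg(source_id, SOURCE_IDS)
  check_scalar(offset_from_isocenter_m, "offset_from_isocenter_m")
  check_unit_interval(loss_fraction, "loss_fraction", open_lo = TRUE)
  if (source_id == "phantom" && offset_from_isocenter_m != 0) {
    stop("the phantom source sits at isocenter (offset must be 0)",
         call. = FALSE)
  }
  structure(list(source_id = source_id,
                 offset_from_isocenter_m = offset_from_isocenter_m,
                 loss_fraction = loss_fraction,
                 beam_axis_reference =
                   unit_vector(check_point3(beam_axis_reference,
                                            "beam_axis_reference"),
                               "beam_axis_reference")),
            class = "neutron_source_spec")
}

#' Default three-source set for an in-room cyclotron unit
#'
#' Cyclotron iron target 2 m upstream, treatment nozzle 1 m upstream,
#' water phantom at isocenter, with beam-loss fractions 10%, 10% and 100%.
#' The upstream offsets are configurable geometry, not measured machine
#' constants.
#'
#' @param cyclotron_offset_m,nozzle_offset_m Signed beam-axis offsets (m).
#' @param beam_axis_reference Beam direction at gantry angle 0.
#' @return Named list of three [neutron_source_spec()] objects.
#' @export
default_sources <- function(cyclotron_offset_m = -2.0,
                            nozzle_offset_m = -1.0,
                            beam_axis_reference = c(0, 1, 0)) {
  list(
    cyclotron = neutron_source_spec("cyclotron", cyclotron_offset_m, 0.1,
                                    beam_axis_reference),
    nozzle = neutron_source_spec("nozzle", nozzle_offset_m, 0.1,
                                 beam_axis_reference),
    phantom = neutron_source_spec("phantom", 0, 1.0, beam_axis_reference))
}

# beam direction at a gantry angle: rigid rotation of the reference axis
# about the horizontal gantry axis (+x) through isocenter
beam_direction <- function(spec, gantry_angle_deg) {
  b <- spec$beam_axis_reference
  cg <- cospi(gantry_angle_deg / 180)
  sg <- sinpi(gantry_angle_deg / 180)
  c(b[1], b[2] * cg - b[3] * sg, b[2] * sg + b[3] * cg)
}

#' Position of a neutron source at a gantry angle
#'
#' The source sits on the beam axis at its signed offset from isocenter;
#' the axis rotates rigidly with the gantry about the horizontal gantry
#' axis (+x) through isocenter. The phantom (offset 0) is always at the
#' origin.
#'
#' @param spec A [neutron_source_spec()].
#' @param gantry_angle_deg Gantry angle in degrees, `[0, 360)`.
#' @return Numeric 3-vector, meters, isocenter origin.
#' @export
source_position <- function(spec, gantry_angle_deg) {
  stopifnot(inherits(spec, "neutron_source_spec"))
  check_scalar(gantry_angle_deg, "gantry_angle_deg")
  if (gantry_angle_deg < 0 || gantry_angle_deg >= 360) {
    stop("`gantry_angle_deg` must lie in [0, 360)", call. = FALSE)
  }
  spec$offset_from_isocenter_m * beam_direction(spec, gantry_angle_deg)
}

#' Beam normalization
#'
#' The number of protons that must reach isocenter to deliver 1 Gy to the
#' phantom. This machine- and configuration-specific constant is required
#' user input; no default is provided because a placeholder would silently
#' scale every dose.
#'
#' @param protons_per_gray_at_isocenter Protons per Gy at isocenter, `> 0`.
#' @return Object of class `"beam_normalization"`.
#' @export
beam_normalization <- function(protons_per_gray_at_isocenter) {
  check_scalar(protons_per_gray_at_isocenter,
               "protons_per_gray_at_isocenter", positive = TRUE)
  structure(list(protons_per_gray_at_isocenter =
                   protons_per_gray_at_isocenter),
            class = "beam_normalization")
}

#' Protons interacting in a source per Gy delivered
#'
#' Converts the isocenter normalization P (protons/Gy) into the number of
#' protons interacting in each source per Gy, by back-propagating P
#' through the survival fractions of the upstream beam line
#' (cyclotron -> nozzle -> phantom). With 10% loss at the cyclotron and
#' 10% at the nozzle:
#' phantom `N = P`; nozzle `N = 0.1 P / 0.9`; cyclotron
#' `N = 0.1 P / (0.9 * 0.9)`. An alternative reading — losses as simple
#' fractions of the isocenter count — is available via
#' `method = "fraction_of_isocenter"` (`N = loss_fraction * P` upstream).
#'
#' @param spec A [neutron_source_spec()].
#' @param norm A [beam_normalization()].
#' @param method `"back_propagate"` (default) or
#'   `"fraction_of_isocenter"`.
#' @param nozzle_loss_fraction Loss fraction of the intervening nozzle
#'   stage, needed only to back-propagate past it for the cyclotron.
#' @return Protons per Gy interacting in the source.
#' @export
protons_per_gray <- function(spec, norm,
                             method = c("back_propagate",
                                        "fraction_of_isocenter"),
                             nozzle_loss_fraction = 0.1) {
  stopifnot(inherits(spec, "neutron_source_spec"),
            inherits(norm, "beam_normalization"))
  method <- match.arg(method)
  p <- norm$protons_per_gray_at_isocenter
  if (spec$source_id == "phantom") return(p)
  if (method == "fraction_of_isocenter") {
    return(spec$loss_fraction * p)
  }
  switch(spec$source_id,
    # protons entering the nozzle per Gy: P / (1 - loss); lost there:
    # loss * P / (1 - loss)
    nozzle = spec$loss_fraction * p / (1 - spec$loss_fraction),
    # one more survival stage (the nozzle) between cyclotron and isocenter
    cyclotron = spec$loss_fraction * p /
      ((1 - spec$loss_fraction) * (1 - nozzle_loss_fraction)))
}
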