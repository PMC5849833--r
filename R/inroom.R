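#' Beam configuration
#'
#' One of the passive-scattering option groups of a compact proton unit.
#' The three configurations used for in-room surveys are `large`
#' (range 25 cm, modulation 20 cm, fields up to 26.5 cm diameter), `deep`
#' (range 30 cm, modulation 10 cm) and `small` (range 15 cm, modulation
#' 10 cm), the latter two with fields up to 15 cm diameter.
#'
#' @param name `"large"`, `"deep"` or `"small"`.
#' @param range_cm Beam range in water, cm, `> 0`.
#' @param modulation_width_cm Spread-out Bragg peak width, cm, in
#'   `(0, range]`.
#' @param max_field_diameter_cm Largest deliverable field diameter, cm.
#' @return Object of class `"beam_configuration"`.
#' @export
beam_configuration <- function(name = c("large", "deep", "small"),
                               range_cm = NULL,
                               modulation_width_cm = NULL,
                               max_field_diameter_cm = NULL) {
  name <- match.arg(name)
  defaults <- list(
    large = list(range_cm = 25, modulation_width_cm = 20,
                 max_field_diameter_cm = 26.5),
    deep = list(range_cm = 30, modulation_width_cm = 10,
                max_field_diameter_cm = 15),
    small = list(range_cm = 15, modulation_width_cm = 10,
                 max_field_diameter_cm = 15))[[name]]
  range_cm <- if (is.null(range_cm)) defaults$range_cm else range_cm
  modulation_width_cm <- if (is.null(modulation_width_cm))
    defaults$modulation_width_cm else modulation_width_cm
  max_field_diameter_cm <- if (is.null(max_field_diameter_cm))
    defaults$max_field_diameter_cm else max_field_diameter_cm
  check_scalar(range_cm, "range_cm", positive = TRUE)
  check_scalar(modulation_width_cm, "modulation_width_cm", positive = TRUE)
  check_scalar(max_field_diameter_cm, "max_field_diameter_cm",
               positive = TRUE)
  if (modulation_width_cm > range_cm) {
    stop("`modulation_width_cm` cannot exceed `range_cm`", call. = FALSE)
  }
  structure(list(name = name, range_cm = range_cm,
                 modulation_width_cm = modulation_width_cm,
                 max_field_diameter_cm = max_field_diameter_cm),
            class = "beam_configuration")
}

#' H*/D from a rate measurement
#'
#' Converts a measured neutron ambient dose equivalent rate into neutron
#' dose per therapeutic proton dose: `H/D = Hr / (MUr * c)`, where `Hr`
#' is the measured neutron dose-equivalent rate (mSv/hr), `MUr` the
#' machine output rate (MU/hr) and `c` the dose calibration coefficient
#' (Gy/MU) for the configuration in use.
#'
#' @param Hr_mSv_per_hr Measured neutron dose equivalent rate, `>= 0`.
#' @param MUr_MU_per_hr Machine output rate, `> 0`.
#' @param c_Gy_per_MU Dose per monitor unit, `> 0`.
#' @return H*/D in mSv/Gy.
#' @examples
#' h_over_d_from_measurement(3, 6000, 0.01)  # 0.05 mSv/Gy
#' @export
h_over_d_from_measurement <- function(Hr_mSv_per_hr, MUr_MU_per_hr,
                                      c_Gy_per_MU) {
  check_scalar(Hr_mSv_per_hr, "Hr_mSv_per_hr", nonnegative = TRUE)
  check_scalar(MUr_MU_per_hr, "MUr_MU_per_hr", positive = TRUE)
  check_scalar(c_Gy_per_MU, "c_Gy_per_MU", positive = TRUE)
  Hr_mSv_per_hr / (MUr_MU_per_hr * c_Gy_per_MU)
}

#' Aperture blocking weight
#'
#' Fraction of an isotropic aperture source term activated by field-size
#' collimation. Smaller fields block more of the beam on the brass
#' aperture, producing more neutrons there; the weight is modeled as the
#' blocked-area fraction of the maximum circular field,
#' `1 - (field / max_field)^2`: 0 for a fully open field, 1 for a closed
#' aperture, strictly decreasing in between.
#'
#' @param field_diameter_cm Circular field diameter, cm, in
#'   `[0, max_field_diameter_cm]`.
#' @param config A [beam_configuration()].
#' @return Dimensionless weight in `[0, 1]`.
#' @export
aperture_weight <- function(field_diameter_cm, config) {
  stopifnot(inherits(config, "beam_configuration"))
  check_scalar(field_diameter_cm, "field_diameter_cm", nonnegative = TRUE)
  if (field_diameter_cm > config$max_field_diameter_cm) {
    stop(sprintf(
      "`field_diameter_cm` (%g) exceeds the %s configuration maximum (%g cm)",
      field_diameter_cm, config$name, config$max_field_diameter_cm),
      call. = FALSE)
  }
  1 - (field_diameter_cm / config$max_field_diameter_cm)^2
}

#' Predict in-room H*/D around the phantom
#'
#' Additive point-source prediction of the in-room neutron ambient dose
#' equivalent per therapeutic Gy at a survey point near isocenter. Each
#' source contributes `N_x * H*(theta_x) / r_x^2` with no barrier in the
#' way (everything is inside the vault), plus an optional brass-aperture
#' term co-located with the nozzle and scaled by [aperture_weight()].
#' Survey points lie in the horizontal plane through isocenter at
#' `(distance, angle)` polar coordinates, with angle 0 pointing downstream
#' along the beam axis at gantry angle 0 and increasing toward the
#' upstream (gantry) side.
#'
#' The model reproduces geometric trends — falloff with distance, rise
#' toward the upstream sources with angle, decrease with field size — and
#' per-source breakdowns. It is not calibrated to absolute survey values:
#' a line-of-sight point-source model inside a concrete room ignores
#' room-scattered (and in-phantom moderated) neutrons and overstates the
#' cyclotron as an unshielded point.
#'
#' @param distance_cm Distance from isocenter, cm, `> 0`.
#' @param angle_deg Angle around isocenter in the horizontal plane,
#'   degrees in `[0, 180]`; 0 = downstream.
#' @param config A [beam_configuration()].
#' @param sources Named list of [neutron_source_spec()].
#' @param normalization A [beam_normalization()].
#' @param terms Named list of [angular_source_term()] matching `sources`.
#' @param field_diameter_cm Field diameter for the aperture term; defaults
#'   to the configuration maximum (open field, no aperture contribution).
#' @param aperture_term_Sv_m2_per_p Aperture source magnitude per blocked
#'   proton (Sv m^2/p), applied isotropically at the nozzle position;
#'   0 disables the term.
#' @param gantry_angle_deg Gantry angle (default 0; survey geometry).
#' @param loss_method Passed to [protons_per_gray()].
#' @return Object of class `"h_over_d"`: list with `value_mSv_per_Gy` and
#'   `per_source_mSv_per_Gy` (named vector, including `aperture` when
#'   active).
#' @export
predict_h_over_d <- function(distance_cm, angle_deg, config,
                             sources, normalization, terms,
                             field_diameter_cm = NULL,
                             aperture_term_Sv_m2_per_p = 0,
                             gantry_angle_deg = 0,
                             loss_method = "back_propagate") {
  stopifnot(inherits(config, "beam_configuration"),
            inherits(normalization, "beam_normalization"))
  check_scalar(distance_cm, "distance_cm", positive = TRUE)
  check_scalar(angle_deg, "angle_deg")
  if (angle_deg < 0 || angle_deg > 180) {
    stop("`angle_deg` must lie in [0, 180]", call. = FALSE)
  }
  check_scalar(aperture_term_Sv_m2_per_p, "aperture_term_Sv_m2_per_p",
               nonnegative = TRUE)
  if (is.null(field_diameter_cm)) {
    field_diameter_cm <- config$max_field_diameter_cm
  }
  w_ap <- aperture_weight(field_diameter_cm, config)  # validates range

  # survey point in the horizontal plane; beam axis at gantry 0 is +y,
  # gantry axis +x: angle 0 -> downstream (+y), 180 -> upstream (-y)
  r_m <- distance_cm / 100
  point <- c(r_m * sinpi(angle_deg / 180), r_m * cospi(angle_deg / 180), 0)

  per_source <- vapply(names(sources), function(sid) {
    spec <- sources[[sid]]
    term <- terms[[sid]]
    if (is.null(term)) {
      stop(sprintf("no angular source term supplied for source '%s'", sid),
           call. = FALSE)
    }
    pos <- source_position(spec, gantry_angle_deg)
    ray <- point - pos
    r <- sqrt(sum(ray^2))
    theta <- angle_between_deg(beam_direction(spec, gantry_angle_deg), ray)
    n_gy <- protons_per_gray(spec, normalization, method = loss_method)
    n_gy * source_term_at_angle(term, theta) / r^2
  }, numeric(1))

  if (aperture_term_Sv_m2_per_p > 0 && w_ap > 0) {
    noz <- sources$nozzle
    if (is.null(noz)) {
      stop("aperture term requires a 'nozzle' source for its position",
           call. = FALSE)
    }
    pos <- source_position(noz, gantry_angle_deg)
    r <- sqrt(sum((point - pos)^2))
    n_gy <- protons_per_gray(noz, normalization, method = loss_method)
    per_source <- c(per_source,
                    aperture = w_ap * n_gy * aperture_term_Sv_m2_per_p / r^2)
  }
  per_source <- per_source * 1e3  # Sv/Gy -> mSv/Gy
  structure(list(value_mSv_per_Gy = sum(per_source),
                 per_source_mSv_per_Gy = per_source,
                 distance_cm = distance_cm, angle_deg = angle_deg,
                 config = config$name,
                 field_diameter_cm = field_diameter_cm),
            class = "h_over_d")
}

#' @export
print.h_over_d <- function(x, ...) {
  cat(sprintf("<h_over_d> %s, %g cm @ %g deg, field %g cm: %.3g mSv/Gy\n",
              x$config, x$distance_cm, x$angle_deg, x$field_diameter_cm,
              x$value_mSv_per_Gy))
  invisible(x)
}

#' Map predicted H*/D over distances and angles
#'
#' Convenience wrapper calling [predict_h_over_d()] on the cross product
#' of survey distances and angles (the conventional grid is 20-150 cm and
#' 0/45/90/135 degrees).
#'
#' @inheritParams predict_h_over_d
#' @param distances_cm,angles_deg Numeric vectors defining the grid.
#' @return A data frame with one row per (distance, angle): columns
#'   `distance_cm`, `angle_deg`, `H_over_D_mSv_per_Gy` and one
#'   `mSv_per_Gy_<source>` column per contribution.
#' @export
h_over_d_map <- function(distances_cm, angles_deg, config, sources,
                         normalization, terms, ...) {
  grid <- expand.grid(distance_cm = distances_cm, angle_deg = angles_deg,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    h <- predict_h_over_d(grid$distance_cm[k], grid$angle_deg[k], config,
                          sources, normalization, terms, ...)
    per <- as.list(h$per_source_mSv_per_Gy)
    names(per) <- paste0("mSv_per_Gy_", names(per))
    cbind(data.frame(distance_cm = h$distance_cm, angle_deg = h$angle_deg,
                     H_over_D_mSv_per_Gy = h$value_mSv_per_Gy),
          as.data.frame(per))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
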