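#' Barrier slab
#'
#' A finite rectangular shielding wall, floor or door section. The slab is
#' described by its midplane: a center point, a unit normal, and two
#' orthogonal in-plane half-extent vectors spanning the rectangle.
#'
#' @param id Slab identifier.
#' @param center_m Midplane center, meters (isocenter origin).
#' @param normal Plane normal (normalized internally).
#' @param u_m,v_m In-plane half-extent vectors (meters): the rectangle is
#'   `center + a*u + b*v` for `a, b` in `[-1, 1]`. Must be orthogonal to
#'   the normal.
#' @param thickness_m Slab thickness along the normal, `> 0`.
#' @param material Material name keying an attenuation table (e.g.
#'   `"concrete"`).
#' @return Object of class `"barrier_slab"`.
#' @export
barrier_slab <- function(id, center_m, normal, u_m, v_m, thickness_m,
                         material = "concrete") {
  center_m <- check_point3(center_m, "center_m")
  normal <- unit_vector(check_point3(normal, "normal"), "normal")
  u_m <- check_point3(u_m, "u_m")
  v_m <- check_point3(v_m, "v_m")
  check_scalar(thickness_m, "thickness_m", positive = TRUE)
  if (abs(sum(normal * u_m)) > 1e-8 * sqrt(sum(u_m^2)) ||
      abs(sum(normal * v_m)) > 1e-8 * sqrt(sum(v_m^2))) {
    stop(sprintf("slab '%s': extent vectors must lie in the plane", id),
         call. = FALSE)
  }
  structure(list(id = as.character(id)[1], center_m = center_m,
                 normal = normal, u_m = u_m, v_m = v_m,
                 thickness_m = thickness_m,
                 material = as.character(material)[1]),
            class = "barrier_slab")
}

#' Point of interest beyond a barrier
#'
#' A location where the weekly and annual neutron ambient dose equivalent
#' is evaluated against an NCRP-style shielding design goal, weighted by
#' the occupancy factor of the most-exposed individual.
#'
#' @param id Point identifier (report rows are ordered by it).
#' @param position_m 3-vector, meters, isocenter origin.
#' @param occupancy Occupancy factor T in `[0, 1]`.
#' @param design_goal_mSv_per_yr Annual design goal, mSv, `> 0`
#'   (typically 5 for controlled, 1 for uncontrolled areas).
#' @param area_class `"controlled"` or `"uncontrolled"`.
#' @return Object of class `"point_of_interest"`.
#' @export
point_of_interest <- function(id, position_m, occupancy,
                              design_goal_mSv_per_yr,
                              area_class = c("uncontrolled", "controlled")) {
  position_m <- check_point3(position_m, "position_m")
  check_unit_interval(occupancy, "occupancy")
  check_scalar(design_goal_mSv_per_yr, "design_goal_mSv_per_yr",
               positive = TRUE)
  area_class <- match.arg(area_class)
  structure(list(id = as.character(id)[1], position_m = position_m,
                 occupancy = occupancy,
                 design_goal_mSv_per_yr = design_goal_mSv_per_yr,
                 area_class = area_class),
            class = "point_of_interest")
}

#' Attenuation-length table
#'
#' Per-material, per-source neutron attenuation lengths lambda(theta) in
#' meters, binned on the same 18 ten-degree polar-angle grid as the source
#' terms: the spectrum emitted toward theta hardens or softens with angle,
#' so the effective attenuation length is source- and angle-specific.
#'
#' @param material Material name.
#' @param lambda_m 18 x 3 numeric matrix (or data frame), columns named
#'   `cyclotron`, `nozzle`, `phantom`, all entries `> 0` (meters).
#' @return Object of class `"attenuation_table"`.
#' @seealso [read_attenuation_tables()] for the packaged synthetic
#'   concrete example.
#' @export
attenuation_table <- function(material, lambda_m) {
  lambda_m <- as.matrix(lambda_m)
  if (!all(SOURCE_IDS %in% colnames(lambda_m)) ||
      nrow(lambda_m) != N_ANGLE_BINS) {
    stop("`lambda_m` must be 18 rows with columns cyclotron, nozzle, phantom",
         call. = FALSE)
  }
  lambda_m <- lambda_m[, SOURCE_IDS, drop = FALSE]
  storage.mode(lambda_m) <- "double"
  if (any(!is.finite(lambda_m)) || any(lambda_m <= 0)) {
    stop("all attenuation lengths must be positive", call. = FALSE)
  }
  structure(list(material = as.character(material)[1], lambda_m = lambda_m),
            class = "attenuation_table")
}

#' Read attenuation-length tables
#'
#' Reads a long-format CSV with columns `material`, `angle_bin_lo`,
#' `angle_bin_hi`, `cyclotron`, `nozzle`, `phantom` (lambda in meters)
#' into a named list of [attenuation_table()] objects, one per material.
#' With no argument, loads the packaged synthetic concrete example — a
#' smooth, forward-hardened profile intended for examples and tests, not a
#' measured data set.
#'
#' @param path CSV file path.
#' @return Named list of [attenuation_table()] objects.
#' @export
read_attenuation_tables <- function(path = nv_extdata("attenuation_concrete_synthetic.csv")) {
  df <- utils::read.csv(path)
  need <- c("material", "angle_bin_lo", "angle_bin_hi", SOURCE_IDS)
  if (!all(need %in% names(df))) {
    stop(sprintf("attenuation table '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(split(df, df$material), function(d) {
    d <- d[order(d$angle_bin_lo), ]
    attenuation_table(d$material[1],
                      as.matrix(d[, SOURCE_IDS]))
  })
  out
}

# lambda (m) for a material/source at polar angle theta
attenuation_length_at <- function(tables, material, source_id, theta_deg) {
  tab <- tables[[material]]
  if (is.null(tab)) {
    stop(sprintf(
      "no attenuation lengths for material '%s' (needed for source '%s')",
      material, source_id), call. = FALSE)
  }
  tab$lambda_m[angle_bin_index(theta_deg), source_id]
}

#' Slant paths of a ray through barrier slabs
#'
#' Intersects the straight segment from a source position to a point of
#' interest with each slab midplane and reports, for every slab actually
#' crossed within its rectangular extent, the material, the slant
#' thickness and the incidence angle. The slant thickness is
#' `thickness / cos(phi)` for incidence angle `phi` between ray and slab
#' normal, capped at `phi = 70` degrees: line-of-sight attenuation models
#' are not credible at grazing incidence, so the path length is not allowed
#' to grow beyond `thickness / cos(70)`.
#'
#' @param source_pos_m Source position, meters.
#' @param poi A [point_of_interest()] (or bare 3-vector position).
#' @param barriers List of [barrier_slab()] objects.
#' @param max_obliquity_deg Obliquity cap, degrees (default 70).
#' @return A data frame with columns `slab_id`, `material`,
#'   `slant_thickness_m`, `incidence_deg`; zero rows if no slab is crossed.
#' @export
path_through_barriers <- function(source_pos_m, poi, barriers,
                                  max_obliquity_deg = 70) {
  source_pos_m <- check_point3(source_pos_m, "source_pos_m")
  target <- if (inherits(poi, "point_of_interest")) poi$position_m
            else check_point3(poi, "poi")
  d <- target - source_pos_m
  len <- sqrt(sum(d^2))
  if (len < 1e-12) {
    stop("degenerate ray: source and point of interest coincide",
         call. = FALSE)
  }
  dir <- d / len
  out <- lapply(barriers, function(slab) {
    denom <- sum(slab$normal * d)
    if (abs(denom) < 1e-12 * len) return(NULL)  # ray parallel to slab
    t <- sum(slab$normal * (slab$center_m - source_pos_m)) / denom
    if (t <= 0 || t >= 1) return(NULL)          # crossing not between ends
    q <- source_pos_m + t * d - slab$center_m
    for (ax in list(slab$u_m, slab$v_m)) {
      if (abs(sum(q * ax)) > sum(ax * ax) * (1 + 1e-12)) return(NULL)
    }
    cos_phi <- abs(sum(dir * slab$normal))
    phi <- acos(min(1, cos_phi)) * 180 / pi
    cos_eff <- max(cos_phi, cospi(max_obliquity_deg / 180))
    data.frame(slab_id = slab$id, material = slab$material,
               slant_thickness_m = slab$thickness_m / cos_eff,
               incidence_deg = phi)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(slab_id = character(), material = character(),
                      slant_thickness_m = numeric(),
                      incidence_deg = numeric())
  }
  out
}

#' Clinical weekly workload
#'
#' Weekly therapeutic dose delivered to isocenter: patients per day times
#' dose per fraction, multiplied by a QA factor (equivalent
#' machine-QA beams delivered on top of treatments), times treatment days
#' per week. The default schedule — 20 patients at 2 Gy with matching QA
#' over a 5-day week — gives the conventional 400 Gy/wk design workload.
#'
#' @param patients_per_day Treated patients per day.
#' @param dose_per_fraction_Gy Dose per fraction, Gy.
#' @param qa_factor Multiplier for QA beams (2 = one QA beam per
#'   treatment beam).
#' @param days_per_week Treatment days per week.
#' @return Workload in Gy/wk.
#' @examples
#' weekly_workload()  # 400
#' @export
weekly_workload <- function(patients_per_day = 20, dose_per_fraction_Gy = 2,
                            qa_factor = 2, days_per_week = 5) {
  check_scalar(patients_per_day, "patients_per_day", positive = TRUE)
  check_scalar(dose_per_fraction_Gy, "dose_per_fraction_Gy", positive = TRUE)
  check_scalar(qa_factor, "qa_factor", positive = TRUE)
  check_scalar(days_per_week, "days_per_week", positive = TRUE)
  patients_per_day * dose_per_fraction_Gy * qa_factor * days_per_week
}

#' Weekly ambient dose equivalent at a point of interest
#'
#' The three-source line-of-sight barrier model. For each neutron source x
#' at the given gantry angle,
#' `H = W * T * sum_x N_x * H*(theta_x) / r_x^2 * exp(-sum_slabs d / lambda_x(theta_x))`
#' where `W` is the weekly workload (Gy/wk), `T` the occupancy factor,
#' `N_x` the protons interacting in source x per Gy ([protons_per_gray()]),
#' `H*(theta_x)` the angular source term (Sv m^2/p) at the polar angle
#' between the beam direction at x and the ray from x to the point,
#' `r_x` the source-to-point distance (m), and `d` the slant thickness of
#' each slab crossed ([path_through_barriers()]). By default the
#' attenuation length is looked up at the same source-term angle
#' `theta_x`; set `lambda_angle = "incidence"` to use each slab's
#' incidence angle instead.
#'
#' @param poi A [point_of_interest()].
#' @param gantry_angle_deg Gantry angle, degrees.
#' @param workload_Gy_per_wk Weekly workload W, Gy/wk, `> 0`.
#' @param sources Named list of [neutron_source_spec()] (any subset of the
#'   three sources).
#' @param normalization A [beam_normalization()].
#' @param terms Named list of [angular_source_term()] matching `sources`.
#' @param barriers List of [barrier_slab()] (may be empty).
#' @param attenuation Named list of [attenuation_table()] per material
#'   (required only when a barrier is crossed).
#' @param weeks_per_year Weeks of operation per year for the annual figure
#'   (default 50).
#' @param lambda_angle `"source"` (default) or `"incidence"`.
#' @param loss_method Passed to [protons_per_gray()].
#' @return Object of class `"dose_result"`: a list with `poi_id`,
#'   `gantry_angle_deg`, `per_source_mSv_per_wk` (named vector),
#'   `total_mSv_per_wk`, `annual_mSv`, `design_goal_mSv_per_yr`,
#'   `margin_mSv`, `verdict` (`"pass"`/`"fail"`), and `minimal` (annual
#'   below 0.001 mSv).
#' @export
weekly_dose <- function(poi, gantry_angle_deg, workload_Gy_per_wk,
                        sources, normalization, terms,
                        barriers = list(), attenuation = list(),
                        weeks_per_year = 50,
                        lambda_angle = c("source", "incidence"),
                        loss_method = "back_propagate") {
  stopifnot(inherits(poi, "point_of_interest"),
            inherits(normalization, "beam_normalization"))
  check_scalar(workload_Gy_per_wk, "workload_Gy_per_wk", positive = TRUE)
  lambda_angle <- match.arg(lambda_angle)
  if (!length(sources) || is.null(names(sources))) {
    stop("`sources` must be a named list of neutron_source_spec objects",
         call. = FALSE)
  }
  per_source <- vapply(names(sources), function(sid) {
    spec <- sources[[sid]]
    term <- terms[[sid]]
    if (is.null(term)) {
      stop(sprintf("no angular source term supplied for source '%s'", sid),
           call. = FALSE)
    }
    pos <- source_position(spec, gantry_angle_deg)
    ray <- poi$position_m - pos
    r <- sqrt(sum(ray^2))
    if (r < 1e-9) {
      stop(sprintf("point '%s' coincides with source '%s'", poi$id, sid),
           call. = FALSE)
    }
    theta <- angle_between_deg(beam_direction(spec, gantry_angle_deg), ray)
    hstar <- source_term_at_angle(term, theta)
    n_gy <- protons_per_gray(spec, normalization, method = loss_method)
    transmission <- 1
    if (length(barriers)) {
      path <- path_through_barriers(pos, poi, barriers)
      if (nrow(path)) {
        lam <- vapply(seq_len(nrow(path)), function(k) {
          ang <- if (lambda_angle == "source") theta
                 else path$incidence_deg[k]
          attenuation_length_at(attenuation, path$material[k], sid, ang)
        }, numeric(1))
        transmission <- exp(-sum(path$slant_thickness_m / lam))
      }
    }
    workload_Gy_per_wk * poi$occupancy * n_gy * hstar / r^2 * transmission
  }, numeric(1))
  per_source_mSv <- per_source * 1e3  # Sv/wk -> mSv/wk
  total <- sum(per_source_mSv)
  annual <- annual_dose(total, weeks_per_year)
  structure(list(
    poi_id = poi$id,
    gantry_angle_deg = gantry_angle_deg,
    per_source_mSv_per_wk = per_source_mSv,
    total_mSv_per_wk = total,
    annual_mSv = annual$value,
    design_goal_mSv_per_yr = poi$design_goal_mSv_per_yr,
    margin_mSv = poi$design_goal_mSv_per_yr - annual$value,
    verdict = if (annual$value <= poi$design_goal_mSv_per_yr)
      "pass" else "fail",
    minimal = annual$minimal),
    class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result> %s @ gantry %g deg: %.3g mSv/wk (%.3g mSv/yr%s) — %s vs goal %g mSv\n",
              x$poi_id, x$gantry_angle_deg, x$total_mSv_per_wk,
              x$annual_mSv, if (x$minimal) ", minimal" else "",
              toupper(x$verdict), x$design_goal_mSv_per_yr))
  invisible(x)
}

#' Annualize a weekly dose
#'
#' Multiplies a weekly dose by the operating weeks per year (default 50).
#' Annual values below 0.001 mSv are flagged `"minimal"`: at that level
#' the figure is below what a shielding survey can resolve and reports
#' print it as such rather than as a number.
#'
#' @param weekly_mSv Weekly dose, mSv, `>= 0`.
#' @param weeks_per_year Operating weeks per year, `> 0`.
#' @param minimal_threshold_mSv Annual level below which the result is
#'   flagged minimal (default 0.001 mSv).
#' @return A list with `value` (mSv/yr) and `minimal` (logical).
#' @export
annual_dose <- function(weekly_mSv, weeks_per_year = 50,
                        minimal_threshold_mSv = 0.001) {
  check_scalar(weekly_mSv, "weekly_mSv", nonnegative = TRUE)
  check_scalar(weeks_per_year, "weeks_per_year", positive = TRUE)
  value <- weekly_mSv * weeks_per_year
  list(value = value, minimal = value < minimal_threshold_mSv)
}

#' Worst-case gantry angle for a point of interest
#'
#' Evaluates [weekly_dose()] at every candidate gantry angle and returns
#' the maximizer, for a conservative shielding estimate: with the
#' cyclotron mounted on the gantry, the source positions — and hence both
#' the distances and the source-term angles — change with gantry rotation.
#' Ties go to the smallest angle.
#'
#' @param poi A [point_of_interest()].
#' @param candidate_angles_deg Nonempty numeric vector of gantry angles.
#' @param ... Remaining arguments passed to [weekly_dose()].
#' @return A list with `gantry_angle_deg` and `result` (the
#'   `dose_result` at that angle).
#' @export
worst_case_gantry_angle <- function(poi, candidate_angles_deg, ...) {
  if (!length(candidate_angles_deg)) {
    stop("`candidate_angles_deg` must be nonempty", call. = FALSE)
  }
  candidate_angles_deg <- sort(unique(as.numeric(candidate_angles_deg)))
  results <- lapply(candidate_angles_deg, function(g) {
    weekly_dose(poi, gantry_angle_deg = g, ...)
  })
  totals <- vapply(results, `[[`, numeric(1), "total_mSv_per_wk")
  best <- which.max(totals)  # first max -> smallest angle on ties
  list(gantry_angle_deg = candidate_angles_deg[best],
       result = results[[best]])
}

#' Vault-wide compliance report
#'
#' Runs the worst-case gantry-angle search for every point of interest in
#' a vault and tabulates annual dose, design goal and verdict, one row per
#' point, ordered by point id.
#'
#' @param vault A `vault_geometry` (see [vault_geometry()]): barriers and
#'   points of interest.
#' @param sources,normalization,terms,attenuation See [weekly_dose()].
#' @param workload_Gy_per_wk Weekly workload, Gy/wk.
#' @param candidate_angles_deg Gantry-angle grid searched per point
#'   (default `c(0, 90, 180, 270)`).
#' @param weeks_per_year Operating weeks per year.
#' @param ... Passed on to [weekly_dose()].
#' @return A data frame of class `"compliance_report"` with one row per
#'   point: `poi_id`, `gantry_angle_deg`, `occupancy`,
#'   per-source weekly columns (`mSv_per_wk_<source>`),
#'   `total_mSv_per_wk`, `annual_mSv`, `minimal`,
#'   `design_goal_mSv_per_yr`, `margin_mSv`, `verdict`.
#' @export
compliance_report <- function(vault, sources, normalization, terms,
                              workload_Gy_per_wk,
                              attenuation = list(),
                              candidate_angles_deg = c(0, 90, 180, 270),
                              weeks_per_year = 50, ...) {
  stopifnot(inherits(vault, "vault_geometry"))
  pois <- vault$pois[order(vapply(vault$pois, `[[`, character(1), "id"))]
  rows <- lapply(pois, function(poi) {
    worst <- worst_case_gantry_angle(
      poi, candidate_angles_deg,
      workload_Gy_per_wk = workload_Gy_per_wk, sources = sources,
      normalization = normalization, terms = terms,
      barriers = vault$barriers, attenuation = attenuation,
      weeks_per_year = weeks_per_year, ...)
    res <- worst$result
    per <- as.list(res$per_source_mSv_per_wk)
    names(per) <- paste0("mSv_per_wk_", names(per))
    cbind(data.frame(poi_id = res$poi_id,
                     gantry_angle_deg = res$gantry_angle_deg,
                     occupancy = poi$occupancy),
          as.data.frame(per),
          data.frame(total_mSv_per_wk = res$total_mSv_per_wk,
                     annual_mSv = res$annual_mSv,
                     minimal = res$minimal,
                     design_goal_mSv_per_yr = res$design_goal_mSv_per_yr,
                     margin_mSv = res$margin_mSv,
                     verdict = res$verdict))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("compliance_report", "data.frame")
  out
}
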