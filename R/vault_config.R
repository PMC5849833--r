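#' Vault geometry
#'
#' Container for the structural side of an assessment: the barrier slabs
#' and the points of interest beyond them.
#'
#' @param barriers List of [barrier_slab()] objects.
#' @param pois List of [point_of_interest()] objects with distinct ids.
#' @return Object of class `"vault_geometry"`.
#' @export
vault_geometry <- function(barriers, pois) {
  if (!all(vapply(barriers, inherits, logical(1), "barrier_slab"))) {
    stop("`barriers` must be a list of barrier_slab objects", call. = FALSE)
  }
  if (!length(pois) ||
      !all(vapply(pois, inherits, logical(1), "point_of_interest"))) {
    stop("`pois` must be a nonempty list of point_of_interest objects",
         call. = FALSE)
  }
  ids <- vapply(pois, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate point-of-interest id '%s'",
                 ids[duplicated(ids)][1]), call. = FALSE)
  }
  structure(list(barriers = barriers, pois = pois),
            class = "vault_geometry")
}

#' Assessment configuration
#'
#' Bundles everything a shielding assessment needs: the vault geometry,
#' the three neutron sources, the beam normalization, the weekly workload,
#' operating weeks per year and the gantry-angle search grid. Serialized
#' to/from YAML by [write_vault_config()] / [read_vault_config()], with
#' units embedded in key names.
#'
#' @param geometry A [vault_geometry()].
#' @param sources Named list of [neutron_source_spec()].
#' @param normalization A [beam_normalization()].
#' @param workload_Gy_per_wk Weekly workload, Gy/wk, `> 0`.
#' @param weeks_per_year Operating weeks per year, `> 0`.
#' @param gantry_angles_deg Candidate gantry angles, degrees.
#' @return Object of class `"vault_config"`.
#' @export
vault_config <- function(geometry, sources, normalization,
                         workload_Gy_per_wk = weekly_workload(),
                         weeks_per_year = 50,
                         gantry_angles_deg = c(0, 90, 180, 270)) {
  stopifnot(inherits(geometry, "vault_geometry"),
            inherits(normalization, "beam_normalization"))
  if (!length(sources) || is.null(names(sources)) ||
      !all(vapply(sources, inherits, logical(1), "neutron_source_spec"))) {
    stop("`sources` must be a named list of neutron_source_spec objects",
         call. = FALSE)
  }
  check_scalar(workload_Gy_per_wk, "workload_Gy_per_wk", positive = TRUE)
  check_scalar(weeks_per_year, "weeks_per_year", positive = TRUE)
  if (!length(gantry_angles_deg) || anyNA(gantry_angles_deg)) {
    stop("`gantry_angles_deg` must be a nonempty numeric vector",
         call. = FALSE)
  }
  structure(list(geometry = geometry, sources = sources,
                 normalization = normalization,
                 workload_Gy_per_wk = workload_Gy_per_wk,
                 weeks_per_year = weeks_per_year,
                 gantry_angles_deg = as.numeric(gantry_angles_deg)),
            class = "vault_config")
}

#' @export
print.vault_config <- function(x, ...) {
  cat(sprintf(
    "<vault_config> %d barriers, %d points of interest, %d sources\n",
    length(x$geometry$barriers), length(x$geometry$pois),
    length(x$sources)))
  cat(sprintf("  workload %g Gy/wk x %g wk/yr; gantry angles: %s deg\n",
              x$workload_Gy_per_wk, x$weeks_per_year,
              paste(x$gantry_angles_deg, collapse = ", ")))
  invisible(x)
}

#' Write / read a vault configuration as YAML
#'
#' The YAML layout mirrors the object structure with explicit units in
#' key names (`thickness_m`, `design_goal_mSv_per_yr`, ...). Reading
#' re-runs every constructor, so a malformed file fails with an error
#' naming the offending field.
#'
#' @param config A [vault_config()].
#' @param path YAML file path.
#' @return `path` invisibly (write); a [vault_config()] (read).
#' @export
write_vault_config <- function(config, path) {
  stopifnot(inherits(config, "vault_config"))
  x <- list(
    workload_Gy_per_wk = config$workload_Gy_per_wk,
    weeks_per_year = config$weeks_per_year,
    gantry_angles_deg = as.list(config$gantry_angles_deg),
    normalization = list(
      protons_per_gray_at_isocenter =
        config$normalization$protons_per_gray_at_isocenter),
    sources = lapply(config$sources, function(s) {
      list(source_id = s$source_id,
           offset_from_isocenter_m = s$offset_from_isocenter_m,
           loss_fraction = s$loss_fraction,
           beam_axis_reference = as.list(s$beam_axis_reference))
    }),
    geometry = list(
      barriers = lapply(config$geometry$barriers, function(b) {
        list(id = b$id, center_m = as.list(b$center_m),
             normal = as.list(b$normal), u_m = as.list(b$u_m),
             v_m = as.list(b$v_m), thickness_m = b$thickness_m,
             material = b$material)
      }),
      pois = lapply(config$geometry$pois, function(p) {
        list(id = p$id, position_m = as.list(p$position_m),
             occupancy = p$occupancy,
             design_goal_mSv_per_yr = p$design_goal_mSv_per_yr,
             area_class = p$area_class)
      })))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

# fetch a required field from a parsed YAML node, with a schema-style error
cfg_field <- function(node, name, where) {
  if (is.null(node[[name]])) {
    stop(sprintf("config field `%s` missing in %s", name, where),
         call. = FALSE)
  }
  node[[name]]
}

#' @rdname write_vault_config
#' @export
read_vault_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("vault config file '%s' does not exist", path),
         call. = FALSE)
  }
  x <- yaml::read_yaml(path)
  geom <- cfg_field(x, "geometry", "config root")
  barriers <- lapply(geom$barriers, function(b) {
    barrier_slab(cfg_field(b, "id", "barrier"),
                 unlist(cfg_field(b, "center_m", "barrier")),
                 unlist(cfg_field(b, "normal", "barrier")),
                 unlist(cfg_field(b, "u_m", "barrier")),
                 unlist(cfg_field(b, "v_m", "barrier")),
                 cfg_field(b, "thickness_m", "barrier"),
                 cfg_field(b, "material", "barrier"))
  })
  pois <- lapply(cfg_field(geom, "pois", "geometry"), function(p) {
    point_of_interest(cfg_field(p, "id", "poi"),
                      unlist(cfg_field(p, "position_m", "poi")),
                      cfg_field(p, "occupancy", "poi"),
                      cfg_field(p, "design_goal_mSv_per_yr", "poi"),
                      cfg_field(p, "area_class", "poi"))
  })
  sources <- lapply(cfg_field(x, "sources", "config root"), function(s) {
    neutron_source_spec(cfg_field(s, "source_id", "source"),
                        cfg_field(s, "offset_from_isocenter_m", "source"),
                        cfg_field(s, "loss_fraction", "source"),
                        unlist(cfg_field(s, "beam_axis_reference",
                                         "source")))
  })
  norm <- beam_normalization(
    cfg_field(cfg_field(x, "normalization", "config root"),
              "protons_per_gray_at_isocenter", "normalization"))
  vault_config(
    geometry = vault_geometry(barriers, pois),
    sources = sources,
    normalization = norm,
    workload_Gy_per_wk = cfg_field(x, "workload_Gy_per_wk", "config root"),
    weeks_per_year = cfg_field(x, "weeks_per_year", "config root"),
    gantry_angles_deg = unlist(cfg_field(x, "gantry_angles_deg",
                                         "config root")))
}
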