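#' Run a full shielding assessment
#'
#' End-to-end driver behind the `assess` command line: parses (or accepts)
#' a vault configuration, loads source-term and attenuation tables, runs
#' the worst-case gantry-angle compliance search for every point of
#' interest, and writes the report. Outputs are deterministic for
#' deterministic inputs: rerunning on the same files reproduces the report
#' byte for byte.
#'
#' @param config A [vault_config()] object or the path to its YAML file.
#' @param out_csv Optional path for the CSV report (3-significant-digit
#'   scientific notation, units in column headers).
#' @param out_json Optional path for a JSON report with full-precision
#'   values.
#' @param source_terms_csv Path to the angular source-term table (default:
#'   the packaged Mevion S250 table).
#' @param attenuation_csv Path to the attenuation-length table (default:
#'   the packaged synthetic concrete example).
#' @param workload_Gy_per_wk,weeks_per_year,gantry_angles_deg Optional
#'   overrides of the corresponding config entries.
#' @param verbose Log every per-source contribution to stderr.
#' @param ... Passed on to [weekly_dose()] (e.g. `lambda_angle`,
#'   `loss_method`).
#' @return Invisibly, a list with `report` (the [compliance_report()]
#'   data frame), `all_pass` (logical) and `status` (0 if every point
#'   passes, 1 otherwise — the `assess` CLI exit code).
#' @export
run_assessment <- function(config, out_csv = NULL, out_json = NULL,
                           source_terms_csv = NULL, attenuation_csv = NULL,
                           workload_Gy_per_wk = NULL, weeks_per_year = NULL,
                           gantry_angles_deg = NULL, verbose = FALSE, ...) {
  if (is.character(config)) config <- read_vault_config(config)
  stopifnot(inherits(config, "vault_config"))
  terms <- if (is.null(source_terms_csv)) read_source_terms()
           else read_source_terms(source_terms_csv)
  attenuation <- if (is.null(attenuation_csv)) read_attenuation_tables()
                 else read_attenuation_tables(attenuation_csv)
  w <- if (is.null(workload_Gy_per_wk)) config$workload_Gy_per_wk
       else workload_Gy_per_wk
  wk <- if (is.null(weeks_per_year)) config$weeks_per_year
        else weeks_per_year
  angles <- if (is.null(gantry_angles_deg)) config$gantry_angles_deg
            else gantry_angles_deg
  report <- compliance_report(
    config$geometry, sources = config$sources,
    normalization = config$normalization, terms = terms,
    workload_Gy_per_wk = w, attenuation = attenuation,
    candidate_angles_deg = angles, weeks_per_year = wk, ...)
  if (verbose) {
    for (k in seq_len(nrow(report))) {
      message(sprintf(
        "%s @ gantry %g deg: %s -> %.3g mSv/yr (%s)",
        report$poi_id[k], report$gantry_angle_deg[k],
        paste(sprintf("%s %.3g", sub("mSv_per_wk_", "",
                                     grep("^mSv_per_wk_", names(report),
                                          value = TRUE)),
                      unlist(report[k, grep("^mSv_per_wk_", names(report))])),
              collapse = ", "),
        report$annual_mSv[k], report$verdict[k]))
    }
  }
  if (!is.null(out_csv)) write_report_csv(report, out_csv)
  if (!is.null(out_json)) write_report_json(report, out_json)
  all_pass <- all(report$verdict == "pass")
  invisible(list(report = report, all_pass = all_pass,
                 status = if (all_pass) 0L else 1L))
}

#' Write a compliance report
#'
#' CSV output renders every dose in scientific notation with 3
#' significant digits (the precision at which source-term tables are
#' published); annual values flagged minimal are additionally marked in
#' the `minimal` column. JSON output keeps full precision.
#'
#' @param report A [compliance_report()] data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(is.data.frame(report))
  out <- report
  num <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("gantry_angle_deg", "occupancy",
                        "design_goal_mSv_per_yr"))
  out[num] <- lapply(out[num], function(x) formatC(x, format = "e",
                                                   digits = 2))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
write_report_json <- function(report, path) {
  stopifnot(is.data.frame(report))
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
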