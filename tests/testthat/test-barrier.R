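# a 1 m thick concrete wall in the y = 3 plane, 10 m wide, 5 m tall
wall <- barrier_slab("wall", c(0, 3, 0), c(0, 1, 0),
                     u_m = c(5, 0, 0), v_m = c(0, 0, 2.5),
                     thickness_m = 1)

test_that("slant thickness follows 1/cos(incidence) with a 70-degree cap", {
  # normal incidence
  p <- path_through_barriers(c(0, 0, 0), c(0, 6, 0), list(wall))
  expect_equal(nrow(p), 1L)
  expect_equal(p$slant_thickness_m, 1)
  expect_equal(p$incidence_deg, 0)
  wide <- barrier_slab("wide", c(0, 3, 0), c(0, 1, 0), c(50, 0, 0),
                       c(0, 0, 2.5), 1)
  # 60 degrees of incidence: endpoint offset 6 * tan(60) doubles the path
  p60 <- path_through_barriers(c(0, 0, 0), c(6 * tanpi(60 / 180), 6, 0),
                               list(wide))
  expect_equal(p60$slant_thickness_m, 2, tolerance = 1e-9)
  expect_equal(p60$incidence_deg, 60, tolerance = 1e-9)
  # beyond the cap the path stops growing: 80 degrees uses cos(70)
  p80 <- path_through_barriers(c(0, 0, 0), c(6 * tanpi(80 / 180), 6, 0),
                               list(wide))
  expect_equal(p80$slant_thickness_m, 1 / cospi(70 / 180), tolerance = 1e-9)
  # a ray missing the bounded extent contributes nothing
  miss <- path_through_barriers(c(0, 0, 0), c(20, 6, 0), list(wall))
  expect_equal(nrow(miss), 0L)
  # ray parallel to the slab never crosses it
  par <- path_through_barriers(c(0, 0, 0), c(1, 0, 0), list(wall))
  expect_equal(nrow(par), 0L)
  expect_error(path_through_barriers(c(0, 0, 0), c(0, 0, 0), list(wall)),
               "degenerate")
})

test_that("weekly dose reproduces the closed-form single-source case", {
  src <- phantom_only()
  norm <- beam_normalization(1e10)
  terms <- list(phantom = flat_term(1e-15))
  poi <- point_of_interest("p1", c(0, 2, 0), occupancy = 1,
                           design_goal_mSv_per_yr = 5)
  res <- weekly_dose(poi, 0, workload_Gy_per_wk = 400, sources = src,
                     normalization = norm, terms = terms)
  # W T N H* / r^2 = 400 * 1 * 1e10 * 1e-15 / 4 = 1e-3 Sv/wk = 1 mSv/wk
  expect_equal(res$total_mSv_per_wk, 1, tolerance = 1e-12)
  expect_equal(res$annual_mSv, 50, tolerance = 1e-12)
  expect_identical(res$verdict, "fail")  # 50 mSv/yr >> 5 mSv goal

  # occupancy zero kills the dose regardless of geometry
  poi0 <- point_of_interest("p0", c(0, 2, 0), occupancy = 0,
                            design_goal_mSv_per_yr = 5)
  expect_equal(weekly_dose(poi0, 0, 400, src, norm,
                           terms)$total_mSv_per_wk, 0)
})

test_that("one half-value slab halves the unshielded dose", {
  src <- phantom_only()
  norm <- beam_normalization(1e10)
  terms <- list(phantom = flat_term(1e-15))
  poi <- point_of_interest("p1", c(0, 6, 0), occupancy = 1,
                           design_goal_mSv_per_yr = 5)
  lam <- 0.4
  half_wall <- barrier_slab("hv", c(0, 3, 0), c(0, 1, 0), c(5, 0, 0),
                            c(0, 0, 2.5), thickness_m = lam * log(2))
  att <- list(concrete = attenuation_table(
    "concrete", matrix(lam, 18, 3,
                       dimnames = list(NULL,
                                       c("cyclotron", "nozzle",
                                         "phantom")))))
  free <- weekly_dose(poi, 0, 400, src, norm, terms)
  shielded <- weekly_dose(poi, 0, 400, src, norm, terms,
                          barriers = list(half_wall), attenuation = att)
  expect_equal(free$total_mSv_per_wk / shielded$total_mSv_per_wk, 2,
               tolerance = 1e-9)
  # a missing material entry fails loudly, naming material and source
  expect_error(
    weekly_dose(poi, 0, 400, src, norm, terms,
                barriers = list(half_wall), attenuation = list()),
    "concrete.*phantom")
})

test_that("annualization multiplies by operating weeks and flags minimal", {
  z <- annual_dose(0)
  expect_equal(z$value, 0)
  expect_true(z$minimal)
  expect_equal(annual_dose(0.002, 50)$value, 0.1, tolerance = 1e-12)
  expect_false(annual_dose(0.002, 50)$minimal)
  tiny <- annual_dose(1e-5, 50)
  expect_equal(tiny$value, 5e-4, tolerance = 1e-12)
  expect_true(tiny$minimal)
  expect_error(annual_dose(-1), "weekly_mSv")
})

test_that("worst-case gantry search maximizes with smallest-angle ties", {
  terms <- read_source_terms()
  src <- default_sources()
  norm <- beam_normalization(1e11)
  poi <- point_of_interest("dn", c(0, 6, 0), occupancy = 1,
                           design_goal_mSv_per_yr = 5)
  args <- list(poi = poi, workload_Gy_per_wk = 400, sources = src,
               normalization = norm, terms = terms)
  single <- do.call(worst_case_gantry_angle,
                    c(list(candidate_angles_deg = 37), args))
  expect_equal(single$gantry_angle_deg, 37)
  # 90 and 270 are mirror-symmetric about the z = 0 plane holding the poi:
  # an exact tie resolved to the smaller angle
  tie <- do.call(worst_case_gantry_angle,
                 c(list(candidate_angles_deg = c(270, 90)), args))
  expect_equal(tie$gantry_angle_deg, 90)
  # downstream poi with forward-peaked terms: gantry 0 wins; equals the
  # brute-force maximum over the grid
  grid <- c(0, 90, 180, 270)
  best <- do.call(worst_case_gantry_angle,
                  c(list(candidate_angles_deg = grid), args))
  totals <- vapply(grid, function(g) {
    weekly_dose(poi, g, 400, src, norm, terms)$total_mSv_per_wk
  }, numeric(1))
  expect_equal(best$gantry_angle_deg, 0)
  expect_equal(best$result$total_mSv_per_wk, max(totals))
  expect_error(do.call(worst_case_gantry_angle,
                       c(list(candidate_angles_deg = numeric()), args)),
               "nonempty")
})

test_that("compliance report orders rows by id and renders verdicts", {
  terms <- read_source_terms()
  src <- default_sources()
  norm <- beam_normalization(1e11)
  # far point with goal 5 passes; unshielded point hugging the phantom
  # fails
  vault <- vault_geometry(
    barriers = list(),
    pois = list(
      point_of_interest("b_far", c(0, 12, 0), 0.25, 5),
      point_of_interest("a_near", c(0.5, 1, 0), 1, 1)))
  rep <- compliance_report(vault, src, norm, terms,
                           workload_Gy_per_wk = 400)
  expect_equal(rep$poi_id, c("a_near", "b_far"))  # deterministic order
  expect_identical(rep$verdict[rep$poi_id == "a_near"], "fail")
  expect_true(all(rep$total_mSv_per_wk ==
                    rep$mSv_per_wk_cyclotron + rep$mSv_per_wk_nozzle +
                    rep$mSv_per_wk_phantom))
  # all-zero occupancy: every row 0 and pass
  vault0 <- vault_geometry(
    barriers = list(),
    pois = list(point_of_interest("z1", c(0, 8, 0), 0, 1),
                point_of_interest("z2", c(8, 0, 0), 0, 1)))
  rep0 <- compliance_report(vault0, src, norm, terms,
                            workload_Gy_per_wk = 400)
  expect_true(all(rep0$annual_mSv == 0))
  expect_true(all(rep0$verdict == "pass"))
  expect_true(all(rep0$minimal))
})

test_that("dose scales linearly in workload, occupancy and normalization", {
  terms <- read_source_terms()
  src <- default_sources()
  poi <- point_of_interest("p", c(3, 4, 0), 0.25, 1)
  base <- weekly_dose(poi, 0, 400, src, beam_normalization(1e11), terms)
  dbl_w <- weekly_dose(poi, 0, 800, src, beam_normalization(1e11), terms)
  dbl_n <- weekly_dose(poi, 0, 400, src, beam_normalization(2e11), terms)
  poi2 <- point_of_interest("p", c(3, 4, 0), 0.5, 1)
  dbl_t <- weekly_dose(poi2, 0, 400, src, beam_normalization(1e11), terms)
  for (x in list(dbl_w, dbl_n, dbl_t)) {
    expect_equal(x$total_mSv_per_wk, 2 * base$total_mSv_per_wk,
                 tolerance = 1e-12)
  }
})

test_that("the default clinical schedule gives a 400 Gy/wk workload", {
  expect_equal(weekly_workload(), 400)
  expect_equal(weekly_workload(patients_per_day = 10), 200)
  expect_error(weekly_workload(days_per_week = 0), "days_per_week")
})
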