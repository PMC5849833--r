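terms <- read_source_terms()
src <- default_sources()
norm <- beam_normalization(1e11)
large <- beam_configuration("large")

test_that("measured H/D conversion divides rate by output times calibration", {
  expect_equal(h_over_d_from_measurement(0, 6000, 0.01), 0)
  expect_equal(h_over_d_from_measurement(3, 6000, 0.01), 0.05,
               tolerance = 1e-12)
  # doubling both rates leaves H/D unchanged
  expect_equal(h_over_d_from_measurement(6, 12000, 0.01),
               h_over_d_from_measurement(3, 6000, 0.01), tolerance = 1e-12)
  expect_error(h_over_d_from_measurement(3, 0, 0.01), "MUr")
  expect_error(h_over_d_from_measurement(3, 6000, 0), "c_Gy_per_MU")
  expect_error(h_over_d_from_measurement(-1, 6000, 0.01), "Hr")
})

test_that("aperture weight is the blocked-area fraction", {
  expect_equal(aperture_weight(26.5, large), 0)  # open field
  expect_equal(aperture_weight(0, large), 1)     # closed aperture
  fields <- seq(0, 26.5, by = 0.5)
  w <- vapply(fields, aperture_weight, numeric(1), config = large)
  expect_true(all(diff(w) < 0))  # strictly decreasing
  expect_true(all(w >= 0 & w <= 1))
  expect_error(aperture_weight(27, large), "exceeds")
  small <- beam_configuration("small")
  expect_error(aperture_weight(16, small), "exceeds")
})

test_that("beam configurations carry the standard option-group parameters", {
  expect_equal(large$range_cm, 25)
  expect_equal(large$modulation_width_cm, 20)
  expect_equal(large$max_field_diameter_cm, 26.5)
  deep <- beam_configuration("deep")
  expect_equal(c(deep$range_cm, deep$modulation_width_cm), c(30, 10))
  expect_equal(beam_configuration("small")$range_cm, 15)
  expect_error(beam_configuration("large", range_cm = 10,
                                  modulation_width_cm = 20),
               "modulation")
})

test_that("all-zero source terms predict zero H/D", {
  zeros <- list(cyclotron = flat_term(0, "cyclotron"),
                nozzle = flat_term(0, "nozzle"),
                phantom = flat_term(0, "phantom"))
  h <- predict_h_over_d(100, 45, large, src, norm, zeros)
  expect_equal(h$value_mSv_per_Gy, 0)
})

test_that("upstream sources contribute more at large angles (geometry oracle)", {
  h0 <- predict_h_over_d(100, 0, large, src, norm, terms)
  h135 <- predict_h_over_d(100, 135, large, src, norm, terms)
  # oracle: explicit distances from the two survey points to the upstream
  # sources (beam axis +y at gantry 0; cyclotron (0,-2,0), nozzle (0,-1,0))
  p0 <- c(0, 1, 0)
  p135 <- c(sinpi(135 / 180), cospi(135 / 180), 0)
  for (s_pos in list(c(0, -2, 0), c(0, -1, 0))) {
    expect_lt(sqrt(sum((p135 - s_pos)^2)), sqrt(sum((p0 - s_pos)^2)))
  }
  up <- c("cyclotron", "nozzle")
  expect_gt(sum(h135$per_source_mSv_per_Gy[up]),
            sum(h0$per_source_mSv_per_Gy[up]))
})

test_that("phantom-only H/D follows exact inverse square in distance", {
  ph_src <- phantom_only()
  ph_terms <- terms["phantom"]
  h40 <- predict_h_over_d(40, 90, large, ph_src, norm, ph_terms)
  h80 <- predict_h_over_d(80, 90, large, ph_src, norm, ph_terms)
  expect_equal(h40$value_mSv_per_Gy / h80$value_mSv_per_Gy, 4,
               tolerance = 1e-9)
  # monotone decreasing with distance at every measured angle
  for (a in c(0, 45, 90, 135)) {
    v <- vapply(c(20, 40, 60, 80, 100, 150), function(d) {
      predict_h_over_d(d, a, large, ph_src, norm, ph_terms)$value_mSv_per_Gy
    }, numeric(1))
    expect_true(all(diff(v) < 0))
  }
})

test_that("H/D is non-increasing in field diameter", {
  fields <- c(0, 8, 16, 20, 26.5)
  v <- vapply(fields, function(f) {
    predict_h_over_d(100, 90, large, src, norm, terms,
                     field_diameter_cm = f,
                     aperture_term_Sv_m2_per_p = 1e-15)$value_mSv_per_Gy
  }, numeric(1))
  expect_true(all(diff(v) <= 0))
  expect_true(v[1] > v[length(v)])  # strictly lower for the open field
  expect_error(
    predict_h_over_d(100, 90, large, src, norm, terms,
                     field_diameter_cm = 30), "exceeds")
})

test_that("aperture contribution sits at the nozzle and scales with weight", {
  open <- predict_h_over_d(100, 90, large, src, norm, terms,
                           field_diameter_cm = 26.5,
                           aperture_term_Sv_m2_per_p = 1e-15)
  expect_false("aperture" %in% names(open$per_source_mSv_per_Gy))
  closed <- predict_h_over_d(100, 90, large, src, norm, terms,
                             field_diameter_cm = 0,
                             aperture_term_Sv_m2_per_p = 1e-15)
  ap <- closed$per_source_mSv_per_Gy[["aperture"]]
  # hand value: w=1, N_nozzle * S / r^2, r = |(0,1,0)/... point (1,0,0) to
  # nozzle (0,-1,0)| = sqrt(2)
  n_noz <- protons_per_gray(src$nozzle, norm)
  expect_equal(ap, 1 * n_noz * 1e-15 / 2 * 1e3, tolerance = 1e-9)
})

test_that("the survey map covers the distance-angle grid", {
  map <- h_over_d_map(c(50, 100), c(0, 90), large, src, norm, terms)
  expect_equal(nrow(map), 4L)
  expect_true(all(c("distance_cm", "angle_deg", "H_over_D_mSv_per_Gy",
                    "mSv_per_Gy_phantom") %in% names(map)))
  expect_equal(map$H_over_D_mSv_per_Gy,
               map$mSv_per_Gy_cyclotron + map$mSv_per_Gy_nozzle +
                 map$mSv_per_Gy_phantom, tolerance = 1e-12)
})
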