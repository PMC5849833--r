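test_that("empty tally gives an all-zero spectrum", {
  sp <- score_fluence(crossing_records(), n_protons = 100)
  expect_identical(dim(sp$values), c(18L, 250L))
  expect_true(all(sp$values == 0))
})

test_that("a single crossing lands in its bin with zone-area normalization", {
  sp <- score_fluence(crossing_records(5.5, 12), n_protons = 1, radius = 1)
  # hand-computed spherical-zone area of [10, 20): 2*pi*(cos10 - cos20)
  expected <- 1 / (2 * pi * (cospi(10 / 180) - cospi(20 / 180)))
  expect_equal(sp$values[2, 6], expected, tolerance = 1e-12)
  expect_equal(expected, 3.5278, tolerance = 1e-4)
  expect_equal(sum(sp$values > 0), 1L)
})

test_that("bin edges follow half-open convention with 180 folded in", {
  sp <- score_fluence(
    crossing_records(c(0, 9.999, 10, 249.5, 100), c(0, 9.99, 10, 180, 170)),
    n_protons = 1)
  expect_true(sp$values[1, 1] > 0)      # theta 0, E 0 -> first bin
  expect_true(sp$values[1, 10] > 0)     # theta 9.99 still first angle bin
  expect_true(sp$values[2, 11] > 0)     # theta 10 -> second angle bin
  expect_true(sp$values[18, 250] > 0)   # theta 180 folds into last bin
  expect_true(sp$values[18, 101] > 0)
})

test_that("tally conserves total weight and matches the brute-force oracle", {
  for (seed in c(11, 12, 13)) {
    cr <- random_crossings(500, seed, weights = TRUE)
    n_p <- 137
    sp <- score_fluence(cr, n_protons = n_p)
    # conservation: values * areas * n_protons recovers the input weight
    areas <- 2 * pi * (cospi(seq(0, 170, 10) / 180) -
                         cospi(seq(10, 180, 10) / 180))
    expect_equal(sum(sp$values * areas) * n_p, sum(cr$weight),
                 tolerance = 1e-9)
    oracle <- brute_force_fluence(cr$energy_MeV, cr$theta_deg, cr$weight,
                                  n_p)
    expect_equal(sp$values, oracle, tolerance = 1e-12)
  }
})

test_that("invalid records and proton counts are rejected by name", {
  expect_error(crossing_records(250, 10), "energy 250")
  expect_error(crossing_records(-1, 10), "energy -1")
  expect_error(crossing_records(10, 180.5), "angle 180.5")
  expect_error(crossing_records(c(5, 6), c(10, 200)), "record 2")
  expect_error(score_fluence(crossing_records(), n_protons = 0),
               "n_protons")
  expect_error(score_fluence(crossing_records(), n_protons = -5),
               "n_protons")
})

test_that("coefficient interpolation is log-log with flat extrapolation", {
  tab <- conversion_table(c(0.01, 0.1, 1, 10, 100), c(10, 90, 400, 440, 285))
  # grid-point identity
  expect_identical(interpolate_coefficient(tab, 1), 400)
  # geometric-mean midpoint: E = sqrt(0.1 * 1) -> sqrt(90 * 400)
  expect_equal(interpolate_coefficient(tab, sqrt(0.1 * 1)),
               sqrt(90 * 400), tolerance = 1e-12)
  # flat beyond both ends
  expect_equal(interpolate_coefficient(tab, 250), 285)
  expect_equal(interpolate_coefficient(tab, 1e-6), 10)
  expect_error(interpolate_coefficient(tab, 0), "positive")
  expect_error(interpolate_coefficient(tab, -3), "positive")
})

test_that("packaged conversion table loads and spans the scoring range", {
  tab <- read_conversion_table()
  expect_s3_class(tab, "conversion_table")
  expect_true(all(diff(tab$energies_MeV) > 0))
  expect_true(all(tab$coefficients_pSv_cm2 >= 0))
  # flat-extrapolation policy covers [1e-8, 250] MeV
  expect_true(is.finite(interpolate_coefficient(tab, 1e-8)))
  expect_true(is.finite(interpolate_coefficient(tab, 250)))
  rt <- withr::local_tempfile(fileext = ".csv")
  write_conversion_table(tab, rt)
  expect_equal(read_conversion_table(rt), tab, tolerance = 1e-12)
})

test_that("spectrum-to-source-term applies the pSv cm2 -> Sv m2 conversion", {
  tab <- conversion_table(c(1e-8, 250), c(100, 100))  # constant f = 100
  sp <- score_fluence(crossing_records(), n_protons = 1)
  zero <- spectrum_to_source_term(sp, tab)
  expect_true(all(zero$values == 0))

  sp$values[4, 17] <- 1  # 1 m^-2 per proton in one bin
  term <- spectrum_to_source_term(sp, tab)
  expect_equal(term$values[4], 1 * 100 * 1e-16, tolerance = 1e-15)
  expect_true(all(term$values[-4] == 0))

  sp2 <- sp
  sp2$values <- 2 * sp$values
  expect_equal(spectrum_to_source_term(sp2, tab)$values, 2 * term$values)
})

test_that("spectrum conversion rejects wrong radius or shape", {
  tab <- read_conversion_table()
  sp <- score_fluence(crossing_records(), n_protons = 1, radius = 2)
  expect_error(spectrum_to_source_term(sp, tab), "radius 1 m")
  sp1 <- score_fluence(crossing_records(), n_protons = 1)
  sp1$values <- sp1$values[, 1:100]
  expect_error(spectrum_to_source_term(sp1, tab), "18 angle bins")
})

test_that("fluence spectra round-trip through CSV and JSON", {
  cr <- random_crossings(200, 77)
  sp <- score_fluence(cr, n_protons = 50)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_fluence_spectrum(sp, csv)
  write_fluence_spectrum(sp, js)
  expect_equal(read_fluence_spectrum(csv)$values, sp$values,
               tolerance = 1e-12)
  got <- read_fluence_spectrum(js)
  expect_equal(got$values, sp$values, tolerance = 1e-12)
  expect_equal(got$n_protons, 50)
})
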