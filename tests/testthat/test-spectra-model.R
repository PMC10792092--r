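test_that("wavenumber scaling evaluates the linear ratio correction", {
  expect_equal(scale_wavenumber(1000, scaling_model(a = 0, b = 1)), 1000)
  # direct arithmetic with the default coefficients
  expect_equal(scale_wavenumber(1000),
               1000 * (-0.0000083526 * 1000 + 0.98134))
  expect_equal(scale_wavenumber(1000), 972.9874)
  # limit toward zero from above
  expect_lt(scale_wavenumber(1e-9), 1e-8)
  expect_error(scale_wavenumber(-5), "> 0")
  expect_error(scaling_model(a = -1, b = 0.5), "positive")
})

test_that("scaling with the default coefficients is strictly increasing", {
  nu <- seq(0.5, 4000, by = 0.5)
  out <- scale_wavenumber(nu)
  expect_true(all(diff(out) > 0))
})

test_that("intensity conversion matches its scalar pieces", {
  # thermal factor alone at 1000 cm-1, room temperature
  p <- intensity_params(temperature = 298.15, c2 = 1.4388)
  thermal <- 1 - exp(-1.4388 * 1000 / 298.15)
  expect_equal(thermal, 1 - exp(-4.825759), tolerance = 1e-6)
  got <- activity_to_intensity(1000, 1, p)
  expect_equal(got, (p$nu0 - 1000)^4 / (1000 * thermal))
  # zero activity maps to zero; linearity in activity and in f
  expect_equal(activity_to_intensity(1000, 0, p), 0)
  p2 <- intensity_params(f = 2)
  p1 <- intensity_params(f = 1)
  expect_equal(activity_to_intensity(800, 0.3, p2),
               2 * activity_to_intensity(800, 0.3, p1))
  expect_error(activity_to_intensity(2e4, 1, p), "nu0")
  expect_error(activity_to_intensity(-1, 1, p), "> 0")
})

test_that("intensity conversion agrees with a brute-force oracle", {
  set.seed(11)
  n <- 2000L
  nu0 <- runif(n, 5000, 30000)
  nu <- runif(n, 100, 4000)
  A <- runif(n, 0, 10)
  temp <- runif(n, 50, 600)
  f <- runif(n, 0.1, 5)
  for (i in seq_len(n)) {
    p <- intensity_params(nu0[i], temp[i], f[i])
    expect_equal(activity_to_intensity(nu[i], A[i], p),
                 oracle_intensity(nu0[i], nu[i], A[i], temp[i], f[i],
                                  p$c2),
                 tolerance = 1e-12)
  }
})

test_that("low-temperature limit removes the thermal factor", {
  p <- intensity_params(temperature = 1e-6, f = 1)
  nu <- c(400, 1000, 1800)
  expect_equal(activity_to_intensity(nu, 1, p),
               (p$nu0 - nu)^4 / nu, tolerance = 1e-9)
})

test_that("Lorentzian synthesis obeys height and FWHM identities", {
  tbl <- mode_table(1L, 1000, 2.5)
  shape <- lineshape_params(fwhm = 5, grid_min = 900, grid_max = 1100,
                            grid_step = 0.5)
  s <- fixture_spectrum(tbl, shape)
  at <- function(w) s$intensity[which(s$wavenumber == w)]
  expect_equal(at(1000), 2.5)               # peak height
  expect_equal(at(997.5), 2.5 / 2)          # half height at center - fwhm/2
  expect_equal(at(1002.5), 2.5 / 2)
})

test_that("synthesis is additive over modes and permutation-invariant", {
  shape <- lineshape_params(fwhm = 5, grid_min = 950, grid_max = 1060,
                            grid_step = 0.5)
  one <- fixture_spectrum(mode_table(1L, 1000, 1.0), shape)
  two <- fixture_spectrum(mode_table(1L, 1010, 0.5), shape)
  both <- fixture_spectrum(mode_table(1:2, c(1000, 1010), c(1.0, 0.5)),
                           shape)
  expect_equal(both$intensity, one$intensity + two$intensity)
  flipped <- fixture_spectrum(mode_table(2:1, c(1010, 1000), c(0.5, 1.0)),
                              shape)
  expect_equal(both$intensity, flipped$intensity)
  expect_true(all(both$intensity >= 0))
})

test_that("full synthesis normalises to 100 when f is automatic", {
  tbl <- reference_mode_table("clopidogrel")
  s <- synthesize_spectrum(tbl, scaling = NULL)
  expect_equal(max(s$intensity), 100)
  meta <- attr(s, "meta")
  expect_false(meta$scaled)
  expect_true(is.finite(meta$f))
  s2 <- synthesize_spectrum(tbl)   # with scaling applied
  expect_true(attr(s2, "meta")$scaled)
})

test_that("empty tables yield an all-zero spectrum with a warning", {
  empty <- mode_table(integer(), numeric(), numeric())
  expect_warning(s <- fixture_spectrum(empty), "empty")
  expect_true(all(s$intensity == 0))
})

test_that("reference-table synthesis peaks at the strongest tabulated mode", {
  tbl <- reference_mode_table("clopidogrel")
  s <- fixture_spectrum(tbl)
  apex <- s$wavenumber[which.max(s$intensity)]
  strongest <- tbl$wavenumber[which.max(tbl$raman_activity)]
  expect_equal(strongest, 1303)
  expect_lt(abs(apex - strongest), 2.5)
  # the lone-mode term at 1303 dominates any other mode's own peak height
  expect_gte(s$intensity[s$wavenumber == 1303],
             max(tbl$raman_activity[tbl$wavenumber != 1303]))
})
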