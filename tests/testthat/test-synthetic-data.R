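test_that("generation is fully deterministic under a fixed seed", {
  sp <- synthetic_spec(seed = 99L)
  a <- generate_mode_table(sp)
  b <- generate_mode_table(sp)
  expect_identical(as.data.frame(a), as.data.frame(b))
  ra <- generate_sers_spectrum(a, sp)
  rb <- generate_sers_spectrum(b, sp)
  expect_identical(ra$intensity, rb$intensity)
  # the caller's RNG stream is not disturbed
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_mode_table(sp)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("generated tables respect their specification", {
  sp <- synthetic_spec(n_modes = 300L, wavenumber_range = c(600, 1200),
                       activity_law = c(0.05, 0.9), joint_fraction = 0,
                       seed = 7L)
  tab <- generate_mode_table(sp)
  expect_equal(nrow(tab), 300L)
  expect_true(all(tab$wavenumber >= 600 & tab$wavenumber <= 1200))
  expect_true(!is.unsorted(tab$wavenumber))
  expect_true(all(tab$raman_activity >= 0.05 & tab$raman_activity <= 0.9))
  expect_equal(sum(tab$fragment == "joint"), 0L)   # joint_fraction = 0
  expect_error(synthetic_spec(wavenumber_range = c(800, 800)), "range")
})

test_that("joint counts follow the binomial law across seeds", {
  counts <- vapply(1:100, function(s) {
    tab <- generate_mode_table(synthetic_spec(n_modes = 200L,
                                              joint_fraction = 0.1,
                                              seed = s))
    sum(tab$fragment == "joint")
  }, numeric(1))
  # pooled count over 100 seeds is Binomial(20000, 0.1); exact 99% bounds
  bounds <- qbinom(c(0.005, 0.995), 20000, 0.1)
  expect_gte(sum(counts), bounds[1L])
  expect_lte(sum(counts), bounds[2L])
  # and the per-seed counts center near 20
  expect_gt(mean(counts), 15)
  expect_lt(mean(counts), 25)
})

test_that("noise-free generation reduces to the forward Lorentzian model", {
  sp <- synthetic_spec(n_modes = 10L, noise_sd = 0, baseline_coeffs = 0,
                       injected_shift = 0, seed = 2L)
  tab <- generate_mode_table(sp)
  raw <- generate_sers_spectrum(tab, sp, grid_spec(), sampling_step = 5)
  ref <- fixture_spectrum(tab, lineshape_params(fwhm = sp$fwhm,
                                                grid_min = 400,
                                                grid_max = 1800,
                                                grid_step = 5))
  expect_equal(raw$intensity, ref$intensity)
})

test_that("an injected shift rigidly translates every peak apex", {
  sp0 <- synthetic_spec(n_modes = 5L, noise_sd = 0, baseline_coeffs = 0,
                        injected_shift = 0, seed = 3L,
                        wavenumber_range = c(600, 1400))
  sp4 <- synthetic_spec(n_modes = 5L, noise_sd = 0, baseline_coeffs = 0,
                        injected_shift = 4, seed = 3L,
                        wavenumber_range = c(600, 1400))
  tab <- generate_mode_table(sp0)
  r0 <- generate_sers_spectrum(tab, sp0, grid_spec(), sampling_step = 0.5)
  r4 <- generate_sers_spectrum(tab, sp4, grid_spec(), sampling_step = 0.5)
  # the shifted trace equals the unshifted one translated by +4 cm-1
  idx <- match(r0$wavenumber + 4, r4$wavenumber)
  ok <- !is.na(idx)
  expect_equal(r4$intensity[idx[ok]], r0$intensity[ok], tolerance = 1e-12)
})

test_that("noise magnitude matches its specification across seeds", {
  resid <- unlist(lapply(1:50, function(s) {
    spn <- synthetic_spec(n_modes = 8L, noise_sd = 0.02,
                          baseline_coeffs = 0, seed = s)
    sp0 <- synthetic_spec(n_modes = 8L, noise_sd = 0,
                          baseline_coeffs = 0, seed = s)
    tab <- generate_mode_table(spn)
    noisy <- generate_sers_spectrum(tab, spn, sampling_step = 5)
    clean <- generate_sers_spectrum(tab, sp0, sampling_step = 5)
    (noisy$intensity - clean$intensity) / max(clean$intensity)
  }))
  expect_lt(abs(sd(resid) - 0.02) / 0.02, 0.2)
})
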