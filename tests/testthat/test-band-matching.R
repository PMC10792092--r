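make_binned <- function(values, start = 400, step = 5) {
  g <- grid_spec(start, start + step * (length(values) - 1L), step)
  vibraman:::new_binned_spectrum(g, values, rep(1L, length(values)))
}

test_that("band detection finds strict local maxima above the threshold", {
  # single triangular peak centered at 1000
  g <- grid_spec(980, 1020, 5)
  v <- c(1, 2, 3, 4, 5, 4, 3, 2, 1)
  spec <- vibraman:::new_binned_spectrum(g, v, rep(1L, 9))
  expect_equal(detect_bands(spec, 0.1), 1000)
  # flat spectrum: no strict maxima
  flat <- make_binned(rep(5, 9))
  expect_equal(detect_bands(flat, 0.1), numeric(0))
  expect_error(detect_bands(make_binned(c(1, NA, NA, NA, 2)), 0.1),
               "3 present")
  expect_error(detect_bands(flat, 1.5), "prominence_fraction")
})

test_that("prominence threshold suppresses small peaks", {
  # two isolated peaks of prominence 60 and 5 on a max-100 spectrum
  # (valleys at zero, so each peak's prominence equals its height)
  v <- rep(0, 41)
  v[6] <- 60; v[5] <- 30; v[7] <- 30
  v[30] <- 5; v[29] <- 2; v[31] <- 2
  v[20] <- 100; v[19] <- 50; v[21] <- 50   # global max elsewhere
  spec <- make_binned(v)
  got <- detect_bands(spec, 0.1)
  # exhaustive scan oracle: strict local maxima with prominence >= 10
  centers <- spec$wavenumber
  oracle <- centers[sapply(seq_along(v), function(i)
    i > 1 && i < length(v) && v[i] > v[i - 1] && v[i] > v[i + 1] &&
      v[i] >= 10)]
  expect_equal(got, oracle)
  expect_true(centers[6] %in% got)
  expect_false(centers[30] %in% got)
})

test_that("a tall ripple on a larger band's shoulder is not a band", {
  v <- rep(0, 41)
  v[19] <- 50; v[20] <- 100; v[21] <- 50   # main band, prominence 100
  v[22] <- 55; v[23] <- 50; v[24] <- 0     # shoulder bump, prominence 5
  spec <- make_binned(v)
  got <- detect_bands(spec, 0.1)
  expect_true(spec$wavenumber[20] %in% got)
  expect_false(spec$wavenumber[22] %in% got)  # height 55 but prominence 5
})

test_that("matching pairs the 997 mode with the 1001 band at shift +4", {
  m <- match_modes_to_bands(997, 1001, tolerance = 10)
  expect_equal(nrow(m), 1L)
  expect_equal(m$shift, 4)
  # a tight tolerance excludes the pair
  expect_equal(nrow(match_modes_to_bands(997, 1001, tolerance = 2)), 0L)
})

test_that("greedy matching is globally closest with lower-first ties", {
  # tie: band 505 is 5 away from both modes; lower mode wins
  m <- match_modes_to_bands(c(500, 510), 505, tolerance = 10)
  expect_equal(m$mode_wavenumber, 500)
  expect_equal(m$shift, 5)
  # globally closest pair is taken first even if listed later
  m2 <- match_modes_to_bands(c(500, 520), c(508, 521), tolerance = 10)
  expect_equal(m2$band_wavenumber[m2$mode_wavenumber == 520], 521)
  expect_equal(m2$band_wavenumber[m2$mode_wavenumber == 500], 508)
  # empty inputs
  expect_equal(nrow(match_modes_to_bands(numeric(0), 1001)), 0L)
  expect_error(match_modes_to_bands(997, 1001, tolerance = -1), "tolerance")
})

test_that("matching is invariant under a common wavenumber offset", {
  set.seed(21)
  modes <- sort(runif(15, 500, 1500))
  bands <- sort(modes[sample(15, 8)] + runif(8, -6, 6))
  base <- match_modes_to_bands(modes, bands, tolerance = 10)
  shifted <- match_modes_to_bands(modes + 100, bands + 100, tolerance = 10)
  expect_equal(shifted$shift, base$shift)
  expect_equal(shifted$mode_wavenumber, base$mode_wavenumber + 100)
})

test_that("biomarker selection applies the joint rule within the region", {
  t1 <- reference_mode_table("clopidogrel")
  b <- select_biomarkers(t1)
  expect_equal(b$index,
               c(72, 85, 93, 96, 97, 146, 147, 151, 152, 153, 163, 164,
                 165))
  expect_equal(b$wavenumber,
               c(767, 905, 997, 1017, 1019, 1450, 1451, 1474, 1475, 1475,
                 1731, 1733, 1764))
  # no joint modes -> empty selection
  expect_equal(nrow(select_biomarkers(toy_modes(frag = "ligand"))), 0L)
  # region bounds exclude out-of-window modes
  narrow <- select_biomarkers(t1, region = grid_spec(900, 1100, 5))
  expect_equal(narrow$index, c(85, 93, 96, 97))
})

test_that("override include/exclude reproduces the curated aspirin set", {
  t2 <- reference_mode_table("aspirin")
  ov <- read_override()
  b <- select_biomarkers(t2, include = ov$include, exclude = ov$exclude)
  ref <- reference_biomarkers()
  expect_setequal(b$index, ref$index[ref$drug == "Aspirin"])
  expect_equal(nrow(b), 18L)
  # without the override the raw joint rule disagrees on exactly 37/45/43/110
  raw <- select_biomarkers(t2)
  expect_setequal(setdiff(b$index, raw$index), c(37, 45))
  expect_setequal(setdiff(raw$index, b$index), c(43, 110))
})

test_that("matches are joined onto selected biomarkers", {
  t1 <- reference_mode_table("clopidogrel")
  m <- match_modes_to_bands(997, 1001, tolerance = 10)
  m$mode_index <- 93L
  b <- select_biomarkers(t1, matches = m)
  expect_equal(b$shift[b$index == 93], 4)
  expect_true(all(is.na(b$shift[b$index != 93])))
})

test_that("overlay report looks up nearest bins per group", {
  t1 <- reference_mode_table("clopidogrel")
  g <- grid_spec(400, 1800, 5)
  set.seed(5)
  mk <- function() vibraman:::new_binned_spectrum(g, runif(281),
                                                  rep(1L, 281))
  cand <- select_biomarkers(t1)
  rep_ <- overlay_report(t1, list(none = mk(), clopidogrel = mk()), cand)
  expect_equal(nrow(rep_), 13L)
  expect_true(all(c("intensity_none", "intensity_clopidogrel") %in%
                    names(rep_)))
  # 997 sits nearest the 995 bin (tie-free: 997 - 995 = 2 < 3)
  expect_equal(rep_$nearest_bin[rep_$index == 93], 995)
  expect_false(any(rep_$out_of_range))
  # candidate outside the experimental grid is flagged
  small <- grid_spec(400, 500, 5)
  sm <- vibraman:::new_binned_spectrum(small, runif(21), rep(1L, 21))
  rep2 <- overlay_report(t1, list(g = sm), cand)
  expect_true(all(rep2$out_of_range))
  # empty candidates give an empty report
  empty <- select_biomarkers(toy_modes(frag = "ligand"))
  expect_equal(nrow(overlay_report(t1, list(g = sm), empty)), 0L)
})
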