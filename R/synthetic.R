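#' Specification for synthetic test data
#'
#' Describes the statistical structure of the inputs the pipeline consumes,
#' so every stage can be exercised without electronic-structure output or
#' instrument exports: a mode table with fingerprint-region wavenumbers and
#' log-uniform activities, and a SERS-like spectrum made of Lorentzian
#' peaks over a smooth polynomial baseline with additive Gaussian noise and
#' an optional controlled peak shift.
#'
#' The defaults mirror the transcribed reference tables: 120 modes across
#' 400-1800 cm^-1, activities log-uniform on [0.01, 1.5] (the dynamic range
#' of the printed strengths), roughly one mode in nine attributed jointly
#' to both fragments, 5 cm^-1 Lorentzians, a gently rising quadratic
#' baseline and 2% noise.
#'
#' @param n_modes number of modes to draw.
#' @param wavenumber_range length-2 interval, cm^-1.
#' @param activity_law length-2 interval for the log-uniform activity draw.
#' @param joint_fraction probability that a mode is joint.
#' @param fwhm Lorentzian FWHM of the synthetic peaks, cm^-1.
#' @param baseline_coeffs polynomial coefficients (constant first) of the
#'   baseline, evaluated in `(wavenumber - range_min)`.
#' @param noise_sd additive Gaussian noise standard deviation, as a
#'   fraction of the noiseless signal maximum.
#' @param injected_shift rigid shift applied to every peak position,
#'   cm^-1.
#' @param seed integer seed fixing every draw.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_modes = 120L,
                           wavenumber_range = c(400, 1800),
                           activity_law = c(0.01, 1.5),
                           joint_fraction = 0.11,
                           fwhm = 5,
                           baseline_coeffs = c(0.1, 1e-4),
                           noise_sd = 0.02,
                           injected_shift = 0,
                           seed = 1L) {
  stopifnot(length(wavenumber_range) == 2L, length(activity_law) == 2L)
  if (n_modes < 0) stop("synthetic_spec: n_modes must be >= 0", call. = FALSE)
  if (diff(wavenumber_range) <= 0 || wavenumber_range[1L] <= 0)
    stop("synthetic_spec: invalid wavenumber range", call. = FALSE)
  if (diff(activity_law) < 0 || activity_law[1L] <= 0)
    stop("synthetic_spec: invalid activity interval", call. = FALSE)
  if (joint_fraction < 0 || joint_fraction > 1)
    stop("synthetic_spec: joint_fraction must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("synthetic_spec: noise_sd must be >= 0",
                         call. = FALSE)
  if (fwhm <= 0) stop("synthetic_spec: fwhm must be > 0", call. = FALSE)
  structure(list(n_modes = as.integer(n_modes),
                 wavenumber_range = wavenumber_range,
                 activity_law = activity_law,
                 joint_fraction = joint_fraction,
                 fwhm = fwhm,
                 baseline_coeffs = baseline_coeffs,
                 noise_sd = noise_sd,
                 injected_shift = injected_shift,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic mode table
#'
#' Draws `n_modes` modes with wavenumbers uniform over the range (returned
#' sorted), activities log-uniform over `activity_law`, and fragment labels
#' drawn `ligand`/`residue`/`joint` with joint probability
#' `joint_fraction` (the remainder split evenly). Fully reproducible from
#' `spec$seed`; the caller's RNG state is left untouched.
#'
#' @param spec a [synthetic_spec].
#' @return A [mode_table].
#' @export
generate_mode_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_modes
    wn <- sort(stats::runif(n, spec$wavenumber_range[1L],
                            spec$wavenumber_range[2L]))
    act <- exp(stats::runif(n, log(spec$activity_law[1L]),
                            log(spec$activity_law[2L])))
    jf <- spec$joint_fraction
    frag <- sample(c("ligand", "residue", "joint"), n, replace = TRUE,
                   prob = c((1 - jf) / 2, (1 - jf) / 2, jf))
    mode_table(seq_len(n), wn, act, frag,
               description = "synthetic mode",
               complex_name = "synthetic complex",
               provenance = sprintf("generate_mode_table(seed=%d)",
                                    spec$seed))
  })
}

#' Generate a synthetic SERS-like spectrum
#'
#' Samples a raw spectrum at `sampling_step` resolution over the grid
#' range: height-normalised Lorentzian peaks at the table's mode positions
#' (rigidly shifted by `spec$injected_shift`) with heights equal to the
#' activities, plus the polynomial baseline, plus zero-mean Gaussian noise
#' with standard deviation `noise_sd` times the noiseless maximum.
#' Reproducible from `spec$seed`.
#'
#' @param table a [mode_table] (typically from [generate_mode_table()]).
#' @param spec a [synthetic_spec].
#' @param grid a [grid_spec] giving the sampled range.
#' @param sampling_step raw sampling interval, cm^-1; default 1, finer than
#'   the 5 cm^-1 analysis grid as an instrument would provide.
#' @return A [raw_spectrum].
#' @export
generate_sers_spectrum <- function(table, spec, grid = grid_spec(),
                                   sampling_step = 1) {
  stopifnot(inherits(table, "mode_table"), inherits(spec, "synthetic_spec"),
            inherits(grid, "grid_spec"))
  w <- seq(grid$start, grid$stop, by = sampling_step)
  signal <- lorentzian_sum(w, table$wavenumber + spec$injected_shift,
                           table$raman_activity, spec$fwhm)
  x <- w - grid$start
  baseline <- numeric(length(w))
  for (k in seq_along(spec$baseline_coeffs))
    baseline <- baseline + spec$baseline_coeffs[k] * x^(k - 1L)
  clean <- signal + baseline
  noisy <- if (spec$noise_sd > 0) {
    with_seed(spec$seed + 1L,
              clean + stats::rnorm(length(w), 0,
                                   spec$noise_sd * max(clean)))
  } else clean
  raw_spectrum(w, noisy,
               label = sprintf("synthetic (seed=%d, shift=%g)",
                               spec$seed, spec$injected_shift))
}
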