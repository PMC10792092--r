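#' Linear harmonic wavenumber scaling
#'
#' Harmonic frequencies from electronic-structure calculations
#' systematically overshoot observed band positions; an empirical linear
#' correction of the ratio between experimental and calculated wavenumbers,
#' nu_exp / nu_calc = a * nu_calc + b, compensates. The defaults are the
#' coefficients appropriate to B3LYP/6-31G(d) harmonic frequencies:
#' a = -0.0000083526 cm and b = 0.98134.
#'
#' @param a slope coefficient (cm); multiplies the calculated wavenumber in
#'   the ratio.
#' @param b dimensionless intercept, > 0.
#' @return An object of class `scaling_model`.
#' @export
scaling_model <- function(a = -0.0000083526, b = 0.98134) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (b <= 0) stop("scaling_model: b must be > 0", call. = FALSE)
  # a*nu + b is linear: positivity on (0, 4000] follows from the endpoints
  if (4000 * a + b <= 0)
    stop("scaling_model: a*nu + b must stay positive on (0, 4000] cm-1",
         call. = FALSE)
  structure(list(a = a, b = b), class = "scaling_model")
}

#' @export
print.scaling_model <- function(x, ...) {
  cat(sprintf("Wavenumber scaling: nu_exp/nu_calc = %g * nu_calc + %g\n",
              x$a, x$b))
  invisible(x)
}

#' Apply wavenumber scaling
#'
#' Maps a calculated harmonic wavenumber to its scaled (experiment-like)
#' value: `nu * (a*nu + b)`.
#'
#' @param nu_th calculated wavenumbers, cm^-1, > 0 (vectorised).
#' @param model a [scaling_model].
#' @return Scaled wavenumbers, cm^-1.
#' @examples
#' scale_wavenumber(1000, scaling_model())  # 972.9874
#' @export
scale_wavenumber <- function(nu_th, model = scaling_model()) {
  stopifnot(inherits(model, "scaling_model"), is.numeric(nu_th))
  if (any(nu_th <= 0))
    stop("scale_wavenumber: wavenumbers must be > 0", call. = FALSE)
  out <- nu_th * (model$a * nu_th + model$b)
  if (any(out <= 0))
    stop("scale_wavenumber: coefficients produce non-positive wavenumbers ",
         "in this range", call. = FALSE)
  out
}

#' Raman intensity-conversion parameters
#'
#' Parameters of the conversion from calculated Raman activity A_i to a
#' relative Raman intensity:
#' I_i = f (nu0 - nu_i)^4 A_i / { nu_i [1 - exp(-c2 nu_i / T)] },
#' where nu0 is the excitation wavenumber, T the temperature and
#' c2 = h c / k the second radiation constant. The denominator's Boltzmann
#' factor accounts for the thermal population of the vibrational ground
#' state.
#'
#' @param nu0 excitation wavenumber, cm^-1; default 1e7/532 (532 nm laser).
#' @param temperature temperature in kelvin; default 298.15 (room
#'   temperature measurement).
#' @param f common normalisation factor for all peaks; `NA` (default) lets
#'   [synthesize_spectrum()] choose f so that the spectrum maximum is 100.
#' @param c2 second radiation constant hc/k in cm K (CODATA).
#' @return An object of class `intensity_params`.
#' @export
intensity_params <- function(nu0 = 1e7 / 532, temperature = 298.15,
                             f = NA_real_, c2 = 1.438776877) {
  stopifnot(length(nu0) == 1L, length(temperature) == 1L, length(f) == 1L)
  if (nu0 <= 0) stop("intensity_params: nu0 must be > 0", call. = FALSE)
  if (temperature <= 0)
    stop("intensity_params: temperature must be > 0", call. = FALSE)
  if (!is.na(f) && f <= 0)
    stop("intensity_params: f must be > 0 (or NA for automatic)",
         call. = FALSE)
  structure(list(nu0 = nu0, temperature = temperature, f = f, c2 = c2),
            class = "intensity_params")
}

#' Convert Raman activity to relative intensity
#'
#' Applies the frequency- and temperature-dependent conversion described in
#' [intensity_params()] to each mode. When `params$f` is `NA` the factor is
#' taken as 1, yielding intensities on a relative scale.
#'
#' @param wavenumber mode wavenumbers nu_i, cm^-1, in (0, nu0) (vectorised).
#' @param activity Raman activities A_i, >= 0.
#' @param params an [intensity_params].
#' @return Nonnegative intensities, arbitrary units; linear in `activity`
#'   and in `f`.
#' @export
activity_to_intensity <- function(wavenumber, activity,
                                  params = intensity_params()) {
  stopifnot(inherits(params, "intensity_params"))
  if (any(wavenumber <= 0))
    stop("activity_to_intensity: wavenumbers must be > 0", call. = FALSE)
  if (any(wavenumber >= params$nu0))
    stop("activity_to_intensity: mode wavenumber must lie below the ",
         "excitation wavenumber nu0 = ", format(params$nu0), call. = FALSE)
  if (any(activity < 0))
    stop("activity_to_intensity: activities must be >= 0", call. = FALSE)
  f <- if (is.na(params$f)) 1 else params$f
  thermal <- 1 - exp(-params$c2 * wavenumber / params$temperature)
  f * (params$nu0 - wavenumber)^4 * activity / (wavenumber * thermal)
}

#' Lorentzian lineshape and evaluation grid
#'
#' @param fwhm full width at half maximum of each band, cm^-1; default 5.
#' @param grid_min,grid_max evaluation range, cm^-1 (default the 400-1800
#'   fingerprint region).
#' @param grid_step evaluation step, cm^-1; default 0.5, fine enough to
#'   resolve a 5 cm^-1 FWHM.
#' @return An object of class `lineshape_params`.
#' @export
lineshape_params <- function(fwhm = 5, grid_min = 400, grid_max = 1800,
                             grid_step = 0.5) {
  if (fwhm <= 0) stop("lineshape_params: fwhm must be > 0", call. = FALSE)
  if (grid_min >= grid_max)
    stop("lineshape_params: grid_min must be < grid_max", call. = FALSE)
  if (grid_step <= 0)
    stop("lineshape_params: grid_step must be > 0", call. = FALSE)
  structure(list(fwhm = fwhm, grid_min = grid_min, grid_max = grid_max,
                 grid_step = grid_step),
            class = "lineshape_params")
}

# sum of height-normalised Lorentzians: each term equals `height` at its
# center and height/2 at center +/- fwhm/2
lorentzian_sum <- function(x, centers, heights, fwhm) {
  gamma2 <- (fwhm / 2)^2
  s <- numeric(length(x))
  for (i in seq_along(centers))
    s <- s + heights[i] * gamma2 / ((x - centers[i])^2 + gamma2)
  s
}

new_raman_spectrum <- function(wavenumber, intensity, meta) {
  structure(data.frame(wavenumber = wavenumber, intensity = intensity),
            meta = meta,
            class = c("raman_spectrum", "data.frame"))
}

#' @export
print.raman_spectrum <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Simulated Raman spectrum: %d points, %.1f-%.1f cm-1 (%s)\n",
              nrow(x), min(x$wavenumber), max(x$wavenumber),
              meta$mode %||% "?"))
  cat(sprintf("  max intensity %.4g at %.1f cm-1\n",
              max(x$intensity), x$wavenumber[which.max(x$intensity)]))
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...,
                                xlab = expression(paste("wavenumber (",
                                                        cm^-1, ")")),
                                ylab = "intensity (a.u.)", type = "l") {
  plot(x$wavenumber, x$intensity, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Synthesize a theoretical Raman spectrum from a mode table
#'
#' Builds the continuous theoretical spectrum: mode positions are
#' (optionally) wavenumber-scaled, activities are converted to relative
#' intensities, and each mode contributes a height-normalised Lorentzian of
#' the given FWHM. The spectrum is the pointwise sum over modes:
#' S(nu) = sum_i I_i gamma^2 / ((nu - nu_i)^2 + gamma^2), gamma = fwhm/2,
#' so the contribution of a lone mode evaluated at its own center equals its
#' converted intensity I_i.
#'
#' When `params$f` is `NA` the common factor is chosen so that the spectrum
#' maximum is exactly 100, matching the display convention for normalised
#' spectra; the effective factor is recorded in the `meta` attribute.
#'
#' @param table a [mode_table]; all modes must lie in (0, nu0).
#' @param scaling a [scaling_model], or `NULL` to use the tabulated
#'   wavenumbers as-is (appropriate when they are already scaled).
#' @param params an [intensity_params].
#' @param shape a [lineshape_params].
#' @return A `raman_spectrum` data frame (`wavenumber`, `intensity`) whose
#'   `meta` attribute records the parameters used, whether scaling was
#'   applied, and the normalisation factor.
#' @export
synthesize_spectrum <- function(table, scaling = scaling_model(),
                                params = intensity_params(),
                                shape = lineshape_params()) {
  stopifnot(inherits(table, "mode_table"),
            inherits(params, "intensity_params"),
            inherits(shape, "lineshape_params"))
  if (!is.null(scaling)) stopifnot(inherits(scaling, "scaling_model"))
  grid <- seq(shape$grid_min, shape$grid_max, by = shape$grid_step)
  if (nrow(table) == 0L) {
    warning("empty mode table: returning an all-zero spectrum")
    return(new_raman_spectrum(grid, numeric(length(grid)),
                              list(mode = "activities", scaled = FALSE,
                                   f = NA_real_, params = params,
                                   shape = shape)))
  }
  centers <- if (is.null(scaling)) table$wavenumber
             else scale_wavenumber(table$wavenumber, scaling)
  heights <- activity_to_intensity(centers, table$raman_activity, params)
  s <- lorentzian_sum(grid, centers, heights, shape$fwhm)
  f_eff <- if (is.na(params$f)) {
    m <- max(s)
    if (m > 0) { s <- s * (100 / m); 100 / m } else NA_real_
  } else params$f
  new_raman_spectrum(grid, s,
                     list(mode = "activities", scaled = !is.null(scaling),
                          scaling = scaling, f = f_eff, params = params,
                          shape = shape))
}

#' Synthesize a spectrum using tabulated strengths as peak heights
#'
#' For transcribed reference tables whose "Raman strength" column is already
#' a usable peak amplitude, this builds the Lorentzian-broadened spectrum
#' directly: no activity-to-intensity conversion and no wavenumber
#' re-scaling is applied. The contribution of a lone mode at its own center
#' equals its tabulated strength.
#'
#' @param table a [mode_table].
#' @param shape a [lineshape_params].
#' @return A `raman_spectrum`; see [synthesize_spectrum()].
#' @export
fixture_spectrum <- function(table, shape = lineshape_params()) {
  stopifnot(inherits(table, "mode_table"), inherits(shape, "lineshape_params"))
  grid <- seq(shape$grid_min, shape$grid_max, by = shape$grid_step)
  if (nrow(table) == 0L) {
    warning("empty mode table: returning an all-zero spectrum")
    return(new_raman_spectrum(grid, numeric(length(grid)),
                              list(mode = "fixture", scaled = FALSE,
                                   f = NA_real_, shape = shape)))
  }
  s <- lorentzian_sum(grid, table$wavenumber, table$raman_activity,
                      shape$fwhm)
  new_raman_spectrum(grid, s, list(mode = "fixture", scaled = FALSE,
                                   f = NA_real_, shape = shape))
}
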