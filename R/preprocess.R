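#' Fixed wavenumber grid
#'
#' The fixed grid onto which experimental spectra are decomposed: bin
#' centers at `start, start + step, ..., stop`. The default, 400 to 1800
#' cm^-1 in 5 cm^-1 steps, spans the fingerprint region with 281 bins.
#'
#' @param start,stop grid limits, cm^-1; `stop - start` must be divisible by
#'   `step`.
#' @param step bin spacing, cm^-1, > 0.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(start = 400, stop = 1800, step = 5) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (start >= stop) stop("grid_spec: start must be < stop", call. = FALSE)
  if (step <= 0) stop("grid_spec: step must be > 0", call. = FALSE)
  k <- (stop - start) / step
  if (abs(k - round(k)) > 1e-9)
    stop("grid_spec: (stop - start) must be divisible by step", call. = FALSE)
  structure(list(start = start, stop = stop, step = step),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Wavenumber grid: %g to %g cm-1 in %g cm-1 steps (%d bins)\n",
              x$start, x$stop, x$step, length(grid_centers(x))))
  invisible(x)
}

#' Bin centers of a grid
#' @param grid a [grid_spec].
#' @return Numeric vector of bin centers.
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  seq(grid$start, grid$stop, by = grid$step)
}

new_binned_spectrum <- function(grid, intensity, n_contributing, label = "",
                                normalized = FALSE, dropped = 0L) {
  centers <- grid_centers(grid)
  structure(data.frame(wavenumber = centers, intensity = intensity,
                       n_contributing = as.integer(n_contributing)),
            grid = grid, label = label, normalized = normalized,
            dropped = dropped,
            class = c("binned_spectrum", "data.frame"))
}

#' @export
print.binned_spectrum <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf(
    "Binned spectrum '%s': %d bins (%g:%g:%g), %d present%s\n",
    attr(x, "label"), nrow(x), g$start, g$stop, g$step,
    sum(!is.na(x$intensity)),
    if (isTRUE(attr(x, "normalized"))) ", normalized to 100" else ""))
  invisible(x)
}

#' @export
plot.binned_spectrum <- function(x, ...,
                                 xlab = expression(paste("wavenumber (",
                                                         cm^-1, ")")),
                                 ylab = "intensity (a.u.)", type = "l") {
  plot(x$wavenumber, x$intensity, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Decompose a raw spectrum onto a fixed grid
#'
#' Assigns every raw sample whose wavenumber falls within half a step of the
#' grid to its nearest bin center (a sample exactly halfway between two
#' centers goes to the lower one); each bin's intensity is the arithmetic
#' mean of its assigned samples. Bins that receive no sample are marked
#' missing (`NA`), never interpolated. Samples outside the grid's catchment
#' are dropped and counted in the `dropped` attribute.
#'
#' @param raw a [raw_spectrum].
#' @param grid a [grid_spec].
#' @return A `binned_spectrum` data frame with columns `wavenumber`
#'   (bin center), `intensity` (mean or `NA`) and `n_contributing`.
#' @export
bin_spectrum <- function(raw, grid = grid_spec()) {
  stopifnot(inherits(raw, "raw_spectrum"), inherits(grid, "grid_spec"))
  centers <- grid_centers(grid)
  nb <- length(centers)
  # nearest-center assignment with ties toward the lower center
  k <- ceiling((raw$wavenumber - grid$start) / grid$step - 0.5)
  ok <- k >= 0 & k <= nb - 1L & raw$wavenumber < grid$stop + grid$step / 2
  dropped <- sum(!ok)
  if (!any(ok))
    stop("bin_spectrum: no samples fall inside the grid range", call. = FALSE)
  kf <- factor(k[ok], levels = 0:(nb - 1L))
  sums <- tapply(raw$intensity[ok], kf, sum)
  n <- as.integer(table(kf))
  intensity <- ifelse(n > 0L, as.numeric(sums) / n, NA_real_)
  if (dropped > 0L)
    message("bin_spectrum: dropped ", dropped, " sample(s) outside ",
            grid$start, "-", grid$stop, " cm-1")
  new_binned_spectrum(grid, intensity, n, label = attr(raw, "label") %||% "",
                      dropped = dropped)
}

#' Average replicate binned spectra
#'
#' Per-bin arithmetic mean over replicates measured on the identical grid,
#' emulating the averaging of repeated acquisitions from different spots of
#' the same droplet. A bin is missing in the result only if it is missing in
#' every replicate; otherwise the mean is taken over the replicates in which
#' it is present and `n_contributing` sums their sample counts.
#'
#' @param spectra a list of `binned_spectrum` objects on the same grid.
#' @param label label for the averaged spectrum.
#' @return A `binned_spectrum`.
#' @export
average_replicates <- function(spectra, label = NULL) {
  if (inherits(spectra, "binned_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1), "binned_spectrum")))
  g <- attr(spectra[[1L]], "grid")
  for (s in spectra[-1L]) {
    gi <- attr(s, "grid")
    if (!isTRUE(all.equal(unclass(g), unclass(gi))))
      stop("average_replicates: replicates are on different grids",
           call. = FALSE)
  }
  vals <- sapply(spectra, function(s) s$intensity)   # nb x r
  ns <- sapply(spectra, function(s) s$n_contributing)
  vals <- matrix(vals, ncol = length(spectra))
  ns <- matrix(ns, ncol = length(spectra))
  present <- !is.na(vals)
  cnt <- rowSums(present)
  mean_i <- ifelse(cnt > 0L,
                   rowSums(vals * present, na.rm = TRUE) / pmax(cnt, 1L),
                   NA_real_)
  n_tot <- rowSums(ns * present)
  new_binned_spectrum(g, mean_i, n_tot,
                      label = label %||%
                        paste(unique(vapply(spectra, attr, "", "label")),
                              collapse = "+"))
}

#' Normalize a binned spectrum to a maximum of 100
#'
#' Multiplies all present intensities by `100 / max` so the tallest bin
#' becomes exactly 100; relative intensities between bins are preserved and
#' the operation is idempotent.
#'
#' @param spec a `binned_spectrum` with at least one positive bin.
#' @return The normalized `binned_spectrum` (the `normalized` attribute is
#'   set).
#' @export
normalize_to_100 <- function(spec) {
  stopifnot(inherits(spec, "binned_spectrum"))
  m <- suppressWarnings(max(spec$intensity, na.rm = TRUE))
  if (!is.finite(m) || m <= 0)
    stop("normalize_to_100: spectrum has no positive bin to normalize by",
         call. = FALSE)
  out <- spec
  out$intensity <- spec$intensity * (100 / m)
  attr(out, "normalized") <- TRUE
  out
}
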