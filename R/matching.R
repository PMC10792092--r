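#' Detect experimental bands in a binned spectrum
#'
#' Reports the bin centers of characteristic bands: bins that are strict
#' local maxima over their nearest present neighbours and whose topographic
#' prominence reaches `prominence_fraction` of the spectrum's global
#' maximum. The prominence of a peak is its height above the higher of the
#' two valley minima found walking outward on each side until a taller bin
#' (or the spectrum edge) is met — so small ripples riding on a baseline or
#' on a larger band's shoulder are suppressed even when their absolute
#' height is large. Missing bins are skipped (a bin's neighbours are the
#' nearest present bins on either side); edge bins cannot be verified as
#' maxima and are never reported.
#'
#' @param spec a `binned_spectrum`, normally normalized to 100.
#' @param prominence_fraction prominence threshold as a fraction of the
#'   global maximum, in (0, 1); default 0.05.
#' @return Sorted numeric vector of band wavenumbers (bin centers), possibly
#'   empty.
#' @export
detect_bands <- function(spec, prominence_fraction = 0.05) {
  stopifnot(inherits(spec, "binned_spectrum"))
  if (!(prominence_fraction > 0 && prominence_fraction < 1))
    stop("detect_bands: prominence_fraction must lie in (0, 1)",
         call. = FALSE)
  present <- !is.na(spec$intensity)
  if (sum(present) < 3L)
    stop("detect_bands: need at least 3 present bins", call. = FALSE)
  v <- spec$intensity[present]
  w <- spec$wavenumber[present]
  m <- max(v)
  n <- length(v)
  out <- numeric(0)
  for (i in 2:(n - 1L)) {
    if (!(v[i] > v[i - 1L] && v[i] > v[i + 1L])) next
    left <- Inf
    for (j in (i - 1L):1L) {
      if (v[j] > v[i]) break
      left <- min(left, v[j])
    }
    right <- Inf
    for (j in (i + 1L):n) {
      if (v[j] > v[i]) break
      right <- min(right, v[j])
    }
    prom <- v[i] - max(min(left, v[i]), min(right, v[i]))
    if (prom >= prominence_fraction * m) out <- c(out, w[i])
  }
  sort(out)
}

#' Match theoretical modes to experimental bands
#'
#' Greedy globally-closest pairing: repeatedly pair the (mode, band) pair
#' with the smallest wavenumber distance not exceeding `tolerance`,
#' removing both from further consideration. Ties in distance are broken
#' deterministically toward the lower mode wavenumber, then the lower band
#' wavenumber. The signed shift is reported as experimental minus
#' theoretical (band - mode), so a mode calculated at 997 cm^-1 matched to
#' a band at 1001 cm^-1 carries a shift of +4 cm^-1.
#'
#' @param modes a [mode_table], or a numeric vector of mode wavenumbers.
#' @param bands numeric vector of band wavenumbers, cm^-1.
#' @param tolerance maximum pairing distance, cm^-1, > 0; default 10.
#' @return A data frame of class `band_match` with columns `mode_index`,
#'   `mode_wavenumber`, `band_wavenumber`, `shift`, sorted by mode
#'   wavenumber. Empty inputs yield an empty (zero-row) result.
#' @export
match_modes_to_bands <- function(modes, bands, tolerance = 10) {
  if (tolerance <= 0)
    stop("match_modes_to_bands: tolerance must be > 0", call. = FALSE)
  if (inherits(modes, "mode_table")) {
    mode_wn <- modes$wavenumber
    mode_idx <- modes$index
  } else {
    mode_wn <- as.numeric(modes)
    mode_idx <- seq_along(mode_wn)
  }
  empty <- data.frame(mode_index = integer(), mode_wavenumber = numeric(),
                      band_wavenumber = numeric(), shift = numeric())
  if (!length(mode_wn) || !length(bands))
    return(structure(empty, class = c("band_match", "data.frame")))
  pairs <- expand.grid(m = seq_along(mode_wn), b = seq_along(bands))
  pairs$d <- abs(mode_wn[pairs$m] - bands[pairs$b])
  pairs <- pairs[pairs$d <= tolerance, , drop = FALSE]
  pairs <- pairs[order(pairs$d, mode_wn[pairs$m], bands[pairs$b]), ,
                 drop = FALSE]
  used_m <- logical(length(mode_wn)); used_b <- logical(length(bands))
  sel <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    m <- pairs$m[r]; b <- pairs$b[r]
    if (!used_m[m] && !used_b[b]) {
      used_m[m] <- TRUE; used_b[b] <- TRUE
      sel <- c(sel, r)
    }
  }
  out <- pairs[sel, , drop = FALSE]
  out <- data.frame(mode_index = mode_idx[out$m],
                    mode_wavenumber = mode_wn[out$m],
                    band_wavenumber = bands[out$b],
                    shift = bands[out$b] - mode_wn[out$m])
  out <- out[order(out$mode_wavenumber, out$mode_index), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("band_match", "data.frame"))
}

#' Select biomarker candidate modes
#'
#' Applies the default biomarker rule: every joint-attributed mode (motion
#' spanning both the drug/metabolite and the receptor residue) whose
#' wavenumber lies inside the region of interest is a candidate. An
#' explicit override can force-include or force-exclude specific mode
#' indices where curated selections deviate from the rule. Candidates are
#' returned ordered by wavenumber, each carrying any experimental band
#' match found for it.
#'
#' @param table a [mode_table].
#' @param attributions list of `fragment_attribution`, one per mode in table
#'   order; defaults to [attribution_from_table()].
#' @param matches an optional `band_match` data frame from
#'   [match_modes_to_bands()]; matched band positions and shifts are joined
#'   by mode index.
#' @param region a [grid_spec] giving the wavenumber window (its `start`
#'   and `stop` bound the selection).
#' @param include,exclude integer mode indices to force-include or
#'   force-exclude regardless of the joint rule.
#' @return A data frame of class `biomarker_table`: `index`, `wavenumber`,
#'   `raman_activity`, `fragment`, `description`, `band_wavenumber`,
#'   `shift` (the last two `NA` where unmatched).
#' @export
select_biomarkers <- function(table, attributions = NULL, matches = NULL,
                              region = grid_spec(), include = integer(),
                              exclude = integer()) {
  stopifnot(inherits(table, "mode_table"), inherits(region, "grid_spec"))
  attributions <- attributions %||% attribution_from_table(table)
  if (length(attributions) != nrow(table))
    stop("select_biomarkers: attributions must cover the table",
         call. = FALSE)
  labels <- vapply(attributions, `[[`, character(1), "label")
  keep <- labels == "joint"
  keep[table$index %in% include] <- TRUE
  keep[table$index %in% exclude] <- FALSE
  keep <- keep & table$wavenumber >= region$start &
    table$wavenumber <= region$stop
  out <- as.data.frame(table)[keep, , drop = FALSE]
  out$band_wavenumber <- rep(NA_real_, nrow(out))
  out$shift <- rep(NA_real_, nrow(out))
  if (!is.null(matches) && nrow(matches)) {
    hit <- match(out$index, matches$mode_index)
    out$band_wavenumber <- matches$band_wavenumber[hit]
    out$shift <- matches$shift[hit]
  }
  out <- out[order(out$wavenumber, out$index), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, complex_name = attr(table, "complex_name"),
            class = c("biomarker_table", "data.frame"))
}

#' Overlay report: candidate modes over experimental spectra
#'
#' Pairs each biomarker candidate with the experimental intensity at its
#' nearest grid bin in every group's binned spectrum — the tabular backbone
#' of an overlay figure in which theoretical stems (right-hand scale) are
#' drawn over experimental traces (left-hand scale). Candidates outside a
#' grid's catchment are flagged rather than dropped.
#'
#' @param theoretical a [mode_table] supplying the stem heights (its
#'   `raman_activity` column).
#' @param experimental a named list of `binned_spectrum` objects, one per
#'   sample group.
#' @param candidates a `biomarker_table` from [select_biomarkers()].
#' @return A data frame of class `overlay_report`: one row per candidate
#'   with `index`, `mode_wavenumber`, `stem_height`, `nearest_bin`, one
#'   intensity column per group, and `out_of_range`.
#' @export
overlay_report <- function(theoretical, experimental, candidates) {
  stopifnot(inherits(theoretical, "mode_table"),
            inherits(candidates, "biomarker_table"))
  if (inherits(experimental, "binned_spectrum"))
    experimental <- list(sample = experimental)
  stopifnot(all(vapply(experimental, inherits, logical(1),
                       "binned_spectrum")))
  groups <- names(experimental) %||% paste0("group", seq_along(experimental))
  n <- nrow(candidates)
  out <- data.frame(index = candidates$index,
                    mode_wavenumber = candidates$wavenumber,
                    stem_height = candidates$raman_activity,
                    nearest_bin = rep(NA_real_, n),
                    out_of_range = rep(FALSE, n))
  for (g in groups) out[[paste0("intensity_", g)]] <- rep(NA_real_, n)
  if (n == 0L)
    return(structure(out, class = c("overlay_report", "data.frame")))
  for (i in seq_len(n)) {
    wn <- candidates$wavenumber[i]
    for (j in seq_along(experimental)) {
      spec <- experimental[[j]]
      g <- attr(spec, "grid")
      if (wn < g$start - g$step / 2 || wn >= g$stop + g$step / 2) {
        out$out_of_range[i] <- TRUE
        next
      }
      nb <- which.min(abs(spec$wavenumber - wn))
      out$nearest_bin[i] <- spec$wavenumber[nb]
      out[[paste0("intensity_", groups[j])]][i] <- spec$intensity[nb]
    }
  }
  structure(out, class = c("overlay_report", "data.frame"))
}
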