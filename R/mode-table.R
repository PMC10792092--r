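#' Vibrational mode tables
#'
#' A `mode_table` holds the harmonic normal modes of one molecular complex:
#' one row per mode with its ordinal index, wavenumber (cm^-1), Raman
#' activity (A^4 amu^-1 convention; for transcribed reference tables this
#' column carries the printed "Raman strength"), a fragment attribution and a
#' free-text oscillation description. Rows are kept sorted by wavenumber.
#'
#' Fragment labels are canonicalised to one of `"ligand"`, `"residue"`,
#' `"joint"`, `"unknown"`. Molecule names used in reference tables are
#' accepted as synonyms: "Metabolite" and "Aspirin" map to `ligand`,
#' "Arginine" to `residue`, and a dash ("-" or en-dash) marks a `joint` mode
#' whose displacement spans both molecules.
#'
#' @param index integer ordinals, unique within the table.
#' @param wavenumber mode wavenumbers in cm^-1, strictly positive.
#' @param raman_activity nonnegative Raman activities (or printed strengths).
#' @param fragment fragment labels (canonicalised, see Details).
#' @param description free-text oscillation type.
#' @param complex_name name of the molecular complex.
#' @param provenance file or generator of origin.
#' @param displacements optional list (one element per mode, in input order)
#'   of n_atoms x 3 numeric matrices of mass-unweighted Cartesian
#'   displacements.
#' @return A data frame of class `mode_table` sorted by wavenumber, with
#'   attributes `complex_name`, `provenance` and (optionally) `displacements`.
#' @examples
#' mode_table(1:2, c(997, 450), c(0.07, 0.01), c("-", "joint"))
#' @export
mode_table <- function(index, wavenumber, raman_activity,
                       fragment = "unknown", description = "",
                       complex_name = "", provenance = NA_character_,
                       displacements = NULL) {
  n <- length(wavenumber)
  fragment <- canonical_fragment(rep_len(as.character(fragment), n))
  tbl <- data.frame(
    index = as.integer(index),
    wavenumber = as.numeric(wavenumber),
    raman_activity = as.numeric(raman_activity),
    fragment = fragment,
    description = rep_len(as.character(description), n),
    stringsAsFactors = FALSE
  )
  if (anyNA(tbl$index) || anyNA(tbl$wavenumber) || anyNA(tbl$raman_activity))
    stop("mode_table: missing values in index/wavenumber/raman_activity",
         call. = FALSE)
  if (any(tbl$wavenumber <= 0))
    stop("mode_table: wavenumbers must be > 0", call. = FALSE)
  if (any(tbl$raman_activity < 0))
    stop("mode_table: Raman activities must be >= 0", call. = FALSE)
  if (anyDuplicated(tbl$index))
    stop("mode_table: duplicate mode indices: ",
         paste(unique(tbl$index[duplicated(tbl$index)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(displacements)) {
    if (length(displacements) != n)
      stop("mode_table: need one displacement matrix per mode", call. = FALSE)
    displacements <- lapply(displacements, function(d) {
      d <- as.matrix(d)
      if (ncol(d) != 3) stop("displacements must be n_atoms x 3 matrices",
                             call. = FALSE)
      storage.mode(d) <- "double"
      d
    })
  }
  ord <- order(tbl$wavenumber, tbl$index)
  tbl <- tbl[ord, , drop = FALSE]
  rownames(tbl) <- NULL
  if (!is.null(displacements)) displacements <- displacements[ord]
  structure(tbl,
            complex_name = complex_name,
            provenance = provenance,
            displacements = displacements,
            class = c("mode_table", "data.frame"))
}

#' @export
`[.mode_table` <- function(x, ...) {
  # a subset is no longer a validated mode table; return a plain data frame
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.mode_table <- function(x, ...) {
  nm <- attr(x, "complex_name") %||% ""
  cat(sprintf("Vibrational mode table%s: %d modes",
              if (nzchar(nm)) paste0(" '", nm, "'") else "", nrow(x)))
  if (nrow(x))
    cat(sprintf(", %.0f-%.0f cm-1, %d joint",
                min(x$wavenumber), max(x$wavenumber),
                sum(x$fragment == "joint")))
  cat("\n")
  if (!is.null(attr(x, "displacements")))
    cat("Per-atom displacement vectors attached.\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more modes)\n", sep = "")
  invisible(x)
}

# canonical fragment vocabulary; dashes are the joint marker used by
# printed assignment tables
canonical_fragment <- function(x) {
  x0 <- trimws(x)
  key <- tolower(x0)
  out <- character(length(key))
  ligand_syn  <- c("ligand", "metabolite", "aspirin", "drug")
  residue_syn <- c("residue", "arginine", "receptor", "amino acid")
  joint_syn   <- c("joint", "-", "–", "—", "--")
  for (i in seq_along(key)) {
    out[i] <- if (key[i] %in% ligand_syn) "ligand"
    else if (key[i] %in% residue_syn) "residue"
    else if (key[i] %in% joint_syn) "joint"
    else if (key[i] %in% c("unknown", "")) "unknown"
    else stop("unrecognised fragment label: '", x0[i], "'", call. = FALSE)
  }
  out
}

#' Raw experimental spectrum
#'
#' Container for a two-column instrument export: (wavenumber, intensity)
#' pairs in arbitrary units. Samples are sorted by wavenumber; exactly
#' duplicated wavenumbers are averaged into a single sample so the stored
#' abscissa is strictly increasing.
#'
#' @param wavenumber numeric wavenumbers in cm^-1.
#' @param intensity numeric intensities, arbitrary units.
#' @param label sample label (e.g. therapy group).
#' @return A data frame of class `raw_spectrum` with columns `wavenumber`
#'   and `intensity`.
#' @export
raw_spectrum <- function(wavenumber, intensity, label = "") {
  if (length(wavenumber) != length(intensity))
    stop("raw_spectrum: column lengths differ", call. = FALSE)
  if (anyNA(wavenumber) || anyNA(intensity))
    stop("raw_spectrum: missing values", call. = FALSE)
  o <- order(wavenumber)
  wavenumber <- wavenumber[o]; intensity <- intensity[o]
  if (anyDuplicated(wavenumber)) {
    intensity <- as.numeric(tapply(intensity, wavenumber, mean))
    wavenumber <- sort(unique(wavenumber))
  }
  if (length(wavenumber) < 2L)
    stop("raw_spectrum: need at least 2 distinct samples", call. = FALSE)
  structure(data.frame(wavenumber = wavenumber, intensity = intensity),
            label = label,
            class = c("raw_spectrum", "data.frame"))
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("Raw spectrum '%s': %d samples, %.1f-%.1f cm-1\n",
              attr(x, "label"), nrow(x),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}
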