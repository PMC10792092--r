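#' Attribute a normal mode to a molecular fragment
#'
#' Quantifies how much of a mode's motion lives on each fragment (ligand
#' vs. receptor residue) using the standard mass-weighted squared
#' displacement participation measure: the fraction for fragment F is
#' sum_{atoms i in F} m_i |d_i|^2 / sum_i m_i |d_i|^2. A mode is labelled
#' with a fragment when that fragment's fraction reaches the threshold
#' `theta`; otherwise it is `joint`, i.e. its displacement genuinely spans
#' both molecules. Fractions are invariant under a common rescaling of the
#' displacement vectors.
#'
#' @param displacements n_atoms x 3 numeric matrix of Cartesian displacement
#'   vectors for the mode.
#' @param atom_map character vector of fragment labels, one per atom
#'   (canonicalised as in [mode_table()]).
#' @param masses atomic masses in amu, one per atom.
#' @param theta labelling threshold, in (0.5, 1]; default 0.8.
#' @param mode_index optional mode index recorded in the result.
#' @return An object of class `fragment_attribution`: a list with
#'   `mode_index`, `fractions` (named, summing to 1) and `label`.
#' @export
attribute_mode <- function(displacements, atom_map, masses, theta = 0.8,
                           mode_index = NA_integer_) {
  if (is.null(displacements))
    stop("attribute_mode: mode has no displacement vectors; ",
         "use table-provided fragment labels instead", call. = FALSE)
  d <- as.matrix(displacements)
  if (ncol(d) != 3)
    stop("attribute_mode: displacements must be n_atoms x 3", call. = FALSE)
  na <- nrow(d)
  if (length(atom_map) != na || length(masses) != na)
    stop("attribute_mode: atom_map and masses must label every atom",
         call. = FALSE)
  if (!(theta > 0.5 && theta <= 1))
    stop("attribute_mode: theta must lie in (0.5, 1]", call. = FALSE)
  frag <- canonical_fragment(atom_map)
  w <- masses * rowSums(d^2)
  tot <- sum(w)
  if (tot <= 0)
    stop("attribute_mode: zero total mass-weighted displacement",
         call. = FALSE)
  fr <- tapply(w, frag, sum) / tot
  fractions <- stats::setNames(as.numeric(fr), names(fr))
  fractions <- fractions[order(names(fractions))]
  top <- which(fractions >= theta)
  label <- if (length(top) == 1L) names(fractions)[top] else "joint"
  structure(list(mode_index = as.integer(mode_index),
                 fractions = fractions, label = label),
            class = "fragment_attribution")
}

#' @export
print.fragment_attribution <- function(x, ...) {
  cat(sprintf("Mode %s: %s (%s)\n",
              ifelse(is.na(x$mode_index), "?", x$mode_index), x$label,
              paste(sprintf("%s %.3f", names(x$fractions), x$fractions),
                    collapse = ", ")))
  invisible(x)
}

#' Fragment attributions from tabulated labels
#'
#' Passes the fragment labels recorded in a mode table through verbatim,
#' one `fragment_attribution` per mode. Joint rows yield label `joint` with
#' unknown participation fractions. When tabulated labels and
#' displacement-derived labels are both available the tabulated ones win.
#'
#' @param table a [mode_table] in which every mode carries a known fragment
#'   label (`ligand`, `residue` or `joint`).
#' @return A list of `fragment_attribution` objects, in table order.
#' @export
attribution_from_table <- function(table) {
  stopifnot(inherits(table, "mode_table"))
  if (any(table$fragment == "unknown"))
    stop("attribution_from_table: table contains modes with unknown ",
         "fragment labels (indices ",
         paste(table$index[table$fragment == "unknown"], collapse = ", "),
         ")", call. = FALSE)
  lapply(seq_len(nrow(table)), function(i) {
    lab <- table$fragment[i]
    fr <- if (lab == "joint") c(joint = NA_real_)
          else stats::setNames(1, lab)
    structure(list(mode_index = table$index[i], fractions = fr,
                   label = lab),
              class = "fragment_attribution")
  })
}
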