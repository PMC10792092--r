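#' Read normal modes from a frequency-job text log
#'
#' Parses the conventional plain-text frequency-block layout emitted by
#' quantum-chemistry harmonic frequency jobs: modes are printed in groups of
#' up to three, each block carrying a `Frequencies --` line, a
#' `Raman Activ --` line, and (optionally) per-atom displacement columns in
#' x/y/z triples under an `Atom AN ...` header. One [mode_table] row is
#' produced per harmonic mode, in file order, with mass-unweighted Cartesian
#' displacement vectors attached when present. Fragment labels are set to
#' `unknown`; use [attribute_mode()] with an atom-to-fragment map to assign
#' them.
#'
#' @param path path to the log file.
#' @param complex_name optional complex name; defaults to the file name.
#' @return A [mode_table] (sorted by wavenumber; the original file order is
#'   recoverable through the `index` column).
#' @export
read_freqjob_log <- function(path, complex_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  freq_at <- grep("^\\s*Frequencies\\s*--", lines)
  if (!length(freq_at))
    stop("no frequency block found in ", path, call. = FALSE)
  freqs <- numeric(0); acts <- numeric(0)
  displ <- list()
  for (start in freq_at) {
    f <- parse_block_numbers(lines[[start]])
    k <- length(f)
    # the matching Raman activity line within this block
    stop_at <- min(c(freq_at[freq_at > start] - 1L, length(lines)))
    block <- lines[start:stop_at]
    ra_rel <- grep("^\\s*Raman Activ\\s*--", block)
    if (!length(ra_rel))
      stop("frequency block at line ", start,
           " has no 'Raman Activ' line in ", path, call. = FALSE)
    a <- parse_block_numbers(block[[ra_rel[1L]]])
    if (length(a) != k)
      stop("mismatched column counts in block at line ", start, " of ", path,
           call. = FALSE)
    d <- parse_block_displacements(block, k, path, start)
    freqs <- c(freqs, f); acts <- c(acts, a)
    displ <- c(displ, d)
  }
  have_displ <- !all(vapply(displ, is.null, logical(1)))
  mode_table(seq_along(freqs), freqs, acts, fragment = "unknown",
             description = "",
             complex_name = complex_name %||% basename(path),
             provenance = path,
             displacements = if (have_displ) displ else NULL)
}

parse_block_numbers <- function(line) {
  value <- sub(".*--", "", line)
  fields <- strsplit(trimws(value), "\\s+")[[1L]]
  out <- suppressWarnings(as.numeric(fields))
  if (anyNA(out) || !length(out))
    stop("cannot parse numeric fields in line: ", trimws(line), call. = FALSE)
  out
}

# per-atom displacement rows: "atom AN x y z [x y z [x y z]]"
parse_block_displacements <- function(block, k, path, start) {
  hdr <- grep("^\\s*Atom\\s+AN\\b", block)
  if (!length(hdr)) return(rep(list(NULL), k))
  rows <- list()
  for (j in seq(hdr[1L] + 1L, length(block))) {
    if (j > length(block)) break
    fields <- strsplit(trimws(block[[j]]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals) || length(vals) < 2L + 3L) break
    if (length(vals) != 2L + 3L * k)
      stop("mismatched displacement columns at block starting line ", start,
           " of ", path, ": expected ", 2L + 3L * k, " fields, got ",
           length(vals), call. = FALSE)
    rows[[length(rows) + 1L]] <- vals[-(1:2)]
  }
  if (!length(rows)) return(rep(list(NULL), k))
  mat <- do.call(rbind, rows)   # n_atoms x 3k
  lapply(seq_len(k), function(m) mat[, (3L * m - 2L):(3L * m), drop = FALSE])
}

#' Write a mode table as a frequency-job text log
#'
#' Emits the three-modes-per-block layout read by [read_freqjob_log()],
#' including displacement columns when the table carries them. Mainly used
#' to exercise the parser on synthesized inputs.
#'
#' @param table a [mode_table].
#' @param path output path.
#' @param atomic_numbers integer atomic numbers for the displacement rows;
#'   defaults to carbon for every atom.
#' @return `path`, invisibly.
#' @export
write_freqjob_log <- function(table, path, atomic_numbers = NULL) {
  stopifnot(inherits(table, "mode_table"))
  displ <- attr(table, "displacements")
  n <- nrow(table)
  out <- c(" Harmonic frequencies (cm**-1), Raman scattering activities (A**4/AMU)")
  for (b in seq_len(ceiling(n / 3))) {
    sel <- ((b - 1L) * 3L + 1L):min(b * 3L, n)
    out <- c(out,
             paste0(" ", paste(sprintf("%10d", table$index[sel]),
                               collapse = "           ")),
             paste0(" Frequencies --",
                    paste(sprintf("%12.4f", table$wavenumber[sel]),
                          collapse = "   ")),
             paste0(" Raman Activ --",
                    paste(sprintf("%12.4f", table$raman_activity[sel]),
                          collapse = "   ")))
    if (!is.null(displ)) {
      dsel <- displ[sel]
      na <- nrow(dsel[[1L]])
      an <- atomic_numbers %||% rep(6L, na)
      out <- c(out, paste0("  Atom  AN",
                           paste(rep("      X      Y      Z", length(sel)),
                                 collapse = " ")))
      for (at in seq_len(na)) {
        vals <- unlist(lapply(dsel, function(d) d[at, ]))
        out <- c(out, paste0(sprintf("  %4d  %2d ", at, an[at]),
                             paste(sprintf("%7.2f", vals), collapse = " ")))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}
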