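#' Read a vibrational mode table from TSV
#'
#' Reads the package's tab-separated mode-table dialect: UTF-8, mandatory
#' header naming the columns `index`, `wavenumber`, `raman_activity`,
#' `fragment`, `description` (any order). The `fragment` column accepts the
#' canonical labels as well as molecule names and the dash marker used by
#' printed assignment tables ("-" or en-dash, meaning a joint mode).
#' Rows are re-sorted by wavenumber on read.
#'
#' @param path path to a TSV file.
#' @param complex_name optional complex name; defaults to the file name.
#' @return A [mode_table].
#' @seealso [write_mode_table_tsv()] for the inverse operation.
#' @export
read_mode_table_tsv <- function(path, complex_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty mode-table file: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  required <- c("index", "wavenumber", "raman_activity", "fragment",
                "description")
  if (!all(required %in% header))
    stop("mode-table header must name columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  col <- match(required, header)
  n <- length(lines) - 1L
  if (n == 0L)
    return(mode_table(integer(), numeric(), numeric(), character(),
                      character(),
                      complex_name = complex_name %||% basename(path),
                      provenance = path))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    # a trailing empty description is dropped by strsplit; restore it
    if (length(fields) == length(header) - 1L) fields <- c(fields, "")
    if (length(fields) < max(col))
      stop(sprintf("malformed row at line %d of %s: expected %d fields, got %d",
                   i + 1L, path, length(header), length(fields)),
           call. = FALSE)
    idx <- suppressWarnings(as.integer(fields[col[1L]]))
    wn <- suppressWarnings(as.numeric(fields[col[2L]]))
    act <- suppressWarnings(as.numeric(fields[col[3L]]))
    if (is.na(idx) || is.na(wn) || is.na(act))
      stop(sprintf("non-numeric value at line %d of %s", i + 1L, path),
           call. = FALSE)
    if (wn <= 0)
      stop(sprintf("non-positive wavenumber %g at line %d of %s",
                   wn, i + 1L, path), call. = FALSE)
    rows[[i]] <- list(index = idx, wavenumber = wn, raman_activity = act,
                      fragment = fields[col[4L]],
                      description = fields[col[5L]])
  }
  idx <- vapply(rows, `[[`, integer(1), "index")
  if (anyDuplicated(idx))
    stop("duplicate mode index in ", path, ": ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "), call. = FALSE)
  mode_table(idx,
             vapply(rows, `[[`, numeric(1), "wavenumber"),
             vapply(rows, `[[`, numeric(1), "raman_activity"),
             vapply(rows, `[[`, character(1), "fragment"),
             vapply(rows, `[[`, character(1), "description"),
             complex_name = complex_name %||% basename(path),
             provenance = path)
}

#' Write a vibrational mode table to TSV
#'
#' Inverse of [read_mode_table_tsv()]: writing then re-reading reproduces the
#' table field-for-field. Fragment labels are written with their canonical
#' spelling (`joint`, never a dash).
#'
#' @param table a [mode_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mode_table_tsv <- function(table, path) {
  stopifnot(inherits(table, "mode_table"))
  lines <- c(paste(c("index", "wavenumber", "raman_activity", "fragment",
                     "description"), collapse = "\t"),
             sprintf("%d\t%s\t%s\t%s\t%s",
                     table$index,
                     formatC(table$wavenumber, format = "g", digits = 15),
                     formatC(table$raman_activity, format = "g", digits = 15),
                     table$fragment, table$description))
  tryCatch(writeLines(lines, path, useBytes = TRUE),
           error = function(e) stop("cannot write mode table to ", path,
                                    ": ", conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a two-column experimental spectrum
#'
#' Reads a plain-text instrument export with two numeric columns
#' (wavenumber, intensity), whitespace- or comma-delimited. Lines starting
#' with `#` are ignored. Samples are sorted ascending and strictly
#' duplicated wavenumbers are averaged.
#'
#' @param path path to the text file.
#' @param label sample label; defaults to the file name.
#' @return A [raw_spectrum].
#' @export
read_spectrum_txt <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  wn <- numeric(0); it <- numeric(0)
  for (i in which(keep)) {
    fields <- strsplit(trimws(lines[[i]]), "[,;[:space:]]+")[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L)
      stop(sprintf("expected two columns at line %d of %s", i, path),
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals))
      stop(sprintf("non-numeric cell at line %d of %s", i, path),
           call. = FALSE)
    wn <- c(wn, vals[1L]); it <- c(it, vals[2L])
  }
  if (length(unique(wn)) < 2L)
    stop("fewer than 2 valid samples in ", path, call. = FALSE)
  raw_spectrum(wn, it, label = label %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
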