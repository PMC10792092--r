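#' Packaged reference fixtures
#'
#' The package ships plain-text transcriptions of the published reference
#' results for the two binding-site complexes: the clopidogrel thiol
#' metabolite H4 with arginine (P2Y12 binding site) and aspirin with
#' arginine (COX-1 binding site), plus the curated biomarker listing and
#' the aspirin selection override.
#'
#' @param name fixture file name; with no argument, lists available files.
#' @return `fixture_path` returns the absolute path to a packaged fixture.
#' @export
fixture_path <- function(name = NULL) {
  dir <- system.file("extdata", package = "vibraman", mustWork = TRUE)
  if (is.null(name)) return(list.files(dir))
  p <- file.path(dir, name)
  if (!file.exists(p)) stop("no packaged fixture named '", name, "'",
                            call. = FALSE)
  p
}

#' @rdname fixture_path
#' @param complex which binding-site complex to load.
#' @return `reference_mode_table` returns the transcribed [mode_table] for
#'   the requested complex.
#' @export
reference_mode_table <- function(complex = c("clopidogrel", "aspirin")) {
  complex <- match.arg(complex)
  file <- switch(complex,
                 clopidogrel = "clopidogrel_arginine_modes.tsv",
                 aspirin = "aspirin_arginine_modes.tsv")
  nm <- switch(complex,
               clopidogrel = "clopidogrel thiol metabolite H4 + arginine",
               aspirin = "aspirin + arginine")
  read_mode_table_tsv(fixture_path(file), complex_name = nm)
}

#' @rdname fixture_path
#' @return `reference_biomarkers` returns the curated biomarker listing as
#'   a data frame (`index`, `wavenumber`, `drug`, `description`).
#' @export
reference_biomarkers <- function() {
  utils::read.delim(fixture_path("biomarker_reference.tsv"),
                    stringsAsFactors = FALSE)
}

#' Read a biomarker selection override
#'
#' An override file is a TSV with columns `index` and `action`
#' (`include` or `exclude`), listing mode indices to force into or out of
#' the default joint-mode biomarker rule.
#'
#' @param path path to the override TSV; defaults to the packaged aspirin
#'   override.
#' @return A list with integer vectors `include` and `exclude`.
#' @export
read_override <- function(path = fixture_path("aspirin_biomarker_override.tsv")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("index", "action") %in% names(d)))
    stop("override file must have columns 'index' and 'action'",
         call. = FALSE)
  if (!all(d$action %in% c("include", "exclude")))
    stop("override actions must be 'include' or 'exclude'", call. = FALSE)
  list(include = as.integer(d$index[d$action == "include"]),
       exclude = as.integer(d$index[d$action == "exclude"]))
}

#' Materialise the packaged fixtures into a directory
#'
#' Verifies every packaged fixture against its recorded MD5 checksum and
#' copies the set (mode tables, biomarker listing, override) into `dir`.
#'
#' @param dir output directory; created if needed.
#' @return Invisibly, the copied file paths.
#' @export
make_paper_fixtures <- function(dir) {
  sums <- utils::read.delim(fixture_path("fixture_checksums.tsv"),
                            stringsAsFactors = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (i in seq_len(nrow(sums))) {
    src <- fixture_path(sums$file[i])
    got <- unname(tools::md5sum(src))
    if (!identical(got, sums$md5[i]))
      stop("packaging error: checksum mismatch for ", sums$file[i],
           " (expected ", sums$md5[i], ", got ", got, ")", call. = FALSE)
    dst <- file.path(dir, sums$file[i])
    file.copy(src, dst, overwrite = TRUE)
    out <- c(out, dst)
  }
  invisible(out)
}
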