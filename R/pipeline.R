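#' Build and validate a pipeline run configuration
#'
#' Collects every tunable of the pipeline in one validated object. Values
#' come from the built-in defaults, optionally overridden by a YAML file,
#' optionally overridden again by arguments in `...` (named as
#' `section.field`, e.g. `matching.tolerance = 8`). Every field is checked
#' against its module's contract before any stage runs, so an invalid
#' configuration is rejected up front.
#'
#' Sections and defaults:
#' \describe{
#'   \item{scaling}{`enabled` (FALSE: transcribed tables are already
#'     scaled), `a`, `b` — see [scaling_model()].}
#'   \item{intensity}{`nu0`, `temperature`, `f` — see [intensity_params()];
#'     `f: auto` normalises the simulated maximum to 100.}
#'   \item{lineshape}{`fwhm`, `grid_min`, `grid_max`, `grid_step` — see
#'     [lineshape_params()].}
#'   \item{simulate}{`mode`: `"fixture"` (tabulated strengths as heights)
#'     or `"activities"` (full conversion).}
#'   \item{preprocess}{`start`, `stop`, `step` of the analysis grid;
#'     `normalize`; `order` (`"average_then_normalize"` or
#'     `"normalize_then_average"`).}
#'   \item{matching}{`tolerance` (cm^-1), `prominence`.}
#'   \item{selection}{`start`, `stop` of the biomarker region; `override`
#'     (path to an override TSV, or empty for none).}
#'   \item{seed}{integer seed echoed into the manifest.}
#' }
#'
#' @param file optional YAML configuration file.
#' @param ... `section.field` overrides.
#' @return An object of class `run_config`.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list(
    scaling = list(enabled = FALSE, a = -0.0000083526, b = 0.98134),
    intensity = list(nu0 = 1e7 / 532, temperature = 298.15, f = "auto"),
    lineshape = list(fwhm = 5, grid_min = 400, grid_max = 1800,
                     grid_step = 0.5),
    simulate = list(mode = "fixture"),
    preprocess = list(start = 400, stop = 1800, step = 5, normalize = TRUE,
                      order = "average_then_normalize"),
    matching = list(tolerance = 10, prominence = 0.05),
    selection = list(start = 400, stop = 1800, override = ""),
    seed = 1L
  )
  if (!is.null(file)) {
    user <- yaml::read_yaml(file)
    for (sec in names(user)) {
      if (!sec %in% names(cfg))
        stop("run_config: unknown section '", sec, "'", call. = FALSE)
      if (is.list(cfg[[sec]])) {
        for (key in names(user[[sec]])) {
          if (!key %in% names(cfg[[sec]]))
            stop("run_config: unknown field '", sec, ".", key, "'",
                 call. = FALSE)
          cfg[[sec]][[key]] <- user[[sec]][[key]]
        }
      } else cfg[[sec]] <- user[[sec]]
    }
  }
  dots <- list(...)
  for (nm in names(dots)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 1L && parts %in% names(cfg) &&
        !is.list(cfg[[parts]])) {
      cfg[[parts]] <- dots[[nm]]
    } else if (length(parts) == 2L && parts[1L] %in% names(cfg) &&
               parts[2L] %in% names(cfg[[parts[1L]]])) {
      cfg[[parts[1L]]][[parts[2L]]] <- dots[[nm]]
    } else stop("run_config: unknown override '", nm, "'", call. = FALSE)
  }
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  scaling_model(cfg$scaling$a, cfg$scaling$b)
  f <- cfg$intensity$f
  intensity_params(cfg$intensity$nu0, cfg$intensity$temperature,
                   f = if (identical(f, "auto")) NA_real_ else f)
  lineshape_params(cfg$lineshape$fwhm, cfg$lineshape$grid_min,
                   cfg$lineshape$grid_max, cfg$lineshape$grid_step)
  if (!cfg$simulate$mode %in% c("fixture", "activities"))
    stop("run_config: simulate.mode must be 'fixture' or 'activities'",
         call. = FALSE)
  grid_spec(cfg$preprocess$start, cfg$preprocess$stop, cfg$preprocess$step)
  if (!cfg$preprocess$order %in% c("average_then_normalize",
                                   "normalize_then_average"))
    stop("run_config: unknown preprocess.order", call. = FALSE)
  if (cfg$matching$tolerance <= 0)
    stop("run_config: matching.tolerance must be > 0", call. = FALSE)
  if (cfg$matching$prominence <= 0 || cfg$matching$prominence >= 1)
    stop("run_config: matching.prominence must lie in (0, 1)", call. = FALSE)
  if (cfg$selection$start >= cfg$selection$stop)
    stop("run_config: selection region start must be < stop", call. = FALSE)
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Orchestrates every stage end-to-end: read the theoretical mode table,
#' simulate its Raman spectrum, preprocess each group's experimental
#' spectra (bin, average replicates, normalise), detect bands, match
#' biomarker-candidate modes to bands per group, select biomarkers, build
#' the overlay report, and write everything to `out_dir` as TSV plus a JSON
#' manifest. Outputs carry no timestamps: identical configuration and
#' inputs produce byte-identical outputs.
#'
#' @param config a [run_config].
#' @param mode_file path to a mode-table TSV.
#' @param spectrum_files named list: one character vector of raw spectrum
#'   paths (replicates) per sample group.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the manifest as a list. Side effect: files
#'   `simulated_spectrum.tsv`, `binned_<group>.tsv`, `bands_<group>.tsv`,
#'   `matches_<group>.tsv`, `biomarkers.tsv`, `overlay.tsv`,
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, mode_file, spectrum_files, out_dir) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  if (!file.exists(mode_file))
    stop("run_pipeline: mode file not found: ", mode_file, call. = FALSE)
  if (!is.list(spectrum_files) || is.null(names(spectrum_files)) ||
      any(!nzchar(names(spectrum_files))))
    stop("run_pipeline: spectrum_files must be a named list of file paths",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  stage <- function(name, expr) {
    stages <<- c(stages, name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  modes <- stage("read_modes", read_mode_table_tsv(mode_file))

  shape <- lineshape_params(config$lineshape$fwhm, config$lineshape$grid_min,
                            config$lineshape$grid_max,
                            config$lineshape$grid_step)
  theo <- stage("simulate", {
    if (config$simulate$mode == "fixture") fixture_spectrum(modes, shape)
    else {
      f <- config$intensity$f
      synthesize_spectrum(
        modes,
        scaling = if (isTRUE(config$scaling$enabled))
          scaling_model(config$scaling$a, config$scaling$b) else NULL,
        params = intensity_params(config$intensity$nu0,
                                  config$intensity$temperature,
                                  f = if (identical(f, "auto")) NA_real_
                                      else f),
        shape = shape)
    }
  })

  grid <- grid_spec(config$preprocess$start, config$preprocess$stop,
                    config$preprocess$step)
  binned <- stage("preprocess", {
    lapply(spectrum_files, function(files) {
      reps <- lapply(files, function(f) bin_spectrum(read_spectrum_txt(f),
                                                     grid))
      if (config$preprocess$order == "normalize_then_average" &&
          config$preprocess$normalize)
        reps <- lapply(reps, normalize_to_100)
      avg <- average_replicates(reps)
      if (config$preprocess$order == "average_then_normalize" &&
          config$preprocess$normalize)
        avg <- normalize_to_100(avg)
      avg
    })
  })

  bands <- stage("detect_bands",
                 lapply(binned, detect_bands,
                        prominence_fraction = config$matching$prominence))

  override <- if (!is.null(config$selection$override) &&
                  !is.na(config$selection$override) &&
                  nzchar(config$selection$override))
    read_override(config$selection$override)
  else list(include = integer(), exclude = integer())
  region <- grid_spec(config$selection$start, config$selection$stop,
                      config$preprocess$step)
  candidates <- stage("select_biomarkers",
                      select_biomarkers(modes, region = region,
                                        include = override$include,
                                        exclude = override$exclude))

  cand_modes <- mode_table(candidates$index, candidates$wavenumber,
                           candidates$raman_activity, candidates$fragment,
                           candidates$description)
  matches <- stage("match", lapply(bands, function(b)
    match_modes_to_bands(cand_modes, b,
                         tolerance = config$matching$tolerance)))

  overlay <- stage("overlay", overlay_report(modes, binned, candidates))

  # --- write outputs ---------------------------------------------------
  write_tsv <- function(d, file) {
    utils::write.table(as.data.frame(d), file.path(out_dir, file),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    file
  }
  outputs <- c(write_tsv(theo, "simulated_spectrum.tsv"),
               unlist(lapply(names(binned), function(g)
                 write_tsv(binned[[g]], paste0("binned_", g, ".tsv")))),
               unlist(lapply(names(bands), function(g)
                 write_tsv(data.frame(band_wavenumber = bands[[g]]),
                           paste0("bands_", g, ".tsv")))),
               unlist(lapply(names(matches), function(g)
                 write_tsv(matches[[g]], paste0("matches_", g, ".tsv")))),
               write_tsv(candidates, "biomarkers.tsv"),
               write_tsv(overlay, "overlay.tsv"))

  manifest <- list(
    package = "vibraman",
    version = as.character(utils::packageVersion("vibraman")),
    seed = config$seed,
    config = unclass(config),
    inputs = list(
      mode_file = list(path = mode_file,
                       md5 = unname(tools::md5sum(mode_file))),
      spectra = lapply(spectrum_files, function(files)
        lapply(files, function(f)
          list(path = f, md5 = unname(tools::md5sum(f)))))),
    stages = stages,
    outputs = lapply(stats::setNames(outputs, outputs), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(manifest)
}
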