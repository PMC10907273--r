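#' Load a simulation configuration from YAML or JSON
#'
#' Reads a configuration file with optional blocks `parameters` (rate
#' constants, [rate_parameters()] field names), `initial_conditions`
#' (species concentrations), `clamped` (species held constant), `tz_grid`
#' and `simulation` (`t_end`, `rtol`, `atol`, `rate_window`). Concentrations
#' may be bare numbers (micromolar) or strings with a unit (`"1 mM"`,
#' `"50 nM"`, `"0.04 uM"`); everything is normalised to micromolar and
#' seconds on read. Missing fields fall back to the packaged defaults (the
#' published rate constants and the in vitro initial conditions) with a
#' notice; unknown keys are an error.
#'
#' An empty file therefore yields the full default protocol. A copy of the
#' default configuration ships as
#' `system.file("extdata", "table1_defaults.yaml", package = "tzpgk")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param quiet Suppress the defaults-filled notice.
#' @return A list with elements `params` ([rate_parameters()]), `config`
#'   ([sim_config()]) and `clamped` (character vector), ready for
#'   `pgk_network(params, clamped = clamped)`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- c("parameters", "initial_conditions", "clamped", "tz_grid",
             "simulation")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  par_in <- raw$parameters %||% list()
  bad <- setdiff(names(par_in), names(formals(rate_parameters)))
  if (length(bad)) {
    stop("unknown rate parameter(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(par_in)) {
    if (!is.numeric(par_in[[nm]]) || par_in[[nm]] < 0) {
      stop("rate parameter '", nm, "' must be a non-negative number",
           call. = FALSE)
    }
  }
  params <- do.call(rate_parameters, par_in)

  ic_in <- raw$initial_conditions %||% list()
  ic_map <- c(enzyme_total = "enzyme_total", E = "enzyme_total",
              ADP = "adp", BPG = "bpg", ATP = "atp", PG = "pg", TZ = "tz")
  bad <- setdiff(names(ic_in), names(ic_map))
  if (length(bad)) {
    stop("unknown initial-condition key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ic <- lapply(ic_in, parse_concentration)
  names(ic) <- unname(ic_map[names(ic_in)])

  sim_in <- raw$simulation %||% list()
  bad <- setdiff(names(sim_in), c("t_end", "rtol", "atol", "rate_window"))
  if (length(bad)) {
    stop("unknown simulation key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  cfg_args <- c(ic, sim_in)
  if (!is.null(raw$tz_grid)) {
    cfg_args$tz_grid <- vapply(raw$tz_grid, parse_concentration, numeric(1))
  }
  config <- do.call(sim_config, cfg_args)

  clamped <- raw$clamped %||% "BPG"

  defaulted <- c(
    if (!length(par_in)) "parameters",
    if (!length(ic_in)) "initial_conditions",
    if (is.null(raw$clamped)) "clamped",
    if (is.null(raw$tz_grid)) "tz_grid",
    if (!length(sim_in)) "simulation"
  )
  if (length(defaulted) && !quiet) {
    message("config: using packaged defaults for ",
            paste(defaulted, collapse = ", "))
  }
  list(params = params, config = config, clamped = clamped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "1 mM" / "50 nM" / "0.04 uM" / bare number -> micromolar.
parse_concentration <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L) {
    stop("concentration must be a number or a 'value unit' string",
         call. = FALSE)
  }
  m <- regmatches(x, regexec(
    "^\\s*([0-9.eE+-]+)\\s*(nM|uM|µM|mM|M)\\s*$", x))[[1]]
  if (length(m) != 3L) {
    stop("cannot parse concentration: '", x,
         "' (expected e.g. '80 uM', '1 mM', '50 nM')", call. = FALSE)
  }
  val <- as.numeric(m[2])
  if (is.na(val)) stop("cannot parse concentration: '", x, "'", call. = FALSE)
  val * switch(m[3], nM = 1e-3, uM = 1, "µM" = 1, mM = 1e3, M = 1e6)
}

# Deterministic numeric formatting used by all CSV writers.
format_cell <- function(x) {
  if (is.numeric(x)) {
    out <- sprintf("%.12g", x)
    out[is.na(x)] <- ""
    out
  } else {
    as.character(x)
  }
}

#' Write result tables as deterministic CSV files with a run manifest
#'
#' Writes each table as an RFC-4180 CSV with a fixed column order and fixed
#' numeric formatting (12 significant digits), so identical results produce
#' byte-identical files. A JSON manifest recording the package version,
#' solver settings (when supplied) and an MD5 checksum of every file is
#' written alongside.
#'
#' @param tables A named list of data frames, or a single data frame (then
#'   `name` supplies its file stem).
#' @param out_dir Output directory, created if needed.
#' @param name File stem used when `tables` is a single data frame.
#' @param config Optional [sim_config()] recorded in the manifest.
#' @param manifest Write `manifest.json` (default `TRUE`).
#' @return Invisibly, the paths of the files written.
#' @export
write_tables <- function(tables, out_dir, name = "result", config = NULL,
                         manifest = TRUE) {
  if (is.data.frame(tables)) tables <- setNames(list(tables), name)
  if (!length(names(tables)) || any(names(tables) == "")) {
    stop("tables must be named", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    path <- file.path(out_dir, paste0(nm, ".csv"))
    formatted <- as.data.frame(lapply(df, format_cell),
                               stringsAsFactors = FALSE, check.names = FALSE,
                               col.names = names(df))
    if (nrow(df) == 0) {
      formatted <- as.data.frame(setNames(
        rep(list(character(0)), ncol(df)), names(df)), check.names = FALSE)
    }
    utils::write.csv(formatted, path, row.names = FALSE, quote = FALSE,
                     eol = "\r\n")
    paths <- c(paths, path)
  }
  if (manifest) {
    man_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(run_manifest(paths, config = config), man_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, man_path)
  }
  invisible(paths)
}

#' Build a run manifest for a set of output files
#'
#' @param paths Files to checksum.
#' @param config Optional [sim_config()] whose resolved settings are
#'   recorded.
#' @return A list: package version, R version, timestamp, configuration and
#'   per-file MD5 checksums.
#' @export
run_manifest <- function(paths = character(0), config = NULL) {
  list(
    package = "tzpgk",
    version = as.character(utils::packageVersion("tzpgk")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (!is.null(config)) unclass(config),
    files = if (length(paths)) {
      lapply(setNames(as.list(unname(tools::md5sum(paths))), basename(paths)),
             identity)
    } else {
      NULL
    }
  )
}
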