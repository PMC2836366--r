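# Configuration keys, their quoted units and conversion to SI. The config
# dialect mirrors how the parameters are conventionally quoted (S/m, As/Vm,
# um, nm, tesla, kHz, mm), so a reader can copy values straight from a
# parameter table; everything is converted to SI on read.
config_keys <- function() {
  p <- parameter_ranges()
  data.frame(
    key = c(p$name, "C"),
    unit = c(p$unit, "mm"),
    si = c(p$si, 1e-3),
    standard = c(p$standard, 10),
    stringsAsFactors = FALSE
  )
}

validate_config_value <- function(key, value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("config key '", key, "' must be a single finite number")
  neg_ok <- FALSE                    # all model parameters are nonnegative
  if (!neg_ok && value < 0)
    stop("config key '", key, "' must be >= 0 (got ", value, ")")
  if (grepl("^epsilon_", key) && value <= 0)
    stop("config key '", key, "' must be > 0 (got ", value, ")")
  if (key %in% c("R", "D", "r", "d") && value <= 0)
    stop("config key '", key, "' must be > 0 (got ", value, ")")
  invisible(TRUE)
}

#' Read and write model configurations
#'
#' A configuration is a flat key-to-number mapping in JSON or YAML (chosen
#' by file extension) using the conventional parameter names and units:
#' `sigma_0`..`sigma_4` (S/m), `epsilon_0`..`epsilon_4` (As/Vm), `R`, `r`
#' (um), `D`, `d` (nm), `B0` (T), `f` (kHz), `C` (mm). Missing keys default
#' to the standard values; unknown keys are rejected. The resolved
#' configuration is validated into a cell + stimulus pair, so out-of-range
#' values fail with the offending key in the message.
#'
#' @param path File path; `.json`, `.yaml` or `.yml`.
#' @return `read_config()`: an object of class `run_config` with fields
#'   `values` (named vector, quoted units), `cell`, `stimulus`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- switch(tolower(tools::file_ext(path)),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = , yml = yaml::read_yaml(path),
                stop("unsupported config extension '",
                     tools::file_ext(path), "' (use .json, .yaml or .yml)"))
  if (!is.list(raw) && !is.numeric(raw)) stop("malformed config: ", path)
  raw <- as.list(raw)
  as_run_config(raw)
}

#' @param values Named list or vector of configuration values in the quoted
#'   units.
#' @rdname read_config
#' @export
as_run_config <- function(values = list()) {
  keys <- config_keys()
  values <- as.list(values)
  unknown <- setdiff(names(values), keys$key)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known keys: ", paste(keys$key, collapse = ", "))
  v <- stats::setNames(keys$standard, keys$key)
  for (nm in names(values)) {
    validate_config_value(nm, values[[nm]])
    v[[nm]] <- as.numeric(values[[nm]])
  }
  si <- stats::setNames(v * keys$si, keys$key)
  cell <- tryCatch(
    two_shell_cell(
      media = lapply(0:4, function(i)
        dielectric_medium(si[[paste0("sigma_", i)]],
                          si[[paste0("epsilon_", i)]])),
      cell_shell = shell_geometry(si[["R"]], si[["D"]]),
      organelle_shell = shell_geometry(si[["r"]], si[["d"]])
    ),
    error = function(e) stop("invalid configuration: ", conditionMessage(e)))
  stimulus <- magnetic_stimulus(si[["B0"]], si[["f"]], si[["C"]])
  structure(list(values = v, cell = cell, stimulus = stimulus),
            class = "run_config")
}

#' @param config A `run_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- as.list(config$values)
  switch(tolower(tools::file_ext(path)),
         json = jsonlite::write_json(vals, path, auto_unbox = TRUE,
                                     digits = I(17)),
         yaml = , yml = yaml::write_yaml(
           lapply(vals, function(x) as.numeric(format(x, digits = 17))),
           path),
         stop("unsupported config extension '", tools::file_ext(path), "'"))
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  keys <- config_keys()
  cat("<run_config>\n")
  for (i in seq_len(nrow(keys)))
    cat(sprintf("  %-10s %g %s\n", keys$key[i], x$values[[keys$key[i]]],
                keys$unit[i]))
  invisible(x)
}

# Serialize a data.frame with full float precision.
format_full <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Write and read sweep tables
#'
#' Sweep results serialize to RFC-4180 CSV with a `#`-prefixed metadata
#' header (scenario label, package version, and the full resolved parameter
#' set in SI units), one row per grid point, floats at full precision; or to
#' a JSON document mirroring the same content. `read_sweep()` restores the
#' CSV including its metadata attributes.
#'
#' @param x A `sweep_result`.
#' @param path Destination; `.csv` or `.json`.
#' @export
write_sweep <- function(x, path) {
  stopifnot(inherits(x, "sweep_result"))
  meta <- list(scenario = attr(x, "scenario"), version = attr(x, "version"),
               axes = attr(x, "axes"),
               parameters = as.list(attr(x, "parameters")))
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(list(metadata = meta, rows = as.data.frame(x)),
                         path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# scenario: %s", meta$scenario),
    sprintf("# version: %s", meta$version),
    sprintf("# axes: %s", paste(meta$axes, collapse = ",")),
    sprintf("# parameter %s: %.17g", names(meta$parameters),
            unlist(meta$parameters))
  ), con)
  utils::write.csv(format_full(as.data.frame(x)), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  grab <- function(what) sub(paste0("^# ", what, ": "), "",
                             grep(paste0("^# ", what, ":"), meta_lines,
                                  value = TRUE))
  pl <- grep("^# parameter ", meta_lines, value = TRUE)
  pm <- regmatches(pl, regexec("^# parameter ([^:]+): (.*)$", pl))
  params <- stats::setNames(vapply(pm, function(m) as.numeric(m[3]),
                                   numeric(1)),
                            vapply(pm, `[[`, character(1), 2))
  new_sweep_result(df, grab("scenario"), params,
                   strsplit(grab("axes"), ",")[[1]])
}

#' Write a surface polarization map
#'
#' @param x A `surface_map`.
#' @param path Destination; `.csv` or `.json`.
#' @export
write_map <- function(x, path) {
  stopifnot(inherits(x, "surface_map"))
  meta <- list(membrane = attr(x, "membrane"),
               time_phase = attr(x, "time_phase"),
               parameters = as.list(attr(x, "parameters")))
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(list(metadata = meta, rows = as.data.frame(x)),
                         path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# membrane: %s", meta$membrane),
    sprintf("# time_phase_rad: %.17g", meta$time_phase),
    sprintf("# parameter %s: %.17g", names(meta$parameters),
            unlist(meta$parameters))
  ), con)
  utils::write.csv(format_full(as.data.frame(x)), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
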