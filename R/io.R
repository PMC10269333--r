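#' Write an energy time series to delimited text
#'
#' Tab-separated table with a header row; values are serialized with 17
#' significant digits so that a write/read round trip reproduces them
#' bit-exactly. A `#`-prefixed metadata line records the state labels, the
#' offsets, RT, lambda and the acceleration parameters.
#'
#' @param ts An `aeds_energy_series`.
#' @param path Output path.
#' @param force Overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_energy_series <- function(ts, path, force = FALSE) {
  if (file.exists(path) && !force) {
    abort(sprintf("`%s` exists; use `force = TRUE` to overwrite.", path),
          class = "aedskit_io_error")
  }
  accel <- attr(ts, "accel")
  meta <- sprintf(
    "# aedskit energy series | labels=%s | offsets=%s | RT=%.17g | lambda=%.17g | e_min=%s | e_max=%s",
    paste(series_labels(ts), collapse = ","),
    paste(sprintf("%.17g", attr(ts, "offsets")), collapse = ","),
    attr(ts, "RT"), attr(ts, "lambda"),
    if (is.null(accel)) "NA" else sprintf("%.17g", accel$e_min),
    if (is.null(accel)) "NA" else sprintf("%.17g", accel$e_max))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(names(ts), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(ts, function(col) sprintf("%.17g", col)),
                           sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read an energy time series from delimited text
#'
#' Parses the format written by [write_energy_series()], validates the header
#' (the per-state energy columns and `E_R`, `E_R_star` must be present; extra
#' columns are accepted with a warning for forward compatibility) and runs the
#' self-consistency check that `E_R` is recomputable from the stored end-state
#' energies and offsets.
#'
#' @param path Input path.
#' @param validate Run [validate_energy_series()] (default `TRUE`).
#' @return An `aeds_energy_series`.
#' @export
read_energy_series <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: `%s`.", path), class = "aedskit_io_error")
  }
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !startsWith(lines[1], "# aedskit energy series")) {
    abort(sprintf("Malformed header in `%s` (line 1).", path),
          class = "aedskit_parse_error")
  }
  meta <- strsplit(lines[1], " | ", fixed = TRUE)[[1]]
  grab <- function(key) {
    hit <- grep(paste0("^", key, "="), meta, value = TRUE)
    if (!length(hit)) {
      abort(sprintf("Missing `%s` in the metadata line of `%s`.", key, path),
            class = "aedskit_parse_error")
    }
    sub(paste0("^", key, "="), "", hit[1])
  }
  labels <- strsplit(grab("labels"), ",", fixed = TRUE)[[1]]
  offsets <- as.numeric(strsplit(grab("offsets"), ",", fixed = TRUE)[[1]])
  RT <- as.numeric(grab("RT"))
  lambda <- as.numeric(grab("lambda"))
  e_min <- suppressWarnings(as.numeric(grab("e_min")))
  e_max <- suppressWarnings(as.numeric(grab("e_max")))
  accel <- if (is.finite(e_min) && is.finite(e_max)) accel_params(e_min, e_max)

  ## read.table parses doubles with correctly rounded strtod, so a
  ## 17-significant-digit round trip is bit-exact
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "", colClasses = "character"),
    error = function(e) {
      abort(sprintf("Cannot parse `%s`: %s", path, conditionMessage(e)),
            class = "aedskit_parse_error")
    })
  required <- c("time_ps", "lambda", paste0("H_", labels), "E_R", "E_R_star")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(sprintf("`%s` is missing required column(s): %s.", path,
                  paste(missing_cols, collapse = ", ")),
          class = "aedskit_parse_error")
  }
  known <- c(required, "V_restraint", "dHs_dl", paste0("dH_", labels, "_dl"),
             "dHdl", "x", "y")
  extra <- setdiff(names(tab), known)
  if (length(extra)) {
    warn(sprintf("Ignoring unknown column(s) in `%s`: %s.", path,
                 paste(extra, collapse = ", ")))
  }
  for (col in names(tab)) {
    num <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(num))
    if (length(bad) && col %in% required) {
      abort(sprintf("Malformed row at data line %d of `%s` (column %s).",
                    bad[1], path, col),
            class = "aedskit_parse_error")
    }
    tab[[col]] <- num
  }
  ts <- new_energy_series(tibble::as_tibble(tab), labels = labels,
                          offsets = offsets, RT = RT, accel = accel,
                          lambda = lambda)
  if (validate) validate_energy_series(ts, tol = 1e-9)
  ts
}

run_config_schema <- list(
  system = c("pocket", "bulk", "harmonic_pair"),
  sampling_commands = c("search", "probe", "ti"))

#' Parse and validate a run configuration
#'
#' YAML key-value document describing a run: system selection and parameters,
#' reference definition, acceleration parameters (or `"search"`), protocol,
#' seed and output paths. Unknown keys are rejected; defaults (temperature
#' 300 K, weights-method occupancy, trapezoidal integration, 41-window
#' protocol) are filled in and echoed.
#'
#' @param path Path to a YAML document.
#' @param command The subcommand the config is for; a `seed` is mandatory for
#'   any sampling command (`search`, `probe`, `ti`).
#' @return A validated named list (class `aeds_run_config`).
#' @export
parse_config <- function(path, command = "probe") {
  if (!file.exists(path)) {
    abort(sprintf("No such config file: `%s`.", path),
          class = "aedskit_io_error")
  }
  cfg <- yaml::read_yaml(path)
  allowed <- c("system", "g_a", "g_b", "well_width", "restraint_k", "ligand",
               "temperature", "e_min", "e_max", "offsets", "seed", "n_steps",
               "save_interval", "burn_in", "step_size", "mode", "n_windows",
               "n_equil", "direction", "lambdas", "out", "k", "d", "delta_e")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")),
          class = "aedskit_schema_error")
  }
  defaults <- list(system = "pocket", temperature = 300, mode = "metropolis",
                   n_steps = 1e5, save_interval = 10L, burn_in = 2000L,
                   step_size = 0.1, n_windows = 41L, n_equil = 2000L,
                   direction = "forward", g_a = 15, g_b = 2)
  cfg <- modifyList(defaults, cfg)
  if (command %in% run_config_schema$sampling_commands && is.null(cfg$seed)) {
    abort(sprintf("A `seed` is mandatory for the `%s` command.", command),
          class = "aedskit_schema_error")
  }
  if (!is.null(cfg$lambdas)) {
    if (anyDuplicated(cfg$lambdas) || is.unsorted(cfg$lambdas)) {
      abort("`lambdas` must be sorted and unique.",
            class = "aedskit_schema_error")
    }
  }
  if (!cfg$system %in% run_config_schema$system) {
    abort(sprintf("Unknown system `%s`.", cfg$system),
          class = "aedskit_schema_error")
  }
  structure(cfg, class = "aeds_run_config")
}

## Build (system, reference) from a validated config.
config_build_system <- function(cfg) {
  accel <- if (!is.null(cfg$e_min) && !is.null(cfg$e_max))
    accel_params(cfg$e_min, cfg$e_max)
  switch(cfg$system,
    pocket = make_pocket_probe_system(
      cfg$g_a, cfg$g_b,
      well_width = cfg$well_width %||% 0.12,
      restraint_k = cfg$restraint_k %||% 200,
      ligand = cfg$ligand %||% c(400, 0.3, 25),
      temperature = cfg$temperature, accel = accel,
      offsets = if (!is.null(cfg$offsets)) as.list(cfg$offsets)),
    bulk = make_bulk_probe_system(
      well_width = cfg$well_width %||% 0.12,
      restraint_k = cfg$restraint_k %||% 200,
      temperature = cfg$temperature, accel = accel),
    harmonic_pair = {
      pair <- make_displaced_harmonic_pair(cfg$k %||% 1000, cfg$d %||% 0.5,
                                           cfg$delta_e %||% 4)
      list(system = pair$system,
           reference = toy_reference(pair$system,
             offsets = if (!is.null(cfg$offsets)) as.list(cfg$offsets),
             temperature = cfg$temperature, accel = accel))
    })
}
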