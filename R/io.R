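# Flat key-value configuration (YAML), one config = one scenario run.
CONFIG_DEFAULTS <- list(
  n = 200L,              # grid side length (cells)
  sigma = 40,            # plume spread (cells)
  u = 5,                 # wind speed (m/s)
  H = 100,               # boundary-layer height (m)
  k = 0,                 # first-order decay rate (1/s)
  cell_length = 100,     # physical cell size (m)
  center_peak_density = 100,  # persons/cell at the city center
  source_x0 = NA_real_,  # default: floor(0.75 n)
  source_y0 = NA_real_,  # default: floor(0.5 n)
  E0 = 10,               # initial emission rate (g/s)
  n_steps = 1000L,       # scenario steps
  scenario = "reduce_E"  # scenario kind
)

validate_config <- function(cfg) {
  num_pos <- c("sigma", "u", "H", "cell_length", "center_peak_density", "E0")
  for (key in num_pos) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_validation(sprintf("config key '%s' must be a single positive number", key))
  }
  for (key in c("n", "n_steps")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 3 || v != round(v))
      stop_validation(sprintf("config key '%s' must be an integer >= 3", key))
    cfg[[key]] <- as.integer(v)
  }
  if (!is.numeric(cfg$k) || length(cfg$k) != 1L || !is.finite(cfg$k) || cfg$k < 0)
    stop_validation("config key 'k' must be a single number >= 0")
  for (key in c("source_x0", "source_y0")) {
    v <- cfg[[key]]
    if (!(length(v) == 1L && (is.na(v) || (is.numeric(v) && is.finite(v)))))
      stop_validation(sprintf("config key '%s' must be a number or omitted", key))
  }
  if (!is.character(cfg$scenario) || !cfg$scenario %in% SCENARIO_KINDS)
    stop_validation(sprintf("config key 'scenario' must be one of %s",
                            paste(SCENARIO_KINDS, collapse = ", ")))
  cfg
}

#' Load a run configuration
#'
#' Reads a flat YAML key-value file describing one scenario run; missing
#' keys take the documented defaults (the illustrative-model values: n =
#' 200, u = 5 m/s, H = 100 m, E0 = 10 g/s, 1000 steps). Unknown keys are
#' rejected, and invalid values raise a validation error naming the key.
#'
#' @param path Path to a YAML file; an empty file yields all defaults.
#' @return Object of class `"run_config"` (a named list).
#' @seealso [write_config()], [config_city()], [config_params()],
#'   [config_scenario()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  # keep bare "n"/"y" keys as strings instead of YAML 1.1 booleans
  keep_key <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
  user <- yaml::read_yaml(path, handlers = keep_key)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop_parse(sprintf("config file is not a key-value document: %s", path))
  unknown <- setdiff(names(user), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0L)
    stop_validation(sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(CONFIG_DEFAULTS, user)
  cfg <- validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration
#'
#' @param config A `"run_config"` (or plain named list of known keys).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, function(v) length(v) == 1L && is.na(v), logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname load_config
#' @return `default_config()`: the all-defaults `"run_config"`.
#' @export
default_config <- function() {
  cfg <- validate_config(CONFIG_DEFAULTS)
  class(cfg) <- "run_config"
  cfg
}

#' Materialize model objects from a configuration
#'
#' `config_city()`, `config_params()` and `config_scenario()` build the
#' [build_city()] grid, [dispersion_params()] and [make_scenario()] spec a
#' configuration describes.
#'
#' @param config A `"run_config"` from [load_config()] or [default_config()].
#' @name config_objects
NULL

#' @rdname config_objects
#' @export
config_city <- function(config) {
  build_city(n = config$n, center_peak_density = config$center_peak_density)
}

#' @rdname config_objects
#' @export
config_params <- function(config) {
  dispersion_params(n = config$n, wind_speed = config$u,
                    boundary_height = config$H, sigma = config$sigma,
                    decay_rate = config$k, cell_length = config$cell_length)
}

#' @rdname config_objects
#' @param city,params Optionally pre-built objects (rebuilt from `config`
#'   when omitted).
#' @export
config_scenario <- function(config, city = config_city(config),
                            params = config_params(config)) {
  start <- c(config$source_x0, config$source_y0)
  if (anyNA(start)) start <- NULL
  make_scenario(config$scenario, city, params, n_steps = config$n_steps,
                initial_emissions = config$E0, source_start = start)
}

# full-precision float rendering that round-trips exactly
fmt_num <- function(x) sprintf("%.17g", x)

#' Read and write gridded rasters as CSV
#'
#' Plain-text raster format for user-supplied population or concentration
#' grids: a header line `nrow,ncol` followed by one comma-separated line
#' per row (row-major), values at full round-trip precision.
#'
#' @param mat Numeric matrix.
#' @param path File path.
#' @return `read_raster_csv()` returns the numeric matrix;
#'   `write_raster_csv()` returns `path` invisibly.
#' @export
write_raster_csv <- function(mat, path) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop_validation("'mat' must be a numeric matrix")
  lines <- c(paste(nrow(mat), ncol(mat), sep = ","),
             apply(mat, 1L, function(row) paste(fmt_num(row), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("raster file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2L) stop_parse(sprintf("%s: expected a header and data rows", path))
  hdr <- suppressWarnings(as.numeric(strsplit(lines[1L], ",", fixed = TRUE)[[1L]]))
  if (length(hdr) != 2L || anyNA(hdr) || any(hdr < 1) || any(hdr != round(hdr)))
    stop_parse(sprintf("%s: line 1: header must be 'nrow,ncol'", path))
  nr <- hdr[1L]; nc <- hdr[2L]
  if (length(lines) - 1L != nr)
    stop_parse(sprintf("%s: expected %d data rows, found %d", path, nr, length(lines) - 1L))
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    vals <- suppressWarnings(as.numeric(strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]]))
    if (length(vals) != nc || anyNA(vals))
      stop_parse(sprintf("%s: line %d: expected %d numeric values", path, i + 1L, nc))
    out[i, ] <- vals
  }
  out
}

RESULT_COLUMNS <- c("step", "group", "E", "XF_bar", "D_R", "D_A",
                    "PWM_group", "PWM_total")

#' Read and write scenario results as CSV
#'
#' One row per step and group with the full disparity decomposition, at
#' full floating-point precision so that write-then-read round-trips
#' losslessly and repeated runs are byte-identical. Columns: `step`,
#' `group`, `E`, `XF_bar`, `D_R`, `D_A`, `PWM_group`, `PWM_total`.
#'
#' @param result A [run_scenario()] result (or an object read back by
#'   `read_result_csv()`).
#' @param path File path.
#' @return `read_result_csv()` returns a `"scenario_result"` (with a
#'   minimal spec carrying the step count and starting emissions);
#'   `write_result_csv()` returns `path` invisibly.
#' @export
write_result_csv <- function(result, path) {
  stopifnot(inherits(result, "scenario_result"))
  r <- result$records
  lines <- c(paste(RESULT_COLUMNS, collapse = ","),
             paste(r$step, r$group, fmt_num(r$E), fmt_num(r$XF_bar),
                   fmt_num(r$D_R), fmt_num(r$D_A), fmt_num(r$PWM_group),
                   fmt_num(r$PWM_total), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("result file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2L) stop_parse(sprintf("%s: expected a header and data rows", path))
  hdr <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(hdr, RESULT_COLUMNS))
    stop_parse(sprintf("%s: line 1: expected columns '%s'",
                       path, paste(RESULT_COLUMNS, collapse = ",")))
  n_row <- length(lines) - 1L
  rec <- list(step = integer(n_row), group = character(n_row),
              E = numeric(n_row), XF_bar = numeric(n_row),
              D_R = numeric(n_row), D_A = numeric(n_row),
              PWM_group = numeric(n_row), PWM_total = numeric(n_row))
  for (i in seq_len(n_row)) {
    parts <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]]
    if (length(parts) != length(RESULT_COLUMNS))
      stop_parse(sprintf("%s: line %d: expected %d fields, found %d",
                         path, i + 1L, length(RESULT_COLUMNS), length(parts)))
    nums <- suppressWarnings(as.numeric(parts[-2L]))
    if (anyNA(nums) || parts[1L] != as.character(as.integer(nums[1L])))
      stop_parse(sprintf("%s: line %d: malformed numeric field", path, i + 1L))
    rec$step[i] <- as.integer(nums[1L]); rec$group[i] <- parts[2L]
    rec$E[i] <- nums[2L]; rec$XF_bar[i] <- nums[3L]; rec$D_R[i] <- nums[4L]
    rec$D_A[i] <- nums[5L]; rec$PWM_group[i] <- nums[6L]; rec$PWM_total[i] <- nums[7L]
  }
  records <- as.data.frame(rec, stringsAsFactors = FALSE)
  n_steps <- max(records$step) + 1L
  e0 <- records$E[records$step == 0L][1L]
  structure(list(records = records,
                 emission_fraction_reduced = (seq_len(n_steps) - 1L) / n_steps,
                 spec = structure(list(kind = NA_character_, n_steps = n_steps,
                                       initial_emissions = e0,
                                       source_start = NULL, trajectory = NULL),
                                  class = "scenario_spec"),
                 params = NULL),
            class = "scenario_result")
}

#' Small city grid for tests and examples
#'
#' The same deterministic construction as [build_city()] at a reduced side
#' length (3 to 50 cells), where a full scenario suite runs in well under a
#' second.
#'
#' @param n Grid side length, between 3 and 50.
#' @param center_peak_density Persons per cell at the center (default 100).
#' @return A `"population_grid"`.
#' @export
make_fixture_city <- function(n, center_peak_density = 100) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 3 || n > 50 ||
      n != round(n))
    stop_validation("'n' must be an integer between 3 and 50")
  build_city(n = n, center_peak_density = center_peak_density)
}

#' Generic disparity decomposition from raster files
#'
#' The decomposition path for user-supplied data: reads a concentration
#' raster and per-group population rasters written by [write_raster_csv()]
#' and returns the framework decomposition for the group.
#'
#' @param conc_path,pop_group_path,pop_total_path Raster CSV paths.
#' @param emissions Emission rate associated with the concentration field.
#' @param group_label Label for the group.
#' @return A [decompose_disparity()] object.
#' @export
decompose_from_files <- function(conc_path, pop_group_path, pop_total_path,
                                 emissions, group_label = "group") {
  decompose_disparity(read_raster_csv(conc_path),
                      read_raster_csv(pop_group_path),
                      read_raster_csv(pop_total_path),
                      emissions = emissions, group_label = group_label)
}
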