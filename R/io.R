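# Scenario configuration files (YAML or JSON), result serialization and run
# manifests. CSV output is plain text, full precision, deterministic column
# order, so written results round-trip bit-exactly and diff cleanly.

SCENARIO_KEYS <- c("name", "days", "body_weight", "routes", "solver",
                   "mehp_mw")
ROUTE_KEYS <- list(
  oral = c("total_mg", "ratios", "times", "duration_h"),
  dermal = c("rate_mg_h"),
  inhalation = c("rate_mg_h")
)
SOLVER_KEYS <- c("dt", "rtol", "atol")

#' Load a scenario configuration
#'
#' Reads a YAML or JSON scenario file with strict schema validation:
#' unknown keys are rejected by name, doses must be non-negative, and any
#' field left out falls back to the reference oral scenario defaults
#' (1.95 mg/day over three meals, 2 days, 60 kg). An empty file yields the
#' default oral scenario.
#'
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @return an object of class `scenario_spec`: list with `name`, `days`,
#'   `body_weight`, `routes` (per-route dose blocks), `solver` and
#'   `mehp_mw`.
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  scenario_spec(raw)
}

#' Construct a scenario specification
#'
#' @param config named list following the scenario schema (see
#'   [load_scenario_config()]); empty list gives the default oral scenario.
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(config = list()) {
  bad <- setdiff(names(config), SCENARIO_KEYS)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  routes <- config$routes
  if (is.null(routes)) {
    routes <- list(oral = list(total_mg = 1.95, ratios = c(0.5, 0.8, 0.65),
                               times = c(8, 12, 18), duration_h = 0.5))
  }
  bad_routes <- setdiff(names(routes), names(ROUTE_KEYS))
  if (length(bad_routes)) {
    stop("unknown route(s): ", paste(bad_routes, collapse = ", "),
         call. = FALSE)
  }
  for (r in names(routes)) {
    bad_keys <- setdiff(names(routes[[r]]), ROUTE_KEYS[[r]])
    if (length(bad_keys)) {
      stop("unknown key(s) in route '", r, "': ",
           paste(bad_keys, collapse = ", "), call. = FALSE)
    }
    vals <- unlist(routes[[r]][intersect(names(routes[[r]]),
                                         c("total_mg", "rate_mg_h"))])
    if (any(vals < 0)) {
      stop("negative dose in route '", r, "'", call. = FALSE)
    }
  }
  solver <- config$solver
  if (!is.null(solver)) {
    bad_keys <- setdiff(names(solver), SOLVER_KEYS)
    if (length(bad_keys)) {
      stop("unknown solver key(s): ", paste(bad_keys, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(
      name = if (is.null(config$name)) "default_oral" else config$name,
      days = if (is.null(config$days)) 2 else config$days,
      body_weight = if (is.null(config$body_weight)) 60 else config$body_weight,
      routes = routes,
      solver = utils::modifyList(list(dt = 0.05, rtol = 1e-8, atol = 1e-10),
                                 if (is.null(solver)) list() else solver),
      mehp_mw = if (is.null(config$mehp_mw)) MW_MEHP else config$mehp_mw
    ),
    class = "scenario_spec"
  )
}

#' Build the dose schedule of a scenario specification
#' @param spec a `scenario_spec`.
#' @return a `dose_schedule` combining all configured routes.
#' @export
scenario_schedule <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  t_end <- spec$days * 24
  parts <- list()
  r <- spec$routes
  if (!is.null(r$oral)) {
    o <- r$oral
    parts <- c(parts, list(oral_schedule(
      total_mg_per_day = o$total_mg, ratios = o$ratios,
      meal_times = o$times, duration_h = o$duration_h, days = spec$days)))
  }
  for (cr in c("dermal", "inhalation")) {
    if (!is.null(r[[cr]])) {
      parts <- c(parts, list(continuous_dose(cr, r[[cr]]$rate_mg_h, t_end)))
    }
  }
  do.call(combine_schedules, parts)
}

#' Run a scenario specification
#' @param spec a `scenario_spec`.
#' @param ... further arguments to [simulate.pbpk_model()].
#' @return a `pbpk_sim`.
#' @export
run_scenario <- function(spec, ...) {
  stopifnot(inherits(spec, "scenario_spec"))
  model <- pbpk_model(
    physiology = build_default_physiology(body_weight = spec$body_weight),
    chemistry = default_chemistry(mehp_mw = spec$mehp_mw)
  )
  simulate(model, schedule = scenario_schedule(spec),
           t_end = spec$days * 24, dt = spec$solver$dt,
           rtol = spec$solver$rtol, atol = spec$solver$atol, ...)
}

# full-precision numeric formatting so CSV round-trips are bit-exact
fmt_full <- function(x) sprintf("%.17g", x)

#' Write a simulation to CSV plus a JSON run manifest
#'
#' Writes `timeseries.csv` (long format: time_h, compartment, species,
#' amount_ug, concentration_ug_per_mL; full precision) and
#' `manifest.json` (schedule, solver options, state names, mass-balance
#' residual, package version) into a directory.
#'
#' @param sim a `pbpk_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_timeseries <- function(sim, dir) {
  stopifnot(inherits(sim, "pbpk_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(sim)
  out <- data.frame(
    time_h = fmt_full(df$time_h),
    compartment = df$compartment,
    species = df$species,
    amount_ug = fmt_full(df$amount_ug),
    concentration_ug_per_mL = ifelse(is.na(df$concentration_ug_per_mL), "",
                                     fmt_full(df$concentration_ug_per_mL)),
    stringsAsFactors = FALSE
  )
  csv_path <- file.path(dir, "timeseries.csv")
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)

  mb <- mass_balance(sim)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dehptk")),
    schedule = sim$schedule$events,
    solver = sim$diagnostics,
    t_end_h = max(sim$time),
    n_times = length(sim$time),
    state_names = colnames(sim$amounts),
    mass_balance_worst_residual = mb$worst_residual,
    written_at = format(Sys.time(), tz = "UTC")
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv = csv_path, manifest = manifest_path))
}

#' Read back a written time series
#'
#' @param dir directory written by [write_timeseries()].
#' @return data frame in the long output format with numeric columns
#'   restored bit-exactly.
#' @export
read_timeseries <- function(dir) {
  path <- file.path(dir, "timeseries.csv")
  if (!file.exists(path)) stop("no timeseries.csv under ", dir, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character",
                                       "character", "character"))
  df$time_h <- as.numeric(df$time_h)
  df$amount_ug <- as.numeric(df$amount_ug)
  df$concentration_ug_per_mL <- suppressWarnings(
    as.numeric(df$concentration_ug_per_mL))
  df
}
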