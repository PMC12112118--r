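#' Read a time-series measurement table
#'
#' The standard exchange format is a plain CSV with a header row, a `time_s`
#' column (seconds, strictly increasing, starting at 0) and one numeric
#' column per species in normalized units, optionally including `h2o2_star`.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("time_s", first, fixed = TRUE))
    stop("missing header row with a time_s column in ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(tab)) stop("missing time_s column in ", path)
  for (col in names(tab)) {
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1L]
      stop("non-numeric cell in column '", col, "', row ", bad, " of ", path)
    }
  }
  if (any(diff(tab$time_s) <= 0))
    stop("time_s must be strictly increasing in ", path)
  if (tab$time_s[1L] < 0) stop("time_s must start at or after 0 in ", path)
  vals <- as.matrix(tab[setdiff(names(tab), "time_s")])
  if (any(vals < -1e-9))
    stop("negative concentrations beyond rounding tolerance in ", path)
  tab[setdiff(names(tab), "time_s")] <- pmax(vals, 0)
  tab
}

#' Write a time-series table
#'
#' Values are written with 15 significant digits so a write/read round trip
#' is lossless to at least 12 significant digits.
#'
#' @param table data frame with a `time_s` column.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(table, path) {
  if (!"time_s" %in% names(table)) stop("table must contain a time_s column")
  out <- table
  for (col in names(out))
    out[[col]] <- vapply(out[[col]], function(v)
      formatC(v, digits = 15, format = "g", width = 1), character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory as a time-series CSV
#'
#' @param traj a `chain_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "chain_trajectory"))
  write_timeseries(cbind(data.frame(time_s = traj$times),
                         as.data.frame(traj$states)), path)
}

scenario_keys <- c("name", "species", "c0_mol_per_L", "initial_state",
                   "rates_1_per_M_s", "b_coeffs", "t_max_s", "duration_s",
                   "grid_step_s", "k_prop", "current_density_mA_cm2", "law")

#' Load a scenario from a YAML configuration file
#'
#' The config mirrors [builtin_scenario()] structure with units spelled out
#' in the key names: `species`, `c0_mol_per_L`, `rates_1_per_M_s`,
#' `b_coeffs` (H2O2 polynomial, ascending powers), `t_max_s`, `duration_s`,
#' `grid_step_s`, and either a direct `k_prop` or a
#' `current_density_mA_cm2` together with a `law:` section
#' (`slope_cm2_per_mA`, `intercept`) from which the factor is resolved via
#' [k_of_j()]. Unknown keys are rejected rather than silently ignored.
#'
#' @param path YAML file.
#' @return an `ohkin_scenario`.
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), scenario_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  need <- c("name", "species", "c0_mol_per_L", "rates_1_per_M_s",
            "b_coeffs", "t_max_s", "duration_s")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("missing mandatory config key(s): ", paste(miss, collapse = ", "))
  system <- chain_system(cfg$species, cfg$c0_mol_per_L,
                         initial_state = cfg$initial_state)
  rates <- check_rates(cfg$rates_1_per_M_s, length(cfg$species))
  poly <- h2o2_poly(as.numeric(cfg$b_coeffs), t_max_s = cfg$t_max_s)
  law <- NULL
  if (!is.null(cfg$law)) {
    lk <- setdiff(names(cfg$law), c("slope_cm2_per_mA", "intercept"))
    if (length(lk)) stop("unknown law key(s): ", paste(lk, collapse = ", "))
    law <- current_density_law(cfg$law$slope_cm2_per_mA, cfg$law$intercept)
  }
  if (!is.null(cfg$k_prop)) {
    k_prop <- cfg$k_prop
  } else if (!is.null(cfg$current_density_mA_cm2) && !is.null(law)) {
    k_prop <- k_of_j(law, cfg$current_density_mA_cm2)
  } else {
    stop("config must provide k_prop, or current_density_mA_cm2 plus law")
  }
  if (cfg$duration_s > cfg$t_max_s)
    stop("duration_s exceeds the polynomial domain t_max_s")
  step <- if (!is.null(cfg$grid_step_s)) cfg$grid_step_s else 3600
  structure(list(name = cfg$name, system = system, rates = rates,
                 poly = poly, k_prop = k_prop, law = law,
                 j = if (!is.null(cfg$current_density_mA_cm2))
                   cfg$current_density_mA_cm2 else NA_real_,
                 duration_s = cfg$duration_s,
                 grid_s = seq(0, cfg$duration_s, by = step)),
            class = "ohkin_scenario")
}

#' Write a scenario to a YAML configuration file
#'
#' @param scenario an `ohkin_scenario`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "ohkin_scenario"))
  cfg <- list(name = scenario$name,
              species = scenario$system$species,
              c0_mol_per_L = scenario$system$c0_mol_L,
              rates_1_per_M_s = scenario$rates,
              b_coeffs = scenario$poly$coefficients,
              t_max_s = scenario$poly$t_max_s,
              duration_s = scenario$duration_s,
              grid_step_s = if (length(scenario$grid_s) > 1L)
                diff(scenario$grid_s)[1L] else 3600,
              k_prop = scenario$k_prop)
  if (!is.null(scenario$law))
    cfg$law <- list(slope_cm2_per_mA = scenario$law$slope,
                    intercept = scenario$law$intercept)
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

#' Write a fit result to JSON
#'
#' @param fit an `ohkin_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "ohkin_fit"))
  jsonlite::write_json(
    list(estimates = fit$estimates, ci95 = fit$ci95, stats = fit$stats,
         convergence = fit$convergence),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
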