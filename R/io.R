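# CSV dialects and configuration round-tripping. All readers validate the
# header, check value domains with row diagnostics, preserve and ignore
# extra columns, and are locale independent (decimal points, UTF-8).

read_csv_checked <- function(path, required, label) {
  if (!file.exists(path)) {
    stop(label, " file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) {
      stop("schema error in ", label, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error in ", label, " file '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

check_numeric_col <- function(df, col, label, min = -Inf) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!is.finite(x) | x < min)
  if (length(bad) > 0L) {
    # +1 for the header line so the numbers match the file
    stop(sprintf("%s: column '%s' invalid at line(s) %s", label, col,
                 paste(utils::head(bad + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  }
  df[[col]] <- x
  df
}

#' Read and write the hourly weather CSV
#'
#' Columns: `date` (ISO-8601), `hour` (0-23), `temp_c`, `par_mol_m2`.
#' Extra columns are preserved and ignored. Reading validates the schema
#' and value domains with line numbers in the diagnostics.
#'
#' @param path File path.
#' @param weather A weather data frame as from [generate_weather()].
#' @return `read_weather_csv`: the validated weather data frame.
#' @export
read_weather_csv <- function(path) {
  df <- read_csv_checked(path, c("date", "hour", "temp_c", "par_mol_m2"),
                         "weather")
  df <- check_numeric_col(df, "temp_c", "weather")
  df <- check_numeric_col(df, "par_mol_m2", "weather", min = 0)
  validate_weather(df)
}

#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(weather, path) {
  stopifnot(all(c("date", "hour", "temp_c", "par_mol_m2") %in%
                  names(weather)))
  utils::write.csv(weather, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the destructive plant-sample CSV
#'
#' Columns: `day` (1-based trial day), `n_rate` (g N/kg), `fw`, `dw`
#' (g/plant) and `n_pct` (% of DW); an optional `plant` column identifies
#' the individual.
#'
#' @param path File path.
#' @param samples A plant-sample data frame as from [generate_trial()].
#' @return `read_plant_samples_csv`: the validated data frame.
#' @export
read_plant_samples_csv <- function(path) {
  df <- read_csv_checked(path, c("day", "n_rate", "fw", "dw", "n_pct"),
                         "plant samples")
  df <- check_numeric_col(df, "day", "plant samples", min = 1)
  df <- check_numeric_col(df, "n_rate", "plant samples", min = 0)
  df <- check_numeric_col(df, "fw", "plant samples", min = 0)
  df <- check_numeric_col(df, "dw", "plant samples", min = 0)
  df <- check_numeric_col(df, "n_pct", "plant samples", min = 0)
  bad <- which(df$fw < df$dw)
  if (length(bad) > 0L) {
    stop("plant samples: fw < dw at line(s) ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_plant_samples_csv
#' @export
write_plant_samples_csv <- function(samples, path) {
  stopifnot(all(c("day", "n_rate", "fw", "dw", "n_pct") %in% names(samples)))
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read dilution-curve sample pairs
#'
#' Columns: `dw_t_ha` (t/ha) and `n_pct` (% of DW), the input of
#' [fit_dilution()].
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_dilution_samples_csv <- function(path) {
  df <- read_csv_checked(path, c("dw_t_ha", "n_pct"), "dilution samples")
  df <- check_numeric_col(df, "dw_t_ha", "dilution samples", min = 0)
  check_numeric_col(df, "n_pct", "dilution samples", min = 0)
}

#' Read a plant-state CSV for demand reporting
#'
#' Columns: `fw_g` (g/plant), `dw_t_ha` (t/ha) and `na_pct` (% of DW),
#' the input of [demand_report()].
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_plant_state_csv <- function(path) {
  df <- read_csv_checked(path, c("fw_g", "dw_t_ha", "na_pct"), "plant state")
  df <- check_numeric_col(df, "fw_g", "plant state", min = 0)
  df <- check_numeric_col(df, "dw_t_ha", "plant state", min = 0)
  check_numeric_col(df, "na_pct", "plant state", min = 0)
}

#' Pipeline configuration
#'
#' Bundles every parameter group the pipeline needs, plus the seed and the
#' NNI tolerance. Round-trips losslessly through [write_config()] /
#' [read_config()] as JSON whose keys carry explicit units.
#'
#' @param thermal_light A [thermal_light_params()].
#' @param dilution A [dilution_params()].
#' @param conversion A [conversion_params()].
#' @param demand A [demand_params()].
#' @param seed Integer seed for any stochastic stage.
#' @param nni_tolerance Tolerance of the optimal NNI band.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(thermal_light = thermal_light_params(),
                            dilution = dilution_params(),
                            conversion = conversion_params(),
                            demand = demand_params(),
                            seed = 1L,
                            nni_tolerance = 0.05) {
  stopifnot(inherits(thermal_light, "thermal_light_params"),
            inherits(dilution, "dilution_params"),
            inherits(conversion, "conversion_params"),
            inherits(demand, "demand_params"),
            is.numeric(nni_tolerance), nni_tolerance >= 0)
  structure(list(thermal_light = thermal_light, dilution = dilution,
                 conversion = conversion, demand = demand,
                 seed = as.integer(seed), nni_tolerance = nni_tolerance),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration (seed", x$seed, ")\n")
  print(x$thermal_light)
  print(x$dilution)
  print(x$conversion)
  print(x$demand)
  cat(sprintf("  NNI tolerance: %g\n", x$nni_tolerance))
  invisible(x)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` object.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  tl <- config$thermal_light
  dl <- config$dilution
  cv <- config$conversion
  dm <- config$demand
  obj <- list(
    thermal_light = list(t_base_c = tl$t_base, t_opt_c = tl$t_opt,
                         t_max_c = tl$t_max,
                         alpha_per_mmol_m2_d = tl$alpha),
    dilution = list(n_max_pct = dl$n_max_pct,
                    plateau_fraction_c = dl$plateau_fraction_c,
                    plateau_fraction_min = dl$plateau_fraction_min,
                    exponent_b = dl$exponent_b,
                    dw_break_t_ha = dl$dw_break,
                    mode = dl$mode),
    conversion = list(fw_dw_ratio = cv$fw_dw_ratio,
                      plant_density_per_ha = cv$plant_density),
    demand = list(system = dm$system,
                  crop_coefficient = dm$crop_coefficient,
                  use_efficiency = dm$use_efficiency),
    seed = config$seed,
    nni_tolerance = config$nni_tolerance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    thermal_light = thermal_light_params(
      t_base = obj$thermal_light$t_base_c,
      t_opt = obj$thermal_light$t_opt_c,
      t_max = obj$thermal_light$t_max_c,
      alpha = obj$thermal_light$alpha_per_mmol_m2_d),
    dilution = dilution_params(
      n_max_pct = obj$dilution$n_max_pct,
      plateau_fraction_c = obj$dilution$plateau_fraction_c,
      plateau_fraction_min = obj$dilution$plateau_fraction_min,
      exponent_b = obj$dilution$exponent_b,
      dw_break = obj$dilution$dw_break_t_ha,
      mode = obj$dilution$mode),
    conversion = conversion_params(
      fw_dw_ratio = obj$conversion$fw_dw_ratio,
      plant_density = obj$conversion$plant_density_per_ha),
    demand = demand_params(
      system = obj$demand$system,
      crop_coefficient = obj$demand$crop_coefficient,
      use_efficiency = obj$demand$use_efficiency),
    seed = obj$seed,
    nni_tolerance = obj$nni_tolerance
  )
}
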