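#' Run the full nitrogen-demand pipeline
#'
#' Ties the stages together for one trial: reads (or accepts) the hourly
#' weather and destructive plant samples, accumulates the daily
#' photothermal effects and the running LTF, fits the exponential growth
#' models per nitrogen rate and response on per-day treatment means, fits
#' the dilution power law from samples above the areal breakpoint (when at
#' least three such points exist), and emits a per-sample nitrogen status
#' and demand/supply report. Deterministic: identical inputs and
#' configuration give identical outputs.
#'
#' @param config A [pipeline_config()]; its conversion parameters must
#'   carry a plant density for the areal steps.
#' @param weather Hourly weather: a data frame or a CSV path (see
#'   [read_weather_csv()]).
#' @param samples Destructive samples: a data frame or a CSV path (see
#'   [read_plant_samples_csv()]).
#' @param out_dir Optional directory; when given, writes `ltf.csv`,
#'   `demand.csv` and `fits.json` there.
#' @param quiet Suppress the stage log? Default `TRUE`.
#' @return Invisibly, a list with `effects` (daily table with `ltf`),
#'   `growth_fits` (nested list by rate and response), `dilution_fit`
#'   (a [fit_dilution()] result or `NULL`), `demand` (the per-sample
#'   [demand_report()]), and `paths` of any files written.
#' @export
#' @examples
#' paths <- make_fixture("minimal")
#' cfg <- pipeline_config(conversion = conversion_params(plant_density = 2e7))
#' res <- run_pipeline(cfg, paths[["weather"]], paths[["samples"]])
#' res$demand
run_pipeline <- function(config, weather, samples, out_dir = NULL,
                         quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$conversion$plant_density)) {
    stop("configuration error: conversion plant_density is unset but the ",
         "pipeline needs areal biomass", call. = FALSE)
  }
  say <- function(...) if (!quiet) message(...)
  if (!quiet) {
    message("Resolved configuration:")
    print(config)
  }

  if (is.character(weather)) weather <- read_weather_csv(weather)
  else weather <- validate_weather(weather)
  if (is.character(samples)) samples <- read_plant_samples_csv(samples)

  say("Stage 1/4: daily photothermal effects")
  effects <- ltf_series(daily_effects(weather, config$thermal_light))

  if (any(samples$day > nrow(effects))) {
    stop("samples reference day(s) beyond the weather series (",
         nrow(effects), " days)", call. = FALSE)
  }

  say("Stage 2/4: growth fits per nitrogen rate")
  pts <- trial_growth_points(samples, effects)
  growth_fits <- list()
  for (rate in sort(unique(pts$n_rate))) {
    sub <- pts[pts$n_rate == rate, , drop = FALSE]
    fits <- list()
    if (nrow(sub) >= 3L) {
      fits$fw <- fit_growth(data.frame(ltf = sub$ltf, y = sub$fw), "fw")
      fits$dw <- fit_growth(data.frame(ltf = sub$ltf, y = sub$dw), "dw")
      fits$n_uptake <- fit_growth(
        data.frame(ltf = sub$ltf, y = sub$n_uptake), "n_uptake")
    }
    growth_fits[[as.character(rate)]] <- fits
  }

  say("Stage 3/4: dilution curve fit")
  dw_area <- per_plant_to_area(samples$dw, config$conversion)
  dil_input <- data.frame(dw_t_ha = dw_area, n_pct = samples$n_pct)
  n_above <- sum(dil_input$dw_t_ha > config$dilution$dw_break &
                   dil_input$n_pct > 0)
  dilution_fit <- if (n_above >= 3L) {
    fit_dilution(dil_input, dw_break = config$dilution$dw_break)
  } else {
    say("  skipped: fewer than 3 samples above the breakpoint")
    NULL
  }

  say("Stage 4/4: demand and supply report")
  demand <- demand_report(fw = samples$fw, dw_area = dw_area,
                          na_pct = samples$n_pct,
                          dil = config$dilution, params = config$demand,
                          tolerance = config$nni_tolerance)
  demand <- cbind(day = samples$day, n_rate = samples$n_rate, demand)
  demand$n_demand_mg <- demand$n_demand_g * 1000
  demand$n_supply_mg <- demand$n_supply_g * 1000

  paths <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    ltf_path <- file.path(out_dir, "ltf.csv")
    utils::write.csv(effects, ltf_path, row.names = FALSE, quote = FALSE)
    demand_path <- file.path(out_dir, "demand.csv")
    utils::write.csv(demand, demand_path, row.names = FALSE, quote = FALSE)
    fits_path <- file.path(out_dir, "fits.json")
    fit_to_list <- function(f) list(
      a = f$intercept_a, b = f$rate_b, r2_adj = f$r2_adj,
      f_stat = if (is.finite(f$f_stat)) f$f_stat else NULL, n = f$n_obs)
    obj <- list(
      growth = lapply(growth_fits, function(fits) lapply(fits, fit_to_list)),
      dilution = if (!is.null(dilution_fit)) list(
        a = dilution_fit$a, b = dilution_fit$b, r2 = dilution_fit$r2,
        n_points = dilution_fit$n_points) else NULL
    )
    jsonlite::write_json(obj, fits_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(ltf = ltf_path, demand = demand_path, fits = fits_path)
  }

  invisible(list(effects = effects, growth_fits = growth_fits,
                 dilution_fit = dilution_fit, demand = demand,
                 paths = paths))
}
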