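#' Greenhouse weather regime
#'
#' Statistical description of a greenhouse season used by
#' [generate_weather()]: a diurnal temperature sinusoid around `t_mean`
#' with half-range `t_amplitude`, and daily PAR integrals drawn from a
#' normal distribution truncated at zero and spread over `daylight_hours`
#' as a half-sine.
#'
#' Two presets describe the study conditions the package targets:
#' `"exp13"` is a cool autumn season (mean 19 degC fluctuating roughly
#' 13-23 degC, daily PAR about 5.3 mol m-2) and `"exp2"` a warm
#' high-radiation season (mean 26.3 degC, roughly 19-31 degC, daily PAR
#' about 9.5 mol m-2). Either preset can be partially overridden.
#'
#' @param name `"exp13"`, `"exp2"`, or any label for a custom regime (in
#'   which case all fields must be supplied or the exp13 defaults apply).
#' @param t_mean Seasonal mean air temperature, degC.
#' @param t_amplitude Half-range of the diurnal sinusoid, degC (>= 0).
#' @param par_daily_mean Mean daily PAR integral, mol m-2 d-1.
#' @param par_daily_sd SD of the daily PAR integral, mol m-2 d-1 (>= 0).
#' @param daylight_hours Length of the daylight window, h (0, 24].
#' @return An object of class `weather_regime`.
#' @export
#' @examples
#' weather_regime("exp2")
weather_regime <- function(name = "exp13", t_mean = NULL, t_amplitude = NULL,
                           par_daily_mean = NULL, par_daily_sd = NULL,
                           daylight_hours = NULL) {
  presets <- list(
    exp13 = list(t_mean = 19, t_amplitude = 5, par_daily_mean = 5.3,
                 par_daily_sd = 1.2, daylight_hours = 11),
    exp2 = list(t_mean = 26.3, t_amplitude = 6, par_daily_mean = 9.5,
                par_daily_sd = 2.0, daylight_hours = 10)
  )
  base <- if (name %in% names(presets)) presets[[name]] else presets$exp13
  pick <- function(given, default) if (is.null(given)) default else given
  out <- list(name = name,
              t_mean = pick(t_mean, base$t_mean),
              t_amplitude = pick(t_amplitude, base$t_amplitude),
              par_daily_mean = pick(par_daily_mean, base$par_daily_mean),
              par_daily_sd = pick(par_daily_sd, base$par_daily_sd),
              daylight_hours = pick(daylight_hours, base$daylight_hours))
  stopifnot(is.numeric(out$t_mean), is.numeric(out$t_amplitude),
            is.numeric(out$par_daily_mean), is.numeric(out$par_daily_sd),
            is.numeric(out$daylight_hours))
  if (out$t_amplitude < 0 || out$par_daily_sd < 0 || out$par_daily_mean < 0) {
    stop("amplitudes, means and sds must be >= 0", call. = FALSE)
  }
  if (out$daylight_hours <= 0 || out$daylight_hours > 24) {
    stop("'daylight_hours' must lie in (0, 24]", call. = FALSE)
  }
  structure(out, class = "weather_regime")
}

#' @export
print.weather_regime <- function(x, ...) {
  cat(sprintf("Weather regime '%s': T = %g +/- %g degC, PAR = %g (sd %g) mol m-2 d-1, %g h daylight\n",
              x$name, x$t_mean, x$t_amplitude, x$par_daily_mean,
              x$par_daily_sd, x$daylight_hours))
  invisible(x)
}

# Truncated-at-zero normal draws via the inverse CDF; degenerates to the
# mean when sd = 0 and consumes exactly n uniforms either way.
rtruncnorm0 <- function(n, mean, sd) {
  u <- stats::runif(n)
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + u * (1 - lo), mean, sd)
}

#' Generate an hourly greenhouse weather series
#'
#' Temperature is a diurnal sinusoid (minimum pre-dawn around 03:00,
#' maximum mid-afternoon around 15:00) around the regime mean, plus a small
#' AR(1) noise whose stationary SD is 5% of the amplitude — so a
#' zero-amplitude regime is perfectly periodic. Each day's PAR integral is
#' drawn from Normal(mean, sd) truncated at zero and distributed over the
#' daylight window as a half-sine, zero at night. Fully deterministic given
#' `seed`.
#'
#' @param regime A [weather_regime()] object.
#' @param days Number of complete days (>= 1).
#' @param seed Integer seed for all draws.
#' @param start_date First calendar date of the series.
#' @return Data frame with columns `date`, `hour`, `temp_c`, `par_mol_m2`
#'   (PAR received during that hour, mol m-2), 24 rows per day.
#' @export
#' @examples
#' w <- generate_weather(weather_regime("exp13"), days = 2, seed = 42)
#' head(w)
generate_weather <- function(regime, days, seed,
                             start_date = as.Date("2020-01-01")) {
  stopifnot(inherits(regime, "weather_regime"), days >= 1)
  set.seed(as.integer(seed))
  n <- days * 24L
  hour <- rep(0:23, days)
  date <- rep(start_date + seq_len(days) - 1L, each = 24L)

  # daily PAR totals first, then temperature noise: a fixed draw order
  # keeps series reproducible across calls
  totals <- rtruncnorm0(days, regime$par_daily_mean, regime$par_daily_sd)

  diurnal <- -regime$t_amplitude * cos(2 * pi * (hour - 3) / 24)
  sd_stat <- 0.05 * regime$t_amplitude
  rho <- 0.8
  eps <- stats::rnorm(n)
  noise <- numeric(n)
  if (sd_stat > 0) {
    noise[1L] <- sd_stat * eps[1L]
    for (i in 2:n) {
      noise[i] <- rho * noise[i - 1L] + sd_stat * sqrt(1 - rho^2) * eps[i]
    }
  }
  temp_c <- regime$t_mean + diurnal + noise

  dl <- regime$daylight_hours
  start <- 12 - dl / 2
  mids <- 0:23 + 0.5
  w <- ifelse(mids > start & mids < start + dl,
              sin(pi * (mids - start) / dl), 0)
  w <- w / sum(w)
  par_mol_m2 <- as.vector(outer(w, totals))

  data.frame(date = date, hour = hour, temp_c = temp_c,
             par_mol_m2 = par_mol_m2)
}

#' Destructive-sampling trial design
#'
#' Layout of a virtual pot trial: nitrogen rates, duration, destructive
#' sampling days, plants harvested per sampling, the multiplicative
#' between-plant noise (as a coefficient of variation), and the seed.
#' Defaults emulate a 42-day greenhouse run with four nitrogen rates
#' spanning 0-0.2 g N/kg, weekly destructive sampling and 8% between-plant
#' variability.
#'
#' @param n_rates Nitrogen application rates, g N/kg (>= 0).
#' @param duration_days Trial length in days.
#' @param sampling_days Destructive sampling days (1-based, within the
#'   duration).
#' @param plants_per_sample Plants harvested per rate per sampling day.
#' @param noise_cv Coefficient of variation of the per-plant lognormal
#'   noise (>= 0; 0 puts samples exactly on the model trajectories).
#' @param seed Integer seed; one generator drives all draws in a trial.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_rates = c(0, 0.05, 0.1, 0.2),
                         duration_days = 42,
                         sampling_days = seq(7, 42, by = 7),
                         plants_per_sample = 12,
                         noise_cv = 0.08,
                         seed = 1) {
  stopifnot(is.numeric(n_rates), length(n_rates) >= 1,
            is.numeric(sampling_days), length(sampling_days) >= 1)
  if (any(n_rates < 0)) stop("'n_rates' must be >= 0", call. = FALSE)
  if (duration_days < 1) stop("'duration_days' must be >= 1", call. = FALSE)
  if (any(sampling_days < 1) || any(sampling_days > duration_days)) {
    stop("'sampling_days' must lie within 1..duration_days", call. = FALSE)
  }
  if (plants_per_sample < 1) stop("'plants_per_sample' must be >= 1",
                                  call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  structure(list(n_rates = n_rates,
                 duration_days = as.integer(duration_days),
                 sampling_days = as.integer(sort(sampling_days)),
                 plants_per_sample = as.integer(plants_per_sample),
                 noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design: %d N rates (%s g/kg), %d days, sampling on day %s\n",
              length(x$n_rates), paste(x$n_rates, collapse = ", "),
              x$duration_days, paste(x$sampling_days, collapse = ", ")))
  cat(sprintf("  %d plants/sample, noise CV = %g, seed = %d\n",
              x$plants_per_sample, x$noise_cv, x$seed))
  invisible(x)
}

lognorm_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate a destructive-sampling trial
#'
#' Forward-simulates the package's own model. For each nitrogen rate the
#' exponential rate parameters are taken from the calibrated b(F)
#' quadratics; fresh biomass starts from `fw_intercept`, dry biomass from
#' `fw_intercept / fw_dw_ratio`, and nitrogen uptake from the dry-biomass
#' intercept at the maximum N concentration. Trajectories follow
#' `a * exp(b * LTF)` on the generated weather's cumulative photothermal
#' effect; the N concentration implied by uptake/biomass is clipped into
#' the \[Nmin, Nmax\] envelope (evaluated at the areal biomass), giving the
#' plateau-then-decline structure of real seasons. Each harvested plant
#' receives independent multiplicative lognormal noise with CV
#' `design$noise_cv` on each response.
#'
#' @param design A [trial_design()] object.
#' @param regime A [weather_regime()] object.
#' @param thermal_light A [thermal_light_params()] object.
#' @param dilution A [dilution_params()] object.
#' @param conversion A [conversion_params()] with `plant_density` set; the
#'   default nominal density of 2e7 plants/ha maps the default trial's
#'   final biomass a few-fold past the 1.5 t/ha breakpoint so both the
#'   plateau and the dilution phase are exercised.
#' @param quadratics Rate-parameter quadratics per response, as from
#'   [pakchoi_b_quadratics()].
#' @param fw_intercept Fresh biomass at LTF = 0, g/plant.
#' @return Data frame of class `plant_samples` with columns `day`,
#'   `n_rate`, `plant`, `fw`, `dw` (g/plant) and `n_pct` (% of DW), plus
#'   attributes `truth` (the injected per-rate parameters), `effects` (the
#'   daily photothermal table with its `ltf` column) and `conversion`.
#' @export
#' @examples
#' trial <- generate_trial(trial_design(noise_cv = 0, seed = 3))
#' head(trial)
generate_trial <- function(design = trial_design(),
                           regime = weather_regime("exp2"),
                           thermal_light = thermal_light_params(),
                           dilution = dilution_params(),
                           conversion = conversion_params(plant_density = 2e7),
                           quadratics = pakchoi_b_quadratics(),
                           fw_intercept = 0.2816) {
  stopifnot(inherits(design, "trial_design"),
            inherits(regime, "weather_regime"),
            inherits(conversion, "conversion_params"))
  if (is.null(conversion$plant_density)) {
    stop("'conversion' must carry a plant density for the envelope clipping",
         call. = FALSE)
  }
  weather <- generate_weather(regime, design$duration_days, design$seed)
  effects <- ltf_series(daily_effects(weather, thermal_light))
  ltf_by_day <- effects$ltf  # ltf through day d at position d

  a_fw <- fw_intercept
  a_dw <- fw_intercept / conversion$fw_dw_ratio
  a_nup_mg <- a_dw * dilution$n_max_pct * 10  # g * %/100 * 1000 mg/g

  rows <- list()
  truth <- list()
  for (rate in design$n_rates) {
    b_fw <- b_response(rate, quadratics$fw)
    b_dw <- b_response(rate, quadratics$dw)
    b_nup <- b_response(rate, quadratics$n_uptake)
    truth[[as.character(rate)]] <- list(
      n_rate = rate, a_fw = a_fw, a_dw = a_dw, a_nup_mg = a_nup_mg,
      b_fw = b_fw, b_dw = b_dw, b_nup = b_nup)
    L <- ltf_by_day[design$sampling_days]
    fw0 <- a_fw * exp(b_fw * L)
    dw0 <- a_dw * exp(b_dw * L)
    nup0 <- a_nup_mg * exp(b_nup * L)
    npct0 <- nup0 / (dw0 * 10)  # mg/plant over g/plant -> % of DW
    dw_area <- per_plant_to_area(dw0, conversion)
    npct0 <- pmin(pmax(npct0, n_min_curve(dw_area, dilution)),
                  n_max_curve(dw_area, dilution))
    p <- design$plants_per_sample
    nd <- length(design$sampling_days)
    rows[[length(rows) + 1L]] <- data.frame(
      day = rep(design$sampling_days, each = p),
      n_rate = rate,
      plant = rep(seq_len(p), times = nd),
      fw = rep(fw0, each = p) * lognorm_factors(nd * p, design$noise_cv),
      dw = rep(dw0, each = p) * lognorm_factors(nd * p, design$noise_cv),
      n_pct = rep(npct0, each = p) * lognorm_factors(nd * p, design$noise_cv)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "effects") <- effects
  attr(out, "conversion") <- conversion
  class(out) <- c("plant_samples", "data.frame")
  out
}

#' Per-sampling-day treatment means for growth fitting
#'
#' Destructive samples are distinct individuals, so growth models are
#' fitted to the per-day treatment means (as trial analyses do), with
#' nitrogen uptake reconstructed as `dw * n_pct * 10` mg/plant.
#'
#' @param samples A [generate_trial()] result or any data frame with
#'   columns `day`, `n_rate`, `fw`, `dw`, `n_pct`.
#' @param effects A daily photothermal table with an `ltf` column (e.g.
#'   from [ltf_series()]); defaults to the table attached to `samples`.
#' @return Data frame with columns `n_rate`, `day`, `ltf`, `fw`, `dw`,
#'   `n_uptake` (one row per rate and sampling day).
#' @export
trial_growth_points <- function(samples, effects = attr(samples, "effects")) {
  stopifnot(is.data.frame(samples),
            all(c("day", "n_rate", "fw", "dw", "n_pct") %in% names(samples)))
  if (is.null(effects) || is.null(effects$ltf)) {
    stop("'effects' with an ltf column is required (see ltf_series())",
         call. = FALSE)
  }
  if (any(samples$day > nrow(effects))) {
    stop("samples reference days beyond the weather series", call. = FALSE)
  }
  agg <- stats::aggregate(
    cbind(fw, dw, n_uptake = dw * n_pct * 10) ~ n_rate + day,
    data = samples, FUN = mean)
  agg <- agg[order(agg$n_rate, agg$day), , drop = FALSE]
  agg$ltf <- effects$ltf[agg$day]
  rownames(agg) <- NULL
  agg[, c("n_rate", "day", "ltf", "fw", "dw", "n_uptake")]
}

#' Write a bundled test fixture
#'
#' Deterministic tiny weather and trial CSV pairs used by the test suite
#' and documentation. `"minimal"` is a 3-day series with a two-sample
#' noiseless trial; `"exp2_like"` is a 42-day warm-season trial with four
#' nitrogen rates, noiseless so fitted parameters reproduce the injected
#' ones exactly.
#'
#' @param name Fixture name: `"minimal"` or `"exp2_like"`.
#' @param dir Directory to write into (created if needed).
#' @return Invisibly, a named character vector with the `weather` and
#'   `samples` file paths.
#' @export
make_fixture <- function(name, dir = tempdir()) {
  registry <- list(
    minimal = list(
      regime = weather_regime("exp13"),
      design = trial_design(n_rates = c(0, 0.2), duration_days = 3,
                            sampling_days = 3, plants_per_sample = 1,
                            noise_cv = 0, seed = 101)
    ),
    exp2_like = list(
      regime = weather_regime("exp2"),
      design = trial_design(n_rates = c(0, 0.05, 0.1, 0.2),
                            duration_days = 42,
                            sampling_days = seq(7, 42, by = 7),
                            plants_per_sample = 3,
                            noise_cv = 0, seed = 202)
    )
  )
  if (!name %in% names(registry)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  spec <- registry[[name]]
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  weather <- generate_weather(spec$regime, spec$design$duration_days,
                              spec$design$seed)
  trial <- generate_trial(spec$design, spec$regime)
  weather_path <- file.path(dir, paste0("weather_", name, ".csv"))
  samples_path <- file.path(dir, paste0("samples_", name, ".csv"))
  write_weather_csv(weather, weather_path)
  write_plant_samples_csv(trial, samples_path)
  invisible(c(weather = weather_path, samples = samples_path))
}
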