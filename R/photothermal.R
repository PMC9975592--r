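#' Cardinal-temperature and light-response parameters
#'
#' Parameters of the photothermal suitability functions: a piecewise-linear
#' temperature response rising from the base temperature `t_base` to 1 at the
#' optimum `t_opt` and falling back to 0 at the maximum `t_max`, and a
#' saturating exponential light response with curvature `alpha`.
#'
#' Defaults are the pakchoi calibration: base 7 degC, optimum 24 degC,
#' maximum 35 degC, and light curvature 0.001 per mmol m-2 d-1, under which
#' daily photosynthetically active radiation (PAR) integrals of 5-10
#' mol m-2 d-1 put the light factor close to saturation.
#'
#' @param t_base Base (minimum) growth temperature, degC.
#' @param t_opt Optimal growth temperature, degC.
#' @param t_max Maximum growth temperature, degC.
#' @param alpha Curvature of the light response, per mmol m-2 d-1.
#'
#' @return An object of class `thermal_light_params`.
#' @seealso [temperature_effect()], [light_effect()], [daily_effects()]
#' @export
#' @examples
#' thermal_light_params()
thermal_light_params <- function(t_base = 7, t_opt = 24, t_max = 35,
                                 alpha = 0.001) {
  stopifnot(is.numeric(t_base), is.numeric(t_opt), is.numeric(t_max),
            is.numeric(alpha), length(t_base) == 1L, length(t_opt) == 1L,
            length(t_max) == 1L, length(alpha) == 1L)
  if (!is.finite(t_base) || !is.finite(t_opt) || !is.finite(t_max)) {
    stop("cardinal temperatures must be finite", call. = FALSE)
  }
  if (!(t_base < t_opt && t_opt < t_max)) {
    stop("cardinal temperatures must satisfy t_base < t_opt < t_max",
         call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0) {
    stop("'alpha' must be a positive finite number", call. = FALSE)
  }
  structure(list(t_base = t_base, t_opt = t_opt, t_max = t_max, alpha = alpha),
            class = "thermal_light_params")
}

#' @export
print.thermal_light_params <- function(x, ...) {
  cat("Photothermal response parameters\n")
  cat(sprintf("  cardinal temperatures: Tb = %g, T0 = %g, Tm = %g degC\n",
              x$t_base, x$t_opt, x$t_max))
  cat(sprintf("  light curvature alpha: %g per mmol m-2 d-1\n", x$alpha))
  invisible(x)
}

#' Temperature suitability factor
#'
#' Piecewise-linear relative temperature effect fT: 0 at or below the base
#' temperature and at or above the maximum, rising linearly to 1 at the
#' optimum and falling linearly back to 0 above it.
#'
#' @param t Air temperature(s), degC.
#' @param params A [thermal_light_params()] object.
#'
#' @return Numeric vector in \[0, 1\], same length as `t`.
#' @export
#' @examples
#' temperature_effect(c(7, 15.5, 24, 29.5, 35))
temperature_effect <- function(t, params = thermal_light_params()) {
  stopifnot(inherits(params, "thermal_light_params"), is.numeric(t))
  if (any(!is.finite(t))) stop("temperatures must be finite", call. = FALSE)
  tb <- params$t_base
  t0 <- params$t_opt
  tm <- params$t_max
  f <- ifelse(t <= tb | t >= tm, 0,
              ifelse(t <= t0, (t - tb) / (t0 - tb), (tm - t) / (tm - t0)))
  pmin(pmax(f, 0), 1)
}

#' Light saturation factor
#'
#' Saturating exponential response to the daily PAR integral:
#' fI = 1 - exp(-alpha * I), with I in mmol m-2 d-1. Strictly increasing and
#' bounded below 1.
#'
#' @param daily_par Daily PAR integral(s), mmol m-2 d-1 (multiply mol m-2 d-1
#'   by 1000).
#' @param params A [thermal_light_params()] object.
#'
#' @return Numeric vector in \[0, 1), same length as `daily_par`.
#' @export
#' @examples
#' light_effect(5300)  # a 5.3 mol m-2 day is nearly light-saturated
light_effect <- function(daily_par, params = thermal_light_params()) {
  stopifnot(inherits(params, "thermal_light_params"), is.numeric(daily_par))
  if (any(!is.finite(daily_par)) || any(daily_par < 0)) {
    stop("'daily_par' must be finite and >= 0 (mmol m-2 d-1)", call. = FALSE)
  }
  1 - exp(-params$alpha * daily_par)
}

# Validate an hourly weather table (date, hour, temp_c, par_mol_m2) and stop
# with a line-aware diagnostic on schema or continuity violations.
validate_weather <- function(weather) {
  required <- c("date", "hour", "temp_c", "par_mol_m2")
  if (!is.data.frame(weather)) {
    stop("weather must be a data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(required, names(weather))
  if (length(missing_cols) > 0L) {
    stop("weather table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(weather) == 0L) stop("weather table is empty", call. = FALSE)
  date <- as.Date(weather$date)
  if (any(is.na(date))) {
    stop("weather 'date' column contains unparseable dates (rows ",
         paste(utils::head(which(is.na(date)), 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  hour <- weather$hour
  if (any(!is.finite(hour)) || any(hour != as.integer(hour)) ||
      any(hour < 0) || any(hour > 23)) {
    stop("weather 'hour' must be integers in 0..23", call. = FALSE)
  }
  if (any(!is.finite(weather$temp_c))) {
    stop("weather 'temp_c' must be finite", call. = FALSE)
  }
  if (any(!is.finite(weather$par_mol_m2)) || any(weather$par_mol_m2 < 0)) {
    stop("weather 'par_mol_m2' must be finite and >= 0", call. = FALSE)
  }
  key <- as.numeric(date) * 24 + hour
  if (any(diff(key) <= 0)) {
    bad <- which(diff(key) <= 0)[1L] + 1L
    stop("weather timestamps must be strictly increasing (row ", bad, ")",
         call. = FALSE)
  }
  weather$date <- date
  weather
}

#' Daily photothermal effects from hourly weather
#'
#' Collapses an hourly weather series to one row per calendar day: the daily
#' temperature factor `f_t` is the arithmetic mean of the 24 hourly
#' [temperature_effect()] values, the daily PAR integral is the sum of hourly
#' PAR converted from mol to mmol m-2, and `f_i` is [light_effect()] of that
#' integral.
#'
#' Every day must be complete (hours 0..23 with no gaps); partial first or
#' last days are rejected rather than padded, and a within-day gap larger
#' than one hour is reported as malformed input.
#'
#' @param weather Data frame with columns `date` (coercible to `Date`),
#'   `hour` (0..23), `temp_c` (degC) and `par_mol_m2` (mol m-2 received
#'   during that hour).
#' @param params A [thermal_light_params()] object.
#'
#' @return Data frame of class `daily_effects` with columns `day_index`
#'   (0-based, consecutive), `date`, `f_t`, `f_i` and `daily_par_mmol`.
#' @export
#' @examples
#' w <- generate_weather(weather_regime("exp13"), days = 3, seed = 1)
#' daily_effects(w)
daily_effects <- function(weather, params = thermal_light_params()) {
  weather <- validate_weather(weather)
  days <- split(weather, weather$date)
  for (d in days) {
    h <- sort(d$hour)
    gaps <- diff(h)
    if (any(gaps > 1)) {
      stop(sprintf("weather gap of %d hour(s) on %s: hourly resolution required",
                   max(gaps) - 1L, format(d$date[1L])), call. = FALSE)
    }
    if (h[1L] != 0L || h[length(h)] != 23L || length(h) != 24L) {
      stop(sprintf("partial day %s (hours %d..%d, n = %d): complete 24 h days required",
                   format(d$date[1L]), h[1L], h[length(h)], length(h)),
           call. = FALSE)
    }
  }
  dates <- as.Date(names(days))
  f_t <- vapply(days, function(d) mean(temperature_effect(d$temp_c, params)),
                numeric(1))
  par_mmol <- vapply(days, function(d) sum(d$par_mol_m2) * 1000, numeric(1))
  out <- data.frame(
    day_index = seq_along(days) - 1L,
    date = dates,
    f_t = unname(f_t),
    f_i = unname(light_effect(par_mmol, params)),
    daily_par_mmol = unname(par_mmol),
    row.names = NULL
  )
  class(out) <- c("daily_effects", "data.frame")
  out
}

#' Cumulative photothermal effect (LTF)
#'
#' Sums the daily product fT(j) * fI(j) over an inclusive range of day
#' indices. The empty range (`start_day > end_day`) returns 0; over n days
#' the result lies in \[0, n\] and is non-decreasing in `end_day`.
#'
#' @param effects A [daily_effects()] data frame.
#' @param start_day,end_day 0-based day indices bounding the accumulation
#'   (inclusive). Default to the full series.
#'
#' @return A single non-negative number.
#' @export
#' @examples
#' w <- generate_weather(weather_regime("exp2"), days = 5, seed = 1)
#' cumulative_ltf(daily_effects(w))
cumulative_ltf <- function(effects,
                           start_day = min(effects$day_index),
                           end_day = max(effects$day_index)) {
  stopifnot(is.data.frame(effects),
            all(c("day_index", "f_t", "f_i") %in% names(effects)))
  if (start_day > end_day) return(0)
  if (start_day < min(effects$day_index) || end_day > max(effects$day_index)) {
    stop(sprintf("day range [%s, %s] outside the series [%s, %s]",
                 start_day, end_day,
                 min(effects$day_index), max(effects$day_index)),
         call. = FALSE)
  }
  keep <- effects$day_index >= start_day & effects$day_index <= end_day
  sum(effects$f_t[keep] * effects$f_i[keep])
}

#' Running LTF series
#'
#' Adds a column `ltf` holding the cumulative photothermal effect through
#' each day (from the first day of the series).
#'
#' @param effects A [daily_effects()] data frame.
#' @return The same data frame with an `ltf` column appended.
#' @export
ltf_series <- function(effects) {
  stopifnot(is.data.frame(effects),
            all(c("day_index", "f_t", "f_i") %in% names(effects)))
  effects$ltf <- cumsum(effects$f_t * effects$f_i)
  effects
}
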