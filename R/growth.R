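#' Fit an LTF-driven exponential growth model
#'
#' Fits `y = a * exp(b * LTF)` by Levenberg-Marquardt nonlinear least
#' squares on the natural scale, initialized from the log-linear OLS
#' solution (`lm(log(y) ~ ltf)`). The log-scale estimates are kept alongside
#' for comparison; on noiseless model-generated data the two routes agree.
#'
#' Goodness of fit is reported on the natural scale: R-squared about the
#' mean, its adjusted version with n - 2 residual degrees of freedom, and
#' the regression F statistic (regression mean square over residual mean
#' square with 1 and n - 2 df).
#'
#' @param points Data frame with columns `ltf` (cumulative photothermal
#'   effect, >= 0) and `y` (response, > 0).
#' @param response Which response the points represent: `"fw"` (fresh
#'   biomass, g/plant), `"dw"` (dry biomass, g/plant) or `"n_uptake"`
#'   (mg/plant). Bookkeeping only; the model is the same.
#' @return An object of class `growth_fit` with elements `intercept_a`,
#'   `rate_b`, `r2`, `r2_adj`, `f_stat`, `n_obs`, `response`, `log_scale`
#'   (the log-linear estimates) and the underlying `nls` object.
#' @seealso [predict_growth()]
#' @export
#' @examples
#' ltf <- c(0, 5, 10, 15, 20)
#' fit_growth(data.frame(ltf = ltf, y = 0.2816 * exp(0.121 * ltf)))
fit_growth <- function(points, response = c("fw", "dw", "n_uptake")) {
  response <- match.arg(response)
  if (!is.data.frame(points) || !all(c("ltf", "y") %in% names(points))) {
    stop("'points' must be a data.frame with columns ltf and y",
         call. = FALSE)
  }
  points <- points[is.finite(points$ltf) & is.finite(points$y), , drop = FALSE]
  n <- nrow(points)
  if (n < 3L) stop("need >= 3 points to fit the exponential model",
                   call. = FALSE)
  if (any(points$y <= 0)) {
    stop("all responses 'y' must be > 0 for the exponential model",
         call. = FALSE)
  }
  if (any(points$ltf < 0)) stop("'ltf' must be >= 0", call. = FALSE)
  loglin <- stats::lm(log(y) ~ ltf, data = points)
  start <- list(a = unname(exp(stats::coef(loglin)[1L])),
                b = unname(stats::coef(loglin)[2L]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * ltf), data = points, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) {
      stop("exponential fit failed to converge: ", conditionMessage(e),
           "\n  log-linear start was a = ", signif(start$a, 6),
           ", b = ", signif(start$b, 6), call. = FALSE)
    }
  )
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  sse <- sum(res^2)
  sst <- sum((points$y - mean(points$y))^2)
  r2 <- 1 - sse / sst
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  f_stat <- if (sse > 0) ((sst - sse) / 1) / (sse / (n - 2)) else Inf
  structure(list(intercept_a = unname(co["a"]),
                 rate_b = unname(co["b"]),
                 r2 = r2,
                 r2_adj = r2_adj,
                 f_stat = f_stat,
                 n_obs = n,
                 response = response,
                 log_scale = c(a = start$a, b = start$b),
                 nls_fit = fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  unit <- switch(x$response, fw = "g/plant", dw = "g/plant",
                 n_uptake = "mg/plant")
  cat(sprintf("Exponential growth fit (%s): y = %.4g * exp(%.4g * LTF)\n",
              x$response, x$intercept_a, x$rate_b))
  cat(sprintf("  intercept a in %s; adj R2 = %.4f, F = %.4g, n = %d\n",
              unit, x$r2_adj, x$f_stat, x$n_obs))
  invisible(x)
}

#' Predict growth from cumulative photothermal effect
#'
#' Evaluates `a * exp(b * ltf)`. `fit` may be a [fit_growth()] result or a
#' named vector/list with elements `a` and `b` (e.g. the published pakchoi
#' fresh-biomass calibration `c(a = 0.2816, b = 0.121)`).
#'
#' @param ltf Cumulative photothermal effect value(s), >= 0.
#' @param fit A `growth_fit` object or `c(a = , b = )`.
#' @return Predicted response, same units as the fitted `y`.
#' @export
#' @examples
#' predict_growth(c(0, 10, 20), c(a = 0.2816, b = 0.121))
predict_growth <- function(ltf, fit) {
  if (!is.numeric(ltf) || any(!is.finite(ltf)) || any(ltf < 0)) {
    stop("'ltf' must be finite and >= 0", call. = FALSE)
  }
  if (inherits(fit, "growth_fit")) {
    a <- fit$intercept_a
    b <- fit$rate_b
  } else {
    a <- fit[["a"]]
    b <- fit[["b"]]
  }
  if (is.null(a) || is.null(b)) {
    stop("'fit' must be a growth_fit or carry elements 'a' and 'b'",
         call. = FALSE)
  }
  a * exp(b * ltf)
}

#' @export
predict.growth_fit <- function(object, ltf, ...) predict_growth(ltf, object)

#' Quadratic response of the growth rate to nitrogen rate
#'
#' Container for `b(F) = c0 + c1 * F + c2 * F^2`, the empirical response of
#' the exponential rate parameter b to the nitrogen application rate F
#' (g N per kg of soil or substrate). With `c2 < 0` the response has an
#' interior maximum; see [optimal_n_rate()].
#'
#' @param c0,c1,c2 Polynomial coefficients (intercept, linear, quadratic).
#' @param f_units Units of the N rate axis.
#' @param r2 Optional coefficient of determination of the fit.
#' @return An object of class `b_quadratic`.
#' @export
b_quadratic <- function(c0, c1, c2, f_units = "g N kg-1", r2 = NA_real_) {
  stopifnot(is.numeric(c0), is.numeric(c1), is.numeric(c2),
            length(c0) == 1L, length(c1) == 1L, length(c2) == 1L)
  if (!all(is.finite(c(c0, c1, c2)))) {
    stop("quadratic coefficients must be finite", call. = FALSE)
  }
  structure(list(c0 = c0, c1 = c1, c2 = c2, f_units = f_units, r2 = r2),
            class = "b_quadratic")
}

#' @export
print.b_quadratic <- function(x, ...) {
  cat(sprintf("b(F) = %.4g + %.4g F + %.4g F^2   (F in %s%s)\n",
              x$c0, x$c1, x$c2, x$f_units,
              if (is.na(x$r2)) "" else sprintf(", r2 = %.4f", x$r2)))
  invisible(x)
}

#' Published pakchoi rate-parameter quadratics
#'
#' The calibrated quadratic responses of the exponential rate parameter b
#' to nitrogen application rate for the three responses: fresh biomass,
#' dry biomass and nitrogen uptake. Their vertex values round to 0.121,
#' 0.099 and 0.112 respectively.
#'
#' @return Named list of [b_quadratic()] objects: `fw`, `dw`, `n_uptake`.
#' @export
#' @examples
#' optimal_n_rate(pakchoi_b_quadratics()$fw)
pakchoi_b_quadratics <- function() {
  list(
    fw = b_quadratic(0.0665, 0.4749, -1.0323, r2 = 0.9649),
    dw = b_quadratic(0.0729, 0.2052, -0.3986, r2 = 0.9026),
    n_uptake = b_quadratic(0.0599, 0.4114, -0.8141, r2 = 0.8588)
  )
}

#' Evaluate the rate-parameter quadratic
#'
#' @param n_rate Nitrogen application rate(s), g N/kg, >= 0.
#' @param quad A [b_quadratic()] object.
#' @return Rate parameter b (per unit LTF), vectorized over `n_rate`.
#' @export
b_response <- function(n_rate, quad) {
  stopifnot(inherits(quad, "b_quadratic"))
  if (!is.numeric(n_rate) || any(!is.finite(n_rate)) || any(n_rate < 0)) {
    stop("'n_rate' must be finite and >= 0", call. = FALSE)
  }
  quad$c0 + quad$c1 * n_rate + quad$c2 * n_rate^2
}

#' Nitrogen rate maximizing the growth-rate parameter
#'
#' Vertex of the quadratic: `f_star = -c1 / (2 c2)` and
#' `b_max = c0 - c1^2 / (4 c2)`, requiring `c2 < 0`. When `interval` is
#' given, the maximum over that closed interval is also reported (the
#' vertex if it falls inside, otherwise the better endpoint) — useful when
#' the vertex lies outside the experimentally tested rate range.
#'
#' @param quad A [b_quadratic()] object with `c2 < 0`.
#' @param interval Optional length-2 numeric, a closed rate interval.
#' @return List with `f_star`, `b_max`, and when `interval` is supplied,
#'   `f_star_interval` and `b_max_interval`.
#' @export
#' @examples
#' optimal_n_rate(pakchoi_b_quadratics()$dw)
optimal_n_rate <- function(quad, interval = NULL) {
  stopifnot(inherits(quad, "b_quadratic"))
  if (quad$c2 >= 0) {
    stop("no interior maximum: quadratic coefficient c2 must be < 0",
         call. = FALSE)
  }
  f_star <- -quad$c1 / (2 * quad$c2)
  b_max <- quad$c0 - quad$c1^2 / (4 * quad$c2)
  out <- list(f_star = f_star, b_max = b_max)
  if (!is.null(interval)) {
    stopifnot(is.numeric(interval), length(interval) == 2L)
    lo <- min(interval)
    hi <- max(interval)
    cand_f <- c(lo, hi, if (f_star >= lo && f_star <= hi) f_star)
    cand_b <- b_response(cand_f, quad)
    k <- which.max(cand_b)
    out$f_star_interval <- cand_f[k]
    out$b_max_interval <- cand_b[k]
  }
  out
}

#' Fit the rate-parameter quadratic from (rate, b) pairs
#'
#' Degree-2 polynomial OLS of b on the nitrogen rate. Requires at least 4
#' points over at least 3 distinct rates (otherwise the design is rank
#' deficient).
#'
#' @param points Data frame with columns `n_rate` and `b`.
#' @return A [b_quadratic()] with the fitted coefficients and r2.
#' @export
fit_b_quadratic <- function(points) {
  if (!is.data.frame(points) || !all(c("n_rate", "b") %in% names(points))) {
    stop("'points' must be a data.frame with columns n_rate and b",
         call. = FALSE)
  }
  if (nrow(points) < 4L) {
    stop("need >= 4 points to fit the quadratic", call. = FALSE)
  }
  if (length(unique(points$n_rate)) < 3L) {
    stop("need >= 3 distinct nitrogen rates (design is rank deficient)",
         call. = FALSE)
  }
  fit <- stats::lm(b ~ n_rate + I(n_rate^2), data = points)
  co <- unname(stats::coef(fit))
  b_quadratic(co[1L], co[2L], co[3L],
              r2 = suppressWarnings(summary(fit)$r.squared))
}

#' Biomass and area conversion parameters
#'
#' `fw_dw_ratio` is the fresh-to-dry biomass ratio (pakchoi calibration
#' 25.64). `plant_density` (plants/ha) converts per-plant biomass to an
#' areal basis; it has no default because trials rarely state one — any
#' areal computation requires it explicitly.
#'
#' @param fw_dw_ratio Fresh weight per unit dry weight (> 0).
#' @param plant_density Plants per hectare (> 0), or `NULL` if no areal
#'   conversion is needed.
#' @return An object of class `conversion_params`.
#' @export
conversion_params <- function(fw_dw_ratio = 25.64, plant_density = NULL) {
  stopifnot(is.numeric(fw_dw_ratio), length(fw_dw_ratio) == 1L)
  if (!is.finite(fw_dw_ratio) || fw_dw_ratio <= 0) {
    stop("'fw_dw_ratio' must be > 0", call. = FALSE)
  }
  if (!is.null(plant_density)) {
    stopifnot(is.numeric(plant_density), length(plant_density) == 1L)
    if (!is.finite(plant_density) || plant_density <= 0) {
      stop("'plant_density' must be > 0 (plants/ha)", call. = FALSE)
    }
  }
  structure(list(fw_dw_ratio = fw_dw_ratio, plant_density = plant_density),
            class = "conversion_params")
}

#' @export
print.conversion_params <- function(x, ...) {
  cat(sprintf("Conversions: FW = %g * DW; plant density = %s\n",
              x$fw_dw_ratio,
              if (is.null(x$plant_density)) "<unset>"
              else format(x$plant_density, big.mark = ",")))
  invisible(x)
}

#' Convert between fresh and dry biomass
#'
#' Multiplies (or divides) by the fresh-to-dry ratio; the two functions are
#' exact inverses.
#'
#' @param dw,fw Biomass, g/plant (>= 0).
#' @param conv A [conversion_params()] object.
#' @return Converted biomass, g/plant.
#' @export
dw_to_fw <- function(dw, conv = conversion_params()) {
  stopifnot(inherits(conv, "conversion_params"))
  if (any(dw < 0)) stop("biomass must be >= 0", call. = FALSE)
  dw * conv$fw_dw_ratio
}

#' @rdname dw_to_fw
#' @export
fw_to_dw <- function(fw, conv = conversion_params()) {
  stopifnot(inherits(conv, "conversion_params"))
  if (any(fw < 0)) stop("biomass must be >= 0", call. = FALSE)
  fw / conv$fw_dw_ratio
}

#' Convert per-plant biomass to an areal basis
#'
#' `t/ha = g/plant * plants/ha * 1e-6`. Requires `plant_density` to be set
#' in `conv`; there is deliberately no default density.
#'
#' @param y Per-plant biomass, g/plant.
#' @param dw_area Areal biomass, t/ha.
#' @param conv A [conversion_params()] with `plant_density` set.
#' @return Areal biomass (t/ha), or per-plant biomass (g/plant) for the
#'   inverse.
#' @export
per_plant_to_area <- function(y, conv) {
  stopifnot(inherits(conv, "conversion_params"))
  if (is.null(conv$plant_density)) {
    stop("'plant_density' is not set: areal conversion needs an explicit density",
         call. = FALSE)
  }
  y * conv$plant_density * 1e-6
}

#' @rdname per_plant_to_area
#' @export
area_to_per_plant <- function(dw_area, conv) {
  stopifnot(inherits(conv, "conversion_params"))
  if (is.null(conv$plant_density)) {
    stop("'plant_density' is not set: areal conversion needs an explicit density",
         call. = FALSE)
  }
  dw_area * 1e6 / conv$plant_density
}
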