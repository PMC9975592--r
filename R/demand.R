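#' Nitrogen demand and supply parameters
#'
#' `crop_coefficient` scales the concentration gap into a per-plant N mass
#' (pakchoi calibration 0.39). `use_efficiency` is the fraction of supplied
#' N the crop actually captures; when not given it defaults by cultivation
#' system to the calibrated values 0.38 (substrate) and 0.17 (soil).
#'
#' @param system Cultivation system, `"substrate"` or `"soil"`; selects the
#'   default use efficiency.
#' @param crop_coefficient Dimensionless scaling constant (> 0).
#' @param use_efficiency Fraction in (0, 1]; overrides the system default.
#' @return An object of class `demand_params`.
#' @export
#' @examples
#' demand_params("soil")
demand_params <- function(system = c("substrate", "soil"),
                          crop_coefficient = 0.39,
                          use_efficiency = NULL) {
  system <- match.arg(system)
  if (is.null(use_efficiency)) {
    use_efficiency <- switch(system, substrate = 0.38, soil = 0.17)
  }
  stopifnot(is.numeric(crop_coefficient), length(crop_coefficient) == 1L,
            is.numeric(use_efficiency), length(use_efficiency) == 1L)
  if (!is.finite(crop_coefficient) || crop_coefficient <= 0) {
    stop("'crop_coefficient' must be > 0", call. = FALSE)
  }
  if (!is.finite(use_efficiency) || use_efficiency <= 0 ||
      use_efficiency > 1) {
    stop("'use_efficiency' must lie in (0, 1]", call. = FALSE)
  }
  structure(list(system = system, crop_coefficient = crop_coefficient,
                 use_efficiency = use_efficiency),
            class = "demand_params")
}

#' @export
print.demand_params <- function(x, ...) {
  cat(sprintf("N demand parameters: crop coefficient %g, use efficiency %g (%s)\n",
              x$crop_coefficient, x$use_efficiency, x$system))
  invisible(x)
}

#' Per-plant nitrogen demand
#'
#' `demand (g) = crop_coefficient * FW (g) * (Nc - Na) / 100`. The
#' concentrations enter as percentages of dry weight and are divided by 100
#' so the result is a mass: a 1-point concentration gap on a 30 g plant is
#' 0.39 * 30 * 0.01 = 0.117 g of N. When the plant is in excess
#' (`na_pct > nc_pct`) the raw value is negative; by default it is clamped
#' to zero (fertilizer advice cannot be negative) — the surplus is reported
#' separately by [demand_report()]. Set `clamp = FALSE` for the signed gap.
#'
#' @param fw Aboveground fresh biomass, g/plant (>= 0).
#' @param nc_pct Critical N concentration, % of dry weight.
#' @param na_pct Actual N concentration, % of dry weight.
#' @param params A [demand_params()] object.
#' @param clamp Clamp negative demand to zero? Default `TRUE`.
#' @return Nitrogen demand, g/plant, vectorized.
#' @export
#' @examples
#' n_demand(fw = 30, nc_pct = 4.78, na_pct = 3.78)
n_demand <- function(fw, nc_pct, na_pct, params = demand_params(),
                     clamp = TRUE) {
  stopifnot(inherits(params, "demand_params"))
  if (any(fw < 0) || any(nc_pct < 0) || any(na_pct < 0)) {
    stop("'fw', 'nc_pct' and 'na_pct' must be >= 0", call. = FALSE)
  }
  raw <- params$crop_coefficient * fw * (nc_pct - na_pct) / 100
  if (clamp) pmax(raw, 0) else raw
}

#' Per-plant nitrogen supply
#'
#' Fertilizer N to apply so that, at the configured use efficiency, the
#' plant captures its demand: `supply = demand / use_efficiency`. Equals
#' the demand at efficiency 1.
#'
#' @param demand Nitrogen demand, g/plant (>= 0).
#' @param params A [demand_params()] object.
#' @return Nitrogen supply, g/plant.
#' @export
#' @examples
#' n_supply(0.117, demand_params("substrate"))
n_supply <- function(demand, params = demand_params()) {
  stopifnot(inherits(params, "demand_params"))
  if (any(demand < 0)) stop("'demand' must be >= 0", call. = FALSE)
  demand / params$use_efficiency
}

#' Full nitrogen status and budget for plant states
#'
#' Composes the dilution curve, NNI, status classification and the
#' demand/supply equations for one or more plant states: evaluates the
#' critical concentration at the areal dry biomass, forms the NNI against
#' the measured concentration, classifies the status, and converts the
#' concentration gap into per-plant demand and supply. Excess plants get
#' zero demand and a positive `surplus_g` (the N mass above critical).
#'
#' @param fw Aboveground fresh biomass, g/plant.
#' @param dw_area Aboveground dry biomass on an areal basis, t/ha.
#' @param na_pct Measured N concentration, % of dry weight.
#' @param dil A [dilution_params()] object.
#' @param params A [demand_params()] object.
#' @param tolerance NNI tolerance for [classify_status()].
#' @return Data frame of class `demand_result` with one row per plant
#'   state: `fw_g`, `dw_t_ha`, `na_pct`, `nc_pct`, `nni`, `status`,
#'   `n_demand_g`, `n_supply_g`, `surplus_g`.
#' @export
#' @examples
#' demand_report(fw = 30, dw_area = 1.0, na_pct = 2.39)
demand_report <- function(fw, dw_area, na_pct,
                          dil = dilution_params(),
                          params = demand_params(),
                          tolerance = 0.05) {
  n <- max(length(fw), length(dw_area), length(na_pct))
  fw <- rep_len(fw, n)
  dw_area <- rep_len(dw_area, n)
  na_pct <- rep_len(na_pct, n)
  nc <- critical_n(dw_area, dil)
  idx <- nni(na_pct, nc)
  status <- classify_status(idx, tolerance)
  raw <- n_demand(fw, nc, na_pct, params, clamp = FALSE)
  demand <- pmax(raw, 0)
  out <- data.frame(
    fw_g = fw,
    dw_t_ha = dw_area,
    na_pct = na_pct,
    nc_pct = nc,
    nni = idx,
    status = status$label,
    n_demand_g = demand,
    n_supply_g = n_supply(demand, params),
    surplus_g = pmax(-raw, 0)
  )
  class(out) <- c("demand_result", "data.frame")
  out
}
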