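#' Critical nitrogen dilution curve parameters
#'
#' Parameters of the maximum/critical/minimum nitrogen envelope in the
#' CropSyst tradition. The critical curve is a plateau at
#' `plateau_fraction_c * n_max_pct` up to the dry-biomass breakpoint
#' `dw_break`, declining as a power law `a * DW^-b` beyond it; the maximum
#' and minimum envelopes use the same exponent with coefficients
#' `a_max = n_max_pct * 2^b` and `a_min = plateau_fraction_min * n_max_pct * 0.5^b`,
#' so they join their plateaus at 2 and 0.5 t/ha respectively.
#'
#' The pakchoi defaults put the critical plateau at 0.7 * 6.83 = 4.78 % of
#' dry weight with exponent 0.33 and a 1.5 t/ha breakpoint.
#'
#' Two treatments of the critical curve's breakpoint are provided. In
#' `"as_printed"` mode the power-law coefficient equals the plateau value
#' itself (the curve as usually quoted, `4.78 * DW^-0.33` above 1.5 t/ha),
#' which leaves a downward step of factor `dw_break^-b` at the breakpoint.
#' In `"continuous"` mode the coefficient is
#' `a_c = plateau_fraction_c * n_max_pct * dw_break^b`, which makes the
#' plateau and power law meet exactly at `dw_break`. The two modes agree for
#' `dw <= dw_break` and differ by the constant factor `dw_break^b` beyond it.
#'
#' @param n_max_pct Maximum (early-stage) N concentration, % of dry weight.
#' @param plateau_fraction_c Critical plateau as a fraction of `n_max_pct`.
#' @param plateau_fraction_min Minimum plateau as a fraction of `n_max_pct`.
#' @param exponent_b Dilution exponent b (> 0).
#' @param dw_break Dry biomass breakpoint of the critical curve, t/ha.
#' @param mode `"as_printed"` (default) or `"continuous"`; see Details.
#'
#' @return An object of class `dilution_params`.
#' @seealso [critical_n()], [n_max_curve()], [n_min_curve()], [nni()]
#' @export
#' @examples
#' p <- dilution_params()
#' critical_n(c(1, 1.5, 3), p)
dilution_params <- function(n_max_pct = 6.83,
                            plateau_fraction_c = 0.7,
                            plateau_fraction_min = 0.4,
                            exponent_b = 0.33,
                            dw_break = 1.5,
                            mode = c("as_printed", "continuous")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n_max_pct), is.numeric(plateau_fraction_c),
            is.numeric(plateau_fraction_min), is.numeric(exponent_b),
            is.numeric(dw_break))
  if (n_max_pct <= 0) stop("'n_max_pct' must be > 0", call. = FALSE)
  if (!(plateau_fraction_min > 0 && plateau_fraction_min < plateau_fraction_c &&
        plateau_fraction_c < 1)) {
    stop("need 0 < plateau_fraction_min < plateau_fraction_c < 1",
         call. = FALSE)
  }
  if (exponent_b <= 0) stop("'exponent_b' must be > 0", call. = FALSE)
  if (dw_break <= 0) stop("'dw_break' must be > 0", call. = FALSE)
  structure(list(n_max_pct = n_max_pct,
                 plateau_fraction_c = plateau_fraction_c,
                 plateau_fraction_min = plateau_fraction_min,
                 exponent_b = exponent_b,
                 dw_break = dw_break,
                 mode = mode),
            class = "dilution_params")
}

#' @export
print.dilution_params <- function(x, ...) {
  cat("Nitrogen dilution envelope parameters\n")
  cat(sprintf("  Nmax = %g %% DW, critical plateau = %g %% (fraction %g)\n",
              x$n_max_pct, x$plateau_fraction_c * x$n_max_pct,
              x$plateau_fraction_c))
  cat(sprintf("  exponent b = %g, breakpoint = %g t/ha, mode = %s\n",
              x$exponent_b, x$dw_break, x$mode))
  invisible(x)
}

check_dw <- function(dw) {
  if (!is.numeric(dw) || any(!is.finite(dw)) || any(dw <= 0)) {
    stop("dry biomass 'dw' must be finite and > 0 (t/ha)", call. = FALSE)
  }
  invisible(dw)
}

#' Critical nitrogen concentration
#'
#' Evaluates the critical N dilution curve: the minimal whole-plant N
#' concentration (% of dry weight) that still supports maximum growth at
#' aboveground dry biomass `dw` (t/ha). Constant at the plateau for
#' `dw <= dw_break` (the boundary belongs to the plateau) and declining as a
#' power of `dw` beyond it; non-increasing in `dw` in both modes.
#'
#' @param dw Aboveground dry biomass, t/ha (> 0). Vectorized.
#' @param params A [dilution_params()] object.
#' @return Critical N concentration(s), % of dry weight.
#' @export
#' @examples
#' critical_n(c(1, 1.5, 3))
critical_n <- function(dw, params = dilution_params()) {
  stopifnot(inherits(params, "dilution_params"))
  check_dw(dw)
  plateau <- params$plateau_fraction_c * params$n_max_pct
  b <- params$exponent_b
  if (params$mode == "as_printed") {
    ifelse(dw <= params$dw_break, plateau, plateau * dw^(-b))
  } else {
    a_c <- plateau * params$dw_break^b
    pmin(plateau, a_c * dw^(-b))
  }
}

#' Maximum nitrogen envelope
#'
#' Upper bound of plant N concentration: `min(Nmax, a_max * dw^-b)` with
#' `a_max = Nmax * 2^b`, so the plateau holds up to 2 t/ha.
#'
#' @inheritParams critical_n
#' @return Maximum N concentration(s), % of dry weight.
#' @export
n_max_curve <- function(dw, params = dilution_params()) {
  stopifnot(inherits(params, "dilution_params"))
  check_dw(dw)
  b <- params$exponent_b
  a_max <- params$n_max_pct * 2^b
  pmin(params$n_max_pct, a_max * dw^(-b))
}

#' Minimum nitrogen envelope
#'
#' Lower bound of plant N concentration:
#' `min(fmin * Nmax, a_min * dw^-b)` with
#' `a_min = fmin * Nmax * 0.5^b`, so the plateau joins the power law at
#' 0.5 t/ha.
#'
#' @inheritParams critical_n
#' @return Minimum N concentration(s), % of dry weight.
#' @export
n_min_curve <- function(dw, params = dilution_params()) {
  stopifnot(inherits(params, "dilution_params"))
  check_dw(dw)
  b <- params$exponent_b
  plateau <- params$plateau_fraction_min * params$n_max_pct
  a_min <- plateau * 0.5^b
  pmin(plateau, a_min * dw^(-b))
}

#' Nitrogen nutrition index
#'
#' NNI = actual N concentration / critical N concentration at the same
#' biomass. 1 indicates optimal nutrition; below 1, deficiency; above 1,
#' luxury uptake. Homogeneous of degree zero: scaling both concentrations
#' leaves the index unchanged.
#'
#' @param na_pct Actual (measured) N concentration, % of dry weight (>= 0).
#' @param nc_pct Critical N concentration, % of dry weight (> 0).
#' @return Dimensionless index, vectorized over the inputs.
#' @export
#' @examples
#' nni(2.39, critical_n(1.0))
nni <- function(na_pct, nc_pct) {
  if (!is.numeric(na_pct) || any(!is.finite(na_pct)) || any(na_pct < 0)) {
    stop("'na_pct' must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(nc_pct) || any(!is.finite(nc_pct)) || any(nc_pct <= 0)) {
    stop("'nc_pct' must be finite and > 0", call. = FALSE)
  }
  na_pct / nc_pct
}

#' Classify nitrogen nutrition status from the NNI
#'
#' Labels each NNI value `deficient` when below `1 - tolerance`, `excess`
#' when above `1 + tolerance`, and `optimal` in between. The tolerance band
#' exists because measured pipelines never hit 1 exactly.
#'
#' @param nni_value Nitrogen nutrition index value(s), >= 0.
#' @param tolerance Half-width of the optimal band around 1 (default 0.05).
#' @return A data frame of class `n_status` with columns `nni`, `label`
#'   (factor deficient/optimal/excess) and `tolerance`.
#' @export
#' @examples
#' classify_status(c(0.5, 1.0, 1.5))
classify_status <- function(nni_value, tolerance = 0.05) {
  if (!is.numeric(nni_value) || any(!is.finite(nni_value)) ||
      any(nni_value < 0)) {
    stop("'nni_value' must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    stop("'tolerance' must be a single number >= 0", call. = FALSE)
  }
  label <- ifelse(nni_value < 1 - tolerance, "deficient",
                  ifelse(nni_value > 1 + tolerance, "excess", "optimal"))
  out <- data.frame(
    nni = nni_value,
    label = factor(label, levels = c("deficient", "optimal", "excess")),
    tolerance = tolerance
  )
  class(out) <- c("n_status", "data.frame")
  out
}

#' Fit the dilution power law by log-log regression
#'
#' Ordinary least squares of `ln(n_pct)` on `ln(dw)` restricted to samples
#' with dry biomass above the plateau breakpoint (plateau points carry no
#' information about the power law). Returns the allometric coefficient
#' `a = exp(intercept)` and exponent `b = -slope`.
#'
#' @param samples Data frame with columns `dw_t_ha` and `n_pct`, or a
#'   two-column numeric data frame in that order.
#' @param dw_break Breakpoint below which samples are excluded (t/ha).
#' @return An object of class `dilution_fit`: a list with `a`, `b`, `r2`,
#'   `n_points` and the underlying `lm` fit.
#' @export
#' @examples
#' dw <- c(2, 3, 4, 5)
#' fit_dilution(data.frame(dw_t_ha = dw, n_pct = 4.78 * dw^-0.33))
fit_dilution <- function(samples, dw_break = 1.5) {
  if (!is.data.frame(samples)) stop("'samples' must be a data.frame",
                                    call. = FALSE)
  if (!all(c("dw_t_ha", "n_pct") %in% names(samples))) {
    stop("'samples' needs columns dw_t_ha and n_pct", call. = FALSE)
  }
  ok <- is.finite(samples$dw_t_ha) & is.finite(samples$n_pct) &
    samples$dw_t_ha > dw_break & samples$n_pct > 0
  usable <- samples[ok, , drop = FALSE]
  if (nrow(usable) < 3L) {
    stop(sprintf("need >= 3 samples with dw > %g t/ha to fit the power law (have %d)",
                 dw_break, nrow(usable)), call. = FALSE)
  }
  fit <- stats::lm(log(n_pct) ~ log(dw_t_ha), data = usable)
  co <- stats::coef(fit)
  structure(list(a = unname(exp(co[1L])),
                 b = unname(-co[2L]),
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 n_points = nrow(usable),
                 dw_break = dw_break,
                 lm_fit = fit),
            class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat("Critical N dilution power-law fit (log-log OLS)\n")
  cat(sprintf("  Nc = %.4g * DW^-%.4g   (r2 = %.4f, n = %d, dw > %g t/ha)\n",
              x$a, x$b, x$r2, x$n_points, x$dw_break))
  invisible(x)
}
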