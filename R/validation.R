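#' Agreement statistics between measured and simulated values
#'
#' The agreement summary used throughout model validation: Pearson
#' correlation `r` and its square `r2` for the 1:1 comparison, root mean
#' square error of the paired differences, the relative standard error of
#' prediction, and the slope of the OLS regression of simulated on
#' measured. The relative standard error is the residual standard deviation
#' of that regression expressed as a percentage of the mean measured value;
#' the regression direction (simulated on measured) is fixed, so `re_pct`
#' and `slope_1to1` are not symmetric in their arguments while `r` and
#' `rmse` are.
#'
#' @param measured Numeric vector of measured values (not all identical).
#' @param simulated Numeric vector of simulated/predicted values, same
#'   length.
#' @return An object of class `agreement_report`: list with `r`, `r2`,
#'   `rmse`, `re_pct`, `slope_1to1`, `intercept_1to1`, `n`.
#' @export
#' @examples
#' agreement(c(1, 2, 3), c(1.1, 1.9, 3.2))
agreement <- function(measured, simulated) {
  if (!is.numeric(measured) || !is.numeric(simulated)) {
    stop("'measured' and 'simulated' must be numeric", call. = FALSE)
  }
  if (length(measured) != length(simulated)) {
    stop("'measured' and 'simulated' must have equal length", call. = FALSE)
  }
  n <- length(measured)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (any(!is.finite(measured)) || any(!is.finite(simulated))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::var(measured) == 0) {
    stop("'measured' has zero variance", call. = FALSE)
  }
  r <- if (stats::var(simulated) == 0) 0 else
    stats::cor(measured, simulated)
  fit <- stats::lm(simulated ~ measured)
  sigma_hat <- suppressWarnings(summary(fit)$sigma)
  structure(list(
    r = r,
    r2 = r^2,
    rmse = sqrt(mean((simulated - measured)^2)),
    re_pct = 100 * sigma_hat / mean(measured),
    slope_1to1 = unname(stats::coef(fit)[2L]),
    intercept_1to1 = unname(stats::coef(fit)[1L]),
    n = n
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Measured vs simulated agreement\n")
  cat(sprintf("  r = %.4f (r2 = %.4f), RMSE = %.4g, RE = %.2f%%\n",
              x$r, x$r2, x$rmse, x$re_pct))
  cat(sprintf("  simulated ~ measured: slope %.4f, intercept %.4g, n = %d\n",
              x$slope_1to1, x$intercept_1to1, x$n))
  invisible(x)
}

#' Monte-Carlo parameter-recovery study
#'
#' Repeatedly simulates trials with [generate_trial()], refits the growth
#' and dilution models, and summarizes bias and RMSE of each recovered
#' parameter against the injected truth. Growth parameters (fresh- and
#' dry-biomass intercept and rate) are recovered from per-day treatment
#' means at one nitrogen rate; the dilution coefficient and exponent are
#' recovered by [fit_dilution()] from critical-curve points at `dw_grid`
#' carrying the same multiplicative noise. With `noise_cv = 0` every
#' parameter is recovered exactly — the strongest end-to-end pipeline
#' check.
#'
#' @param n_replicates Number of simulated trials (>= 1).
#' @param noise_cv Per-plant multiplicative noise CV used in every trial.
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @param design A [trial_design()] (its `noise_cv` and `seed` are
#'   overridden per replicate).
#' @param regime A [weather_regime()].
#' @param rate Nitrogen rate whose growth fit is tracked; defaults to the
#'   highest rate in the design.
#' @param dw_grid Dry-biomass grid (t/ha, above the breakpoint) for the
#'   dilution-recovery channel.
#' @param dilution A [dilution_params()] defining the injected truth.
#' @return Data frame of class `recovery_summary` with one row per
#'   parameter: `parameter`, `truth`, `mean_estimate`, `bias`, `rmse`,
#'   `n_replicates`.
#' @export
#' @examples
#' recovery_study(n_replicates = 5, noise_cv = 0, seed = 1)
recovery_study <- function(n_replicates = 200, noise_cv = 0.08, seed = 1,
                           design = trial_design(),
                           regime = weather_regime("exp2"),
                           rate = max(design$n_rates),
                           dw_grid = c(2, 3, 4, 5),
                           dilution = dilution_params()) {
  stopifnot(n_replicates >= 1, noise_cv >= 0)
  if (any(dw_grid <= dilution$dw_break)) {
    stop("'dw_grid' must lie above the dilution breakpoint", call. = FALSE)
  }
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, n_replicates)

  quads <- pakchoi_b_quadratics()
  truth <- c(a_fw = 0.2816,
             b_fw = b_response(rate, quads$fw),
             b_dw = b_response(rate, quads$dw),
             dilution_a = dilution$plateau_fraction_c * dilution$n_max_pct,
             dilution_b = dilution$exponent_b)
  nc_true <- critical_n(dw_grid, dilution)

  est <- matrix(NA_real_, nrow = n_replicates, ncol = length(truth),
                dimnames = list(NULL, names(truth)))
  for (i in seq_len(n_replicates)) {
    d <- design
    d$noise_cv <- noise_cv
    d$seed <- rep_seeds[i]
    trial <- generate_trial(d, regime, dilution = dilution)
    pts <- trial_growth_points(trial)
    pts <- pts[pts$n_rate == rate, , drop = FALSE]
    fit_fw <- fit_growth(data.frame(ltf = pts$ltf, y = pts$fw), "fw")
    fit_dw <- fit_growth(data.frame(ltf = pts$ltf, y = pts$dw), "dw")
    # dilution channel: critical-curve points with the same noise model,
    # drawn from the trial's RNG stream
    nc_noisy <- nc_true * lognorm_factors(length(dw_grid), noise_cv)
    dfit <- fit_dilution(data.frame(dw_t_ha = dw_grid, n_pct = nc_noisy),
                         dw_break = dilution$dw_break)
    est[i, ] <- c(fit_fw$intercept_a, fit_fw$rate_b, fit_dw$rate_b,
                  dfit$a, dfit$b)
  }
  out <- data.frame(
    parameter = names(truth),
    truth = unname(truth),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - unname(truth),
    rmse = sqrt(colMeans(sweep(est, 2, truth)^2)),
    n_replicates = n_replicates,
    row.names = NULL
  )
  class(out) <- c("recovery_summary", "data.frame")
  out
}
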