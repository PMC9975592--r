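# Independent oracles and small constructors used across the suite.

# 1-D grid search for the dilution power law: for each candidate exponent b
# the optimal log-coefficient is the mean of ln(n) + b*ln(dw), so a dense
# grid over b brute-forces the log-log least-squares problem.
oracle_fit_dilution_grid <- function(dw, n_pct,
                                     b_grid = seq(0.1, 0.6, by = 1e-4)) {
  ln <- log(n_pct)
  ld <- log(dw)
  sse <- vapply(b_grid, function(b) {
    la <- mean(ln + b * ld)
    sum((ln - (la - b * ld))^2)
  }, numeric(1))
  b <- b_grid[which.min(sse)]
  list(a = exp(mean(ln + b * ld)), b = b)
}

# Degree-2 polynomial least squares solved directly from the normal
# equations, independent of lm().
oracle_quad_normal_eq <- function(n_rate, b) {
  X <- cbind(1, n_rate, n_rate^2)
  as.numeric(solve(t(X) %*% X, t(X) %*% b))
}

# Hourly weather table with a fixed 24-hour temperature profile (recycled
# over days) and a daily PAR total spread evenly over hours 6..17.
make_const_weather <- function(days, temp = 24, par_total_mol = 5) {
  hour <- rep(0:23, days)
  data.frame(
    date = rep(as.Date("2020-03-01") + seq_len(days) - 1L, each = 24L),
    hour = hour,
    temp_c = rep(rep_len(temp, 24L), days),
    par_mol_m2 = ifelse(hour %in% 6:17, par_total_mol / 12, 0)
  )
}

# Daily-effects table built directly (bypassing daily_effects) for LTF
# arithmetic checks.
make_effects <- function(f_t, f_i) {
  structure(
    data.frame(day_index = seq_along(f_t) - 1L,
               date = as.Date("2020-03-01") + seq_along(f_t) - 1L,
               f_t = f_t, f_i = f_i,
               daily_par_mmol = NA_real_),
    class = c("daily_effects", "data.frame"))
}
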