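test_that("critical N plateau and power law match the pakchoi calibration", {
  p <- dilution_params()
  expect_equal(critical_n(1.0, p), 0.7 * 6.83)
  expect_equal(round(critical_n(1.0, p), 2), 4.78)
  expect_equal(critical_n(1.5, p), critical_n(1.0, p))  # boundary on plateau
  # direct evaluation cross-checked by log-space arithmetic
  expect_equal(critical_n(3.0, p), 0.7 * 6.83 * 3^(-0.33))
  expect_equal(critical_n(3.0, p), exp(log(0.7 * 6.83) - 0.33 * log(3)))
  expect_equal(critical_n(3.0, p), 3.327122, tolerance = 1e-6)
  expect_error(critical_n(0, p), "dw")
  expect_error(critical_n(-1, p), "dw")
})

test_that("continuous mode removes the breakpoint step, as_printed keeps it", {
  pa <- dilution_params(mode = "as_printed")
  pc <- dilution_params(mode = "continuous")
  eps <- 1e-9
  # continuity by construction just above the break
  expect_equal(critical_n(1.5 + eps, pc), critical_n(1.5, pc),
               tolerance = 1e-8)
  # the printed curve steps down by the factor dw_break^-b
  expect_equal(critical_n(1.5 + eps, pa) / critical_n(1.5, pa),
               1.5^(-0.33), tolerance = 1e-6)
  # modes agree below the break and differ by dw_break^b above it
  dw <- c(0.2, 0.7, 1.2, 1.5)
  expect_equal(critical_n(dw, pa), critical_n(dw, pc))
  dw_hi <- c(1.6, 2.5, 4, 8)
  expect_equal(critical_n(dw_hi, pc) / critical_n(dw_hi, pa),
               rep(1.5^0.33, length(dw_hi)))
})

test_that("maximum and minimum envelopes join their plateaus where derived", {
  p <- dilution_params()
  expect_equal(n_max_curve(2.0, p), 6.83)          # both branches equal
  expect_equal(n_max_curve(1.0, p), 6.83)          # plateau
  expect_equal(n_max_curve(4.0, p), 6.83 * (4 / 2)^(-0.33))
  expect_equal(n_max_curve(4.0, p), 5.433514, tolerance = 1e-6)
  expect_equal(n_min_curve(0.5, p), 0.4 * 6.83)    # join point
  expect_equal(n_min_curve(0.25, p), 2.732)        # plateau side
  expect_equal(n_min_curve(1.0, p), 0.4 * 6.83 * 0.5^0.33)
  expect_equal(n_min_curve(1.0, p), 2.173406, tolerance = 1e-6)
})

test_that("envelopes stay ordered and non-increasing over a biomass grid", {
  pc <- dilution_params(mode = "continuous")
  pa <- dilution_params(mode = "as_printed")
  dw <- exp(seq(log(0.05), log(20), length.out = 400))
  lo <- n_min_curve(dw, pc)
  mid <- critical_n(dw, pc)
  hi <- n_max_curve(dw, pc)
  expect_true(all(lo <= mid + 1e-12 & mid <= hi + 1e-12))
  expect_true(all(diff(mid) <= 1e-12))
  expect_true(all(diff(critical_n(dw, pa)) <= 1e-12))
  expect_true(all(diff(lo) <= 1e-12) && all(diff(hi) <= 1e-12))
})

test_that("NNI is the concentration ratio and is scale invariant", {
  expect_identical(nni(4.78, 4.78), 1)
  expect_equal(nni(2.39, 4.78), 0.5)
  expect_equal(nni(0, 4.78), 0)
  for (k in c(0.1, 1, 3, 17)) {
    expect_equal(nni(k * 2.1, k * 4.2), nni(2.1, 4.2))
  }
  expect_error(nni(1, 0), "nc_pct")
  expect_error(nni(-1, 2), "na_pct")
})

test_that("status classification splits at 1 minus/plus the tolerance", {
  s <- classify_status(c(0.5, 0.9499, 0.95, 1, 1.05, 1.0501, 1.5),
                       tolerance = 0.05)
  expect_equal(as.character(s$label),
               c("deficient", "deficient", "optimal", "optimal", "optimal",
                 "excess", "excess"))
  # label is optimal exactly when nni lies inside [1 - tol, 1 + tol]
  expect_equal(s$label == "optimal",
               s$nni >= 1 - s$tolerance & s$nni <= 1 + s$tolerance)
  strict <- classify_status(c(0.999, 1, 1.001), tolerance = 0)
  expect_equal(as.character(strict$label),
               c("deficient", "optimal", "excess"))
})

test_that("log-log fit recovers the dilution curve from model points", {
  dw <- c(2, 3, 4, 5)
  pts <- data.frame(dw_t_ha = dw, n_pct = 4.78 * dw^(-0.33))
  fit <- fit_dilution(pts)
  expect_equal(fit$a, 4.78, tolerance = 1e-9)
  expect_equal(fit$b, 0.33, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$n_points, 4L)
})

test_that("noisy dilution fit agrees with the grid-search oracle", {
  set.seed(42)
  dw <- c(2, 2.5, 3, 3.5, 4, 4.5, 5)
  n_pct <- 4.78 * dw^(-0.33) * exp(rnorm(length(dw), 0, 0.02))
  fit <- fit_dilution(data.frame(dw_t_ha = dw, n_pct = n_pct))
  oracle <- oracle_fit_dilution_grid(dw, n_pct)
  expect_equal(fit$b, oracle$b, tolerance = 1e-3)  # grid resolution 1e-4
  expect_equal(fit$a, oracle$a, tolerance = 1e-3)
  expect_lt(abs(fit$b - 0.33), 0.03)
})

test_that("dilution fit refuses plateau-only or sparse data", {
  # plateau points (dw <= break) are excluded, leaving too few
  pts <- data.frame(dw_t_ha = c(0.5, 1.0, 1.4, 2, 3), n_pct = rep(4.78, 5))
  expect_error(fit_dilution(pts), ">= 3 samples")
  expect_error(
    fit_dilution(data.frame(dw_t_ha = c(2, 3), n_pct = c(3.8, 3.3))),
    ">= 3 samples")
})

test_that("dilution parameter validation catches inverted fractions", {
  expect_error(dilution_params(plateau_fraction_min = 0.8), "plateau_fraction")
  expect_error(dilution_params(exponent_b = -0.1), "exponent_b")
  expect_error(dilution_params(n_max_pct = 0), "n_max_pct")
})
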