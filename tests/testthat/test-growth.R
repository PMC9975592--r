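test_that("growth prediction evaluates a*exp(b*LTF)", {
  cal <- c(a = 0.2816, b = 0.121)
  expect_equal(predict_growth(0, cal), 0.2816)
  expect_equal(predict_growth(10, cal), 0.2816 * exp(1.21))
  expect_equal(predict_growth(10, cal), 0.944341, tolerance = 1e-6)
  expect_equal(predict_growth(c(1, 5, 50), c(a = 3, b = 0)), rep(3, 3))
  expect_error(predict_growth(-1, cal), "ltf")
})

test_that("exponential fit recovers noiseless parameters on both scales", {
  ltf <- c(0, 5, 10, 15, 20)
  pts <- data.frame(ltf = ltf, y = 0.2816 * exp(0.121 * ltf))
  fit <- fit_growth(pts, "fw")
  expect_equal(fit$intercept_a, 0.2816, tolerance = 1e-8)
  expect_equal(fit$rate_b, 0.121, tolerance = 1e-8)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-9)
  expect_equal(fit$n_obs, 5L)
  # log-linear route agrees with the nonlinear route on noiseless data
  expect_equal(unname(fit$log_scale["a"]), fit$intercept_a, tolerance = 1e-8)
  expect_equal(unname(fit$log_scale["b"]), fit$rate_b, tolerance = 1e-8)
})

test_that("exponential fit rejects invalid inputs", {
  expect_error(fit_growth(data.frame(ltf = c(0, 1), y = c(1, 2))),
               ">= 3 points")
  expect_error(
    fit_growth(data.frame(ltf = c(0, 1, 2), y = c(1, -2, 3))),
    "> 0")
})

test_that("F statistic uses the 1 and n-2 regression decomposition", {
  set.seed(7)
  ltf <- seq(0, 30, by = 5)
  y <- 0.3 * exp(0.1 * ltf) * exp(rnorm(length(ltf), 0, 0.05))
  fit <- fit_growth(data.frame(ltf = ltf, y = y))
  yhat <- predict_growth(ltf, fit)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  n <- length(y)
  expect_equal(fit$f_stat, ((sst - sse) / 1) / (sse / (n - 2)))
  expect_equal(fit$r2_adj, 1 - (1 - (1 - sse / sst)) * (n - 1) / (n - 2))
  expect_lte(fit$r2_adj, 1)
})

test_that("rate-parameter quadratics reproduce the printed calibration", {
  q <- pakchoi_b_quadratics()
  # hand arithmetic at F = 0.2 g/kg
  expect_equal(b_response(0.2, q$fw), 0.120188)
  expect_equal(b_response(0.2, q$dw), 0.097996)
  expect_equal(b_response(0, q$fw), 0.0665)
  # vertex values round to the published maxima
  b_max <- vapply(q, function(x) optimal_n_rate(x)$b_max, numeric(1))
  expect_equal(round(unname(b_max), 3), c(0.121, 0.099, 0.112))
})

test_that("the vertex satisfies the first-order condition", {
  for (quad in pakchoi_b_quadratics()) {
    v <- optimal_n_rate(quad)
    expect_lt(abs(quad$c1 + 2 * quad$c2 * v$f_star), 1e-12)
    expect_equal(b_response(v$f_star, quad), v$b_max)
  }
  toy <- optimal_n_rate(b_quadratic(0, 2, -1))
  expect_equal(toy$f_star, 1)
  expect_equal(toy$b_max, 1)
  expect_error(optimal_n_rate(b_quadratic(1, 1, 0.5)), "interior maximum")
})

test_that("interval-constrained maximum picks the best feasible rate", {
  q <- pakchoi_b_quadratics()$dw  # vertex at 0.257 g/kg, outside [0, 0.2]
  v <- optimal_n_rate(q, interval = c(0, 0.2))
  expect_gt(v$f_star, 0.2)
  expect_equal(v$f_star_interval, 0.2)
  expect_equal(v$b_max_interval, b_response(0.2, q))
  # vertex inside the interval is returned as is
  v2 <- optimal_n_rate(pakchoi_b_quadratics()$fw, interval = c(0, 0.5))
  expect_equal(v2$f_star_interval, v2$f_star)
})

test_that("quadratic fit recovers coefficients exactly and matches the
           normal-equations oracle under noise", {
  q <- pakchoi_b_quadratics()$fw
  rates <- c(0, 0.05, 0.1, 0.2)
  pts <- data.frame(n_rate = rates, b = b_response(rates, q))
  fit <- fit_b_quadratic(pts)
  expect_equal(c(fit$c0, fit$c1, fit$c2), c(q$c0, q$c1, q$c2),
               tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  set.seed(5)
  rates2 <- rep(c(0, 0.05, 0.1, 0.15, 0.2), each = 3)
  b_noisy <- b_response(rates2, q) + rnorm(length(rates2), 0, 0.003)
  fit2 <- fit_b_quadratic(data.frame(n_rate = rates2, b = b_noisy))
  oracle <- oracle_quad_normal_eq(rates2, b_noisy)
  expect_equal(c(fit2$c0, fit2$c1, fit2$c2), oracle, tolerance = 1e-9)

  expect_error(fit_b_quadratic(pts[1:3, ]), ">= 4 points")
  expect_error(
    fit_b_quadratic(data.frame(n_rate = c(0, 0, 0.1, 0.1),
                               b = c(1, 1.1, 2, 2.1))),
    "distinct")
})

test_that("biomass conversions apply the ratio and round trip", {
  conv <- conversion_params()
  expect_equal(dw_to_fw(1), 25.64)
  expect_equal(dw_to_fw(1.5), 38.46)
  x <- c(0, 0.3, 2.7)
  expect_equal(fw_to_dw(dw_to_fw(x)), x)
  expect_error(dw_to_fw(-1), ">= 0")
})

test_that("areal conversion needs an explicit density and composes", {
  conv <- conversion_params(plant_density = 1e6)
  expect_equal(per_plant_to_area(1, conv), 1)
  expect_equal(area_to_per_plant(per_plant_to_area(2.5, conv), conv), 2.5)
  conv3 <- conversion_params(plant_density = 577000)
  expect_equal(per_plant_to_area(2.6, conv3), 1.5, tolerance = 1e-2)
  expect_error(per_plant_to_area(1, conversion_params()), "plant_density")
  # ratio commutes with the areal scaling
  expect_equal(per_plant_to_area(dw_to_fw(2, conv), conv),
               dw_to_fw(per_plant_to_area(2, conv), conv))
})
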