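test_that("weather generation is deterministic and hits the regime mean", {
  reg <- weather_regime("exp13")
  w1 <- generate_weather(reg, days = 30, seed = 1)
  w2 <- generate_weather(reg, days = 30, seed = 1)
  expect_identical(w1, w2)
  w3 <- generate_weather(reg, days = 30, seed = 2)
  expect_false(identical(w1$temp_c, w3$temp_c))

  expect_equal(nrow(w1), 30 * 24)
  daily_means <- tapply(w1$temp_c, w1$date, mean)
  expect_lt(abs(mean(daily_means) - 19), 0.5)
  expect_true(all(w1$par_mol_m2 >= 0))
  expect_true(all(w1$par_mol_m2[w1$hour %in% c(0:5, 20:23)] == 0))
  daily_par <- tapply(w1$par_mol_m2, w1$date, sum)
  expect_lt(abs(mean(daily_par) - 5.3), 1.0)
})

test_that("zero amplitude and zero PAR spread give a perfectly periodic series", {
  reg <- weather_regime("custom", t_mean = 22, t_amplitude = 0,
                        par_daily_mean = 6, par_daily_sd = 0)
  w <- generate_weather(reg, days = 4, seed = 9)
  m <- matrix(w$temp_c, nrow = 24)
  expect_true(all(m == m[, 1]))
  expect_true(all(w$temp_c == 22))
  p <- matrix(w$par_mol_m2, nrow = 24)
  expect_true(all(p == p[, 1]))
  expect_equal(unname(colSums(p)), rep(6, 4))
})

test_that("diurnal profile has its minimum pre-dawn and maximum mid-afternoon", {
  reg <- weather_regime("custom", t_mean = 20, t_amplitude = 5,
                        par_daily_sd = 0)
  w <- generate_weather(reg, days = 1, seed = 1)
  det <- 20 - 5 * cos(2 * pi * (0:23 - 3) / 24)
  expect_equal(which.min(det) - 1, 3)
  expect_equal(which.max(det) - 1, 15)
  expect_lt(max(abs(w$temp_c - det)), 1.5)  # noise is small vs amplitude
})

test_that("noiseless trials lie exactly on the injected trajectories", {
  design <- trial_design(noise_cv = 0, seed = 5)
  trial <- generate_trial(design)
  eff <- attr(trial, "effects")
  truth <- attr(trial, "truth")
  for (rate in names(truth)) {
    tr <- truth[[rate]]
    sub <- trial[trial$n_rate == tr$n_rate, ]
    L <- eff$ltf[sub$day]
    expect_equal(sub$fw, tr$a_fw * exp(tr$b_fw * L), tolerance = 1e-12)
    expect_equal(sub$dw, tr$a_dw * exp(tr$b_dw * L), tolerance = 1e-12)
  }
  # identical plants within a sampling day when noise is off
  expect_equal(anyDuplicated(trial[trial$plant == 1,
                                   c("day", "n_rate", "fw")]), 0)
})

test_that("fitting a noiseless trial recovers the injected growth parameters", {
  trial <- generate_trial(trial_design(noise_cv = 0, seed = 5))
  pts <- trial_growth_points(trial)
  truth <- attr(trial, "truth")[["0.2"]]
  sub <- pts[pts$n_rate == 0.2, ]
  fit_fw <- fit_growth(data.frame(ltf = sub$ltf, y = sub$fw), "fw")
  fit_dw <- fit_growth(data.frame(ltf = sub$ltf, y = sub$dw), "dw")
  expect_equal(fit_fw$intercept_a, truth$a_fw, tolerance = 1e-8)
  expect_equal(fit_fw$rate_b, truth$b_fw, tolerance = 1e-8)
  expect_equal(fit_dw$rate_b, truth$b_dw, tolerance = 1e-8)
})

test_that("noisy default trial still fits cleanly on treatment means", {
  trial <- generate_trial(trial_design(seed = 7))  # CV 0.08, 12 plants
  pts <- trial_growth_points(trial)
  for (resp in c("fw", "dw", "n_uptake")) {
    sub <- pts[pts$n_rate == 0.2, ]
    fit <- fit_growth(data.frame(ltf = sub$ltf, y = sub[[resp]]), resp)
    expect_gt(fit$r2_adj, 0.99)
  }
})

test_that("pre-noise %N respects the envelope and uptake is self-consistent", {
  trial <- generate_trial(trial_design(noise_cv = 0, seed = 13))
  conv <- attr(trial, "conversion")
  dw_area <- per_plant_to_area(trial$dw, conv)
  expect_true(all(trial$n_pct <= n_max_curve(dw_area) + 1e-9))
  expect_true(all(trial$n_pct >= n_min_curve(dw_area) - 1e-9))
  # uptake used downstream equals dw * n_pct / 100 (in mg)
  pts <- trial_growth_points(trial)
  means <- stats::aggregate(cbind(dw, n_pct) ~ n_rate + day, trial, mean)
  means <- means[order(means$n_rate, means$day), ]
  expect_equal(pts$n_uptake, means$dw * means$n_pct * 10, tolerance = 1e-9)
})

test_that("noise produces envelope violations at roughly the implied rate", {
  cv <- 0.08
  trial <- generate_trial(trial_design(noise_cv = cv, seed = 21,
                                       plants_per_sample = 50))
  conv <- attr(trial, "conversion")
  dw_area <- per_plant_to_area(trial$dw, conv)
  viol <- mean(trial$n_pct > n_max_curve(dw_area) |
                 trial$n_pct < n_min_curve(dw_area))
  # many pre-noise values sit on the Nmax boundary, so violations occur but
  # cannot exceed one half per boundary point plus noise on dw itself
  expect_gt(viol, 0.01)
  expect_lt(viol, 0.6)
})

test_that("trials are reproducible and designs validate", {
  d <- trial_design(seed = 99)
  expect_identical(generate_trial(d), generate_trial(d))
  expect_error(trial_design(sampling_days = 50, duration_days = 42),
               "sampling_days")
  expect_error(trial_design(noise_cv = -0.1), "noise_cv")
  expect_error(trial_design(n_rates = -0.1), "n_rates")
})

test_that("fixtures are written deterministically and parse cleanly", {
  dir1 <- file.path(tempdir(), "fixt1")
  paths <- make_fixture("minimal", dir1)
  expect_true(all(file.exists(paths)))
  expect_no_warning({
    w <- read_weather_csv(paths[["weather"]])
    s <- read_plant_samples_csv(paths[["samples"]])
  })
  expect_equal(nrow(w), 3 * 24)
  expect_equal(nrow(s), 2)  # 2 rates x 1 day x 1 plant

  paths2 <- make_fixture("exp2_like", file.path(tempdir(), "fixt2"))
  s2 <- read_plant_samples_csv(paths2[["samples"]])
  expect_equal(length(unique(s2$n_rate)), 4L)
  expect_equal(max(s2$day), 42)
  # re-generation is byte-identical
  paths3 <- make_fixture("minimal", file.path(tempdir(), "fixt3"))
  expect_identical(readLines(paths[["samples"]]),
                   readLines(paths3[["samples"]]))
  expect_error(make_fixture("nope"), "unknown fixture")
})
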