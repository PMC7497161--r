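test_that("calibration fits the conversion line", {
  cal <- calibrate(data.frame(conc = c(2, 4), au = c(4, 8)))
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)

  # noisy line: slope recovered within 3 standard errors (OLS oracle)
  withr::with_seed(17, {
    conc <- c(20, 6.9, 2.4, 0.8, 0.3, 0.1)
    au <- 3 * conc + stats::rnorm(6, 0, 0.1)
  })
  cal2 <- calibrate(data.frame(conc = conc, au = au))
  ols <- stats::lm(au ~ conc)
  expect_equal(cal2$slope, unname(stats::coef(ols)["conc"]), tolerance = 1e-12)
  se <- summary(ols)$coefficients["conc", "Std. Error"]
  expect_lt(abs(cal2$slope - 3), 3 * se)

  # adding a constant shifts the intercept only
  cal3 <- calibrate(data.frame(conc = conc, au = au + 100))
  expect_equal(cal3$slope, cal2$slope, tolerance = 1e-9)
  expect_equal(cal3$intercept, cal2$intercept + 100, tolerance = 1e-9)

  expect_error(calibrate(data.frame(conc = c(2, 2), au = c(1, 2))),
               "distinct")
})

test_that("initial slopes recover the calibrated rate", {
  cal <- fret_calibration(slope = 50, intercept = 10)
  t <- 0:300
  lin <- progress_curve(t, 10 + 50 * 0.02 * t, substrate_conc = 200,
                        enzyme_conc = 1)
  expect_equal(initial_slope(lin, cal), 0.02, tolerance = 1e-9)

  flat <- progress_curve(t, rep(10, length(t)), 200, 1)
  expect_equal(initial_slope(flat, cal), 0, tolerance = 1e-12)

  # substrate depletion: slope over 60 s stays within 5% of v(S0)
  # oracle: independent adaptive-solver integration of the rate law
  KM <- 100; Vmax <- 0.2; S0 <- 200
  sol <- deSolve::ode(y = c(S = S0), times = 0:60,
                      func = function(t, y, p) list(-Vmax * y[1] / (KM + y[1])),
                      parms = NULL, method = "lsoda")
  curve <- progress_curve(0:60, 10 + 50 * (S0 - sol[, "S"]), S0, 1)
  v0 <- Vmax * S0 / (KM + S0)
  expect_equal(initial_slope(curve, cal, window = 60), v0, tolerance = 0.05)

  expect_error(initial_slope(progress_curve(c(0, 400, 800), c(1, 2, 3), 10, 1),
                             cal, window = 180),
               "fewer than 3")
})

test_that("Michaelis-Menten fitting recovers exact parameters on clean data", {
  KM <- 89; Vmax <- 7.1e-3
  S <- c(200, 100, 50, 20, 10)
  rates <- data.frame(S = S, v = Vmax * S / (KM + S))
  fit <- fit_mm(rates, enzyme_conc = 1)
  expect_equal(fit$KM[["estimate"]], KM, tolerance = 1e-6)
  expect_equal(fit$Vmax[["estimate"]], Vmax, tolerance = 1e-6)
  expect_equal(fit$kcat, Vmax, tolerance = 1e-6)
  expect_equal(fit$efficiency, Vmax / (KM * 1e-6), tolerance = 1e-6)

  # rate law identity: the fitted curve at S = KM gives Vmax / 2
  pred <- stats::predict(fit$model, newdata = data.frame(S = fit$KM[["estimate"]]))
  expect_equal(pred, fit$Vmax[["estimate"]] / 2, tolerance = 1e-9)

  expect_error(fit_mm(data.frame(S = c(1, 1, 2), v = c(1, 1, 2))), "distinct")
})

test_that("round trip from generated rates preserves catalytic efficiency", {
  KM <- 71; Vmax <- 9.3e-4
  S <- c(200, 100, 50, 20, 10)
  fit <- fit_mm(data.frame(S = S, v = Vmax * S / (KM + S)), enzyme_conc = 1)
  k <- catalytic_constants(fit)
  expect_equal(unname(k["efficiency"]), (Vmax / 1) / (KM * 1e-6),
               tolerance = 1e-6)
})

test_that("catalytic constants match the published arithmetic", {
  expect_equal(unname(catalytic_constants(
    kinetics_fit(KM = 89, kcat = 7.1e-3))["efficiency"]), 80, tolerance = 0.01)
  expect_equal(unname(catalytic_constants(
    kinetics_fit(KM = 71, kcat = 9.3e-4))["efficiency"]), 13, tolerance = 0.01)
  expect_equal(unname(catalytic_constants(
    kinetics_fit(KM = 1, Vmax = 1, enzyme_conc = 1))["kcat"]), 1)
})

test_that("free-energy differences convert to rate factors via exp(|ddg|/RT)", {
  expect_equal(ddg_to_rate_factor(7), 16.8, tolerance = 0.01)
  expect_equal(ddg_to_rate_factor(0), 1)
  RT <- 8.314e-3 * 298.15
  expect_equal(ddg_to_rate_factor(RT * log(2)), 2, tolerance = 1e-12)
  expect_equal(ddg_to_rate_factor(-RT * log(2)), 2, tolerance = 1e-12)
  expect_error(ddg_to_rate_factor(1, temperature = -5), "temperature")
})

test_that("plate-reader CSVs load into progress curves", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(time = c(0, 30, 60), A1 = c(10, 20, 30), A2 = c(5, 6, 7))
  utils::write.csv(df, tmp, row.names = FALSE)
  wells <- data.frame(well = c("A1", "A2"), substrate_conc = c(200, 100))
  curves <- read_progress_csv(tmp, wells, enzyme_conc = 1)
  expect_named(curves, c("A1", "A2"))
  expect_equal(curves$A1$substrate_conc, 200)
  expect_equal(curves$A2$fluorescence, c(5, 6, 7))
})
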