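make_series <- function(v, start = "2018-01-01", step = 3600) {
  wq_ts(start, v, step = step, units = "mV")
}

test_that("foul correction ramps linearly between cleanings", {
  x <- make_series(rep(10, 101))
  tt <- ts_times(x)
  # single visit, after - before = +5: 0 at start, +2.5 at midpoint, +5 at visit
  log1 <- data.frame(time = tt[101], before = 95, after = 100)
  out <- apply_foul_correction(x, log1)
  expect_equal(out$values[1], 10)
  expect_equal(out$values[51], 12.5)
  expect_equal(out$values[101], 15)
  # before == after: identity
  out0 <- apply_foul_correction(x, data.frame(time = tt[50], before = 7, after = 7))
  expect_equal(out0$values, x$values)
  # two visits: per-interval ramps, checked against a per-point oracle
  log2 <- data.frame(time = tt[c(41, 81)], before = c(98, 96), after = c(100, 100))
  out2 <- apply_foul_correction(x, log2)
  tn <- as.numeric(tt); t0 <- tn[1]
  oracle <- x$values
  seg1 <- tn > t0 & tn <= tn[41]
  seg2 <- tn > tn[41] & tn <= tn[81]
  oracle[seg1] <- oracle[seg1] + 2 * (tn[seg1] - t0) / (tn[41] - t0)
  oracle[seg2] <- oracle[seg2] + 4 * (tn[seg2] - tn[41]) / (tn[81] - tn[41])
  expect_equal(out2$values, oracle)
  # unordered log errors
  expect_error(apply_foul_correction(x, data.frame(time = tt[c(50, 20)],
                                                   before = c(1, 1),
                                                   after = c(1, 1))),
               "time-ordered")
})

test_that("drift correction interpolates the sensitivity ratio in time", {
  x <- make_series(rep(6, 101))
  std <- data.frame(conc = c(1, 5, 10, 50, 100))
  cal_same <- list(start = transform(std, response = 2 * conc),
                   end = transform(std, response = 2 * conc))
  expect_equal(apply_drift_correction(x, cal_same)$values, x$values)
  # end sensitivity doubled: divide by 1 at start, 1.5 at midpoint, 2 at end
  cal2 <- list(start = transform(std, response = 2 * conc),
               end = transform(std, response = 4 * conc))
  out <- apply_drift_correction(x, cal2)
  expect_equal(out$values[1], 6)
  expect_equal(out$values[51], 6 / 1.5)
  expect_equal(out$values[101], 3)
  cal0 <- list(start = transform(std, response = 2 * conc),
               end = transform(std, response = 0 * conc))
  expect_error(apply_drift_correction(x, cal0), "sensitivity")
})

test_that("unit conversion is exact on a line and guards preconditions", {
  mv <- c(1, 2, 5, 8, 13)
  conv <- fit_unit_conversion(mv, 2 + 0.5 * mv)
  expect_equal(conv$offset, 2)
  expect_equal(conv$slope, 0.5)
  expect_equal(conv$r, 1)
  expect_error(fit_unit_conversion(c(1, 2), c(1, 2)), "3 pairs")
  expect_error(fit_unit_conversion(rep(3, 5), 1:5), "singular")
  # noisy recovery: slope within 3 SE of truth
  dat <- withr::with_seed(1, {
    x <- runif(100, 0, 50)
    list(x = x, y = 2 + 0.5 * x + rnorm(100, 0, 0.4))
  })
  fit <- lm(dat$y ~ dat$x)
  conv2 <- fit_unit_conversion(dat$x, dat$y)
  expect_equal(conv2$slope, unname(coef(fit)[2]))
  expect_lt(abs(conv2$slope - 0.5), 3 * summary(fit)$coefficients[2, 2])
})

test_that("temperature and turbidity compensation implement the stated forms", {
  n <- 50
  f <- wq_ts("2018-06-01", rep(1, n), units = "RU")
  temp_ref <- wq_ts("2018-06-01", rep(20, n), units = "degC")
  temp_hot <- wq_ts("2018-06-01", rep(30, n), units = "degC")
  cc <- comp_coef(rho = -0.01, t_ref = 20)
  expect_equal(compensate_temperature(f, temp_ref, cc)$values, rep(1, n))
  out <- compensate_temperature(f, temp_hot, cc)
  expect_equal(out$values, rep(1 / 0.9, n), tolerance = 1e-12)

  turb0 <- wq_ts("2018-06-01", rep(0, n), units = "FNU")
  turb100 <- wq_ts("2018-06-01", rep(100, n), units = "FNU")
  ck <- comp_coef(k = 0.001)
  expect_equal(compensate_turbidity(f, turb0, ck)$values, rep(1, n))
  expect_equal(compensate_turbidity(f, turb100, ck)$values,
               rep(exp(0.1), n), tolerance = 1e-12)
  # negative turbidity flagged missing, non-positive divisor flagged missing
  turb_neg <- wq_ts("2018-06-01", c(-1, rep(10, n - 1)), units = "FNU")
  expect_warning(outn <- compensate_turbidity(f, turb_neg, ck), "negative")
  expect_identical(outn$flags[1], "missing")
  temp_extreme <- wq_ts("2018-06-01", rep(200, n), units = "degC")
  cc2 <- comp_coef(rho = -0.01, t_ref = 20)
  expect_warning(oute <- compensate_temperature(f, temp_extreme, cc2),
                 "non-positive")
  expect_true(all(oute$flags == "missing"))
})

test_that("compensation coefficients are recovered from clean paired data", {
  dat <- withr::with_seed(4, {
    temp <- runif(150, 2, 28)
    turb <- runif(150, 0, 300)
    lab <- runif(150, 0.5, 3)
    list(temp = temp, turb = turb, lab = lab)
  })
  rho <- -0.012; k <- 0.0009
  sensor <- dat$lab * (1 + rho * (dat$temp - 20)) * exp(-k * dat$turb)
  cc <- fit_compensation(sensor, dat$lab, dat$temp, dat$turb, t_ref = 20)
  expect_lt(abs(cc$rho - rho), 1e-3)
  expect_lt(abs(cc$k - k), 1e-3)
  expect_gte(attr(cc, "r_post"), attr(cc, "r_pre"))
  # null truth: estimates near zero
  cc0 <- fit_compensation(dat$lab, dat$lab, dat$temp, dat$turb, t_ref = 20)
  expect_lt(abs(cc0$rho), 1e-4)
  expect_lt(abs(cc0$k), 1e-5)
  expect_error(fit_compensation(sensor[1:5], dat$lab[1:5], dat$temp[1:5],
                                dat$turb[1:5]), ">= 10")
  expect_error(fit_compensation(dat$lab, dat$lab, rep(10, 150), rep(5, 150)),
               "degenerate")
})

test_that("corrupt-then-correct round trip recovers noise-free truth", {
  h <- generate_hydrograph(hydro_config(seed = 2, days = 90, n_events = 10))
  p <- season_params()
  for (nm in names(p)) p[[nm]]$noise <- 0
  truth <- generate_sensor_truth(h$flow, p, seed = 1)
  cor_in <- corrupt_sensors(truth, seed = 3)
  # zero-magnitude artifacts: identity
  null_cfg <- list(`S2-F` = list(drift = 0, foul = numeric(0)))
  same <- corrupt_sensors(truth, null_cfg, seed = 3)
  expect_equal(same$raw$`S2-F`$values, truth$`S2-F`$values)
  # +100% drift alone: final-point ratio raw/truth = 2
  drift_cfg <- list(`S2-F` = list(drift = 1))
  dr <- corrupt_sensors(truth, drift_cfg, seed = 3)
  n <- length(truth$`S2-F`$values)
  expect_equal(dr$raw$`S2-F`$values[n] / truth$`S2-F`$values[n], 2,
               tolerance = 1e-12)
  # full default artifacts invert to < 1% RMS for every sensor
  corrected <- correct_sensors(cor_in$raw, cor_in$log,
                               turbidity = truth$turbidity,
                               temperature = truth$temperature)
  for (nm in names(corrected)) {
    rel_rms <- sqrt(mean((corrected[[nm]]$values - truth[[nm]]$values)^2)) /
      sqrt(mean(truth[[nm]]$values^2))
    expect_lt(rel_rms, 0.01)
    expect_true(length(attr(corrected[[nm]], "provenance")) >= 2)
  }
  # order contract is recorded: foul before drift before unit/compensation
  prov <- attr(corrected$`S2-F`, "provenance")
  expect_equal(prov, c("foul", "drift", "temperature", "turbidity"))
})
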