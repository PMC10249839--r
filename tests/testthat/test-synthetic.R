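test_that("hydrograph generation is deterministic and respects degenerate configs", {
  h1 <- generate_hydrograph(hydro_config(seed = 7))
  h2 <- generate_hydrograph(hydro_config(seed = 7))
  expect_identical(h1$flow$values, h2$flow$values)
  expect_identical(h1$schedule, h2$schedule)

  h0 <- generate_hydrograph(hydro_config(n_events = 0, days = 10))
  expect_true(all(h0$flow$values == 1.5))
  expect_equal(nrow(h0$schedule), 0)

  expect_error(hydro_config(baseflow = 0), "baseflow")
  expect_error(hydro_config(cso_fraction = 1.2), "cso_fraction")
})

test_that("flow is positive and every CSO interval lies inside an event", {
  h <- generate_hydrograph(hydro_config(seed = 3))
  expect_true(all(h$flow$values > 0))
  expect_equal(nrow(h$schedule), 6)  # 15% of 40 events
  for (i in seq_len(nrow(h$schedule))) {
    containing <- h$events$start <= h$schedule$start[i] &
      h$events$end >= h$schedule$end[i]
    expect_true(any(containing & h$events$cso))
  }
})

test_that("sensor truth has the stated structural properties", {
  sim <- default_sim()
  for (nm in c("S1-CF", "S1-A", "S2-F"))
    expect_true(all(sim$sensors[[nm]]$values > 0))
  tau <- cor(sim$sensors$turbidity$values, sim$flow$values, method = "kendall")
  expect_gt(tau, 0)
  # temperature annual sinusoid: warm in summer, cold in winter
  temp <- sim$sensors$temperature
  d <- optifib:::decimal_doy(ts_times(temp))
  expect_gt(mean(temp$values[d > 180 & d < 230]),
            mean(temp$values[d < 40]) + 10)
})

test_that("seasonal amplitude and noise controls behave as configured", {
  h <- generate_hydrograph(hydro_config(n_events = 0, days = 365))
  p <- season_params()
  for (nm in c("S1-CF", "S1-A", "S2-F")) {
    p[[nm]]$noise <- 0
    p[[nm]]$dom_sd <- 0
  }
  p$turbidity$noise <- 0
  p$turbidity$scatter_sd <- 0
  p$temperature$noise <- 0
  s <- generate_sensor_truth(h$flow, p, seed = 1)
  # constant flow, zero noise: optical range comes from the seasonal term only
  amp <- season_params()$`S1-A`$amp
  expect_gte(diff(range(s$`S1-A`$values)), amp)
  expect_lt(diff(range(s$`S1-A`$values)), 2 * amp + 1e-9)
  # and with zero amplitude everything is constant
  for (nm in c("S1-CF", "S1-A", "S2-F")) p[[nm]]$amp <- 0
  s0 <- generate_sensor_truth(h$flow, p, seed = 1)
  expect_equal(diff(range(s0$`S2-F`$values)), 0)
})

test_that("true concentrations follow the log-linear model with CSO shift", {
  covs <- constant_covariates(n = 2000)
  flow <- covs$flow
  sched <- data.frame(start = ts_times(flow)[500], end = ts_times(flow)[800])
  # seasonal interaction zeroed so in/out-of-schedule covariates match exactly
  tm <- truth_model(sigma = 0, cso_shift = 1.0,
                    optical = list(`S2-F` = c(0.6, 0, 0)))
  conc <- generate_true_concentrations(covs[c("S2-F", "turbidity")], flow,
                                       sched, tm, seed = 1)$HB
  cso <- optifib:::in_schedule(ts_times(flow), sched)
  gm_in <- exp(mean(log(conc$values[cso])))
  gm_out <- exp(mean(log(conc$values[!cso])))
  expect_equal(gm_in / gm_out, 10, tolerance = 1e-10)
  # sigma = 0, constant covariates: values are exactly 10^(beta.x)
  mu <- 2.0 + 0.6 * 1 + 0.8 * log10(2)
  expect_equal(conc$values[!cso], rep(10^mu, sum(!cso)), tolerance = 1e-12)
  expect_error(truth_model(sigma = -1), "sigma")
})

test_that("default synthetic year spans at least five orders of magnitude", {
  sim <- default_sim()
  expect_gte(diff(log10(range(sim$conc$HB$values))), 5)
})

test_that("discrete sampling reproduces the study sample counts and regimes", {
  sim <- default_sim()
  s <- sim$samples
  expect_equal(nrow(s), 153)
  expect_equal(sum(s$regime != "low-flow"), 119)
  expect_equal(sum(s$regime == "event-CSO"), 43)
  expect_equal(sum(s$regime == "low-flow"), 34)
  # regime consistency: every event-CSO sample is inside a schedule interval
  cso_times <- s$timestamp[s$regime == "event-CSO"]
  expect_true(all(optifib:::in_schedule(cso_times, sim$schedule)))
  # censored values are stored at their limit
  expect_true(all(s$value[s$censored] == s$detection_limit[s$censored]))
  expect_true(all(s$value > 0))
})

test_that("detection limit controls the censored fraction", {
  sim <- default_sim()
  # limit below everything: no censoring
  s0 <- draw_discrete_samples(sim$conc, sim$flow, sim$schedule, sim$events,
                              detection_limits = 1e-9, seed = 9)
  expect_equal(sum(s0$censored), 0)
  # limit at the known 30th percentile of the drawn values: censored fraction
  # within binomial 99% bounds of 0.30 (n = 153)
  q30 <- as.numeric(quantile(s0$value, 0.30))
  s1 <- draw_discrete_samples(sim$conc, sim$flow, sim$schedule, sim$events,
                              detection_limits = q30, seed = 9)
  half_width <- 2.576 * sqrt(0.3 * 0.7 / 153)
  expect_lt(abs(mean(s1$censored) - 0.30), half_width)
  # empty schedule + CSO request errors
  expect_error(draw_discrete_samples(sim$conc, sim$flow, sim$schedule[0, ],
                                     sim$events, seed = 1),
               "schedule is empty")
})

test_that("influent composites give 12 monthly values with bounded spread", {
  inf <- generate_influent(seed = 1)
  expect_equal(unname(table(inf$marker)), rep(12L, 4), ignore_attr = TRUE)
  expect_true(all(inf$value > 0))
  # zero spread: all values equal the mean
  inf0 <- generate_influent(means = c(HB = 1e7), sdlog10 = 0, seed = 2)
  expect_equal(inf0$value, rep(1e7, 12))
  # default spread stays under one order of magnitude across many seeds
  ratios <- vapply(1:100, function(s) {
    x <- generate_influent(means = c(HB = 1e7), seed = s)$value
    max(x) / min(x)
  }, numeric(1))
  expect_true(all(ratios < 10))
  expect_error(generate_influent(means = c(HB = -1)), "> 0")
})

test_that("simulate_study is reproducible and internally consistent", {
  a <- simulate_study(hydro_config(seed = 5, days = 60, n_events = 10,
                                   cso_fraction = 0.3),
                      scheme = sampling_scheme(10, 20, 10), seed = 5)
  b <- simulate_study(hydro_config(seed = 5, days = 60, n_events = 10,
                                   cso_fraction = 0.3),
                      scheme = sampling_scheme(10, 20, 10), seed = 5)
  expect_identical(a$samples, b$samples)
  expect_identical(a$conc$HB$values, b$conc$HB$values)
  # conservation of grid
  expect_equal(length(a$flow), length(a$sensors$`S2-F`))
  expect_identical(a$flow$start, a$sensors$turbidity$start)
})
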