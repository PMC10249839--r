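# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# full default-condition synthetic study (year-long, 153 samples)
default_sim <- function(seed = 42) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_study(hydro_config(seed = seed),
                                          truth = truth_model(), seed = seed)
  }
  .fixture_env[[key]]
}

# all eight markers (sHM constructed as HB + L3)
full_sim <- function(seed = 7) {
  key <- paste0("full", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_study(hydro_config(seed = seed),
                                          truth = default_truth_models(),
                                          seed = seed)
  }
  .fixture_env[[key]]
}

# 24-scenario selection report on the full 8-marker study (cached; reps kept
# small since only structure and regime filtering are asserted on it)
full_selection <- function() {
  if (is.null(.fixture_env$full_sel)) {
    sim <- full_sim()
    .fixture_env$full_sel <- fit_all_regimes(
      sim$samples, sim_covariates(sim), markers = marker_names(),
      pool = "S2-F", k = 5, reps = 2, seed = 4)
  }
  .fixture_env$full_sel
}

sim_covariates <- function(sim) {
  covs <- c(sim$sensors, list(flow = sim$flow))
  covs$flow1h <- rolling_hour_mean(sim$flow)
  covs
}

# constant covariate set on a short grid, for closed-form checks
constant_covariates <- function(n = 1000, start = "2018-01-01", step = 600,
                                s2f = 1, flow = 2, turb = 5, temp = 10) {
  list(`S1-CF` = wq_ts(start, rep(s2f + 0.5, n), step = step, units = "RU"),
       `S1-A` = wq_ts(start, rep(s2f + 1, n), step = step, units = "RU"),
       `S2-F` = wq_ts(start, rep(s2f, n), step = step, units = "RU"),
       turbidity = wq_ts(start, rep(turb, n), step = step, units = "FNU"),
       temperature = wq_ts(start, rep(temp, n), step = step, units = "degC"),
       flow = wq_ts(start, rep(flow, n), step = step, units = "m^3/s"))
}

# simulated left-censored Gaussian data with known coefficients
simulate_tobit_data <- function(n, beta = c(1, 0.8, -0.5), sigma = 0.4,
                                cens_quantile = 0.3, seed = 1) {
  withr::with_seed(seed, {
    X <- cbind(1, matrix(rnorm(n * (length(beta) - 1)), n))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(length(beta) - 1)))
    y_star <- drop(X %*% beta) + rnorm(n, 0, sigma)
    L <- as.numeric(stats::quantile(y_star, cens_quantile))
    censored <- y_star <= L
    y <- ifelse(censored, L, y_star)
    list(X = X, y = y, censored = censored, limit = rep(L, n),
         beta = beta, sigma = sigma)
  })
}
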