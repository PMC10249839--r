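#' Synthetic study data
#'
#' Seeded generators that emulate the structure of a year-long urban stream
#' deployment: a 10-minute hydrograph with gamma-kernel runoff events, a
#' subset of which carry combined-sewer-overflow (CSO) discharge; optical
#' fluorescence, turbidity and temperature series; true bacteria
#' concentrations from a known log-linear truth model; flow-weighted discrete
#' samples with left-censoring; and monthly wastewater-influent composites.
#' Every generator takes an explicit seed; none touches the global RNG state.
#'
#' @name synthetic
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Hydrograph generator configuration
#'
#' @param baseflow baseline streamflow, m^3/s (> 0).
#' @param n_events number of runoff events over the deployment.
#' @param event_peak_range range of event peak additions above baseflow, m^3/s.
#' @param event_duration_range range of event durations, hours.
#' @param cso_fraction proportion of events flagged as CSO-influenced.
#' @param year_start deployment start (UTC).
#' @param days deployment length in days.
#' @param step grid spacing, seconds.
#' @param seed integer seed.
#' @return a list of class \code{hydro_config}.
#' @export
hydro_config <- function(baseflow = 1.5, n_events = 40,
                         event_peak_range = c(5, 80),
                         event_duration_range = c(6, 48),
                         cso_fraction = 0.15,
                         year_start = "2017-12-01", days = 365,
                         step = 600, seed = 1) {
  if (!is.numeric(baseflow) || baseflow <= 0) stop("baseflow must be > 0")
  if (cso_fraction < 0 || cso_fraction > 1) stop("cso_fraction must be in [0, 1]")
  structure(list(baseflow = baseflow, n_events = as.integer(n_events),
                 event_peak_range = event_peak_range,
                 event_duration_range = event_duration_range,
                 cso_fraction = cso_fraction,
                 year_start = as_utc(year_start), days = days,
                 step = step, seed = as.integer(seed)),
            class = "hydro_config")
}

# gamma-shaped unit hydrograph kernel: peaks at 1 when tau == tm
gamma_kernel <- function(tau, tm, shape = 3) {
  k <- numeric(length(tau))
  pos <- tau > 0
  x <- tau[pos] / tm
  k[pos] <- x^(shape - 1) * exp(-(shape - 1) * (x - 1))
  k
}

#' Generate a synthetic hydrograph with CSO schedule
#'
#' Runoff events are additive gamma-kernel pulses on constant baseflow; a
#' seeded subset of events is flagged CSO-influenced, and each CSO discharge
#' interval lies inside its event's rise and early recession.
#'
#' @param config a \code{\link{hydro_config}}.
#' @return list with \code{flow} (a \code{wq_ts}, m^3/s), \code{schedule}
#'   (data.frame of CSO start/end intervals) and \code{events} (data.frame of
#'   event start/end/peak/cso).
#' @export
generate_hydrograph <- function(config = hydro_config()) {
  if (!inherits(config, "hydro_config")) stop("config must be a hydro_config")
  n <- as.integer(round(config$days * 86400 / config$step))
  tsec <- (seq_len(n) - 1) * config$step
  flow <- rep(config$baseflow, n)
  ev <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                   end = as.POSIXct(character(), tz = "UTC"),
                   peak = numeric(), cso = logical())
  sched <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"))
  if (config$n_events > 0) {
    gen <- with_seed(config$seed, {
      starts <- sort(runif(config$n_events, 0, config$days * 86400 * 0.95))
      peaks <- runif(config$n_events, config$event_peak_range[1], config$event_peak_range[2])
      durs <- runif(config$n_events, config$event_duration_range[1],
                    config$event_duration_range[2]) * 3600
      n_cso <- as.integer(round(config$cso_fraction * config$n_events))
      cso_idx <- if (n_cso > 0) sort(sample.int(config$n_events, n_cso)) else integer()
      list(starts = starts, peaks = peaks, durs = durs, cso_idx = cso_idx)
    })
    ends <- pmin(gen$starts + 1.5 * gen$durs, config$days * 86400)
    for (i in seq_len(config$n_events)) {
      tm <- gen$durs[i] / 4
      flow <- flow + gen$peaks[i] * gamma_kernel(tsec - gen$starts[i], tm)
    }
    ev <- data.frame(start = config$year_start + gen$starts,
                     end = config$year_start + ends,
                     peak = gen$peaks,
                     cso = seq_len(config$n_events) %in% gen$cso_idx)
    if (length(gen$cso_idx)) {
      cs <- gen$starts[gen$cso_idx] + 0.05 * gen$durs[gen$cso_idx]
      ce <- gen$starts[gen$cso_idx] + 0.60 * gen$durs[gen$cso_idx]
      sched <- data.frame(start = config$year_start + cs,
                          end = config$year_start + ce)
    }
  }
  list(flow = wq_ts(config$year_start, flow, step = config$step, units = "m^3/s"),
       schedule = sched, events = ev)
}

# membership of grid timestamps in a (start, end] interval table
in_schedule <- function(times, schedule) {
  out <- rep(FALSE, length(times))
  if (is.null(schedule) || nrow(schedule) == 0) return(out)
  for (i in seq_len(nrow(schedule))) {
    out <- out | (times >= schedule$start[i] & times <= schedule$end[i])
  }
  out
}

#' Default seasonal/sensor parameters for the synthetic deployment
#'
#' Base levels, flow coupling, seasonal amplitude (annual sinusoid peaking in
#' late summer) and noise scale for each simulated sensor. Optical units are
#' Raman units (RU); turbidity FNU; temperature deg C.
#' @return nested list of per-sensor parameters.
#' @export
season_params <- function() {
  list(
    `S1-CF` = list(base = 2.0, flow_coef = 0.9, amp = 0.25, peak_day = 230,
                   noise = 0.02, dom_sd = 0.35, dom_tau_days = 5),
    `S1-A`  = list(base = 2.5, flow_coef = 1.1, amp = 0.30, peak_day = 230,
                   noise = 0.02, dom_sd = 0.35, dom_tau_days = 5),
    `S2-F`  = list(base = 1.5, flow_coef = 0.9, amp = 0.20, peak_day = 230,
                   noise = 0.015, dom_sd = 0.35, dom_tau_days = 5),
    turbidity = list(base = 4, flow_coef = 25, amp = 0, peak_day = 0, noise = 0.3,
                     scatter_sd = 0.4, scatter_tau_days = 2),
    temperature = list(base = 11, amp = 11, peak_day = 205, noise = 0.2)
  )
}

# stationary AR(1) with marginal sd `sd` and decorrelation time tau (seconds)
ar1_process <- function(n, sd, tau, step) {
  if (sd <= 0) return(numeric(n))
  phi <- exp(-step / tau)
  z <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  z[1] <- rnorm(1, 0, sd)
  as.numeric(stats::filter(z, phi, method = "recursive"))
}

#' Generate noise-free-to-noisy sensor truth series
#'
#' Optical signals are a positive base level plus a seasonal sinusoid, a
#' flow-coupled term in log10(flow/baseflow) (dissolved organic matter flushes
#' with runoff), an independent slowly varying AR(1) component per channel
#' (DOM composition drifts that are not flow-driven, decorrelation time a few
#' days) and additive Gaussian measurement noise. Turbidity couples
#' positively to flow; temperature follows an annual sinusoid.
#'
#' @param flow \code{wq_ts} of streamflow (m^3/s).
#' @param params per-sensor parameter list, see \code{\link{season_params}}.
#' @param seed integer seed (use 0 noise in \code{params} for deterministic
#'   output regardless of seed).
#' @return named list of \code{wq_ts}: \code{S1-CF}, \code{S1-A}, \code{S2-F},
#'   \code{turbidity}, \code{temperature}.
#' @export
generate_sensor_truth <- function(flow, params = season_params(), seed = 1) {
  stopifnot(inherits(flow, "wq_ts"))
  n <- length(flow$values)
  d <- decimal_doy(ts_times(flow))
  base_q <- min(flow$values, na.rm = TRUE)
  lq <- log10(flow$values / base_q)
  seas <- function(amp, peak) amp * cos(2 * pi * (d - peak) / 365.25)
  gen <- with_seed(seed, {
    list(noise = replicate(5, rnorm(n), simplify = FALSE),
         dom = lapply(c("S1-CF", "S1-A", "S2-F"), function(nm) {
           p <- params[[nm]]
           ar1_process(n, p$dom_sd %||% 0, (p$dom_tau_days %||% 5) * 86400,
                       flow$step)
         }),
         turb_scatter = ar1_process(n, params$turbidity$scatter_sd %||% 0,
                                    (params$turbidity$scatter_tau_days %||% 2) *
                                      86400, flow$step))
  })
  noise <- gen$noise
  out <- list()
  for (i in seq_along(c("S1-CF", "S1-A", "S2-F"))) {
    nm <- c("S1-CF", "S1-A", "S2-F")[i]
    p <- params[[nm]]
    v <- p$base + seas(p$amp, p$peak_day) + p$flow_coef * lq +
      gen$dom[[i]] + p$noise * noise[[i]]
    out[[nm]] <- wq_ts(flow$start, pmax(v, 0.01), step = flow$step, units = "RU")
  }
  # turbidity: flow-coupled with multiplicative hysteresis-like scatter
  pt <- params$turbidity
  tv <- pt$base + pt$flow_coef * lq^1.5 * exp(gen$turb_scatter) +
    pt$noise * noise[[4]]
  out$turbidity <- wq_ts(flow$start, pmax(tv, 0.1), step = flow$step, units = "FNU")
  pT <- params$temperature
  Tv <- pT$base + pT$amp * cos(2 * pi * (d - pT$peak_day) / 365.25) + pT$noise * noise[[5]]
  out$temperature <- wq_ts(flow$start, pmax(Tv, 0.1), step = flow$step, units = "degC")
  out
}

#' Truth model for synthetic bacteria concentrations
#'
#' The generative counterpart of the regression: per marker,
#' log10 concentration = beta . x(t) + CSO shift + Normal(0, sigma) noise,
#' where x(t) is the canonical design row (intercept; optical terms with
#' seasonal sine/cosine interactions; optionally turbidity and log10 one-hour
#' mean flow). Coefficient magnitudes are configurable placeholders chosen for
#' realistic dynamic range (about six orders of magnitude over a year), not
#' values asserted about any field site.
#'
#' @param marker marker name, one of \code{marker_names()}.
#' @param intercept intercept, log10 units.
#' @param optical named list of optical coefficients; each element is
#'   \code{c(main, sin, cos)} for that sensor.
#' @param flow_coef coefficient on log10 one-hour mean flow (0 to omit).
#' @param turb_coef coefficient on turbidity (0 to omit).
#' @param sigma residual scale, log10 units (> 0... 0 allowed for noise-free).
#' @param cso_shift additive intercept shift (log10) inside CSO intervals.
#' @param detection_limit left-censoring limit, linear units per 100 mL.
#' @return list of class \code{truth_model}.
#' @export
truth_model <- function(marker = "HB", intercept = 2.0,
                        optical = list(`S2-F` = c(0.60, 0.08, -0.06)),
                        flow_coef = 0.80, turb_coef = 0,
                        sigma = 0.3, cso_shift = 1.0,
                        detection_limit = 225) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (!marker %in% marker_names()) stop("unknown marker: ", marker)
  structure(list(marker = marker, intercept = intercept, optical = optical,
                 flow_coef = flow_coef, turb_coef = turb_coef, sigma = sigma,
                 cso_shift = cso_shift, detection_limit = detection_limit),
            class = "truth_model")
}

#' Marker names used throughout the pipeline
#' @return character vector of the eight response markers.
#' @export
marker_names <- function() {
  c("FC", "EN-culture", "EC-culture", "EN-qPCR", "EC-qPCR", "HB", "L3", "sHM")
}

#' Default truth models for the seven generated markers
#'
#' One \code{\link{truth_model}} per marker except sHM, which
#' \code{\link{simulate_study}} constructs as the pointwise HB + L3 sum.
#' Intercepts are placeholders pitched at realistic urban-stream medians
#' (fecal coliforms highest, the human markers in the low thousands per
#' 100 mL); shared slope structure keeps the generator simple.
#'
#' @return named list of \code{truth_model}.
#' @export
default_truth_models <- function() {
  ic <- c(FC = 2.8, `EN-culture` = 2.0, `EC-culture` = 1.9,
          `EN-qPCR` = 3.6, `EC-qPCR` = 1.9, HB = 2.0, L3 = 1.8)
  lim <- c(FC = 10, `EN-culture` = 10, `EC-culture` = 10,
           `EN-qPCR` = 450, `EC-qPCR` = 450, HB = 225, L3 = 225)
  lapply(stats::setNames(names(ic), names(ic)), function(mk)
    truth_model(marker = mk, intercept = ic[[mk]], detection_limit = lim[[mk]]))
}

# truth_model -> equivalent model_spec (for shared design construction)
truth_spec <- function(truth) {
  model_spec(marker = truth$marker, opticals = names(truth$optical),
             turbidity = truth$turb_coef != 0, flow = truth$flow_coef != 0,
             regime = "combined")
}

truth_beta <- function(truth) {
  b <- truth$intercept
  for (nm in names(truth$optical)) b <- c(b, truth$optical[[nm]])
  if (truth$turb_coef != 0) b <- c(b, truth$turb_coef)
  if (truth$flow_coef != 0) b <- c(b, truth$flow_coef)
  b
}

#' Generate true concentration series from a truth model
#'
#' @param sensors named list of covariate \code{wq_ts} (optical signals,
#'   turbidity).
#' @param flow streamflow \code{wq_ts} on the same grid.
#' @param schedule CSO interval data.frame (start, end).
#' @param truth a \code{\link{truth_model}} or list of them (one per marker).
#' @param seed integer seed for the log-scale noise.
#' @return named list of concentration \code{wq_ts} (linear units per 100 mL),
#'   one per marker.
#' @export
generate_true_concentrations <- function(sensors, flow, schedule, truth, seed = 1) {
  if (inherits(truth, "truth_model")) truth <- list(truth)
  for (s in sensors) check_aligned(flow, s, "sensor/flow grids")
  times <- ts_times(flow)
  cso <- in_schedule(times, schedule)
  covs <- c(sensors, list(flow = flow))
  out <- list()
  for (j in seq_along(truth)) {
    tm <- truth[[j]]
    if (tm$sigma < 0) stop("sigma must be >= 0")
    X <- design_matrix(covs, times, truth_spec(tm))
    mu <- drop(X %*% truth_beta(tm)) + ifelse(cso, tm$cso_shift, 0)
    eps <- if (tm$sigma > 0)
      with_seed(seed + j, rnorm(length(mu), 0, tm$sigma)) else 0
    out[[tm$marker]] <- wq_ts(flow$start, 10^(mu + eps), step = flow$step,
                              units = if (grepl("culture|FC", tm$marker))
                                "CFU/100mL" else "CN/100mL")
  }
  out
}

#' Default discrete sampling scheme
#'
#' Flow-weighted sampling emulating a year-long monitoring campaign: 153
#' samples of which 119 during event runoff (43 of those CSO-influenced) and
#' 34 during low flow.
#'
#' @param n_low,n_event,n_cso sample counts per regime (\code{n_event} is
#'   event runoff without CSO influence).
#' @return list describing the scheme.
#' @export
sampling_scheme <- function(n_low = 34, n_event = 76, n_cso = 43) {
  list(n_low = n_low, n_event = n_event, n_cso = n_cso)
}

#' Draw discrete samples from true concentration series
#'
#' Event samples are placed across event hydrograph intervals (CSO samples
#' inside CSO discharge intervals), low-flow samples outside events. Values
#' below a marker's detection limit are stored censored at the limit.
#'
#' @param conc named list of concentration \code{wq_ts} (one per marker).
#' @param flow streamflow \code{wq_ts}.
#' @param schedule CSO interval data.frame.
#' @param events event interval data.frame (from
#'   \code{\link{generate_hydrograph}}).
#' @param scheme a \code{\link{sampling_scheme}}.
#' @param detection_limits named numeric vector of limits (linear units) per
#'   marker; unnamed scalar recycles.
#' @param seed integer seed.
#' @return data.frame with columns timestamp, marker, value, censored,
#'   detection_limit, regime.
#' @export
draw_discrete_samples <- function(conc, flow, schedule, events,
                                  scheme = sampling_scheme(),
                                  detection_limits = 225, seed = 1) {
  times <- ts_times(flow)
  cso <- in_schedule(times, schedule)
  in_ev <- in_schedule(times, events)
  idx_cso <- which(cso)
  idx_event <- which(in_ev & !cso)
  idx_low <- which(!in_ev)
  if (scheme$n_cso > 0 && length(idx_cso) == 0)
    stop("CSO samples requested but schedule is empty")
  if (scheme$n_cso > length(idx_cso) || scheme$n_event > length(idx_event) ||
      scheme$n_low > length(idx_low))
    stop("scheme counts exceed available time points per regime")
  picks <- with_seed(seed, list(
    cso = sort(sample(idx_cso, scheme$n_cso)),
    event = sort(sample(idx_event, scheme$n_event)),
    low = sort(sample(idx_low, scheme$n_low))
  ))
  idx <- c(picks$low, picks$event, picks$cso)
  regime <- c(rep("low-flow", scheme$n_low), rep("event", scheme$n_event),
              rep("event-CSO", scheme$n_cso))
  rows <- list()
  for (mk in names(conc)) {
    lim <- if (!is.null(names(detection_limits)) && mk %in% names(detection_limits))
      detection_limits[[mk]] else detection_limits[[1]]
    v <- conc[[mk]]$values[idx]
    cen <- v < lim
    rows[[mk]] <- data.frame(
      timestamp = times[idx], marker = mk,
      value = ifelse(cen, lim, v), censored = cen,
      detection_limit = lim, regime = regime, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$marker, out$timestamp), ]
}

#' Generate monthly wastewater-influent composites
#'
#' Twelve monthly composite concentrations per marker with lognormal
#' month-to-month variation; the default spread keeps the max/min ratio under
#' one order of magnitude.
#'
#' @param means named numeric vector of per-marker mean concentrations
#'   (CN/100 mL); defaults are order-of-magnitude placeholders.
#' @param sdlog10 month-to-month standard deviation in log10 units.
#' @param seed integer seed.
#' @return data.frame with columns month (1..12), marker, value.
#' @export
generate_influent <- function(means = c(HB = 1e7, L3 = 1.2e7,
                                        `EN-qPCR` = 3e8, `EC-qPCR` = 1.5e7),
                              sdlog10 = 0.15, seed = 1) {
  if (any(means <= 0)) stop("influent means must be > 0")
  vals <- with_seed(seed, {
    lapply(seq_along(means), function(i)
      means[i] * 10^rnorm(12, -sdlog10^2 * log(10) / 2, sdlog10))
  })
  out <- do.call(rbind, lapply(seq_along(means), function(i)
    data.frame(month = 1:12, marker = names(means)[i], value = vals[[i]],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' One call producing everything the pipeline consumes: hydrograph + CSO
#' schedule, corrected-scale sensor truth, true concentrations for the
#' requested truth models, discrete samples and influent composites.
#'
#' @param config a \code{\link{hydro_config}}.
#' @param truth a \code{\link{truth_model}} or list of them.
#' @param scheme a \code{\link{sampling_scheme}}.
#' @param params sensor parameters, see \code{\link{season_params}}.
#' @param seed integer master seed; stage seeds are derived deterministically.
#' @return list with flow, schedule, events, sensors, conc, samples, influent.
#' @export
simulate_study <- function(config = hydro_config(seed = seed), truth = truth_model(),
                           scheme = sampling_scheme(), params = season_params(),
                           seed = 1) {
  if (inherits(truth, "truth_model")) truth <- list(truth)
  hyd <- generate_hydrograph(config)
  sensors <- generate_sensor_truth(hyd$flow, params, seed = seed + 1000L)
  conc <- generate_true_concentrations(sensors, hyd$flow, hyd$schedule, truth,
                                       seed = seed + 2000L)
  lims <- vapply(truth, function(t) t$detection_limit, numeric(1))
  names(lims) <- vapply(truth, function(t) t$marker, character(1))
  if (all(c("HB", "L3") %in% names(conc)) && !"sHM" %in% names(conc)) {
    conc$sHM <- ts_replace(conc$HB, conc$HB$values + conc$L3$values)
    lims <- c(lims, sHM = unname(lims["HB"] + lims["L3"]))
  }
  samples <- draw_discrete_samples(conc, hyd$flow, hyd$schedule, hyd$events,
                                   scheme, detection_limits = lims,
                                   seed = seed + 3000L)
  influent <- generate_influent(seed = seed + 4000L)
  list(flow = hyd$flow, schedule = hyd$schedule, events = hyd$events,
       sensors = sensors, conc = conc, samples = samples, influent = influent)
}
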