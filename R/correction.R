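#' Field fluorometer corrections
#'
#' Raw in-situ optical series are made laboratory-comparable by a fixed
#' sequence of corrections: fouling (linear ramp between cleanings), drift
#' (multiplicative, linear in time between pre- and post-deployment
#' calibrations), millivolt-to-Raman-unit conversion by least squares,
#' temperature compensation (linear divisor) and turbidity compensation
#' (exponential attenuation). \code{correct_sensors()} enforces the order.
#'
#' @name sensor_correction
NULL

#' Fouling correction from a maintenance log
#'
#' Within each interval between cleanings, adds a correction ramping linearly
#' from 0 at the previous cleaning to (after - before) at the visit, where
#' before/after are the sensor's readings in organic-free reagent water
#' before and after cleaning. Fouling accrues gradually, hence the ramp; a
#' step at the visit is available via \code{mode = "step"}.
#'
#' @param raw a \code{wq_ts}.
#' @param log data.frame with columns time, before, after (one row per visit),
#'   time-ordered.
#' @param mode \code{"ramp"} (default) or \code{"step"}.
#' @return corrected \code{wq_ts}; quality flags preserved.
#' @export
apply_foul_correction <- function(raw, log, mode = c("ramp", "step")) {
  mode <- match.arg(mode)
  stopifnot(inherits(raw, "wq_ts"))
  if (nrow(log) == 0) return(raw)
  vt <- as_utc(log$time)
  if (is.unsorted(as.numeric(vt), strictly = TRUE)) stop("maintenance log not time-ordered")
  times <- as.numeric(ts_times(raw))
  corr <- numeric(length(times))
  prev <- as.numeric(raw$start)
  for (i in seq_len(nrow(log))) {
    v <- as.numeric(vt[i])
    amt <- log$after[i] - log$before[i]
    inseg <- times > prev & times <= v
    corr[inseg] <- corr[inseg] +
      if (mode == "ramp") amt * (times[inseg] - prev) / (v - prev) else amt
    prev <- v
  }
  ts_replace(raw, raw$values + corr)
}

#' Drift correction from deployment calibration curves
#'
#' The pre- and post-deployment response curves over standard concentrations
#' (quinine sulfate or tryptophan) give start and end sensitivities (fitted
#' slopes). Each point is divided by a factor interpolated linearly in time
#' between 1 at deployment start and end/start sensitivity ratio at the end:
#' an optical cell's sensitivity change scales the whole signal.
#'
#' @param series a \code{wq_ts} spanning the deployment.
#' @param cal list with \code{start} and \code{end}, each a data.frame with
#'   columns conc (monotone standards, >= 2) and response.
#' @return corrected \code{wq_ts}.
#' @export
apply_drift_correction <- function(series, cal) {
  stopifnot(inherits(series, "wq_ts"))
  sens <- function(curve) {
    if (nrow(curve) < 2) stop("calibration curve needs >= 2 standards")
    stats::cov(curve$conc, curve$response) / stats::var(curve$conc)
  }
  s0 <- sens(cal$start); s1 <- sens(cal$end)
  if (!is.finite(s1) || s1 == 0) stop("end-of-study sensitivity is zero")
  r <- s1 / s0
  n <- length(series$values)
  frac <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  ts_replace(series, series$values / (1 + (r - 1) * frac))
}

#' Least-squares millivolt-to-Raman-unit conversion
#'
#' Fits lab = offset + slope * sensor by ordinary least squares on paired
#' field (mV) and laboratory (RU) values.
#'
#' @param sensor_mv,lab_ru paired numeric vectors (>= 3 pairs).
#' @return list with offset, slope, r (Pearson correlation of the pairs).
#' @export
fit_unit_conversion <- function(sensor_mv, lab_ru) {
  ok <- is.finite(sensor_mv) & is.finite(lab_ru)
  sensor_mv <- sensor_mv[ok]; lab_ru <- lab_ru[ok]
  if (length(sensor_mv) < 3) stop("need at least 3 pairs for unit conversion")
  if (stats::var(sensor_mv) == 0) stop("constant sensor values: singular fit")
  slope <- stats::cov(sensor_mv, lab_ru) / stats::var(sensor_mv)
  offset <- mean(lab_ru) - slope * mean(sensor_mv)
  list(offset = offset, slope = slope, r = stats::cor(sensor_mv, lab_ru))
}

#' Apply a fitted unit conversion to a series
#' @param series \code{wq_ts} in field units (mV).
#' @param conv list with offset and slope (see \code{\link{fit_unit_conversion}}).
#' @return \code{wq_ts} in laboratory units (RU).
#' @export
apply_unit_conversion <- function(series, conv) {
  out <- ts_replace(series, conv$offset + conv$slope * series$values)
  out$units <- "RU"
  out
}

#' Compensation coefficients for temperature and turbidity interference
#'
#' @param rho linear temperature coefficient, per deg C (fluorescence quenching
#'   is typically negative, around -0.01/degC).
#' @param t_ref reference (laboratory analysis) temperature, deg C.
#' @param k turbidity attenuation coefficient, per FNU.
#' @return list of class \code{comp_coef}.
#' @export
comp_coef <- function(rho = 0, t_ref = 20, k = 0) {
  stopifnot(is.finite(rho), is.finite(t_ref), is.finite(k))
  structure(list(rho = rho, t_ref = t_ref, k = k), class = "comp_coef")
}

#' Temperature compensation (linear divisor)
#'
#' F_ref = F_meas / (1 + rho * (T - T_ref)). Points where the divisor is
#' non-positive are flagged missing with a warning.
#'
#' @param series fluorescence \code{wq_ts}.
#' @param temp water-temperature \code{wq_ts} on the same grid.
#' @param coeff a \code{\link{comp_coef}}.
#' @return compensated \code{wq_ts}.
#' @export
compensate_temperature <- function(series, temp, coeff) {
  check_aligned(series, temp, "fluorescence/temperature grids")
  den <- 1 + coeff$rho * (temp$values - coeff$t_ref)
  bad <- is.finite(den) & den <= 0
  if (any(bad)) warning(sum(bad), " point(s) with non-positive temperature divisor flagged missing")
  v <- series$values / den
  fl <- series$flags
  fl[bad] <- "missing"
  ts_replace(series, v, flags = fl)
}

#' Turbidity compensation (exponential attenuation)
#'
#' F_corr = F_meas * exp(k * turbidity): particles attenuate the optical
#' signal roughly exponentially in turbidity. Negative turbidity points are
#' flagged missing and skipped.
#'
#' @param series fluorescence \code{wq_ts}.
#' @param turb turbidity \code{wq_ts} (FNU) on the same grid.
#' @param coeff a \code{\link{comp_coef}}.
#' @return compensated \code{wq_ts}.
#' @export
compensate_turbidity <- function(series, turb, coeff) {
  check_aligned(series, turb, "fluorescence/turbidity grids")
  neg <- is.finite(turb$values) & turb$values < 0
  if (any(neg)) warning(sum(neg), " negative-turbidity point(s) flagged missing")
  v <- series$values * exp(coeff$k * turb$values)
  v[neg] <- NA_real_
  fl <- series$flags
  fl[neg] <- "missing"
  ts_replace(series, v, flags = fl)
}

#' Estimate compensation coefficients from paired field/laboratory values
#'
#' Finds (rho, k) minimizing the squared log-ratio between the compensated
#' sensor values F / (1 + rho (T - T_ref)) * exp(k * turbidity) and the
#' laboratory values.
#'
#' @param sensor,lab paired positive values (>= 10 pairs).
#' @param temp,turb temperature and turbidity at the same times.
#' @param t_ref reference temperature, deg C.
#' @return a \code{\link{comp_coef}} with attributes \code{r_pre} and
#'   \code{r_post}: Pearson correlations of log sensor vs log lab before and
#'   after compensation.
#' @export
fit_compensation <- function(sensor, lab, temp, turb, t_ref = 20) {
  ok <- is.finite(sensor) & is.finite(lab) & is.finite(temp) & is.finite(turb) &
    sensor > 0 & lab > 0
  sensor <- sensor[ok]; lab <- lab[ok]; temp <- temp[ok]; turb <- turb[ok]
  if (length(sensor) < 10) stop("need >= 10 paired observations")
  if (diff(range(temp)) < 1e-8 && diff(range(turb)) < 1e-8)
    stop("degenerate temperature/turbidity spans; use fixed literature coefficients")
  obj <- function(par) {
    den <- 1 + par[1] * (temp - t_ref)
    if (any(den <= 0)) return(1e10)
    sum((log(sensor / den) + par[2] * turb - log(lab))^2)
  }
  opt <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  cc <- comp_coef(rho = opt$par[1], t_ref = t_ref, k = opt$par[2])
  comp <- sensor / (1 + cc$rho * (temp - t_ref)) * exp(cc$k * turb)
  attr(cc, "r_pre") <- stats::cor(log(sensor), log(lab))
  attr(cc, "r_post") <- stats::cor(log(comp), log(lab))
  cc
}

#' Corrupt clean sensor series with field artifacts
#'
#' Injects, per configured sensor, turbidity attenuation, temperature
#' interference, conversion to millivolts, multiplicative linear drift and
#' linear-ramp fouling between maintenance visits — the exact inverses of the
#' corrections \code{\link{correct_sensors}} applies, so a round trip on
#' noise-free data recovers the truth. Returns the raw series together with a
#' correction log sufficient for inversion.
#'
#' @param truth named list of clean \code{wq_ts} (optical sensors plus
#'   \code{turbidity} and \code{temperature}).
#' @param artifact_config per-sensor list; each element may contain
#'   \code{drift} (fractional sensitivity change over deployment),
#'   \code{foul} (vector of per-visit fouling depressions, sensor units),
#'   \code{mv} (list offset, slope for RU -> mV), \code{rho}, \code{k},
#'   \code{t_ref}.
#' @param n_visits number of evenly spaced maintenance visits.
#' @param seed seed for placement jitter of calibration-pair sampling times.
#' @return list with \code{raw} (named list of corrupted \code{wq_ts}) and
#'   \code{log} (per-sensor correction metadata).
#' @export
corrupt_sensors <- function(truth, artifact_config = default_artifacts(),
                            n_visits = 6, seed = 1) {
  raw <- list(); logm <- list()
  turb <- truth$turbidity; temp <- truth$temperature
  for (nm in names(artifact_config)) {
    cfg <- artifact_config[[nm]]
    x <- truth[[nm]]
    if (is.null(x)) stop("truth series missing for sensor ", nm)
    times <- ts_times(x)
    n <- length(x$values)
    v <- x$values
    coeff <- comp_coef(rho = cfg$rho %||% 0, t_ref = cfg$t_ref %||% 20,
                       k = cfg$k %||% 0)
    if (coeff$k != 0) v <- v * exp(-coeff$k * turb$values)
    if (coeff$rho != 0) v <- v * (1 + coeff$rho * (temp$values - coeff$t_ref))
    conv <- cfg$mv
    if (!is.null(conv)) v <- (v - conv$offset) / conv$slope
    drift <- cfg$drift %||% 0
    frac <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
    v <- v * (1 + drift * frac)
    foul <- cfg$foul %||% numeric(0)
    visits <- NULL
    if (length(foul) > 0) {
      vt <- x$start + x$step * round(seq(1, n - 1, length.out = length(foul)))
      prev <- as.numeric(x$start); tn <- as.numeric(times)
      for (i in seq_along(foul)) {
        vi <- as.numeric(vt[i])
        seg <- tn > prev & tn <= vi
        v[seg] <- v[seg] - foul[i] * (tn[seg] - prev) / (vi - prev)
        prev <- vi
      }
      base_rd <- 100
      visits <- data.frame(time = vt, before = base_rd - foul, after = base_rd)
    }
    std <- c(1, 5, 10, 50, 100)
    cal <- list(start = data.frame(conc = std, response = std),
                end = data.frame(conc = std, response = std * (1 + drift)))
    raw[[nm]] <- wq_ts(x$start, v, step = x$step,
                       units = if (!is.null(conv)) "mV" else x$units,
                       flags = x$flags)
    logm[[nm]] <- list(maintenance = visits, calibration = cal,
                       conversion = conv, coeff = coeff)
  }
  list(raw = raw, log = logm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default field-artifact configuration
#'
#' Mirrors the deployed platforms: the two channel-fluorometer signals report
#' in millivolts and carry drift and fouling but no detectable
#' temperature/turbidity interference; the wiped FDOM sonde reports in RU with
#' mild drift plus temperature and turbidity interference.
#' @return named per-sensor artifact list.
#' @export
default_artifacts <- function() {
  list(
    `S1-CF` = list(drift = 0.6, foul = c(0.05, 0.08, 0.04, 0.07, 0.05, 0.06),
                   mv = list(offset = 0.2, slope = 0.01)),
    `S1-A`  = list(drift = 0.4, foul = c(0.04, 0.06, 0.05, 0.04, 0.06, 0.05),
                   mv = list(offset = 0.1, slope = 0.012)),
    `S2-F`  = list(drift = -0.066, foul = c(0.02, 0.03, 0.02, 0.02, 0.03, 0.02),
                   rho = -0.01, t_ref = 20, k = 0.0008)
  )
}

#' Apply the full correction sequence to raw sensor series
#'
#' Order contract: fouling, then drift, then unit conversion, then temperature
#' compensation, then turbidity compensation. Each step is skipped for sensors
#' whose log carries no metadata for it.
#'
#' @param raw named list of raw \code{wq_ts}.
#' @param log per-sensor correction metadata as produced by
#'   \code{\link{corrupt_sensors}} (maintenance, calibration, conversion,
#'   coeff).
#' @param turbidity,temperature ancillary \code{wq_ts} on the same grid.
#' @return named list of corrected \code{wq_ts}; each carries a
#'   \code{"provenance"} attribute naming the corrections applied.
#' @export
correct_sensors <- function(raw, log, turbidity = NULL, temperature = NULL) {
  out <- list()
  for (nm in names(raw)) {
    x <- raw[[nm]]
    lg <- log[[nm]]
    prov <- character(0)
    if (!is.null(lg$maintenance)) {
      x <- apply_foul_correction(x, lg$maintenance)
      prov <- c(prov, "foul")
    }
    if (!is.null(lg$calibration)) {
      x <- apply_drift_correction(x, lg$calibration)
      prov <- c(prov, "drift")
    }
    if (!is.null(lg$conversion)) {
      x <- apply_unit_conversion(x, lg$conversion)
      prov <- c(prov, "unit")
    }
    if (!is.null(lg$coeff) && lg$coeff$rho != 0) {
      if (is.null(temperature)) stop("temperature series required for ", nm)
      x <- compensate_temperature(x, temperature, lg$coeff)
      prov <- c(prov, "temperature")
    }
    if (!is.null(lg$coeff) && lg$coeff$k != 0) {
      if (is.null(turbidity)) stop("turbidity series required for ", nm)
      x <- compensate_turbidity(x, turbidity, lg$coeff)
      prov <- c(prov, "turbidity")
    }
    attr(x, "provenance") <- prov
    out[[nm]] <- x
  }
  out
}
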