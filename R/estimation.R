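#' Continuous concentration estimation with CSO model switching
#'
#' Produces the 10-minute concentration series for one marker: the non-CSO
#' model predicts everywhere except inside CSO discharge intervals, where the
#' CSO model takes over. Predictions are the smeared back-transform
#' D * 10^(x beta); values above the active model's calibration maximum (the
#' largest uncensored concentration seen in fitting) are set to that maximum
#' and flagged capped — extrapolation beyond the calibration range is not
#' trusted, but capped values are retained (conservatively) for loads and
#' benchmark screening. Missing covariate points propagate missing flags.
#'
#' @param models list with elements \code{CSO} and \code{nonCSO}, both
#'   \code{fib_model} for the same marker.
#' @param covariates named list of covariate \code{wq_ts} covering the full
#'   span (must include \code{flow} if either model uses it).
#' @param schedule CSO interval data.frame (start, end), non-overlapping and
#'   time-ordered; may be empty.
#' @return list of class \code{conc_estimate}: \code{series} (a \code{wq_ts}),
#'   \code{capped} (logical), \code{regime} (character, "CSO"/"nonCSO"),
#'   \code{marker}.
#' @export
estimate_continuous <- function(models, covariates, schedule = NULL) {
  if (!identical(models$CSO$spec$marker, models$nonCSO$spec$marker))
    stop("CSO and non-CSO models are for different markers")
  grid <- covariates[[1]]
  times <- ts_times(grid)
  cso <- in_schedule(times, schedule)
  pred <- predict(models$nonCSO, covariates, times)
  if (any(cso)) pred[cso] <- predict(models$CSO, covariates, times[cso])
  cap <- ifelse(cso, models$CSO$calibration_max, models$nonCSO$calibration_max)
  capped <- is.finite(pred) & pred > cap
  pred[capped] <- cap[capped]
  flags <- ifelse(!is.finite(pred), "missing", ifelse(capped, "capped", "ok"))
  mk <- models$nonCSO$spec$marker
  series <- wq_ts(grid$start, pred, step = grid$step,
                  units = if (grepl("culture|FC", mk)) "CFU/100mL" else "CN/100mL",
                  flags = flags)
  structure(list(series = series, capped = capped,
                 regime = ifelse(cso, "CSO", "nonCSO"), marker = mk),
            class = "conc_estimate")
}

#' @export
print.conc_estimate <- function(x, ...) {
  cat(sprintf("<conc_estimate> %s: %d points, %d capped, %d CSO-period\n",
              x$marker, length(x$series$values), sum(x$capped),
              sum(x$regime == "CSO")))
  invisible(x)
}

# wrap an existing concentration series (e.g. generator truth) as an estimate
as_conc_estimate <- function(series, marker) {
  structure(list(series = series, capped = series$flags == "capped",
                 regime = rep("nonCSO", length(series$values)), marker = marker),
            class = "conc_estimate")
}

#' Daily bacteria loads
#'
#' load(day) = sum over the day's grid steps of
#' c_t [per 100 mL] * 10,000 [100 mL per m^3] * Q_t [m^3/s] * step [s],
#' in organisms per day. Days are calendar days (UTC, no DST shifts); a day
#' with missing points integrates the available points and is flagged when
#' coverage is below 90 percent.
#'
#' @param conc a \code{conc_estimate} (or bare \code{wq_ts}).
#' @param flow streamflow \code{wq_ts} (m^3/s) on the same grid.
#' @return data.frame with date, load, coverage, low_coverage, marker.
#' @export
daily_loads <- function(conc, flow) {
  series <- if (inherits(conc, "conc_estimate")) conc$series else conc
  marker <- if (inherits(conc, "conc_estimate")) conc$marker else ""
  check_aligned(series, flow, "concentration/flow grids")
  times <- ts_times(series)
  day <- as.Date(times, tz = "UTC")
  inc <- series$values * 1e4 * flow$values * series$step
  ok <- is.finite(inc)
  if (!any(ok)) stop("no overlapping finite points for load computation")
  load <- tapply(ifelse(ok, inc, 0), day, sum)
  npts <- tapply(rep(1, length(day)), day, sum)
  nok <- tapply(as.numeric(ok), day, sum)
  per_day <- 86400 / series$step
  coverage <- as.numeric(nok) / per_day
  data.frame(date = as.Date(names(load)), load = as.numeric(load),
             coverage = coverage, low_coverage = coverage < 0.9,
             marker = marker, row.names = NULL)
}

#' Proportion of sewage in the stream
#'
#' Estimated concentration of a human-associated marker divided by its mean
#' wastewater-influent concentration: a unitless dilution fraction. Only
#' meaningful for the human markers (HB, L3, sHM).
#'
#' @param conc a \code{conc_estimate} for HB, L3 or sHM.
#' @param influent_mean mean influent concentration, CN/100 mL (> 0).
#' @return \code{wq_ts} of unitless proportions.
#' @export
proportion_sewage <- function(conc, influent_mean) {
  if (!conc$marker %in% c("HB", "L3", "sHM"))
    stop("proportion of sewage applies to human markers only (HB, L3, sHM), got ",
         conc$marker)
  if (!is.finite(influent_mean) || influent_mean <= 0)
    stop("influent_mean must be > 0")
  out <- ts_replace(conc$series, conc$series$values / influent_mean)
  out$units <- "unitless"
  out
}

#' Sum the two human markers into sHM
#'
#' Pointwise HB + L3; the summed marker trades some assay specificity for
#' sensitivity. The capped flag is set wherever either input is capped. (sHM
#' also gets its own fitted models; this constructor serves sample-level
#' construction and cross-checks.)
#'
#' @param hb,l3 \code{conc_estimate} objects on the same grid and units.
#' @return a \code{conc_estimate} for sHM.
#' @export
sum_human_markers <- function(hb, l3) {
  check_aligned(hb$series, l3$series, "HB/L3 grids")
  if (!identical(hb$series$units, l3$series$units)) stop("unit mismatch")
  v <- hb$series$values + l3$series$values
  capped <- hb$capped | l3$capped
  flags <- ifelse(is.na(v), "missing", ifelse(capped, "capped", "ok"))
  series <- wq_ts(hb$series$start, v, step = hb$series$step,
                  units = hb$series$units, flags = flags)
  structure(list(series = series, capped = capped & !is.na(v),
                 regime = hb$regime, marker = "sHM"),
            class = "conc_estimate")
}

#' Flow-weighted annual mean proportion of sewage
#'
#' Total load divided by total water volume gives the flow-weighted mean
#' stream concentration, which divided by the mean influent concentration
#' gives the annual sewage proportion.
#'
#' @param loads daily-load data.frame from \code{\link{daily_loads}}.
#' @param flow streamflow \code{wq_ts} over the same span.
#' @param influent_mean mean influent concentration, CN/100 mL.
#' @return unitless scalar proportion.
#' @export
annual_flow_weighted_proportion <- function(loads, flow, influent_mean) {
  total_load <- sum(loads$load)
  ok <- is.finite(flow$values)
  total_volume <- sum(flow$values[ok]) * flow$step   # m^3
  if (total_volume <= 0) stop("zero total water volume")
  mean_conc <- total_load / (total_volume * 1e4)     # per 100 mL
  mean_conc / influent_mean
}

#' Annual sewage contamination volume
#'
#' The flow-weighted proportion of sewage applied to the total volume of
#' water over the period.
#'
#' @param proportion unitless flow-weighted sewage proportion (>= 0).
#' @param flow streamflow \code{wq_ts} (m^3/s).
#' @return sewage volume, m^3.
#' @export
annual_sewage_volume <- function(proportion, flow) {
  if (proportion < 0) stop("proportion must be >= 0")
  ok <- is.finite(flow$values)
  proportion * sum(flow$values[ok]) * flow$step
}
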