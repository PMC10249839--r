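#' Read regular time series from CSV
#'
#' Expects an ISO-8601 \code{timestamp} column plus one numeric column per
#' variable (optionally a matching \code{<var>_flag} column). The grid must be
#' regular; missing rows become missing-flagged points; duplicated timestamps
#' are an error.
#'
#' @param path CSV path.
#' @param expected optional character vector of required variable columns.
#' @return named list of \code{wq_ts}.
#' @export
read_timeseries_csv <- function(path, expected = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(df)) stop("no 'timestamp' column in ", path)
  tt <- as_utc(df$timestamp)
  if (anyNA(tt)) stop("unparseable timestamp in ", path)
  if (anyDuplicated(tt)) stop("duplicated timestamp in ", path, ": ",
                              format(tt[duplicated(tt)][1], "%Y-%m-%dT%H:%M:%SZ"))
  o <- order(tt); tt <- tt[o]; df <- df[o, , drop = FALSE]
  dt <- diff(as.numeric(tt))
  step <- min(dt)
  if (step <= 0) stop("non-increasing timestamps in ", path)
  off <- (as.numeric(tt) - as.numeric(tt[1])) / step
  if (any(abs(off - round(off)) > 1e-6))
    stop("irregular spacing in ", path, " at ",
         format(tt[which(abs(off - round(off)) > 1e-6)[1]], "%Y-%m-%dT%H:%M:%SZ"))
  n <- round(max(off)) + 1
  idx <- round(off) + 1
  vars <- setdiff(names(df), c("timestamp", grep("_flag$", names(df), value = TRUE)))
  if (!is.null(expected)) {
    miss <- setdiff(expected, vars)
    if (length(miss)) stop("missing expected column(s): ", paste(miss, collapse = ", "))
  }
  out <- list()
  for (v in vars) {
    vals <- rep(NA_real_, n)
    vals[idx] <- df[[v]]
    flags <- rep("missing", n)
    fcol <- paste0(v, "_flag")
    flags[idx] <- if (fcol %in% names(df)) df[[fcol]] else "ok"
    flags[is.na(vals) & flags == "ok"] <- "missing"
    out[[v]] <- wq_ts(tt[1], vals, step = step, flags = flags)
  }
  out
}

#' Write time series to CSV
#' @param series named list of aligned \code{wq_ts}.
#' @param path output CSV path.
#' @param flags write per-variable flag columns too.
#' @return the path, invisibly.
#' @export
write_timeseries_csv <- function(series, path, flags = TRUE) {
  base <- series[[1]]
  for (s in series) check_aligned(base, s)
  df <- data.frame(timestamp = format(ts_times(base), "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC"))
  for (nm in names(series)) {
    df[[nm]] <- series[[nm]]$values
    if (flags) df[[paste0(nm, "_flag")]] <- series[[nm]]$flags
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read/write discrete-sample tables
#' @param path CSV path.
#' @return data.frame with parsed timestamps and logical censored flags.
#' @export
read_samples_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as_utc(df$timestamp)
  df$censored <- as.logical(df$censored)
  df
}

#' @rdname read_samples_csv
#' @param samples discrete-sample data.frame.
#' @export
write_samples_csv <- function(samples, path) {
  out <- samples
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read/write CSO discharge schedules as (start, end) interval rows
#' @param path CSV path.
#' @return data.frame with POSIXct start/end.
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$start <- as_utc(df$start); df$end <- as_utc(df$end)
  if (nrow(df) > 1 && any(as.numeric(df$start[-1]) < as.numeric(df$end[-nrow(df)])))
    stop("schedule intervals overlap or are out of order")
  df
}

#' @rdname read_schedule_csv
#' @param schedule interval data.frame.
#' @export
write_schedule_csv <- function(schedule, path) {
  out <- data.frame(start = format(schedule$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    end = format(schedule$end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param markers markers to model.
#' @param pool optical variable pool.
#' @param k,reps cross-validation folds and repetitions.
#' @param seed master seed; all stage seeds derive from it.
#' @param tolerance parsimony window of the selection rule.
#' @param normalization error normalization mode.
#' @param criteria benchmark criteria data.frame.
#' @param outdir output directory (created if absent); NULL to skip writing.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(markers = NULL, pool = optical_pool(), k = 5,
                            reps = 50, seed = 1, tolerance = 0.03,
                            normalization = "none",
                            criteria = default_criteria(), outdir = NULL) {
  if (k < 2) stop("k must be >= 2")
  if (reps < 1) stop("reps must be >= 1")
  if (tolerance < 0) stop("tolerance must be >= 0")
  structure(list(markers = markers, pool = pool, k = k, reps = reps,
                 seed = as.integer(seed), tolerance = tolerance,
                 normalization = normalization, criteria = criteria,
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the full estimation pipeline
#'
#' From discrete samples and corrected covariate series to selected models,
#' continuous estimates with CSO switching, daily loads, sewage proportions,
#' an annual summary and a benchmark exceedance table. Artifacts are written
#' to \code{config$outdir} when set (selection report and benchmark table as
#' CSV, fitted models and annual summary as JSON).
#'
#' @param samples discrete-sample data.frame.
#' @param covariates named list of covariate \code{wq_ts} including
#'   \code{flow}.
#' @param schedule CSO interval data.frame.
#' @param influent influent data.frame (month, marker, value) used for sewage
#'   proportions, or NULL to skip them.
#' @param config a \code{\link{pipeline_config}}.
#' @return list with selection (a \code{selection_report}), estimates (named
#'   list of \code{conc_estimate}), loads (named list of daily-load frames),
#'   annual (summary list), benchmarks (data.frame).
#' @export
run_pipeline <- function(samples, covariates, schedule, influent = NULL,
                         config = pipeline_config()) {
  markers <- config$markers
  if (is.null(markers)) markers <- unique(samples$marker)
  if (is.null(covariates$flow)) stop("estimation stage requires a 'flow' covariate")
  covariates$flow1h <- rolling_hour_mean(covariates$flow)

  sel <- fit_all_regimes(samples, covariates, markers = markers,
                         pool = config$pool, k = config$k, reps = config$reps,
                         seed = config$seed, tolerance = config$tolerance,
                         normalization = config$normalization)

  estimates <- list(); loads <- list()
  for (mk in markers) {
    m_cso <- sel$models[[paste(mk, "CSO", sep = "|")]]
    m_non <- sel$models[[paste(mk, "nonCSO", sep = "|")]]
    if (is.null(m_cso) || is.null(m_non)) next
    est <- estimate_continuous(list(CSO = m_cso, nonCSO = m_non),
                               covariates, schedule)
    estimates[[mk]] <- est
    loads[[mk]] <- daily_loads(est, covariates$flow)
  }

  annual <- list(seed = config$seed)
  if (!is.null(influent)) {
    for (mk in intersect(c("HB", "L3", "sHM"), names(estimates))) {
      imean <- influent_mean(influent, mk)
      if (!is.finite(imean)) next
      p <- annual_flow_weighted_proportion(loads[[mk]], covariates$flow, imean)
      annual[[mk]] <- list(
        influent_mean = imean,
        flow_weighted_proportion = p,
        annual_sewage_volume_m3 = annual_sewage_volume(p, covariates$flow))
    }
  }

  bench <- benchmark_report(estimates, config$criteria)

  out <- list(selection = sel, estimates = estimates, loads = loads,
              annual = annual, benchmarks = bench)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sel$report, file.path(config$outdir, "selection_report.csv"),
                     row.names = FALSE)
    utils::write.csv(bench, file.path(config$outdir, "benchmarks.csv"),
                     row.names = FALSE)
    jsonlite::write_json(annual, file.path(config$outdir, "annual_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    for (key in names(sel$models)) {
      write_model_json(sel$models[[key]],
                       file.path(config$outdir,
                                 paste0("model_", gsub("[^A-Za-z0-9]", "_", key),
                                        ".json")))
    }
  }
  out
}

#' Mean influent concentration for a marker
#'
#' For sHM the influent mean is the sum of the HB and L3 means: the summed
#' marker's influent signal is the sum of its components.
#'
#' @param influent data.frame (month, marker, value).
#' @param marker marker name.
#' @return mean concentration, CN/100 mL.
#' @export
influent_mean <- function(influent, marker) {
  if (marker == "sHM") {
    return(mean(influent$value[influent$marker == "HB"]) +
             mean(influent$value[influent$marker == "L3"]))
  }
  mean(influent$value[influent$marker == marker])
}
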