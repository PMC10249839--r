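#' Model specification
#'
#' Describes one candidate surrogate regression: which optical signals enter
#' (each with its seasonal sine/cosine interaction pair unless disabled),
#' whether turbidity and log10 one-hour mean flow enter, and which hydrologic
#' regime the model is fit on.
#'
#' @param marker response marker name.
#' @param opticals character subset of \code{c("S1-CF", "S1-A", "S2-F")}.
#' @param seasonal logical; include the seasonal interaction pair with every
#'   optical variable (the default, following the deployed modeling approach).
#' @param turbidity logical; include untransformed turbidity.
#' @param flow logical; include log10 of the one-hour rolling mean flow.
#' @param regime one of \code{"CSO"}, \code{"nonCSO"}, \code{"combined"}.
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(marker, opticals = "S2-F", seasonal = TRUE,
                       turbidity = FALSE, flow = FALSE, regime = "combined") {
  opticals <- intersect(optical_pool(), opticals)  # canonical order
  if (length(opticals) == 0 && !turbidity && !flow)
    stop("model_spec needs at least one explanatory variable")
  if (!regime %in% c("CSO", "nonCSO", "combined")) stop("unknown regime: ", regime)
  structure(list(marker = marker, opticals = opticals, seasonal = seasonal,
                 turbidity = turbidity, flow = flow, regime = regime),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s [%s]: %s%s%s\n", x$marker, x$regime,
              paste(x$opticals, collapse = "+"),
              if (x$turbidity) " +turbidity" else "",
              if (x$flow) " +flow" else ""))
  invisible(x)
}

optical_pool <- function() c("S1-CF", "S1-A", "S2-F")

# canonical column names for a spec's design matrix
design_colnames <- function(spec) {
  nm <- "(Intercept)"
  for (v in spec$opticals) {
    nm <- c(nm, v)
    if (spec$seasonal) nm <- c(nm, paste0(v, ":sin"), paste0(v, ":cos"))
  }
  if (spec$turbidity) nm <- c(nm, "turbidity")
  if (spec$flow) nm <- c(nm, "log10(flow1h)")
  nm
}

# explanatory-variable terms, i.e. design columns minus the intercept
n_terms <- function(spec) length(design_colnames(spec)) - 1L

# design rows for arbitrary timestamps, from grid covariates
design_matrix <- function(covariates, times, spec) {
  n <- length(times)
  d <- decimal_doy(times)
  ang <- 2 * pi * d / 365.25
  cols <- list(`(Intercept)` = rep(1, n))
  for (v in spec$opticals) {
    if (is.null(covariates[[v]])) stop("covariate series missing: ", v)
    x <- cov_at(covariates[[v]], times)
    cols[[v]] <- x
    if (spec$seasonal) {
      cols[[paste0(v, ":sin")]] <- x * sin(ang)
      cols[[paste0(v, ":cos")]] <- x * cos(ang)
    }
  }
  if (spec$turbidity) {
    if (is.null(covariates$turbidity)) stop("covariate series missing: turbidity")
    cols$turbidity <- cov_at(covariates$turbidity, times)
  }
  if (spec$flow) {
    if (is.null(covariates$flow)) stop("covariate series missing: flow")
    f1h <- covariates$flow1h
    if (is.null(f1h)) f1h <- rolling_hour_mean(covariates$flow)
    cols$`log10(flow1h)` <- log10(cov_at(f1h, times))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

cov_at <- function(series, times) {
  # fast path: times are exactly the series' own grid
  if (length(times) == length(series$values) &&
      abs(as.numeric(times[1]) - as.numeric(series$start)) < 1e-6) {
    return(series$values)
  }
  series$values[ts_index_of(series, times)]
}

#' Build a regression design from discrete samples
#'
#' Assembles the canonical design matrix (intercept; optical signals with
#' seasonal sine/cosine interactions computed from each sample's decimal
#' day-of-year; optional turbidity; optional log10 one-hour mean flow), the
#' log10 response vector and the censoring flags for one marker and regime.
#'
#' @param samples data.frame of discrete samples (see
#'   \code{\link{draw_discrete_samples}}).
#' @param covariates named list of \code{wq_ts} with elements matching the
#'   spec's variables plus \code{flow} when flow is included.
#' @param spec a \code{\link{model_spec}}; its marker and regime filter the
#'   samples (\code{"combined"} keeps all regimes, \code{"CSO"} keeps
#'   event-CSO, \code{"nonCSO"} keeps the rest).
#' @return list with X (matrix), y (log10 response), censored (logical),
#'   detection_limit (log10 limits), timestamps.
#' @export
build_design <- function(samples, covariates, spec) {
  s <- samples[samples$marker == spec$marker, , drop = FALSE]
  s <- switch(spec$regime,
              CSO = s[s$regime == "event-CSO", , drop = FALSE],
              nonCSO = s[s$regime != "event-CSO", , drop = FALSE],
              combined = s)
  if (nrow(s) == 0) stop("no samples for marker ", spec$marker,
                         " in regime ", spec$regime)
  X <- design_matrix(covariates, s$timestamp, spec)
  list(X = X, y = log10(s$value), censored = s$censored,
       detection_limit = log10(s$detection_limit), timestamps = s$timestamp)
}
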