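#' Regular water-quality time series
#'
#' Minimal container for a strictly regular time series: a UTC start time, a
#' fixed step in seconds, numeric values, a unit string and per-point quality
#' flags (\code{"ok"}, \code{"missing"} or \code{"capped"}). All continuous
#' inputs and outputs of the pipeline (streamflow, optical signals, turbidity,
#' temperature, concentration estimates) use this class.
#'
#' @param start POSIXct (UTC) timestamp of the first point, or an ISO-8601
#'   string.
#' @param values numeric vector, length >= 1. Non-finite values are flagged
#'   \code{"missing"} and stored as \code{NA}.
#' @param step grid spacing in seconds (default 600, the 10-minute field grid).
#' @param units unit label, e.g. \code{"m^3/s"}, \code{"RU"}, \code{"FNU"}.
#' @param flags optional character vector of per-point quality codes.
#' @return An object of class \code{wq_ts}.
#' @export
wq_ts <- function(start, values, step = 600, units = "", flags = NULL) {
  start <- as_utc(start)
  if (length(start) != 1L || is.na(start)) stop("'start' must be a single valid timestamp")
  if (!is.numeric(step) || length(step) != 1L || step <= 0) stop("'step' must be a positive number of seconds")
  values <- as.numeric(values)
  if (length(values) < 1L) stop("'values' must have length >= 1")
  if (is.null(flags)) flags <- rep("ok", length(values))
  flags <- as.character(flags)
  if (length(flags) != length(values)) stop("'flags' must match 'values' in length")
  bad <- !flags %in% c("ok", "missing", "capped")
  if (any(bad)) stop("unknown quality flag: ", flags[bad][1])
  nf <- !is.finite(values) & flags != "missing"
  flags[nf] <- "missing"
  values[flags == "missing"] <- NA_real_
  structure(list(start = start, step = as.numeric(step), values = values,
                 units = units, flags = flags),
            class = "wq_ts")
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  out
}

#' @export
print.wq_ts <- function(x, ...) {
  cat(sprintf("<wq_ts> %d points @ %gs, start %s [%s]\n",
              length(x$values), x$step,
              format(x$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), x$units))
  n_miss <- sum(x$flags == "missing")
  n_cap <- sum(x$flags == "capped")
  cat(sprintf("  range %s; missing %d; capped %d\n",
              paste(signif(range(x$values, na.rm = TRUE), 4), collapse = " .. "),
              n_miss, n_cap))
  invisible(x)
}

#' @export
length.wq_ts <- function(x) length(x$values)

#' Timestamps of a regular series
#' @param x a \code{wq_ts}.
#' @return POSIXct vector of per-point timestamps.
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "wq_ts"))
  x$start + x$step * (seq_along(x$values) - 1)
}

#' @export
as.data.frame.wq_ts <- function(x, ...) {
  data.frame(timestamp = ts_times(x), value = x$values, flag = x$flags,
             stringsAsFactors = FALSE)
}

# shared-grid check used by every aligned operation
check_aligned <- function(a, b, what = "series") {
  if (!identical(length(a$values), length(b$values)) ||
      abs(as.numeric(a$start) - as.numeric(b$start)) > 1e-6 ||
      abs(a$step - b$step) > 1e-9) {
    stop("misaligned ", what, ": start/step/length must match")
  }
  invisible(TRUE)
}

# nearest grid index for arbitrary timestamps; error if farther than one step
ts_index_of <- function(x, when, tol_steps = 1) {
  when <- as_utc(when)
  idx <- round(as.numeric(when - x$start, units = "secs") / x$step) + 1
  off <- abs(as.numeric(when - x$start, units = "secs") - (idx - 1) * x$step)
  bad <- idx < 1 | idx > length(x$values) | off > tol_steps * x$step
  if (any(bad)) {
    stop("timestamp(s) outside covariate span or grid: ",
         paste(format(when[bad][seq_len(min(3, sum(bad)))],
                      "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), collapse = ", "))
  }
  idx
}

# modify values keeping class invariants
ts_replace <- function(x, values, flags = x$flags) {
  wq_ts(x$start, values, step = x$step, units = x$units, flags = flags)
}

#' Trailing one-hour mean of a regular series
#'
#' Rolling mean over the trailing hour (inclusive of the current point), the
#' flow covariate convention used in the regression design.
#'
#' @param x a \code{wq_ts}.
#' @return a \code{wq_ts} on the same grid.
#' @export
rolling_hour_mean <- function(x) {
  stopifnot(inherits(x, "wq_ts"))
  w <- max(1L, as.integer(round(3600 / x$step)))
  v <- x$values
  n <- length(v)
  vv <- ifelse(is.na(v), 0, v)
  ok <- as.numeric(!is.na(v))
  cs <- cumsum(vv); ck <- cumsum(ok)
  lag <- c(rep(0, w), cs[seq_len(n - w)])
  lagk <- c(rep(0, w), ck[seq_len(n - w)])
  num <- cs - lag
  den <- ck - lagk
  out <- ifelse(den > 0, num / den, NA_real_)
  ts_replace(x, out, flags = ifelse(is.na(out), "missing", "ok"))
}

# decimal day-of-year (Jan 1 00:00 = 0) used by the seasonal terms
decimal_doy <- function(when) {
  when <- as_utc(when)
  yr <- as.POSIXlt(when, tz = "UTC")$year + 1900L
  jan1 <- as.POSIXct(sprintf("%d-01-01", yr), tz = "UTC")
  as.numeric(when - jan1, units = "days")
}
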