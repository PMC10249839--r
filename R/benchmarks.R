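#' Recreational water-quality criteria
#'
#' A criterion is either a single-sample threshold or a 30-day geometric-mean
#' rule with a statistical threshold value (STV): the GM of any 30-day window
#' must not exceed the GM magnitude, and no more than 10 percent of values in
#' the window may exceed the STV.
#'
#' @param marker marker the criterion applies to.
#' @param method \code{"culture"} or \code{"qPCR"}; criteria are matched to
#'   estimates by marker and method, never cross-applied.
#' @param kind \code{"single_sample"} or \code{"gm_stv"}.
#' @param single single-sample threshold (units/100 mL), for
#'   \code{single_sample}.
#' @param gm,stv geometric-mean and STV magnitudes, for \code{gm_stv}.
#' @param label human-readable label.
#' @return one-row data.frame.
#' @export
criterion <- function(marker, method, kind, single = NA, gm = NA, stv = NA,
                      label = "") {
  if (!kind %in% c("single_sample", "gm_stv")) stop("unknown criterion kind")
  if (kind == "single_sample" && (!is.finite(single) || single <= 0))
    stop("single-sample criterion needs a positive threshold")
  if (kind == "gm_stv" && (!is.finite(gm) || gm <= 0 || !is.finite(stv) || stv <= 0))
    stop("gm_stv criterion needs positive gm and stv thresholds")
  data.frame(marker = marker, method = method, kind = kind,
             single = single, gm = gm, stv = stv, label = label,
             stringsAsFactors = FALSE)
}

#' Default recreational water-quality criteria set
#'
#' The seven criteria used for freshwater primary-contact assessment: EPA
#' culture criteria for enterococci and E. coli as 30-day GM/STV pairs and as
#' single-sample beach action values, the qPCR enterococci single-sample
#' value, and the two human-Bacteroides QMRA risk benchmarks (4,200 and 7,800
#' CN/100 mL), consumed as constants.
#'
#' @return data.frame of seven criteria rows.
#' @export
default_criteria <- function() {
  rbind(
    criterion("EN-culture", "culture", "gm_stv", gm = 35, stv = 130,
              label = "Enterococci 35 cfu GM / 130 cfu STV"),
    criterion("EC-culture", "culture", "gm_stv", gm = 126, stv = 410,
              label = "E. coli 126 cfu GM / 410 cfu STV"),
    criterion("EN-culture", "culture", "single_sample", single = 70,
              label = "Enterococci 70 cfu single sample"),
    criterion("EC-culture", "culture", "single_sample", single = 235,
              label = "E. coli 235 cfu single sample"),
    criterion("EN-qPCR", "qPCR", "single_sample", single = 1000,
              label = "Enterococci 1000 cce single sample"),
    criterion("HB", "qPCR", "single_sample", single = 4200,
              label = "Human Bacteroides 4200 CN QMRA benchmark"),
    criterion("HB", "qPCR", "single_sample", single = 7800,
              label = "Human Bacteroides 7800 CN QMRA benchmark")
  )
}

#' Single-sample exceedance fraction
#'
#' Fraction of non-missing time steps whose estimated concentration exceeds
#' the single-sample threshold.
#'
#' @param conc a \code{conc_estimate}.
#' @param crit one criterion row of kind \code{single_sample}.
#' @return list of class \code{exceedance_result}: label, fraction,
#'   n_evaluated.
#' @export
single_sample_exceedance <- function(conc, crit) {
  stopifnot(crit$kind == "single_sample")
  v <- conc$series$values
  ok <- conc$series$flags != "missing" & is.finite(v)
  if (!any(ok)) stop("no evaluable points")
  frac <- sum(v[ok] > crit$single) / sum(ok)
  structure(list(label = crit$label, fraction = frac, n_evaluated = sum(ok)),
            class = "exceedance_result")
}

#' 30-day geometric-mean / STV exceedance fraction
#'
#' For every time step with a full trailing window available, the window is
#' in exceedance if the geometric mean of its non-missing values exceeds the
#' GM magnitude OR more than 10 percent of them exceed the STV. Windows with
#' under 50 percent coverage are unevaluable and excluded. The result is the
#' fraction of evaluable steps whose window is in exceedance. Trailing
#' windows are anchored at each grid step (the criterion speaks of "any
#' 30-day interval", not calendar months); capped values enter the geometric
#' mean as-is, which understates true exceedance.
#'
#' @param conc a \code{conc_estimate} spanning at least one window.
#' @param crit one criterion row of kind \code{gm_stv}.
#' @param window window length in days (default 30).
#' @param excursion_limit maximum tolerated STV excursion frequency
#'   (default 0.10).
#' @return list of class \code{exceedance_result}: label, fraction,
#'   n_evaluated, plus gm and stv_frac vectors (per evaluable window).
#' @export
gm_stv_exceedance <- function(conc, crit, window = 30,
                              excursion_limit = 0.10) {
  stopifnot(crit$kind == "gm_stv")
  series <- conc$series
  w <- as.integer(round(window * 86400 / series$step))
  n <- length(series$values)
  if (n < w) stop("series span shorter than the ", window, "-day window")
  v <- series$values
  ok <- series$flags != "missing" & is.finite(v) & v > 0
  lv <- ifelse(ok, log(v), 0)
  ex <- as.numeric(ok & v > crit$stv)
  okn <- as.numeric(ok)
  csum <- function(x) { c0 <- cumsum(x); c(c0[w:n] - c(0, c0[seq_len(n - w)])) }
  s_lv <- csum(lv); s_ex <- csum(ex); s_ok <- csum(okn)
  evaluable <- s_ok >= 0.5 * w & s_ok > 0
  gm <- exp(s_lv / s_ok)
  stv_frac <- s_ex / s_ok
  exceed <- gm > crit$gm | stv_frac > excursion_limit
  if (!any(evaluable)) stop("no evaluable windows")
  frac <- sum(exceed[evaluable]) / sum(evaluable)
  structure(list(label = crit$label, fraction = frac,
                 n_evaluated = sum(evaluable),
                 gm = gm[evaluable], stv_frac = stv_frac[evaluable]),
            class = "exceedance_result")
}

#' @export
print.exceedance_result <- function(x, ...) {
  cat(sprintf("<exceedance_result> %s: %.1f%% of %d evaluated steps\n",
              x$label, 100 * x$fraction, x$n_evaluated))
  invisible(x)
}

#' Benchmark exceedance report
#'
#' Evaluates each criterion against the matching marker's continuous estimate
#' and reports percent-of-period exceedance, one row per criterion. Criteria
#' whose marker has no estimate are marked unavailable.
#'
#' @param estimates named list of \code{conc_estimate} keyed by marker.
#' @param criteria criteria data.frame (default \code{\link{default_criteria}}).
#' @param window GM/STV window length, days.
#' @return data.frame with label, marker, method, kind, percent_exceedance,
#'   available.
#' @export
benchmark_report <- function(estimates, criteria = default_criteria(),
                             window = 30) {
  if (nrow(criteria) == 0)
    return(data.frame(label = character(), marker = character(),
                      method = character(), kind = character(),
                      percent_exceedance = numeric(), available = logical()))
  rows <- lapply(seq_len(nrow(criteria)), function(i) {
    cr <- criteria[i, ]
    est <- estimates[[cr$marker]]
    if (is.null(est)) {
      return(data.frame(label = cr$label, marker = cr$marker,
                        method = cr$method, kind = cr$kind,
                        percent_exceedance = NA_real_, available = FALSE))
    }
    res <- if (cr$kind == "single_sample") single_sample_exceedance(est, cr)
           else gm_stv_exceedance(est, cr, window = window)
    data.frame(label = cr$label, marker = cr$marker, method = cr$method,
               kind = cr$kind, percent_exceedance = 100 * res$fraction,
               available = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
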