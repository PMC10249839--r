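#' Reference cross-validated model skill
#'
#' Packaged summary of selected explanatory variables and median
#' cross-validated prediction error (log10 units) for the eight bacteria
#' markers under the three regime splits (CSO-only, non-CSO, combined) from
#' the year-long Menomonee River optical-sensor deployment that motivates the
#' pipeline's defaults. Used as reference input for cross-regime skill
#' comparisons; not recomputed by this package.
#'
#' @return data.frame with marker, regime, per-variable x-marks and
#'   median_nrmsep.
#' @export
reference_model_skill <- function() {
  path <- system.file("extdata", "reference_model_skill.csv",
                      package = "optifib", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = c(median_nrmsep = "numeric"))
}

#' Cross-regime error inflation
#'
#' Per-marker percent change of a regime's median prediction error relative
#' to the combined-data model, averaged across markers: how much worse (or
#' better) the regime-specific models predict than models fit on all data.
#'
#' @param skill model-skill table with columns marker, regime, median_nrmsep
#'   (default the packaged reference table).
#' @param regime regime to compare against \code{"combined"}.
#' @return list with per_marker (named percent changes) and mean_percent.
#' @export
regime_error_inflation <- function(skill = reference_model_skill(),
                                   regime = "CSO") {
  a <- skill[skill$regime == regime, c("marker", "median_nrmsep")]
  b <- skill[skill$regime == "combined", c("marker", "median_nrmsep")]
  m <- merge(a, b, by = "marker", suffixes = c("_regime", "_combined"))
  if (nrow(m) == 0) stop("no overlapping markers between regimes")
  pct <- 100 * (m$median_nrmsep_regime / m$median_nrmsep_combined - 1)
  names(pct) <- m$marker
  list(per_marker = pct, mean_percent = mean(pct))
}
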