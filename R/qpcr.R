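#' qPCR standard-curve arithmetic
#'
#' A standard curve maps log10 copies per reaction to quantification cycle:
#' Cq = intercept + slope * log10(copies), slope < 0. Amplification
#' efficiency, copy-number quantification and volume-based limits of
#' quantification all derive from it.
#'
#' @name qpcr_utils
NULL

#' Construct a qPCR standard curve
#' @param slope Cq change per log10 copies (must be negative; -3.32 is 100
#'   percent efficiency).
#' @param intercept Cq at one copy per reaction.
#' @param r2 optional curve fit r-squared.
#' @return list of class \code{std_curve}.
#' @export
std_curve <- function(slope, intercept, r2 = NA) {
  if (!is.finite(slope) || slope >= 0) stop("standard-curve slope must be negative")
  structure(list(slope = slope, intercept = intercept, r2 = r2),
            class = "std_curve")
}

#' Packaged assay standard curves
#'
#' The four assay curves used for the human and general markers: human
#' Bacteroides (HB), human Lachnospiraceae (L3), enterococci (EN) and E. coli
#' (EC).
#' @return named list of \code{\link{std_curve}}.
#' @export
default_std_curves <- function() {
  list(HB = std_curve(-3.36, 37.11, 0.998),
       L3 = std_curve(-3.45, 38.38, 0.996),
       EN = std_curve(-3.43, 39.77, 1.00),
       EC = std_curve(-3.48, 39.27, 0.999))
}

#' Amplification efficiency from a standard-curve slope
#'
#' E = (10^(-1/slope) - 1) * 100 percent; a slope of -3.3219 (= -1/log10(2))
#' is perfect doubling, 100 percent.
#'
#' @param slope standard-curve slope (negative).
#' @return efficiency in percent.
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.finite(slope) || slope >= 0) stop("slope must be negative")
  (10^(-1 / slope) - 1) * 100
}

#' Concentration from a quantification cycle
#'
#' copies_per_reaction = 10^((cq - intercept)/slope); the reported
#' concentration scales by the extract/template accounting factor and by
#' 100 / volume filtered.
#'
#' @param cq quantification cycle(s).
#' @param curve a \code{\link{std_curve}}.
#' @param volume_filtered_ml volume of water filtered, mL (> 0).
#' @param scaling combined extract/template scaling factor (copies in the
#'   whole filter extract per copy in one reaction), default 1.
#' @return concentration in CN/100 mL.
#' @export
concentration_from_cq <- function(cq, curve, volume_filtered_ml = 100,
                                  scaling = 1) {
  stopifnot(inherits(curve, "std_curve"))
  if (!is.finite(volume_filtered_ml) || volume_filtered_ml <= 0)
    stop("volume filtered must be > 0")
  copies <- 10^((cq - curve$intercept) / curve$slope)
  copies * scaling * 100 / volume_filtered_ml
}

#' Forward map: copies per reaction to quantification cycle
#' @param copies copies per reaction (> 0).
#' @param curve a \code{\link{std_curve}}.
#' @return Cq value(s).
#' @export
cq_from_copies <- function(copies, curve) {
  stopifnot(inherits(curve, "std_curve"))
  curve$intercept + curve$slope * log10(copies)
}

#' Limit of quantification from filtered volume
#'
#' LOQ = lod_per_reaction * scaling * 100 / volume_filtered_ml: the assay's
#' per-reaction detection floor propagated through the volumetric accounting.
#'
#' @param lod_per_reaction assay limit of detection, copies per reaction.
#' @param volume_filtered_ml volume filtered, mL (> 0).
#' @param scaling extract/template scaling factor.
#' @return LOQ in CN/100 mL.
#' @export
loq_from_volume <- function(lod_per_reaction, volume_filtered_ml,
                            scaling = 1) {
  if (any(!is.finite(c(lod_per_reaction, volume_filtered_ml, scaling))) ||
      lod_per_reaction <= 0 || volume_filtered_ml <= 0 || scaling <= 0)
    stop("all inputs must be positive")
  lod_per_reaction * scaling * 100 / volume_filtered_ml
}
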