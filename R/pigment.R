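#' Ground-truth haemocyanin pigment
#'
#' Defines a known oxygen-binding "truth" used by the simulator: a pigment
#' whose pH--oxygen-saturation behaviour at every constant PO2 is a
#' five-parameter logistic in pH, with PO2 entering only through the position
#' of half-saturation (the Bohr line) and temperature entering through the
#' P50 anchor and the residual low-pH saturation.
#'
#' Defaults describe an Antarctic-octopod-like pigment: half-saturation at
#' 2.34 kPa PO2 and pH 7.27 (at the 10 degC reference), Bohr coefficient
#' -1.22, oxygen carrying capacity 1.58 mmol O2 per litre haemolymph, and a
#' temperature sensitivity of 0.193 kPa P50 per degC (which places P50 at
#' 0.41 kPa at 0 degC). The steepness default of 8 per pH unit corresponds to
#' a maximum slope of 2 saturation units per pH unit for a symmetric
#' logistic, i.e. a cooperativity of oxygenation-linked proton binding of
#' about 3.2 mmol O2 L-1 pH-1 at the default capacity.
#'
#' @param capacity Oxygen carrying capacity, mmol O2 per litre haemolymph.
#' @param p50_ref PO2 (kPa) of half-saturation at `ph_ref` and `ref_temp`.
#' @param ph_ref pH anchor of `p50_ref`.
#' @param bohr_slope Bohr coefficient, d log10(P50) / d pH; negative for a
#'   normal Bohr effect. Must be non-zero.
#' @param steepness Logistic slope magnitude per pH unit (> 0).
#' @param asymmetry Five-parameter-logistic asymmetry exponent (> 0); 1 gives
#'   a symmetric logistic.
#' @param lower_asymptote Residual saturation fraction at low pH at
#'   `ref_temp` (0 <= value < 0.5).
#' @param lower_asymptote_slope Change of the residual saturation per degC
#'   (negative values make deoxygenation less complete in the cold).
#' @param temp_coeff Change of P50 (kPa) per degC around `ref_temp`.
#' @param ref_temp Reference temperature, degC.
#' @return An object of class `gt_pigment`.
#' @seealso [build_binding_surface()]
#' @export
ground_truth_pigment <- function(capacity = 1.58,
                                 p50_ref = 2.34,
                                 ph_ref = 7.27,
                                 bohr_slope = -1.22,
                                 steepness = 8,
                                 asymmetry = 1,
                                 lower_asymptote = 0,
                                 lower_asymptote_slope = 0,
                                 temp_coeff = 0.193,
                                 ref_temp = 10) {
  stop_if_not_scalar(capacity, "capacity", positive = TRUE)
  stop_if_not_scalar(p50_ref, "p50_ref", positive = TRUE)
  stop_if_not_scalar(ph_ref, "ph_ref")
  stop_if_not_scalar(bohr_slope, "bohr_slope")
  if (bohr_slope == 0) {
    stop("bohr_slope must be non-zero: pH50 is undefined otherwise")
  }
  stop_if_not_scalar(steepness, "steepness", positive = TRUE)
  stop_if_not_scalar(asymmetry, "asymmetry", positive = TRUE)
  stop_if_not_scalar(lower_asymptote, "lower_asymptote")
  if (lower_asymptote < 0 || lower_asymptote >= 0.5) {
    stop("lower_asymptote must lie in [0, 0.5)")
  }
  stop_if_not_scalar(lower_asymptote_slope, "lower_asymptote_slope")
  stop_if_not_scalar(temp_coeff, "temp_coeff")
  stop_if_not_scalar(ref_temp, "ref_temp")
  structure(
    list(capacity = capacity, p50_ref = p50_ref, ph_ref = ph_ref,
         bohr_slope = bohr_slope, steepness = steepness,
         asymmetry = asymmetry, lower_asymptote = lower_asymptote,
         lower_asymptote_slope = lower_asymptote_slope,
         temp_coeff = temp_coeff, ref_temp = ref_temp),
    class = "gt_pigment"
  )
}

#' @export
print.gt_pigment <- function(x, ...) {
  cat("Ground-truth pigment\n")
  cat(sprintf("  capacity     : %.3f mmol O2/L\n", x$capacity))
  cat(sprintf("  P50          : %.3f kPa at pH %.3f, %.1f degC\n",
              x$p50_ref, x$ph_ref, x$ref_temp))
  cat(sprintf("  Bohr slope   : %.3f dlog10(P50)/dpH\n", x$bohr_slope))
  cat(sprintf("  steepness    : %.2f /pH, asymmetry %.2f\n",
              x$steepness, x$asymmetry))
  cat(sprintf("  temp coeff   : %.3f kPa/degC\n", x$temp_coeff))
  invisible(x)
}

# P50 of the ground truth at temperature t (kPa).
gt_p50_at <- function(gt, temperature) {
  p50 <- gt$p50_ref + gt$temp_coeff * (temperature - gt$ref_temp)
  if (any(p50 <= 0)) {
    stop("ground-truth P50 is non-positive at the requested temperature")
  }
  p50
}

# Residual low-pH saturation of the ground truth at temperature t. The
# < 0.5 constraint applies to the reference-temperature field only: cold
# shifts may push the floor above half saturation (the regime in which
# pH50 becomes undefined), capped well below full saturation.
gt_lower_asymptote_at <- function(gt, temperature) {
  la <- gt$lower_asymptote +
    gt$lower_asymptote_slope * (temperature - gt$ref_temp)
  pmin(0.95, pmax(0, la))
}

#' Build the saturation surface of a ground-truth pigment
#'
#' Returns a function `S(ph, po2, temperature)` giving fractional haemocyanin
#' oxygen saturation. At each constant PO2 the surface is a five-parameter
#' logistic in pH whose half-saturation pH follows the Bohr line
#' `pH50(PO2) = ph_ref + (log10 PO2 - log10 P50(T)) / bohr_slope`.
#' The surface is non-decreasing in both pH (normal Bohr effect) and PO2,
#' and bounded in \[0, 1\].
#'
#' When the residual low-pH saturation at the requested temperature is below
#' 0.5, the logistic anchor is placed so that `S(pH50) = 0.5` exactly, also
#' for asymmetric curves; when the residual saturation reaches 0.5 or more
#' the half-saturation pH is undefined and the Bohr-line pH is used as the
#' inflection anchor directly.
#'
#' @param gt A [ground_truth_pigment()].
#' @return A vectorised function `function(ph, po2, temperature)`.
#' @export
build_binding_surface <- function(gt) {
  stopifnot(inherits(gt, "gt_pigment"))
  force(gt)
  function(ph, po2, temperature = gt$ref_temp) {
    if (any(po2 <= 0)) stop("po2 must be > 0")
    p50t <- gt_p50_at(gt, temperature)
    ph50 <- gt$ph_ref + (log10(po2) - log10(p50t)) / gt$bohr_slope
    cc <- gt_lower_asymptote_at(gt, temperature)
    d <- 1
    b <- gt$steepness
    f <- gt$asymmetry
    e <- ifelse(
      cc < 0.5,
      ph50 + log(((d - cc) / (0.5 - cc))^(1 / f) - 1) / b,
      ph50
    )
    cc + (d - cc) / (1 + exp(b * (e - ph)))^f
  }
}
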