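#' Calibration model for one chamber trace
#'
#' Bundles the quantities needed to turn raw 347 nm absorbance into
#' fractional pigment saturation: the maximum oxygenation signal at t = 0 and
#' its linear drift, the minimum oxygenation signal with its relative
#' uncertainty, and the constant offset taking raw pH to the free hydrogen
#' ion scale.
#'
#' @param amax0 Maximum oxygenation signal at t = 0, AU.
#' @param amax_drift Linear drift of the maximum signal, AU per hour.
#' @param amin Minimum oxygenation signal, AU.
#' @param amin_rel_uncertainty Relative uncertainty of `amin` (default 0.05,
#'   i.e. a 5 percent band).
#' @param ph_offset pH units subtracted from the raw reading to reach the
#'   free scale (default 0.136). Values outside \[0.10, 0.20\] are rejected
#'   unless `check_offset = FALSE`.
#' @param source Either `"measured"` (from the nitrogen calibration phase)
#'   or `"predicted"` (from a reference-wavelength regression).
#' @param check_offset Set `FALSE` to allow unusual pH offsets.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(amax0, amax_drift = 0, amin,
                              amin_rel_uncertainty = 0.05,
                              ph_offset = 0.136,
                              source = c("measured", "predicted"),
                              check_offset = TRUE) {
  source <- match.arg(source)
  stop_if_not_scalar(amax0, "amax0")
  stop_if_not_scalar(amax_drift, "amax_drift")
  stop_if_not_scalar(amin, "amin")
  if (amax0 <= amin) stop("amax0 must exceed amin")
  if (amin_rel_uncertainty < 0 || amin_rel_uncertainty >= 1) {
    stop("amin_rel_uncertainty must lie in [0, 1)")
  }
  if (check_offset && (ph_offset < 0.10 || ph_offset > 0.20)) {
    stop("ph_offset outside [0.10, 0.20]; use check_offset = FALSE to force")
  }
  structure(
    list(amax0 = amax0, amax_drift = amax_drift, amin = amin,
         amin_rel_uncertainty = amin_rel_uncertainty,
         ph_offset = ph_offset, source = source),
    class = "calibration_model"
  )
}

#' Estimate the maximum oxygenation signal and its drift
#'
#' Least-squares line through the pure-oxygen calibration absorbances versus
#' time. With a single calibration time point the drift is set to zero with
#' a warning.
#'
#' @param trace A `chamber_trace`.
#' @return A list with `amax0` (AU at t = 0) and `amax_drift` (AU per hour).
#' @export
calibrate_max_signal <- function(trace) {
  o2 <- trace[trace$segment == "o2_cal", , drop = FALSE]
  if (nrow(o2) == 0) stop("trace has no o2_cal segment")
  if (length(unique(o2$time_s)) == 1) {
    warning("single-time-point oxygen calibration: drift set to 0")
    return(list(amax0 = mean(o2$a347), amax_drift = 0))
  }
  fit <- lm(a347 ~ I(time_s / 3600), data = o2)
  list(amax0 = unname(coef(fit)[1]), amax_drift = unname(coef(fit)[2]))
}

#' Measure the minimum oxygenation signal from the nitrogen phase
#'
#' Median absorbance over the pure-nitrogen calibration rows. Only valid
#' when the pigment deoxygenates completely under nitrogen; in the cold,
#' residual oxygenation biases this estimate upwards and
#' [predict_min_signal()] should be used instead.
#'
#' @param trace A `chamber_trace`.
#' @return A list with `amin`, `band` (equal bounds) and `source`.
#' @export
measure_min_signal <- function(trace) {
  n2 <- trace[trace$segment == "n2_cal", , drop = FALSE]
  if (nrow(n2) == 0) stop("trace has no n2_cal segment")
  amin <- median(n2$a347)
  list(amin = amin, band = c(amin, amin), source = "measured")
}

#' Predict the minimum oxygenation signal from a reference wavelength
#'
#' Applies a linear regression model (intercept, slope) to the
#' reference-wavelength absorbance of the first recorded spectrum, with a
#' 5 percent uncertainty band. This is the route for experiments in which
#' the pigment does not deoxygenate fully under nitrogen.
#'
#' @param ref_value Reference-wavelength absorbance, AU.
#' @param model Numeric `c(intercept, slope)` of the calibration regression.
#' @param uncertainty Relative half-width of the band (default 0.05).
#' @param observed_min Optional minimum ramp absorbance; a warning is issued
#'   if the prediction is at or above it (implying negative saturations).
#' @return A list with `amin`, `band` and `source = "predicted"`.
#' @export
predict_min_signal <- function(ref_value, model, uncertainty = 0.05,
                               observed_min = NULL) {
  if (length(model) != 2 || any(!is.finite(model))) {
    stop("model must be finite c(intercept, slope)")
  }
  amin <- unname(model[1] + model[2] * ref_value)
  if (!is.null(observed_min) && amin >= observed_min) {
    warning("predicted amin >= observed minimum ramp absorbance; ",
            "saturations may be negative before clipping")
  }
  list(amin = amin, band = amin * c(1 - uncertainty, 1 + uncertainty),
       source = "predicted")
}

#' Fit the reference-wavelength minimum-absorbance model
#'
#' Ordinary least squares of observed minimum absorbances on the
#' reference-wavelength values of fully deoxygenated experiments.
#'
#' @param ref_values Reference-wavelength absorbances, AU.
#' @param amin_values Observed minimum absorbances, AU.
#' @return Numeric `c(intercept, slope)`.
#' @export
fit_min_signal_model <- function(ref_values, amin_values) {
  if (length(ref_values) != length(amin_values) || length(ref_values) < 2) {
    stop("need >= 2 paired (ref, amin) observations")
  }
  unname(coef(lm(amin_values ~ ref_values)))
}

#' Correct raw pH to the free hydrogen ion scale
#'
#' `ph_free(t) = ph_raw(t) - ph_offset - drift_rate * t`, where the constant
#' offset accounts for the high ionic strength of cephalopod haemolymph and
#' the optional linear term for instrumental optode drift.
#'
#' @param ph_raw Raw pH readings.
#' @param ph_offset Scale offset, pH units (default 0.136; values outside
#'   \[0.10, 0.20\] rejected unless `check_offset = FALSE`). An offset of 0
#'   is always allowed (identity).
#' @param drift_rate Instrumental drift, pH per hour.
#' @param time_s Times (s) matching `ph_raw`; required when
#'   `drift_rate != 0`.
#' @param check_offset Set `FALSE` to allow unusual offsets.
#' @return Free-scale pH values.
#' @export
correct_ph <- function(ph_raw, ph_offset = 0.136, drift_rate = 0,
                       time_s = NULL, check_offset = TRUE) {
  if (check_offset && ph_offset != 0 &&
      (ph_offset < 0.10 || ph_offset > 0.20)) {
    stop("ph_offset outside [0.10, 0.20]; use check_offset = FALSE to force")
  }
  drift_term <- 0
  if (drift_rate != 0) {
    if (is.null(time_s)) stop("time_s required when drift_rate != 0")
    drift_term <- drift_rate * time_s / 3600
  }
  ph_raw - ph_offset - drift_term
}

#' Compute the saturation series of a chamber trace
#'
#' For the ramp rows only,
#' `S(t) = (A(t) - amin) / (amax0 + amax_drift * t - amin)`, clipped to
#' \[0, 1\], with pH corrected to the free scale. The relative uncertainty of
#' `amin` is propagated into `saturation_lo`/`saturation_hi` bounds that
#' always contain the point value.
#'
#' @param trace A `chamber_trace`.
#' @param cal A [calibration_model()] valid over the trace duration.
#' @return A `saturation_series` data frame with columns `ph_free`,
#'   `saturation`, `saturation_lo`, `saturation_hi`, `po2_kpa`, `temp_c`,
#'   carrying `po2` and `temperature` attributes.
#' @export
compute_saturation <- function(trace, cal) {
  stopifnot(inherits(cal, "calibration_model"))
  ramp <- trace[trace$segment == "ramp", , drop = FALSE]
  if (nrow(ramp) == 0) stop("trace has no ramp segment")
  sat_with_amin <- function(amin) {
    denom <- cal$amax0 + cal$amax_drift * ramp$time_s / 3600 - amin
    if (any(denom <= 0)) {
      stop("calibration denominator (amax - amin) is non-positive ",
           "within the trace")
    }
    clip01((ramp$a347 - amin) / denom)
  }
  s <- sat_with_amin(cal$amin)
  u <- cal$amin_rel_uncertainty
  s_a <- sat_with_amin(cal$amin * (1 - u))
  s_b <- sat_with_amin(cal$amin * (1 + u))
  out <- data.frame(
    ph_free = correct_ph(ramp$ph_raw, cal$ph_offset),
    saturation = s,
    saturation_lo = pmin(s_a, s_b, s),
    saturation_hi = pmax(s_a, s_b, s),
    po2_kpa = ramp$po2_kpa,
    temp_c = ramp$temp_c
  )
  structure(out, po2 = ramp$po2_kpa[1], temperature = ramp$temp_c[1],
            class = c("saturation_series", "data.frame"))
}

#' Write a saturation series as CSV
#'
#' Columns `ph_free,saturation,po2_kpa,temp_c`.
#'
#' @param series A `saturation_series`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_saturation_series <- function(series, path) {
  write.csv(series[, c("ph_free", "saturation", "po2_kpa", "temp_c")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a saturation series CSV
#'
#' @param path CSV written by [write_saturation_series()].
#' @return A `saturation_series` data frame.
#' @export
read_saturation_series <- function(path) {
  x <- read.csv(path)
  structure(x, po2 = x$po2_kpa[1], temperature = x$temp_c[1],
            class = c("saturation_series", "data.frame"))
}
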