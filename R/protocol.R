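#' Diffusion-chamber protocol
#'
#' Describes one run of the diffusion chamber: a continuously decreasing
#' PCO2/pH ramp recorded at several constant PO2 levels, bracketed by
#' pure-oxygen and pure-nitrogen calibration phases. The pure-oxygen phase is
#' recorded both before and after the ramp so that the linear drift of the
#' maximum oxygenation signal can be estimated; the pure-nitrogen phase
#' closes the run.
#'
#' @param po2_levels Constant PO2 levels (kPa), strictly decreasing.
#' @param ph_range Start and end pH of the ramp (start > end).
#' @param pco2_range PCO2 ramp (kPa), informational.
#' @param temperature Experimental temperature, degC.
#' @param sample_interval Sampling interval, seconds.
#' @param ramp_duration Duration of the pH ramp, seconds. The default of
#'   1800 s at 30 s sampling yields 60 ramp samples per PO2 level.
#' @param cal_segments Named durations (s) of the calibration phases,
#'   `c(o2 = ..., n2 = ...)`. The oxygen duration is used twice (before and
#'   after the ramp).
#' @return An object of class `chamber_protocol`.
#' @export
chamber_protocol <- function(po2_levels = c(21, 13, 4, 1),
                             ph_range = c(8.1, 6.4),
                             pco2_range = c(0, 10),
                             temperature = 10,
                             sample_interval = 30,
                             ramp_duration = 1800,
                             cal_segments = c(o2 = 300, n2 = 300)) {
  if (any(po2_levels <= 0)) stop("po2_levels must be positive")
  if (length(po2_levels) > 1 && any(diff(po2_levels) >= 0)) {
    stop("po2_levels must be strictly decreasing")
  }
  stop_if_not_scalar(sample_interval, "sample_interval", positive = TRUE)
  stop_if_not_scalar(ramp_duration, "ramp_duration", positive = TRUE)
  if (length(ph_range) != 2 || ph_range[1] <= ph_range[2]) {
    stop("ph_range must be c(start, end) with start > end")
  }
  if (!all(c("o2", "n2") %in% names(cal_segments))) {
    stop("cal_segments must have elements named 'o2' and 'n2'")
  }
  if (any(cal_segments <= 0)) stop("cal_segments durations must be > 0")
  structure(
    list(po2_levels = po2_levels, ph_range = ph_range,
         pco2_range = pco2_range, temperature = temperature,
         sample_interval = sample_interval, ramp_duration = ramp_duration,
         cal_segments = cal_segments),
    class = "chamber_protocol"
  )
}

#' Measurement noise and instrument-artefact model
#'
#' Gaussian i.i.d. noise on absorbance and raw pH, a signed linear drift of
#' the maximum oxygenation signal, and the constant offset between the raw
#' (NIST-calibrated) pH reading and the free hydrogen ion scale of
#' high-ionic-strength haemolymph.
#'
#' @param abs_sd Absorbance noise sd, AU.
#' @param ph_sd pH noise sd.
#' @param max_drift_rate Linear drift of the maximum oxygenation signal,
#'   AU per hour (signed).
#' @param ph_scale_offset Constant added to true free-scale pH to produce
#'   the raw reading (default +0.136).
#' @param seed Integer seed; identical seed and inputs give bit-identical
#'   output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(abs_sd = 0.005,
                        ph_sd = 0.01,
                        max_drift_rate = -0.02,
                        ph_scale_offset = 0.136,
                        seed = 1L) {
  stop_if_not_scalar(abs_sd, "abs_sd")
  stop_if_not_scalar(ph_sd, "ph_sd")
  if (abs_sd < 0 || ph_sd < 0) stop("noise sds must be >= 0")
  stop_if_not_scalar(max_drift_rate, "max_drift_rate")
  stop_if_not_scalar(ph_scale_offset, "ph_scale_offset")
  stop_if_not_scalar(seed, "seed")
  structure(
    list(abs_sd = abs_sd, ph_sd = ph_sd, max_drift_rate = max_drift_rate,
         ph_scale_offset = ph_scale_offset, seed = as.integer(seed)),
    class = "noise_model"
  )
}
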