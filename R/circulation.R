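# Circulatory supply-demand model: metabolic oxygen demand (allometric and
# Q10 scaled) against haemolymph oxygen delivery per circulation pass.

#' Allometric mass-specific metabolic rate
#'
#' Power-law scaling of octopod oxygen consumption,
#' `MO2 = a * mass^b` with mass in grams (default a = 3.35, b = -0.27),
#' in mmol O2 per kg wet mass per hour at the scaling function's reference
#' temperature.
#'
#' @param mass Body mass, g (> 0).
#' @param a Scaling coefficient.
#' @param b Scaling exponent.
#' @return mmol O2 kg-1 h-1.
#' @export
mo2_allometric <- function(mass, a = 3.35, b = -0.27) {
  if (any(mass <= 0)) stop("mass must be > 0")
  a * mass^b
}

#' Q10 temperature adjustment of a rate
#'
#' `rate * q10^((t_to - t_from) / 10)`.
#'
#' @param rate Rate at `t_from`.
#' @param t_from,t_to Temperatures, degC.
#' @param q10 Temperature coefficient (> 0; default 2.12, an average for
#'   octopods).
#' @return Adjusted rate.
#' @export
q10_adjust <- function(rate, t_from, t_to, q10 = 2.12) {
  if (any(q10 <= 0)) stop("q10 must be > 0")
  rate * q10^((t_to - t_from) / 10)
}

#' Required blood-volume turnover to meet oxygen demand
#'
#' The haemolymph flow needed per kg body mass is demand over delivery per
#' litre; dividing by the mass-specific blood volume gives the number of
#' whole-blood-volume turnovers per hour (and per second).
#'
#' @param mo2 Metabolic demand, mmol O2 kg-1 h-1 (> 0).
#' @param delivered_per_l Oxygen delivered per litre haemolymph per pass,
#'   mmol O2 L-1 (> 0).
#' @param blood_volume_frac Blood volume as L per kg wet mass (default
#'   0.052, i.e. 5.2 percent v/w).
#' @return A list with `flow_l_kg_h`, `turnover_per_h`, `turnover_per_s`.
#' @export
required_turnover <- function(mo2, delivered_per_l,
                              blood_volume_frac = 0.052) {
  stop_if_not_scalar(mo2, "mo2", positive = TRUE)
  stop_if_not_scalar(delivered_per_l, "delivered_per_l", positive = TRUE)
  if (blood_volume_frac <= 0 || blood_volume_frac >= 0.2) {
    stop("blood_volume_frac must lie in (0, 0.2)")
  }
  flow <- mo2 / delivered_per_l
  turnover_h <- flow / blood_volume_frac
  list(flow_l_kg_h = flow, turnover_per_h = turnover_h,
       turnover_per_s = turnover_h / 3600)
}

#' Required increase in circulation between two states
#'
#' Percent change of the required haemolymph flow from a low- to a
#' high-demand state, (i) if oxygen delivery per litre stayed constant
#' (`(mo2_high / mo2_low - 1) * 100`) and (ii) with the measured deliveries
#' at each state (`((mo2_high / delivered_high) / (mo2_low / delivered_low)
#' - 1) * 100`).
#'
#' @param mo2_low,mo2_high Metabolic demand in each state, mmol O2 kg-1 h-1.
#' @param delivered_low,delivered_high Oxygen delivered per litre in each
#'   state, mmol O2 L-1; omit for the constant-supply number only.
#' @return A list with `constant_supply_pct` and `measured_supply_pct`
#'   (the latter `NA` when deliveries are not supplied).
#' @export
circulation_increase <- function(mo2_low, mo2_high,
                                 delivered_low = NULL,
                                 delivered_high = NULL) {
  stop_if_not_scalar(mo2_low, "mo2_low", positive = TRUE)
  stop_if_not_scalar(mo2_high, "mo2_high", positive = TRUE)
  constant <- (mo2_high / mo2_low - 1) * 100
  measured <- NA_real_
  if (!is.null(delivered_low) && !is.null(delivered_high)) {
    stop_if_not_scalar(delivered_low, "delivered_low", positive = TRUE)
    stop_if_not_scalar(delivered_high, "delivered_high", positive = TRUE)
    measured <- ((mo2_high / delivered_high) /
                   (mo2_low / delivered_low) - 1) * 100
  }
  list(constant_supply_pct = constant, measured_supply_pct = measured)
}
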