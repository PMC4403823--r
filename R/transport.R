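# In-vivo projection: alpha-stat pH, seawater oxygen solubility, dissolved
# and haemocyanin-bound oxygen budgets, haemocyanin concentration.

#' Alpha-stat model of haemolymph pH
#'
#' Linear decrease of extracellular pH with temperature, as expected for an
#' imidazole-buffered system. Defaults: slope -0.0153 pH per degC anchored
#' at pH 7.42 at 0 degC (equivalently about 7.27 at 10 degC).
#'
#' @param slope pH units per degC (< 0).
#' @param anchor_ph Venous pH at `anchor_temp`.
#' @param anchor_temp Anchor temperature, degC.
#' @return An object of class `alpha_stat_model`.
#' @export
alpha_stat_model <- function(slope = -0.0153, anchor_ph = 7.42,
                             anchor_temp = 0) {
  stop_if_not_scalar(slope, "slope")
  if (slope >= 0) stop("alpha-stat slope must be negative")
  stop_if_not_scalar(anchor_ph, "anchor_ph")
  stop_if_not_scalar(anchor_temp, "anchor_temp")
  structure(list(slope = slope, anchor_ph = anchor_ph,
                 anchor_temp = anchor_temp),
            class = "alpha_stat_model")
}

#' Alpha-stat venous pH at a temperature
#'
#' @param model An [alpha_stat_model()].
#' @param temperature degC, within \[-2, 30\].
#' @return Venous pH.
#' @export
venous_ph <- function(model = alpha_stat_model(), temperature) {
  stopifnot(inherits(model, "alpha_stat_model"))
  if (any(temperature < -2 | temperature > 30)) {
    stop("temperature outside the supported range [-2, 30] degC")
  }
  model$anchor_ph + model$slope * (temperature - model$anchor_temp)
}

#' Arterial pH from venous pH
#'
#' Arterial haemolymph is assumed a constant offset more alkaline than
#' venous (default +0.11 pH units).
#'
#' @param venous_ph Venous pH.
#' @param offset pH units added.
#' @return Arterial pH.
#' @export
arterial_ph <- function(venous_ph, offset = 0.11) {
  venous_ph + offset
}

# Surface seawater density (kg/L) from the EOS-80 one-atmosphere equation
# of state (UNESCO 1983 polynomial).
sw_density <- function(temperature, salinity) {
  t <- temperature; s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  c0 <- 4.8314e-4
  (rho_w + a * s + b * s^1.5 + c0 * s^2) / 1000
}

# Garcia-Gordon combined fit to the Benson-Krause oxygen solubility data,
# micromol per kg at air saturation.
gg_o2_umol_kg <- function(temperature, salinity) {
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  c0 <- -2.75915e-7
  lnc <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity^2
  exp(lnc)
}

#' Air-saturated oxygen concentration of seawater
#'
#' Oxygen solubility from the Garcia--Gordon combined fit to the
#' Benson--Krause data (micromol per kg), converted to micromol per litre
#' with the EOS-80 surface seawater density. At 0 degC and 35 psu this is
#' about 359 micromol per litre.
#'
#' @param temperature degC, within \[-2, 40\].
#' @param salinity psu, within \[0, 42\].
#' @return Micromol O2 per litre at air saturation.
#' @export
o2_solubility <- function(temperature, salinity = 35) {
  if (any(temperature < -2 | temperature > 40)) {
    stop("temperature outside [-2, 40] degC")
  }
  if (any(salinity < 0 | salinity > 42)) {
    stop("salinity outside [0, 42] psu")
  }
  gg_o2_umol_kg(temperature, salinity) * sw_density(temperature, salinity)
}

#' Dissolved oxygen at a partial pressure
#'
#' Henry-law scaling of the air-saturated value:
#' `o2_solubility(T, S) * po2 / air_po2`.
#'
#' @param po2 Oxygen partial pressure, kPa (0 to 1.1 x `air_po2`).
#' @param temperature degC.
#' @param salinity psu.
#' @param air_po2 PO2 of air-saturated water, kPa (default 21).
#' @return Micromol O2 per litre.
#' @export
dissolved_o2 <- function(po2, temperature, salinity = 35, air_po2 = 21) {
  if (any(po2 < 0)) stop("po2 must be >= 0")
  if (any(po2 > air_po2 * 1.1)) stop("po2 above 1.1 x air_po2")
  o2_solubility(temperature, salinity) * po2 / air_po2
}

#' In-vivo arterial/venous conditions
#'
#' @param temperature degC.
#' @param arterial_po2 kPa (default 13).
#' @param venous_po2 kPa (default 4 for a resting octopus; 1 exercised).
#' @param salinity psu (default 35).
#' @param venous_ph Venous pH; if `NULL`, derived from `alpha_stat` at
#'   `temperature`.
#' @param arterial_ph_offset pH units by which arterial exceeds venous pH.
#' @param air_po2 kPa of air-saturated water.
#' @param alpha_stat An [alpha_stat_model()] used when `venous_ph` is
#'   `NULL`.
#' @return An object of class `in_vivo_conditions`.
#' @export
in_vivo_conditions <- function(temperature,
                               arterial_po2 = 13,
                               venous_po2 = 4,
                               salinity = 35,
                               venous_ph = NULL,
                               arterial_ph_offset = 0.11,
                               air_po2 = 21,
                               alpha_stat = alpha_stat_model()) {
  if (arterial_po2 <= venous_po2 || venous_po2 <= 0) {
    stop("need arterial_po2 > venous_po2 > 0")
  }
  if (salinity <= 0 || salinity > 45) stop("salinity outside (0, 45]")
  if (is.null(venous_ph)) {
    venous_ph <- venous_ph(alpha_stat, temperature)
  }
  structure(
    list(temperature = temperature, arterial_po2 = arterial_po2,
         venous_po2 = venous_po2, salinity = salinity,
         venous_ph = venous_ph,
         arterial_ph_offset = arterial_ph_offset, air_po2 = air_po2),
    class = "in_vivo_conditions"
  )
}

#' Saturation at arbitrary pH and PO2 from fitted curves
#'
#' Evaluates each fixed-PO2 curve at `ph` (clipped to \[0, 1\]) and linearly
#' interpolates across log10(PO2) to the target `po2`. No extrapolation
#' beyond the fitted PO2 range.
#'
#' @param curves List of `ph_o2_curve` objects at one temperature.
#' @param ph Free-scale pH.
#' @param po2 Target PO2, kPa, within the fitted range.
#' @return Saturation fraction.
#' @export
saturation_at <- function(curves, ph, po2) {
  po2s <- vapply(curves, function(cv) cv$po2, numeric(1))
  if (po2 < min(po2s) - 1e-9 || po2 > max(po2s) + 1e-9) {
    stop(sprintf("po2 %g kPa outside the fitted range [%g, %g]",
                 po2, min(po2s), max(po2s)))
  }
  s <- clip01(vapply(curves, function(cv)
    fivepl_eval(cv$params, ph), numeric(1)))
  if (length(curves) == 1) return(s)
  ord <- order(po2s)
  approx(log10(po2s[ord]), s[ord], xout = log10(po2))$y
}

#' Oxygen transport budget per litre of haemolymph
#'
#' Arterial and venous saturations under the stated in-vivo conditions, the
#' haemocyanin-bound oxygen released over the arterial-venous transition,
#' and the dissolved-oxygen terms. `dissolved_fraction_of_total` follows the
#' convention of relating the air-saturated dissolved concentration to the
#' full carrying capacity, `sol / (sol + capacity)`.
#'
#' @param curves List of `ph_o2_curve` objects at the condition temperature.
#' @param capacity Oxygen carrying capacity, mmol O2 L-1 (> 0).
#' @param cond An [in_vivo_conditions()].
#' @return An object of class `transport_budget`; all concentrations in
#'   mmol O2 per litre haemolymph.
#' @export
transport_budget <- function(curves, capacity, cond) {
  stopifnot(inherits(cond, "in_vivo_conditions"))
  stop_if_not_scalar(capacity, "capacity", positive = TRUE)
  ph_v <- cond$venous_ph
  ph_a <- arterial_ph(ph_v, cond$arterial_ph_offset)
  s_a <- saturation_at(curves, ph_a, cond$arterial_po2)
  s_v <- saturation_at(curves, ph_v, cond$venous_po2)
  if (s_a <= 0) stop("arterial saturation is zero; budget undefined")
  sol <- o2_solubility(cond$temperature, cond$salinity) / 1000
  d_a <- dissolved_o2(cond$arterial_po2, cond$temperature, cond$salinity,
                      cond$air_po2) / 1000
  d_v <- dissolved_o2(cond$venous_po2, cond$temperature, cond$salinity,
                      cond$air_po2) / 1000
  bound_release <- capacity * (s_a - s_v)
  dissolved_release <- d_a - d_v
  total_content <- capacity * s_a + d_a
  total_release <- bound_release + dissolved_release
  structure(
    list(s_arterial = s_a, s_venous = s_v,
         arterial_ph = ph_a, venous_ph = ph_v,
         bound_release_frac = (s_a - s_v) / s_a,
         bound_release = bound_release,
         dissolved_arterial = d_a, dissolved_venous = d_v,
         dissolved_release = dissolved_release,
         total_content = total_content,
         total_release = total_release,
         dissolved_fraction_of_total = sol / (sol + capacity),
         dissolved_fraction_of_release =
           if (total_release > 0) dissolved_release / total_release
           else NA_real_,
         conditions = cond, capacity = capacity),
    class = "transport_budget"
  )
}

#' @export
print.transport_budget <- function(x, ...) {
  cond <- x$conditions
  cat(sprintf(
    "Transport budget at %g degC (PO2 %g -> %g kPa, pH %.2f -> %.2f)\n",
    cond$temperature, cond$arterial_po2, cond$venous_po2,
    x$arterial_ph, x$venous_ph))
  cat(sprintf("  saturation        : arterial %.3f, venous %.3f\n",
              x$s_arterial, x$s_venous))
  cat(sprintf("  bound O2 released : %.3f mmol/L (%.1f%% of bound)\n",
              x$bound_release, 100 * x$bound_release_frac))
  cat(sprintf("  dissolved released: %.3f mmol/L\n", x$dissolved_release))
  cat(sprintf("  total released    : %.3f mmol/L (%.1f%% dissolved)\n",
              x$total_release, 100 * x$dissolved_fraction_of_release))
  cat(sprintf("  dissolved share of total content: %.1f%%\n",
              100 * x$dissolved_fraction_of_total))
  invisible(x)
}

#' Haemocyanin concentration from oxygen carrying capacity
#'
#' `c(Hc) = (capacity / binding_sites) * MW`, with capacity in mol O2 per
#' litre; for octopod haemocyanin 70 oxygen binding sites and a molecular
#' weight of 3.5 MDa. The result in g per litre equals mg per ml.
#'
#' @param capacity Oxygen carrying capacity, mmol O2 L-1 (>= 0).
#' @param binding_sites Oxygen binding sites per molecule (default 70).
#' @param mw Molecular weight, g per mol (default 3.5e6).
#' @return Haemocyanin concentration, g L-1.
#' @export
hc_concentration <- function(capacity, binding_sites = 70, mw = 3.5e6) {
  if (any(capacity < 0)) stop("capacity must be >= 0")
  if (binding_sites <= 0) stop("binding_sites must be > 0")
  (capacity / 1000) / binding_sites * mw
}
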