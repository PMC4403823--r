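#' Simulate a set of diffusion-chamber experiments
#'
#' Generates one chamber trace per constant PO2 level of the protocol. Each
#' trace starts with a pure-oxygen calibration phase (saturation 1), runs the
#' linear pH ramp, repeats the oxygen calibration (so the linear drift of the
#' maximum signal is observable), and ends with a pure-nitrogen phase in
#' which the pigment settles to its residual low-pH saturation (which is > 0
#' for cold-incomplete deoxygenation).
#'
#' True absorbance is `amin + S * (amax0 + drift * t - amin)`; the recorded
#' absorbance and raw pH add i.i.d. Gaussian noise, and the raw pH carries
#' the constant scale offset of the noise model. Each trace records, as
#' attributes, its PO2, temperature, the reference-wavelength scalar of the
#' first spectrum (`ref_a347`, constructed equal to the true minimum
#' absorbance), and a `truth` list with the noise-free quantities for
#' round-trip testing.
#'
#' @param gt A [ground_truth_pigment()].
#' @param protocol A [chamber_protocol()].
#' @param noise A [noise_model()].
#' @param amax0 Maximum oxygenation signal at t = 0, AU.
#' @param amin True minimum oxygenation signal, AU.
#' @return An object of class `chamber_run`: a named list of `chamber_trace`
#'   data frames (`time_s`, `a347`, `ph_raw`, `po2_kpa`, `temp_c`,
#'   `segment`), one per PO2 level.
#' @export
simulate_chamber_experiment <- function(gt,
                                        protocol = chamber_protocol(),
                                        noise = noise_model(),
                                        amax0 = 1.0,
                                        amin = 0.1) {
  stopifnot(inherits(gt, "gt_pigment"), inherits(protocol, "chamber_protocol"),
            inherits(noise, "noise_model"))
  if (amax0 <= amin) stop("amax0 must exceed amin")
  surface <- build_binding_surface(gt)
  tC <- protocol$temperature
  la <- gt_lower_asymptote_at(gt, tC)
  d_o2 <- unname(protocol$cal_segments["o2"])
  d_n2 <- unname(protocol$cal_segments["n2"])
  d_ramp <- protocol$ramp_duration
  total <- 2 * d_o2 + d_ramp + d_n2
  time <- seq(0, total, by = protocol$sample_interval)
  segment <- rep("n2_cal", length(time))
  segment[time < d_o2] <- "o2_cal"
  in_ramp <- time >= d_o2 & time < d_o2 + d_ramp
  segment[in_ramp] <- "ramp"
  segment[time >= d_o2 + d_ramp & time < 2 * d_o2 + d_ramp] <- "o2_cal"

  ph_true <- rep(protocol$ph_range[2], length(time))
  ph_true[segment == "o2_cal" & time < d_o2] <- protocol$ph_range[1]
  ph_true[in_ramp] <- protocol$ph_range[1] +
    (protocol$ph_range[2] - protocol$ph_range[1]) *
      (time[in_ramp] - d_o2) / d_ramp

  traces <- withr::with_seed(noise$seed, {
    lapply(protocol$po2_levels, function(po2) {
      s_true <- rep(NA_real_, length(time))
      s_true[segment == "o2_cal"] <- 1
      s_true[segment == "n2_cal"] <- la
      s_true[in_ramp] <- surface(ph_true[in_ramp], po2, tC)
      amax_t <- amax0 + noise$max_drift_rate * time / 3600
      a_true <- amin + s_true * (amax_t - amin)
      a347 <- a_true + rnorm(length(time), sd = noise$abs_sd)
      ph_raw <- ph_true + noise$ph_scale_offset +
        rnorm(length(time), sd = noise$ph_sd)
      tr <- data.frame(time_s = time, a347 = a347, ph_raw = ph_raw,
                       po2_kpa = po2, temp_c = tC, segment = segment,
                       stringsAsFactors = FALSE)
      structure(tr,
                po2 = po2, temperature = tC, ref_a347 = amin,
                truth = list(s = s_true, ph = ph_true, a347 = a_true,
                             amax0 = amax0, amin = amin,
                             drift = noise$max_drift_rate,
                             lower_asymptote = la),
                class = c("chamber_trace", "data.frame"))
    })
  })
  names(traces) <- sprintf("po2_%g", protocol$po2_levels)
  structure(traces, gt = gt, protocol = protocol, noise = noise,
            class = "chamber_run")
}

#' Simulate haemolymph pH measurements across temperature
#'
#' Draws replicated pH observations around a linear alpha-stat
#' pH--temperature relationship, `pH = intercept + slope * T + noise`.
#'
#' @param slope pH units per degC (an alpha-stat pattern has slope < 0;
#'   default -0.0153).
#' @param intercept pH at 0 degC.
#' @param temps Temperatures (degC) at which replicates are drawn; must be
#'   non-empty.
#' @param n_per_temp Number of replicates per temperature (>= 1).
#' @param noise_sd Gaussian pH noise sd. The default 0.072 reproduces an
#'   R-squared of about 0.75 for 11 replicates at each of 0/10/20 degC.
#' @param seed Integer seed.
#' @return A data frame with columns `temperature` and `ph`.
#' @export
simulate_alpha_stat_series <- function(slope = -0.0153,
                                       intercept = 7.42,
                                       temps = c(0, 10, 20),
                                       n_per_temp = 11,
                                       noise_sd = 0.072,
                                       seed = 1L) {
  if (length(temps) < 1) stop("temps must be non-empty")
  if (n_per_temp < 1) stop("n_per_temp must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  temperature <- rep(temps, each = n_per_temp)
  ph <- withr::with_seed(seed, {
    intercept + slope * temperature +
      rnorm(length(temperature), sd = noise_sd)
  })
  data.frame(temperature = temperature, ph = ph)
}

#' Simulate a cyanide-respirometry trace
#'
#' Emulates the oxygen-carrying-capacity assay: a respirometer chamber with a
#' slow linear background oxygen flux into which a small haemolymph (or
#' seawater control) sample is injected, producing a step change in chamber
#' oxygen concentration of `capacity * sample_vol / chamber_vol`.
#'
#' @param capacity Oxygen carrying capacity of the injected sample, mmol O2
#'   per litre (use the dissolved O2 content for a seawater control).
#' @param sample_vol Injected volume, microlitres.
#' @param chamber_vol Chamber volume, millilitres; must exceed the sample
#'   volume.
#' @param background_flux Linear background flux, micromol L-1 h-1.
#' @param noise_sd Concentration noise sd, micromol L-1.
#' @param seed Integer seed.
#' @param c0 Initial chamber O2 concentration, micromol L-1.
#' @param duration Trace duration, s.
#' @param injection_time Time of injection, s.
#' @param interval Sampling interval, s.
#' @return A data frame (`time_s`, `o2_umol_l`) with attributes
#'   `injection_time` and `step_true` (micromol L-1).
#' @export
simulate_respirometry <- function(capacity,
                                  sample_vol = 10,
                                  chamber_vol = 2,
                                  background_flux = 0,
                                  noise_sd = 0.05,
                                  seed = 1L,
                                  c0 = 250,
                                  duration = 1200,
                                  injection_time = 600,
                                  interval = 5) {
  stop_if_not_scalar(sample_vol, "sample_vol", positive = TRUE)
  stop_if_not_scalar(chamber_vol, "chamber_vol", positive = TRUE)
  if (capacity < 0) stop("capacity must be >= 0")
  if (sample_vol / 1000 >= chamber_vol) {
    stop("sample volume must be small relative to the chamber volume")
  }
  step <- capacity * 1000 * (sample_vol / 1000) / chamber_vol
  time <- seq(0, duration, by = interval)
  conc <- withr::with_seed(seed, {
    c0 + background_flux * time / 3600 + step * (time > injection_time) +
      rnorm(length(time), sd = noise_sd)
  })
  structure(data.frame(time_s = time, o2_umol_l = conc),
            injection_time = injection_time, step_true = step)
}

#' Write a chamber run to CSV files plus a JSON manifest
#'
#' One CSV per PO2 level with header
#' `time_s,a347,ph_raw,po2_kpa,temp_c,segment`, plus `manifest.json`
#' recording the ground-truth parameters, protocol and seed. Output is
#' byte-identical for identical inputs and seed.
#'
#' @param run A `chamber_run` from [simulate_chamber_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_chamber_traces <- function(run, dir) {
  stopifnot(inherits(run, "chamber_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(run, function(tr) {
    path <- file.path(dir, sprintf("trace_po2_%gkPa.csv", attr(tr, "po2")))
    write.csv(as.data.frame(tr), path, row.names = FALSE, quote = FALSE)
    path
  }, character(1))
  manifest <- list(
    ground_truth = unclass(attr(run, "gt")),
    protocol = unclass(attr(run, "protocol")),
    noise = unclass(attr(run, "noise"))
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mpath))
}

#' Read chamber traces written by [write_chamber_traces()]
#'
#' @param dir Directory containing `trace_po2_*kPa.csv` files.
#' @return A list of `chamber_trace` data frames, ordered by decreasing PO2.
#' @export
read_chamber_traces <- function(dir) {
  files <- list.files(dir, pattern = "^trace_po2_.*kPa\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no trace CSVs found in ", dir)
  traces <- lapply(files, function(f) {
    tr <- read.csv(f, stringsAsFactors = FALSE)
    structure(tr, po2 = tr$po2_kpa[1], temperature = tr$temp_c[1],
              class = c("chamber_trace", "data.frame"))
  })
  ord <- order(vapply(traces, attr, numeric(1), "po2"), decreasing = TRUE)
  traces <- traces[ord]
  names(traces) <- vapply(traces, function(tr)
    sprintf("po2_%g", attr(tr, "po2")), character(1))
  traces
}
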