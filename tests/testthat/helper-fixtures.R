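# Shared fixtures built in code.

# Antarctic-like default pigment (P50 2.34 kPa at pH 7.27, Bohr -1.22,
# capacity 1.58 mmol O2/L) unless overridden.
make_pigment <- function(...) {
  ground_truth_pigment(...)
}

noiseless <- function(seed = 1L, drift = 0) {
  noise_model(abs_sd = 0, ph_sd = 0, max_drift_rate = drift, seed = seed)
}

# Saturation series sampled directly from a binding surface on a pH grid
# (bypasses the chamber; exact model-class data for fitting tests).
surface_series <- function(gt, po2, temperature = gt$ref_temp,
                           ph = seq(6.0, 8.2, length.out = 60)) {
  S <- build_binding_surface(gt)
  structure(
    data.frame(ph_free = ph, saturation = S(ph, po2, temperature),
               po2_kpa = po2, temp_c = temperature),
    po2 = po2, temperature = temperature,
    class = c("saturation_series", "data.frame"))
}

# Saturation series from explicit 5PL parameters, optionally noisy.
fivepl_series <- function(p, po2 = 4, temperature = 10,
                          ph = seq(6.0, 8.2, length.out = 60),
                          noise_sd = 0, seed = 1L) {
  sat <- fivepl_eval(p, ph)
  if (noise_sd > 0) {
    sat <- withr::with_seed(seed, sat + rnorm(length(ph), sd = noise_sd))
  }
  structure(
    data.frame(ph_free = ph, saturation = sat, po2_kpa = po2,
               temp_c = temperature),
    po2 = po2, temperature = temperature,
    class = c("saturation_series", "data.frame"))
}

# Random valid 5PL parameter draws for oracle-equivalence sweeps.
random_fivepl <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      fivepl(b = runif(1, 1, 10), c = runif(1, 0, 0.4),
             d = runif(1, 0.8, 1.05), e = runif(1, 6.6, 7.8),
             f = runif(1, 0.3, 3))
    })
  })
}

# Dense-grid brute-force oracles, independent of the root-finder and
# optimiser used by the package. The wide pH window covers even extreme
# asymmetric curves whose half-saturation sits far from the anchor.
grid_ph50 <- function(p, lo = -2, hi = 14, n = 640001) {
  ph <- seq(lo, hi, length.out = n)
  s <- fivepl_eval(p, ph)
  ph[which.min(abs(s - 0.5))]
}

grid_max_slope <- function(p, lo = -2, hi = 14, n = 640001) {
  ph <- seq(lo, hi, length.out = n)
  s <- fivepl_eval(p, ph)
  max(diff(s) / diff(ph))
}
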