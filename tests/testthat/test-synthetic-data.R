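# Ground-truth surface and simulators.

test_that("binding surface is half-saturated on the Bohr line", {
  gt <- make_pigment(asymmetry = 1, lower_asymptote = 0)
  S <- build_binding_surface(gt)
  for (po2 in c(21, 13, 4, 1, 2.34)) {
    ph50 <- gt$ph_ref + (log10(po2) - log10(gt$p50_ref)) / gt$bohr_slope
    expect_equal(S(ph50, po2, gt$ref_temp), 0.5, tolerance = 1e-12)
  }
  # also exact for asymmetric curves with a non-zero floor
  gt2 <- make_pigment(asymmetry = 2.5, lower_asymptote = 0.2)
  S2 <- build_binding_surface(gt2)
  ph50 <- gt2$ph_ref + (log10(4) - log10(gt2$p50_ref)) / gt2$bohr_slope
  expect_equal(S2(ph50, 4, gt2$ref_temp), 0.5, tolerance = 1e-12)
})

test_that("doubling PO2 shifts pH50 by -log10(2) per unit Bohr slope", {
  gt <- make_pigment(bohr_slope = -1)
  S <- build_binding_surface(gt)
  ph50_at <- function(po2) {
    uniroot(function(ph) S(ph, po2, gt$ref_temp) - 0.5, c(4, 10),
            tol = 1e-12)$root
  }
  expect_equal(ph50_at(2 * gt$p50_ref) - ph50_at(gt$p50_ref),
               -log10(2), tolerance = 1e-8)
})

test_that("the lower asymptote is the saturation floor", {
  gt <- make_pigment(lower_asymptote = 0.336)
  S <- build_binding_surface(gt)
  expect_equal(min(S(seq(3, 9, by = 0.01), 1, gt$ref_temp)), 0.336,
               tolerance = 1e-4)
})

test_that("surface is monotone in pH and PO2 on a 100 x 4 grid", {
  gt <- make_pigment(asymmetry = 1.7, lower_asymptote = 0.1,
                     lower_asymptote_slope = -0.01)
  S <- build_binding_surface(gt)
  ph <- seq(5.5, 8.5, length.out = 100)
  po2 <- c(1, 4, 13, 21)
  for (tC in c(0, 10)) {
    grid <- sapply(po2, function(p) S(ph, p, tC))
    expect_true(all(grid >= 0 & grid <= 1))
    expect_true(all(apply(grid, 2, function(col) all(diff(col) >= 0))))
    expect_true(all(apply(grid, 1, function(row) all(diff(row) >= 0))))
  }
})

test_that("zero bohr_slope is rejected", {
  expect_error(ground_truth_pigment(bohr_slope = 0), "non-zero")
})

test_that("chamber simulation round-trips saturation exactly at zero noise", {
  gt <- make_pigment()
  run <- simulate_chamber_experiment(gt, chamber_protocol(), noiseless())
  for (tr in run) {
    truth <- attr(tr, "truth")
    cal <- calibration_model(amax0 = truth$amax0, amax_drift = 0,
                             amin = truth$amin)
    ss <- compute_saturation(tr, cal)
    expect_lt(max(abs(ss$saturation - truth$s[tr$segment == "ramp"])), 1e-12)
  }
})

test_that("drifting maximum signal is exact during oxygen calibration", {
  r <- 0.05 # AU per hour
  run <- simulate_chamber_experiment(make_pigment(), chamber_protocol(),
                                     noiseless(drift = r), amax0 = 1.0)
  tr <- run[[1]]
  o2 <- tr[tr$segment == "o2_cal", ]
  expect_equal(o2$a347, 1.0 + r * o2$time_s / 3600, tolerance = 1e-14)
})

test_that("chamber traces are seed-deterministic and seed-sensitive", {
  gt <- make_pigment()
  prot <- chamber_protocol()
  a <- simulate_chamber_experiment(gt, prot, noise_model(seed = 7))
  b <- simulate_chamber_experiment(gt, prot, noise_model(seed = 7))
  c3 <- simulate_chamber_experiment(gt, prot, noise_model(seed = 8))
  expect_identical(as.data.frame(a[[1]]), as.data.frame(b[[1]]))
  expect_false(isTRUE(all.equal(a[[1]]$a347, c3[[1]]$a347)))
})

test_that("written trace CSVs are byte-identical under the same seed", {
  gt <- make_pigment()
  run1 <- simulate_chamber_experiment(gt, chamber_protocol(po2_levels = 4),
                                      noise_model(seed = 3))
  run2 <- simulate_chamber_experiment(gt, chamber_protocol(po2_levels = 4),
                                      noise_model(seed = 3))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_chamber_traces(run1, d1)
  write_chamber_traces(run2, d2)
  f <- "trace_po2_4kPa.csv"
  expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                   readBin(file.path(d2, f), "raw", 1e6))
  back <- read_chamber_traces(d1)
  expect_equal(back[[1]]$a347, run1[[1]]$a347)
})

test_that("trace segments cover all rows and time strictly increases", {
  run <- simulate_chamber_experiment(make_pigment(), chamber_protocol(),
                                     noise_model(seed = 2))
  for (tr in run) {
    expect_true(all(tr$segment %in% c("o2_cal", "n2_cal", "ramp")))
    expect_true(all(diff(tr$time_s) > 0))
    expect_true(all(is.finite(tr$a347)))
    ramp_ph <- attr(tr, "truth")$ph[tr$segment == "ramp"]
    expect_true(all(diff(ramp_ph) < 0)) # pre-noise ramp pH decreases
  }
})

test_that("alpha-stat simulator reproduces its slope without noise", {
  d <- simulate_alpha_stat_series(slope = -0.0153, intercept = 7.42,
                                  temps = c(0, 10, 20), n_per_temp = 11,
                                  noise_sd = 0, seed = 1)
  fit <- lm(ph ~ temperature, data = d)
  expect_equal(unname(coef(fit)[2]), -0.0153, tolerance = 1e-12)

  flat <- simulate_alpha_stat_series(slope = 0, intercept = 7.5,
                                     temps = c(0, 5), n_per_temp = 3,
                                     noise_sd = 0, seed = 1)
  expect_true(all(flat$ph == 7.5))
  expect_error(simulate_alpha_stat_series(temps = numeric(0)), "non-empty")
})

test_that("respirometry step equals capacity scaled by volume ratio", {
  tr <- simulate_respirometry(1.58, sample_vol = 10, chamber_vol = 2,
                              noise_sd = 0, seed = 1)
  expect_equal(attr(tr, "step_true"), 7.9, tolerance = 1e-12)
  post <- tr$o2_umol_l[tr$time_s > attr(tr, "injection_time")]
  pre <- tr$o2_umol_l[tr$time_s <= attr(tr, "injection_time")]
  expect_equal(median(post) - median(pre), 7.9, tolerance = 1e-9)

  z <- simulate_respirometry(0, noise_sd = 0, seed = 1)
  expect_equal(attr(z, "step_true"), 0)

  f <- 12 # umol/L/h background flux
  bf <- simulate_respirometry(1, background_flux = f, noise_sd = 0, seed = 1)
  pre <- bf[bf$time_s < attr(bf, "injection_time"), ]
  expect_equal(unname(coef(lm(o2_umol_l ~ I(time_s / 3600), pre))[2]), f,
               tolerance = 1e-9)
  expect_error(simulate_respirometry(1, sample_vol = 3000, chamber_vol = 2),
               "volume")
})
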