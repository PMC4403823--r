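# 5PL fitting and derived binding parameters.

test_that("noiseless 5PL points are recovered to 1e-6 relative", {
  truth <- fivepl(b = 7.2, c = 0.12, d = 0.98, e = 7.1, f = 1.6)
  ss <- fivepl_series(truth, po2 = 4)
  cv <- fit_5pl(ss, n_boot = 0)
  for (nm in c("b", "c", "d", "e", "f")) {
    expect_equal(cv$params[[nm]], truth[[nm]], tolerance = 1e-6)
  }
  expect_error(fit_5pl(fivepl_series(truth, ph = seq(6.5, 7.5, length.out = 5)),
                       n_boot = 0),
               "6 distinct")
})

test_that("half-saturation recovery under noise stays within 0.02 pH", {
  # the anchor e itself is weakly identified jointly with the asymmetry f,
  # so recovery is asserted on the half-saturation pH of the fitted curve
  truth <- fivepl(b = 8, c = 0, d = 1, e = 7.1, f = 1)
  n_rep <- 200
  hits <- 0
  for (i in seq_len(n_rep)) {
    ss <- fivepl_series(truth, noise_sd = 0.02, seed = i)
    cv <- tryCatch(fit_5pl(ss, n_boot = 0), error = function(e) NULL)
    if (!is.null(cv) && abs(ph50(cv) - ph50(truth)) < 0.02) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("bootstrap intervals bracket point estimates, seeded", {
  truth <- fivepl(b = 7, c = 0.05, d = 1, e = 7.2, f = 1)
  ss <- fivepl_series(truth, noise_sd = 0.02, seed = 42)
  cv1 <- fit_5pl(ss, n_boot = 50, seed = 9)
  cv2 <- fit_5pl(ss, n_boot = 50, seed = 9)
  expect_identical(cv1$boot, cv2$boot)
  pt <- unlist(cv1$params)
  expect_true(all(cv1$boot_ci["lo", ] <= pt & pt <= cv1$boot_ci["hi", ]))
})

test_that("ph50 matches the symmetric closed form and the grid oracle", {
  sym <- fivepl(b = 6, c = 0, d = 1, e = 7.3, f = 1)
  expect_equal(ph50(sym), 7.3, tolerance = 1e-8)
  for (p in random_fivepl(50, seed = 21)) {
    if (p$c >= 0.5 || p$d <= 0.5) next
    expect_equal(ph50(p), grid_ph50(p), tolerance = 2e-4)
  }
  expect_error(ph50(fivepl(b = 6, c = 0.6, d = 1, e = 7, f = 1)),
               "undefined")
})

test_that("P50 interpolation is exact for collinear pH50 values", {
  # construct three symmetric curves whose (pH50, log10 PO2) lie on a line
  a <- 9.5; B <- -1.22 # log10 PO2 = a + B * pH
  mk <- function(ph50) {
    structure(list(params = fivepl(b = 7, c = 0, d = 1, e = ph50, f = 1),
                   po2 = 10^(a + B * ph50), temperature = 10,
                   n_points = 60, boot = NULL, boot_ci = NULL, seed = 1L),
              class = "ph_o2_curve")
  }
  curves <- lapply(c(6.6, 7.0, 7.4), mk)
  expect_equal(as.numeric(p50_at_ph(curves, 7.2)), 10^(a + B * 7.2),
               tolerance = 1e-9)
  expect_equal(bohr_coefficient(curves), B, tolerance = 1e-12)
  expect_error(p50_at_ph(curves[1], 7.2), "2 curves")
  same <- lapply(c(7.0, 7.0), mk)
  expect_error(bohr_coefficient(same), "degenerate")
})

test_that("fitting surface samples recovers the Bohr slope exactly", {
  # steep-Bohr pigment (Bohr -1.97, P50 1.63 kPa at pH 7.27)
  gt <- ground_truth_pigment(p50_ref = 1.63, bohr_slope = -1.97)
  curves <- lapply(c(21, 13, 4, 1), function(po2) {
    fit_5pl(surface_series(gt, po2), n_boot = 0)
  })
  expect_equal(bohr_coefficient(curves), -1.97, tolerance = 1e-6)
  p50 <- suppressWarnings(p50_at_ph(curves, 7.27))
  expect_equal(as.numeric(p50), 1.63, tolerance = 1e-4)
})

test_that("end-to-end zero-noise round trip recovers P50 within 1%", {
  gt <- make_pigment() # P50 2.34 kPa at pH 7.27, Bohr -1.22
  run <- simulate_chamber_experiment(gt, chamber_protocol(), noiseless())
  curves <- process_chamber_run(run, n_boot = 0)
  p50 <- suppressWarnings(p50_at_ph(curves, 7.27))
  expect_lt(abs(p50 - 2.34) / 2.34, 0.01)
  expect_lt(abs(bohr_coefficient(curves) + 1.22) / 1.22, 0.01)
})

test_that("estimated P50 increases with ground-truth P50", {
  est <- vapply(c(1.0, 1.6, 2.34, 3.2, 4.5), function(p50_true) {
    gt <- make_pigment(p50_ref = p50_true)
    curves <- lapply(c(21, 13, 4, 1), function(po2) {
      fit_5pl(surface_series(gt, po2), n_boot = 0)
    })
    as.numeric(suppressWarnings(p50_at_ph(curves, 7.27)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("cooperativity matches the symmetric closed form and the grid", {
  sym <- fivepl(b = 8, c = 0, d = 1, e = 7.2, f = 1)
  cap <- 1.58
  expect_equal(as.numeric(cooperativity(sym, cap)), cap * 8 / 4,
               tolerance = 1e-9)
  expect_equal(as.numeric(cooperativity(sym, 0)), 0)
  for (p in random_fivepl(50, seed = 33)) {
    expect_equal(as.numeric(cooperativity(p, 1)), grid_max_slope(p),
                 tolerance = 1e-6)
  }
})

test_that("P50 temperature sensitivity is plain finite-difference", {
  expect_equal(delta_p50_per_degC(0.41, 2.34, 0, 10), 0.193,
               tolerance = 1e-12)
  expect_equal(delta_p50_per_degC(1.63, 6.07, 10, 20), 0.444,
               tolerance = 1e-12)
  expect_equal(delta_p50_per_degC(2, 2, 0, 10), 0)
  expect_error(delta_p50_per_degC(NA, 2, 0, 10), "undefined")
  expect_error(delta_p50_per_degC(1, 2, 10, 10), "differ")
})

test_that("noisy Bohr recovery stays within 10% in most replicates", {
  gt <- make_pigment()
  hits <- 0
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    curves <- lapply(c(21, 13, 4, 1), function(po2) {
      ss <- fivepl_series(
        fivepl(b = gt$steepness, c = 0, d = 1,
               e = gt$ph_ref + (log10(po2) - log10(gt$p50_ref)) /
                 gt$bohr_slope, f = 1),
        po2 = po2, noise_sd = 0.02, seed = i * 17 + po2)
      tryCatch(fit_5pl(ss, n_boot = 0), error = function(e) NULL)
    })
    if (any(vapply(curves, is.null, logical(1)))) next
    bohr <- tryCatch(bohr_coefficient(curves), error = function(e) NA)
    if (is.finite(bohr) && abs(bohr + 1.22) / 1.22 < 0.10) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
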