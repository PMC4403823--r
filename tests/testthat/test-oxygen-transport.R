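# Alpha-stat projection, solubility, dissolved O2 and transport budgets.

test_that("alpha-stat venous pH reproduces the reference temperatures", {
  m <- alpha_stat_model()
  expect_equal(round(venous_ph(m, 10), 2), 7.27)
  expect_equal(round(venous_ph(m, 0), 2), 7.42)
  expect_equal(round(venous_ph(m, 15), 2), 7.19)
  expect_error(venous_ph(m, 35), "range")
  expect_error(alpha_stat_model(slope = 0.01), "negative")
})

test_that("arterial pH is a constant alkaline offset from venous", {
  expect_equal(arterial_ph(7.42), 7.53)
  expect_equal(arterial_ph(7.27), 7.38)
  expect_equal(arterial_ph(7.0, offset = 0), 7.0)
})

test_that("seawater O2 solubility matches reference values", {
  expect_equal(o2_solubility(0, 35), 359.5, tolerance = 0.01)
  expect_equal(o2_solubility(10, 35), 282, tolerance = 0.005)
  expect_equal(o2_solubility(20, 35), 231, tolerance = 0.005)
  expect_error(o2_solubility(-5, 35), "temperature")
  expect_error(o2_solubility(10, 50), "salinity")
})

test_that("solubility decreases with temperature and salinity", {
  temps <- seq(-2, 40, by = 2)
  expect_true(all(diff(o2_solubility(temps, 35)) < 0))
  sals <- seq(0, 42, by = 2)
  expect_true(all(diff(o2_solubility(10, sals)) < 0))
})

test_that("dissolved O2 scales linearly with PO2", {
  expect_equal(dissolved_o2(21, 0, 35), o2_solubility(0, 35))
  expect_equal(dissolved_o2(0, 0, 35), 0)
  expect_equal(dissolved_o2(13, 0, 35), o2_solubility(0, 35) * 13 / 21,
               tolerance = 1e-12)
  expect_error(dissolved_o2(-1, 0), ">= 0")
  expect_error(dissolved_o2(30, 0), "air_po2")
})

test_that("saturation interpolation is exact at fitted levels and accurate between", {
  # a gently sloped pigment keeps saturation nearly linear in log10(PO2)
  gt <- make_pigment(steepness = 4)
  curves <- lapply(c(21, 13, 4, 1), function(po2) {
    fit_5pl(surface_series(gt, po2), n_boot = 0)
  })
  S <- build_binding_surface(gt)
  # at a fitted level: exact evaluation of that curve
  expect_equal(saturation_at(curves, 7.3, 4),
               pmin(1, pmax(0, fivepl_eval(curves[[3]]$params, 7.3))),
               tolerance = 1e-12)
  # between levels: close to the smooth ground truth
  expect_lt(abs(saturation_at(curves, 7.3, 2) - S(7.3, 2, 10)), 0.01)
  expect_error(saturation_at(curves, 7.3, 30), "outside")
})

test_that("transport budget follows the hand-computed arithmetic", {
  # step-function-like curve: fully saturated arterially, empty venously
  steep_lo <- structure(
    list(params = fivepl(b = 400, c = 0, d = 1, e = 7.38, f = 1),
         po2 = 1, temperature = 10, n_points = 60,
         boot = NULL, boot_ci = NULL, seed = 1L),
    class = "ph_o2_curve")
  steep_hi <- steep_lo; steep_hi$po2 <- 13; steep_hi$params$e <- 7.0
  cond <- in_vivo_conditions(temperature = 10, venous_po2 = 1,
                             venous_ph = 7.27)
  bud <- transport_budget(list(steep_hi, steep_lo), 1.58, cond)
  expect_equal(bud$s_arterial, 1, tolerance = 1e-6)
  expect_equal(bud$s_venous, 0, tolerance = 1e-6)
  expect_equal(bud$bound_release_frac, 1, tolerance = 1e-5)
  expect_equal(bud$bound_release, 1.58, tolerance = 1e-5)

  # independent arithmetic oracle on a smooth fixture
  gt <- make_pigment()
  curves <- lapply(c(21, 13, 4, 1), function(po2)
    fit_5pl(surface_series(gt, po2), n_boot = 0))
  cond <- in_vivo_conditions(temperature = 10, venous_po2 = 4,
                             venous_ph = 7.267)
  bud <- transport_budget(curves, 1.58, cond)
  s_a <- saturation_at(curves, 7.267 + 0.11, 13)
  s_v <- saturation_at(curves, 7.267, 4)
  sol <- o2_solubility(10, 35) / 1000
  expect_equal(bud$bound_release, 1.58 * (s_a - s_v), tolerance = 1e-9)
  expect_equal(bud$dissolved_release, sol * (13 - 4) / 21, tolerance = 1e-9)
  expect_equal(bud$dissolved_fraction_of_total, sol / (sol + 1.58),
               tolerance = 1e-12)
})

test_that("total release conserves arterial minus venous content", {
  gt <- make_pigment()
  curves <- lapply(c(21, 13, 4, 1), function(po2)
    fit_5pl(surface_series(gt, po2), n_boot = 0))
  for (vpo2 in c(4, 1)) {
    cond <- in_vivo_conditions(temperature = 10, venous_po2 = vpo2)
    bud <- transport_budget(curves, 1.58, cond)
    venous_content <- 1.58 * bud$s_venous + bud$dissolved_venous
    expect_equal(bud$total_release, bud$total_content - venous_content,
                 tolerance = 1e-12)
    expect_true(bud$bound_release_frac >= 0 && bud$bound_release_frac <= 1)
  }
})

test_that("bound release grows as venous PO2 falls; dissolved share falls with warming", {
  gt <- make_pigment()
  curves <- lapply(c(21, 13, 4, 1), function(po2)
    fit_5pl(surface_series(gt, po2), n_boot = 0))
  fr <- vapply(c(4, 2, 1), function(vpo2) {
    transport_budget(curves, 1.58,
                     in_vivo_conditions(temperature = 10,
                                        venous_po2 = vpo2)
    )$bound_release_frac
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  dissolved_frac <- vapply(c(0, 10, 20), function(tC) {
    o2_solubility(tC, 35) / 1000 / (o2_solubility(tC, 35) / 1000 + 1.58)
  }, numeric(1))
  expect_true(all(diff(dissolved_frac) < 0))
})

test_that("haemocyanin concentration conversion is linear and exact", {
  expect_equal(hc_concentration(1.58), 79.0, tolerance = 1e-9)
  expect_equal(hc_concentration(1.08), 54.0, tolerance = 1e-9)
  expect_equal(hc_concentration(0), 0)
  expect_equal(hc_concentration(2 * 1.58), 2 * hc_concentration(1.58))
  expect_error(hc_concentration(1, binding_sites = 0), "> 0")
})
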