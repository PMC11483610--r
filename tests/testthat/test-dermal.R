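test_that("maximum flux follows the Fickian product with unit conversions", {
  # identity case with consistent units: D/h = 1 cm/h, K = 1, Csat = 1 mg/mL
  expect_equal(jmax(1e-4, 1, 1, 1), 1e6)  # 1 mg/cm^2/h in ng
  expect_equal(jmax(1e-4, 1, 1, 2), 2 * jmax(1e-4, 1, 1, 1))  # linear in Csat
  expect_equal(jmax(2e-4, 1, 1, 1), 2 * jmax(1e-4, 1, 1, 1))  # linear in D
  # genistein: packaged-scale D, SC 43 um, measured solubility 0.12 mg/mL
  D <- 3.25e-6; h <- 43; K <- 10^(0.69 * 3.04)
  by_hand <- (D / (h * 1e-4)) * K * 0.12 * 1e6
  expect_equal(jmax(D, h, K, 0.12), by_hand, tolerance = 0.005)
  expect_error(jmax(-1, 43, 1, 1), "D")
})

test_that("skin solver conserves mass and stays inert with no dose", {
  grid <- default_skin_grid(genistein)
  fp <- first_pass_spec(0.7, k_met = 0.05)
  zero <- dermal_scenario(chemical_load = 0, product_amount = 0)
  res0 <- solve_skin(grid, zero, fp, duration_h = 6, dt_h = 0.05)
  expect_true(all(abs(res0$influx) < 1e-15))
  expect_true(all(res0$systemic == 0))

  res <- solve_skin(grid, dermal_scenario(), fp, duration_h = 24, dt_h = 0.02)
  expect_lt(res$mass_balance_error, 1e-3)
  # conservation with an arbitrary parameter set
  g2 <- skin_grid(diffusivity = c(sc = 1e-7, ve = 3e-4, de = 2e-4),
                  partition = c(sc = 50, ve = 10, de = 20), sc_scale = 0.3,
                  capillary_exchange = 2)
  res2 <- solve_skin(g2, dermal_scenario(), first_pass_spec(0.5, 0.3),
                     duration_h = 24, dt_h = 0.02)
  expect_lt(res2$mass_balance_error, 1e-3)
})

test_that("homogeneous membrane reaches the analytic steady-state flux", {
  D <- 8e-4; K <- 5
  grid <- skin_grid(thickness_um = c(sc = 500, ve = 500, de = 500),
                    nodes = c(sc = 20L, ve = 20L, de = 20L),
                    diffusivity = c(sc = D, ve = D, de = D),
                    partition = c(sc = K, ve = K, de = K),
                    capillary_exchange = 0)
  # constant-concentration donor: deep vehicle, negligible depletion
  scen <- dermal_scenario(chemical_load = 5000, area = 100,
                          product_amount = 50000, concentration_pct = 0.001)
  a0 <- 5000 / (50000 / 100)               # ug/cm^3 in the vehicle film
  L <- 0.15                                # cm
  res <- solve_skin(grid, scen, first_pass_spec(0), duration_h = 60,
                    dt_h = 0.05)
  expect_equal(res$influx[length(res$influx)],
               oracle_slab_flux(D, K, a0, L), tolerance = 0.01)
})

test_that("delivery responds monotonically to transport and metabolism", {
  grid <- default_skin_grid(genistein)
  scen <- dermal_scenario()
  deliv <- function(scale, k_met) {
    g <- grid; g$sc_scale <- scale
    dermal_delivery_fraction(
      solve_skin(g, scen, first_pass_spec(0.5, k_met), duration_h = 24,
                 dt_h = 0.05))
  }
  d <- sapply(c(0.01, 0.03, 0.1), deliv, k_met = 0.05)
  expect_true(all(diff(d) > 0))            # increasing in SC diffusivity
  m <- sapply(c(0, 0.05, 0.5), function(k) deliv(0.05, k))
  expect_true(all(diff(m) < 0))            # decreasing in metabolism rate
})

test_that("grid and time-step refinement leave delivery unchanged", {
  base <- default_skin_grid(genistein, sc_scale = 0.05)
  fine <- default_skin_grid(genistein, sc_scale = 0.05,
                            nodes = c(sc = 44L, ve = 24L, de = 60L))
  scen <- dermal_scenario()
  fp <- first_pass_spec(0.7, 0.06)
  d1 <- dermal_delivery_fraction(solve_skin(base, scen, fp, 24, dt_h = 0.02))
  d2 <- dermal_delivery_fraction(solve_skin(fine, scen, fp, 24, dt_h = 0.01))
  expect_equal(d1, d2, tolerance = 0.005)
})

test_that("first-pass calibration reaches the stated targets", {
  scen <- dermal_scenario()
  expect_identical(as.numeric(calibrate_first_pass(
    default_skin_grid(genistein), scen, first_pass_spec(0))), 0)
  for (case in list(list(chem = genistein, target = 0.70),
                    list(chem = daidzein, target = 0.36))) {
    grid <- calibrate_delivery(default_skin_grid(case$chem), scen,
                               case$chem$dermal_delivery_target,
                               first_pass_spec(case$target, 0.05),
                               dt_h = 0.05)
    k <- calibrate_first_pass(grid, scen, first_pass_spec(case$target),
                              dt_h = 0.05)
    expect_equal(attr(k, "achieved"), case$target, tolerance = 0.01 / case$target)
  }
})

test_that("delivery calibration recovers a known scaling factor", {
  scen <- dermal_scenario()
  fp <- first_pass_spec(0.7, 0.06)
  true_scale <- 0.05
  truth_grid <- default_skin_grid(genistein, sc_scale = true_scale)
  target <- dermal_delivery_fraction(
    solve_skin(truth_grid, scen, fp, 24, dt_h = 0.02)) / 100

  cal <- calibrate_delivery(default_skin_grid(genistein), scen, target, fp,
                            tol = 2e-4, dt_h = 0.02)
  expect_equal(cal$sc_scale, true_scale, tolerance = 0.02)

  # fixed point: target equal to the model's own output keeps the factor ~1
  g0 <- default_skin_grid(genistein, sc_scale = true_scale)
  own <- dermal_delivery_fraction(solve_skin(g0, scen, fp, 24, dt_h = 0.02)) / 100
  cal0 <- calibrate_delivery(g0, scen, own, fp, tol = 2e-4, dt_h = 0.02)
  expect_equal(attr(cal0, "scale_factor"), 1, tolerance = 0.02)
})

test_that("delivery fraction definition covers its degenerate cases", {
  fake <- structure(list(time = c(0, 24), epidermis = c(0, 0),
                         dermis = c(0, 1), systemic = c(0, 0),
                         applied = c(1, 1)), class = "skin_result")
  expect_equal(dermal_delivery_fraction(fake), 100)  # all mass in dermis
  none <- structure(list(time = c(0, 24), epidermis = c(0, 0),
                         dermis = c(0, 0), systemic = c(0, 0),
                         applied = c(1, 1)), class = "skin_result")
  expect_equal(dermal_delivery_fraction(none), 0)
})
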