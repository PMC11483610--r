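test_that("Weibull dissolution honours its defining points", {
  expect_equal(weibull_fraction_dissolved(250, 250, 0.92), 0.5)
  expect_equal(weibull_fraction_dissolved(0, 250, 0.92), 0)
  expect_equal(weibull_fraction_dissolved(1e7, 250, 0.92), 1)
  expect_equal(weibull_fraction_dissolved(100, 250, 0.92, lag = 150), 0)
  expect_true(all(diff(weibull_fraction_dissolved(0:2000, 250, 0.92)) >= 0))
  expect_error(weibull_fraction_dissolved(10, -1, 0.92), "t50")
  expect_error(weibull_fraction_dissolved(10, 250, 0), "shape")
})

test_that("zero dose leaves every state at zero", {
  mod <- rat_oral_model(genistein, 1)
  mod$dose_umol <- 0  # degenerate: no administration
  res <- simulate_pbpk(mod, duration_days = 1, dt_out_h = 0.25)
  expect_true(all(abs(as.matrix(res$amounts)) < 1e-12))
  expect_true(all(res$plasma_total == 0))
})

test_that("collapsed model matches the one-compartment analytic solution", {
  # homogeneous body: Kp = 1 everywhere, B:P = 1, huge blood flows so the
  # whole body behaves as a single well-mixed volume; first-order absorption
  # with instant dissolution and no transit loss; constant clearance.
  rat <- reference_rat()
  rat$cardiac_output <- rat$cardiac_output * 1e3
  rat$organs$flow_Lh <- rat$organs$flow_Lh * 1e3
  parts <- structure(list(chemical = "probe", species = "rat", fu = 1,
                          blood_plasma_ratio = 1,
                          kp_by_organ = setNames(rep(1, nrow(rat$organs)),
                                                 rat$organs$organ)),
                     class = "partition_set")
  CL <- 0.5  # L/h
  clear <- structure(list(clint_cellular = NA, clint_whole_liver = CL,
                          fu_plasma = 1, fu_blood = 1,
                          hepatic_blood_flow = NA, hepatic_clearance = CL,
                          renal_clearance = 0), class = "clearance_parameters")
  scen <- oral_scenario(1, duration_days = 1, t50 = 0.001, shape = 1)
  ka <- 1.2
  mod <- build_model(genistein, rat, scen, parts, clear,
                     gut_options = list(ka = ka, transit_rate = 0))
  res <- simulate_pbpk(mod, duration_days = 1, dt_out_h = 0.1)

  V <- sum(rat$organs$volume_L) + rat$blood_volume
  dose <- 1 * 0.23 / genistein$molecular_weight * 1e3  # umol
  # dissolution is hazard-capped at 50/h, so the exact reference is the
  # three-exponential chain dissolution -> absorption -> elimination
  pred <- oracle_one_compartment(res$time, dose, V, ka, CL,
                                 k_diss = 50) * 1e3  # nM
  keep <- res$time >= 1  # allow the fast mixing transient to pass
  err <- max(abs(res$plasma_total[keep] - pred[keep])) / max(pred)
  expect_lt(err, 0.01)
})

test_that("mass balance closes within 0.1% over 7 daily doses", {
  for (chem in list(genistein, daidzein)) {
    res <- simulate_pbpk(rat_oral_model(chem, 0.3), dt_out_h = 0.25)
    expect_lt(res$mass_balance_error, 1e-3)
  }
})

test_that("Cmax and AUC scale linearly with dose", {
  doses <- c(0.15, 0.3, 0.6)
  pk <- lapply(doses, function(d) {
    compute_pk_metrics(simulate_pbpk(rat_oral_model(genistein, d),
                                     duration_days = 3, dt_out_h = 0.1))
  })
  for (i in 2:3) {
    ratio <- doses[i] / doses[1]
    expect_equal(pk[[i]]$cmax_total / pk[[1]]$cmax_total, ratio,
                 tolerance = 0.005)
    expect_equal(pk[[i]]$auc / pk[[1]]$auc, ratio, tolerance = 0.005)
  }
})

test_that("solution is converged in solver tolerance and near steady state", {
  mod <- rat_oral_model(genistein, 0.3)
  res1 <- simulate_pbpk(mod, rtol = 1e-6)
  res2 <- simulate_pbpk(mod, rtol = 5e-7)
  pk1 <- compute_pk_metrics(res1)
  pk2 <- compute_pk_metrics(res2)
  expect_equal(pk1$cmax_total, pk2$cmax_total, tolerance = 1e-3)

  # day 6 vs day 7 peak: repeated dosing has reached steady state
  day_cmax <- function(res, day) {
    sel <- res$time >= 24 * (day - 1) & res$time <= 24 * day
    max(res$plasma_total[sel])
  }
  expect_equal(day_cmax(res1, 7), day_cmax(res1, 6), tolerance = 0.05)
})

test_that("PK metrics handle degenerate profiles", {
  flat <- structure(list(time = seq(0, 10, 0.5),
                         plasma_total = rep(20, 21), fu = 0.5),
                    class = "simulation_result")
  pk <- compute_pk_metrics(flat)
  expect_equal(pk$cmax_total, 20)
  expect_equal(pk$cmax_unbound, 10)
  expect_equal(pk$auc, 200)

  tri <- structure(list(time = 0:10,
                        plasma_total = c(0:5 * 20, 4:0 * 20), fu = 1),
                   class = "simulation_result")
  pk2 <- compute_pk_metrics(tri)
  expect_equal(pk2$cmax_total, 100)
  expect_equal(pk2$tmax, 5)
  expect_equal(pk2$cmax_unbound, pk2$cmax_total)  # fu = 1
  expect_error(compute_pk_metrics(
    structure(list(time = numeric(0), plasma_total = numeric(0), fu = 1),
              class = "simulation_result")), "empty")
})

test_that("missing partition data is a configuration error", {
  rat <- reference_rat()
  parts <- tissue_partitions(genistein, rat, "rat")
  parts$kp_by_organ <- parts$kp_by_organ[-1]
  expect_error(
    build_model(genistein, rat, oral_scenario(0.3),
                parts, clearance_parameters(genistein, rat)),
    "missing partition")
})

test_that("population simulation is reproducible and respects ranges", {
  rat <- reference_rat()
  pop <- sample_population(population_spec(8, c(0.185, 0.275), seed = 5), rat)
  scen <- oral_scenario(0.3, duration_days = 2)
  a <- population_simulate(genistein, pop, scen, seed = 5, dt_out_h = 0.25)
  b <- population_simulate(genistein, pop, scen, seed = 5, dt_out_h = 0.25)
  expect_identical(a$metrics, b$metrics)
  expect_true(all(a$metrics$body_weight >= 0.185 &
                    a$metrics$body_weight <= 0.275))
  expect_lte(a$summary$cmax_total["ci5"], a$summary$cmax_total["ci95"])

  # no-uncertainty single individual: degenerate percentiles
  one <- population_simulate(genistein, list(rat), scen, seed = 1,
                             uncertainty = FALSE, dt_out_h = 0.25)
  s <- one$summary$cmax_total
  expect_equal(unname(s["ci5"]), unname(s["mean"]))
  expect_equal(unname(s["ci95"]), unname(s["mean"]))
})
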