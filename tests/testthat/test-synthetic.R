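test_that("pseudo-observed PK reduces to the truth when noise is off", {
  truth <- function(dose) 80 * dose
  obs <- generate_observed_pk(truth, cv = 0, seed = 1)
  expect_equal(obs$observations$cmax,
               80 * obs$observations$dose, tolerance = 1e-12)
  expect_equal(unique(obs$observations$dose), c(2.59, 6.46, 12.82))
  expect_equal(obs$ground_truth$cmax, 80 * c(2.59, 6.46, 12.82))
})

test_that("pseudo-observed PK noise matches the requested dispersion", {
  truth <- function(dose) 80 * dose
  obs <- generate_observed_pk(truth, cv = 0.2, n_per_dose = 6, seed = 99)
  cvs <- with(obs$observations,
              tapply(cmax, dose, function(x) sd(x) / mean(x)))
  expect_gt(mean(cvs), 0.1)
  expect_lt(mean(cvs), 0.3)
  # seed-fixed determinism; different seed differs
  obs2 <- generate_observed_pk(truth, cv = 0.2, n_per_dose = 6, seed = 99)
  expect_identical(obs$observations, obs2$observations)
  obs3 <- generate_observed_pk(truth, cv = 0.2, n_per_dose = 6, seed = 100)
  expect_false(identical(obs$observations, obs3$observations))
})

test_that("systematic perturbation shifts observations multiplicatively", {
  truth <- function(dose) 80 * dose
  obs <- generate_observed_pk(truth, perturbation = 1.5, cv = 0, seed = 1)
  expect_equal(obs$observations$cmax, 1.5 * 80 * obs$observations$dose)
})

test_that("ex vivo generator is linear below and saturating above threshold", {
  truth <- list(delivered_fraction = 0.12, metabolized_fraction = 0.08)
  doses <- c(3, 10, 30, 60, 120)
  x <- generate_exvivo(truth, doses, cv = 0, seed = 1)
  r <- x$replicates[x$replicates$replicate == 1, ]

  below <- r[r$dose <= 30, ]
  tot <- below$sulfate_nmol_cm2 + below$glucuronide_nmol_cm2
  expect_equal(tot / below$dose, rep(tot[1] / below$dose[1], nrow(below)),
               tolerance = 0.01)
  # sulfate strictly linear across the whole range
  expect_equal(r$sulfate_nmol_cm2 / r$dose,
               rep(r$sulfate_nmol_cm2[1] / r$dose[1], nrow(r)),
               tolerance = 1e-12)
  # glucuronide per-dose yield strictly decreasing above saturation
  above <- r[r$dose >= 30, ]
  expect_true(all(diff(above$glucuronide_nmol_cm2 / above$dose) < 0))

  expect_identical(generate_exvivo(truth, doses, cv = 0.25, seed = 4),
                   generate_exvivo(truth, doses, cv = 0.25, seed = 4))
  expect_error(generate_exvivo(truth, doses, n_replicates = 2), "replicates")
})

test_that("noise-free synthetic data close the loop with the estimators", {
  # qualification against identity-perturbed pseudo-data: unit fold errors
  truth <- function(dose) 41 * dose^0.97
  obs <- generate_observed_pk(truth, cv = 0, seed = 2)
  pred <- data.frame(dose = obs$ground_truth$dose,
                     mean = obs$ground_truth$cmax,
                     ci5 = obs$ground_truth$cmax * 0.6,
                     ci95 = obs$ground_truth$cmax * 1.7)
  q <- qualify(pred, obs$observations)
  expect_true(all(abs(q$table$fold_mean - 1) < 0.1))
  expect_gt(q$r_squared, 0.99)

  # dermal calibration against noise-free ex vivo output recovers delivery
  scen <- dermal_scenario()
  fp <- first_pass_spec(0.7, 0.06)
  truth_grid <- default_skin_grid(genistein, sc_scale = 0.05)
  truth_res <- solve_skin(truth_grid, scen, fp, 24, dt_h = 0.05)
  truth_deliv <- dermal_delivery_fraction(truth_res) / 100
  ex <- generate_exvivo(list(delivered_fraction = truth_deliv,
                             metabolized_fraction = 0.1),
                        doses = 3, cv = 0, seed = 1)
  target <- ex$replicates$delivered_fraction[1]
  cal <- calibrate_delivery(default_skin_grid(genistein), scen, target, fp,
                            tol = 1e-4, dt_h = 0.05)
  achieved <- attr(cal, "achieved")
  expect_equal(achieved, truth_deliv, tolerance = 0.01)
})
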