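test_that("local sensitivity recovers proportionality and indifference", {
  runner <- function(p) 7 * p$dose + 0 * p$ignored
  out <- local_sensitivity(runner, c(dose = 2, ignored = 5))
  expect_equal(out$S[out$parameter == "dose"], 1, tolerance = 0.01)
  expect_equal(out$S[out$parameter == "ignored"], 0, tolerance = 1e-9)
  expect_error(local_sensitivity(function(p) 0, c(a = 1)), "zero")
})

test_that("sensitivity classification uses the stated thresholds", {
  expect_equal(unname(classify_sensitivity(0.6)), "high")
  expect_equal(unname(classify_sensitivity(-0.6)), "high")
  expect_equal(unname(classify_sensitivity(0.3)), "medium")
  expect_equal(unname(classify_sensitivity(0.15)), "low")
  expect_equal(unname(classify_sensitivity(0.05)), "negligible")
  expect_equal(unname(classify_sensitivity(0.5)), "high")   # boundary
  expect_equal(unname(classify_sensitivity(0.2)), "medium")
  expect_equal(unname(classify_sensitivity(0.1)), "low")
})

test_that("sensitivity coefficients are invariant to parameter units", {
  runner_h <- function(p) 3 * sqrt(p$cl)          # parameter in L/h
  runner_min <- function(p) 3 * sqrt(p$cl / 60)   # same model, L/min
  s1 <- local_sensitivity(runner_h, c(cl = 2))$S
  s2 <- local_sensitivity(runner_min, c(cl = 120))$S
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("fold errors behave as ratios", {
  expect_equal(fold_error(5, 5), 1)
  expect_equal(fold_error(45.8, 24.1), 1.90, tolerance = 0.01 / 1.9)
  expect_error(fold_error(1, 0), "measured")
})

test_that("qualification reports fold errors, the 2-fold rule and R^2", {
  pred <- data.frame(dose = c(2.59, 6.46, 12.82),
                     mean = c(100, 220, 410), ci5 = c(60, 140, 260),
                     ci95 = c(180, 390, 700))
  obs_equal <- data.frame(dose = pred$dose, mean = pred$mean)
  q <- qualify(pred, obs_equal)
  expect_true(all(q$table$fold_mean == 1))
  expect_equal(q$r_squared, 1)
  expect_true(q$overall_pass)

  # a 3.9-fold CI95 exceeds the 2-fold band even when the mean passes
  expect_false(all(abs(log(q$table$fold_ci95 * 3.9)) <= log(2)))

  # lognormal observation noise around the truth still qualifies
  set.seed(42)
  obs <- do.call(rbind, lapply(seq_len(nrow(pred)), function(i) {
    data.frame(dose = pred$dose[i],
               cmax = pred$mean[i] * exp(rnorm(6, 0, 0.2)))
  }))
  q2 <- qualify(pred, obs)
  expect_true(q2$overall_pass)

  # common rescaling of observations: folds scale exactly, R^2 unchanged
  obs_scaled <- transform(obs, cmax = cmax * 1.9)
  q3 <- qualify(pred, obs_scaled)
  expect_equal(q3$table$fold_mean, q2$table$fold_mean / 1.9)
  expect_equal(q3$r_squared, q2$r_squared)

  expect_error(qualify(pred[1, ], obs_equal[1, ]), ">= 2 dose levels")
  expect_error(qualify(pred, data.frame(dose = c(1, 2, 3), mean = 1:3)),
               "dose sets")
})

test_that("NOEC derivation divides the LOEC by three", {
  expect_equal(round(loec_to_noec(5.2), 2), 1.73)
  expect_equal(round(loec_to_noec(100), 2), 33.33)
  expect_equal(loec_to_noec(3), 1)
  expect_error(loec_to_noec(-5), "loec")
})

test_that("reverse dosimetry inverts a monotone dose-response", {
  runner <- function(d) 12.5 * d^1.1   # mildly non-linear, monotone
  known <- 2.5
  target <- runner(known)
  dose <- reverse_dosimetry(runner, target, bracket = c(0.01, 100))
  expect_equal(as.numeric(dose), known, tolerance = 0.01)
  expect_equal(attr(dose, "achieved_cmax"), target, tolerance = 0.01)
  expect_error(reverse_dosimetry(runner, 1e9, c(0.01, 100)), "achievable")
  expect_error(reverse_dosimetry(function(d) 1 / d, 1, c(0.1, 10)),
               "monotone")
})

test_that("margin of internal exposure reproduces the worked ratios", {
  m <- moie(24.1, 1.73)
  expect_equal(as.numeric(m), 13.9, tolerance = 0.005)
  expect_equal(as.numeric(moie(5, 5)), 1)
  expect_equal(as.numeric(moie(1.37, 1.73)), 0.79, tolerance = 0.01)
  expect_equal(attr(m, "pod_over_cmax"), 1.73 / 24.1)
})

test_that("uncertainty intervals and categories follow the factor bands", {
  u <- uncertainty_ci(rep(3.3, 5))
  expect_equal(u$ci5, u$ci95)
  u2 <- uncertainty_ci(1:100, parameter_factors = c(clint = 2.5, fu = 0.2,
                                                    t50 = 1.0))
  expect_equal(unname(u2$categories["clint"]), "high")
  expect_equal(unname(u2$categories["fu"]), "low")
  expect_equal(unname(u2$categories["t50"]), "medium")
  expect_lt(u2$ci5, u2$ci95)
})
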