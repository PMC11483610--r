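#' Exposure scenarios
#'
#' Constructors for the oral (rat) and dermal (human) dosing regimens.
#'
#' @name scenario
NULL

#' Weibull fraction dissolved
#'
#' Cumulative fraction of an oral suspension dissolved at time `t`,
#' `F(t) = 1 - exp(-((t - lag)/tau)^shape)`, with the time scale `tau` fixed
#' by the definition of `t50`: `F(t50) = 0.5` exactly. `F` is clamped to 0
#' for `t < lag`.
#'
#' @param t time, min (vectorised).
#' @param t50 time to dissolve 50%, min.
#' @param shape Weibull shape (0.92 = slightly sub-exponential, "parabolic").
#' @param lag lag time, min.
#' @return fraction dissolved in `[0, 1)`.
#' @export
weibull_fraction_dissolved <- function(t, t50, shape, lag = 0) {
  assert_positive(t50, "t50")
  assert_positive(shape, "shape")
  if (any(t < 0)) stop_domain("t must be >= 0")
  tau <- (t50 - lag) / log(2)^(1 / shape)
  ifelse(t <= lag, 0, 1 - exp(-(pmax(t - lag, 0) / tau)^shape))
}

# Instantaneous dissolution hazard f(t)/(1-F(t)) in 1/min; used as the
# first-order conversion rate of undissolved to dissolved drug in the lumen.
# For shape < 1 the hazard is singular (but integrable) at t = lag; it is
# capped at 50/h, i.e. dissolution faster than ~minutes is treated as
# instantaneous, which also keeps the ODE system benign at dose times.
weibull_hazard <- function(t, t50, shape, lag = 0) {
  tau <- (t50 - lag) / log(2)^(1 / shape)
  td <- pmax(t - lag, 1e-9)
  hz <- ifelse(t <= lag, 0, (shape / tau) * (td / tau)^(shape - 1))
  pmin(hz, 50 / 60)
}

#' Oral exposure scenario
#'
#' @param dose mg/kg/day.
#' @param duration_days length of the regimen (one dose per day).
#' @param t50,shape,lag Weibull dissolution parameters of the suspension
#'   (min); defaults are the suspension defaults used for the isoflavone
#'   diet (t50 250 min, shape 0.92, no lag).
#' @return object of class `exposure_scenario`.
#' @export
oral_scenario <- function(dose, duration_days = 7, t50 = 250, shape = 0.92,
                          lag = 0) {
  assert_positive(dose, "dose")
  structure(list(route = "oral", dose = dose, frequency = 1,
                 duration_days = duration_days,
                 formulation = list(t50 = t50, shape = shape, lag = lag)),
            class = "exposure_scenario")
}

#' Dermal exposure scenario
#'
#' @param chemical_load ug/cm^2 of active per application.
#' @param area exposed skin area, cm^2 (whole body 15670, face 565).
#' @param product_amount g/day of formulation applied.
#' @param concentration_pct percent of active in the formulation.
#' @param duration_days days of once-daily application.
#' @return object of class `exposure_scenario`.
#' @export
dermal_scenario <- function(chemical_load = 1, area = 15670,
                            product_amount = 7.82, concentration_pct = 0.2,
                            duration_days = 1) {
  if (chemical_load < 0) stop_domain("chemical_load must be >= 0")
  assert_positive(area, "area")
  implied <- concentration_pct / 100 * product_amount * 1e6 / area  # ug/cm^2
  if (chemical_load > 0 && abs(implied - chemical_load) / chemical_load > 0.05) {
    stop_domain(sprintf(
      "inconsistent dermal scenario: %.3g%% of %.3g g/day over %.0f cm^2 implies %.3g ug/cm^2, stated %.3g",
      concentration_pct, product_amount, area, implied, chemical_load))
  }
  structure(list(route = "dermal", chemical_load = chemical_load, area = area,
                 product_amount = product_amount,
                 concentration_pct = concentration_pct, frequency = 1,
                 duration_days = duration_days),
            class = "exposure_scenario")
}
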