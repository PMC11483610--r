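#' Assembled study workflows
#'
#' Convenience constructors for the two study models: the rat oral model
#' (Weibull-suspension dosing at a mg/kg/day dose) and the human dermal
#' model (body-lotion application through the calibrated skin module).
#'
#' @name workflows
NULL

#' Build the rat oral PBPK model for a chemical
#'
#' @param chemical a [chemical_profile()] (or chemical name to load).
#' @param dose mg/kg/day.
#' @param duration_days once-daily dosing duration (default 7).
#' @param individual physiology (default [reference_rat()]).
#' @param fu,clint_cellular optional parameter overrides.
#' @param ... passed to [oral_scenario()].
#' @return a `pbpk_model`.
#' @export
rat_oral_model <- function(chemical, dose, duration_days = 7,
                           individual = reference_rat(), fu = NULL,
                           clint_cellular = NULL, ...) {
  if (is.character(chemical)) chemical <- load_chemical(chemical)
  scen <- oral_scenario(dose, duration_days = duration_days, ...)
  fu <- fu %||% as.numeric(select_fu(chemical, "rat"))
  parts <- tissue_partitions(chemical, individual, "rat", fu = fu)
  cl <- clearance_parameters(chemical, individual, fu = fu,
                             clint_cellular = clint_cellular)
  build_model(chemical, individual, scen, parts, cl)
}

#' Build the human dermal PBPK model for a chemical
#'
#' Calibrates (or reuses) the chemical's skin module, solves it for the
#' exposure, and couples the resulting systemic influx into the whole-body
#' human model.
#'
#' @param chemical a [chemical_profile()] (or name).
#' @param scenario a [dermal_scenario()].
#' @param individual physiology (default [reference_human()]).
#' @param calibration optional precomputed [calibrate_dermal_module()]
#'   result (recommended when building many individuals).
#' @param fu,clint_cellular optional overrides for the systemic model.
#' @param dt_h skin-solver time step.
#' @return list with elements `model` (a `pbpk_model`), `skin` (the solved
#'   `skin_result`) and `calibration`.
#' @export
human_dermal_model <- function(chemical, scenario = dermal_scenario(),
                               individual = reference_human(),
                               calibration = NULL, fu = NULL,
                               clint_cellular = NULL, dt_h = 0.02) {
  if (is.character(chemical)) chemical <- load_chemical(chemical)
  calibration <- calibration %||% calibrate_dermal_module(chemical, scenario,
                                                          dt_h = dt_h)
  skin <- solve_skin(calibration$grid, scenario, calibration$first_pass,
                     duration_h = 24 * scenario$duration_days, dt_h = dt_h)
  influx <- build_dermal_influx(skin, scenario$area,
                                chemical$molecular_weight)
  fu <- fu %||% as.numeric(select_fu(chemical, "human"))
  parts <- tissue_partitions(chemical, individual, "human", fu = fu)
  cl <- clearance_parameters(chemical, individual, fu = fu,
                             clint_cellular = clint_cellular)
  model <- build_model(chemical, individual, scenario, parts, cl,
                       dermal_influx = influx)
  list(model = model, skin = skin, calibration = calibration)
}

#' Dose-response runner for reverse dosimetry (rat oral)
#'
#' @param chemical a [chemical_profile()] (or name).
#' @param metric `"unbound"` (default, the internal dose metric matched to
#'   an in vitro free-concentration PoD) or `"total"`.
#' @param duration_days dosing duration.
#' @param dt_out_h output resolution.
#' @return function(dose mg/kg/day) returning Cmax in nM.
#' @export
rat_cmax_runner <- function(chemical, metric = c("unbound", "total"),
                            duration_days = 7, dt_out_h = 5 / 60) {
  metric <- match.arg(metric)
  if (is.character(chemical)) chemical <- load_chemical(chemical)
  individual <- reference_rat()
  function(dose) {
    mod <- rat_oral_model(chemical, dose, duration_days = duration_days,
                          individual = individual)
    pk <- compute_pk_metrics(simulate_pbpk(mod, dt_out_h = dt_out_h))
    if (metric == "unbound") pk$cmax_unbound else pk$cmax_total
  }
}
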