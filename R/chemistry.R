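#' Chemical profile container
#'
#' Holds all chemical-specific physicochemical and ADME constants needed to
#' parameterise the whole-body models: lipophilicity, ionisation, solubility,
#' intestinal permeabilities, plasma protein binding (with the full candidate
#' list per species), blood:plasma ratio, hepatocyte intrinsic clearance,
#' renal clearance, and the dermal first-pass / ex vivo delivery constants.
#'
#' @param name chemical name.
#' @param molecular_weight g/mol.
#' @param log_pow log10 octanol:water partition coefficient.
#' @param pka list of `list(value=, type=)` entries, `type` one of
#'   `"acid"`/`"base"`; may be empty for neutrals.
#' @param water_solubility mg/mL.
#' @param papp_ab,papp_ba Caco-2 apparent permeabilities, cm/s (`papp_ba`
#'   optional).
#' @param peff effective intestinal permeability, cm/s.
#' @param fu_plasma named list per species, each
#'   `list(selected=, candidates=)`, fractions in (0, 1].
#' @param blood_plasma_ratio named list per species, unitless.
#' @param clint_hepatocytes named list per species, uL/min/10^6 cells.
#' @param renal_clearance L/h (0 for these chemicals).
#' @param skin_first_pass_fraction fraction of dermally penetrated dose
#'   metabolised in the viable skin layers.
#' @param skin_first_pass_range numeric length-2 range for the uncertainty
#'   analysis.
#' @param exvivo_delivery_fraction `list(mean=, sd=)`, fraction of applied
#'   dose delivered through fresh skin over 24 h.
#' @param dermal_delivery_target default calibration target for the dermal
#'   module (fraction of applied dose at 24 h).
#' @param melting_point,vapor_pressure optional physchem extras (degC, mmHg).
#' @return object of class `chemical_profile`.
#' @export
chemical_profile <- function(name, molecular_weight, log_pow, pka = list(),
                             water_solubility, papp_ab, papp_ba = NULL, peff,
                             fu_plasma, blood_plasma_ratio, clint_hepatocytes,
                             renal_clearance = 0,
                             skin_first_pass_fraction = 0,
                             skin_first_pass_range = NULL,
                             exvivo_delivery_fraction = NULL,
                             dermal_delivery_target = NULL,
                             melting_point = NA_real_,
                             vapor_pressure = NA_real_) {
  assert_positive(molecular_weight, "molecular_weight")
  assert_positive(water_solubility, "water_solubility")
  assert_positive(papp_ab, "papp_ab")
  if (!is.null(papp_ba)) assert_positive(papp_ba, "papp_ba")
  assert_positive(peff, "peff")
  assert_fraction(skin_first_pass_fraction, "skin_first_pass_fraction")
  for (sp in names(fu_plasma)) {
    fu <- fu_plasma[[sp]]
    assert_fraction(fu$selected, paste0("fu_plasma$", sp), open_lower = TRUE)
    if (length(fu$candidates) < 1L) {
      stop_domain("fu_plasma for species '", sp, "' needs at least one candidate")
    }
    # the selected value must be one of the candidates, or explicitly composite
    if (!isTRUE(fu$composite) &&
        !any(abs(unlist(fu$candidates) - fu$selected) < 1e-12)) {
      stop_domain("selected fu for '", sp,
                  "' is not a member of the candidate list (set composite = TRUE)")
    }
  }
  renal_clearance <- as.numeric(renal_clearance)
  structure(list(
    name = name,
    molecular_weight = molecular_weight,
    log_pow = log_pow,
    pka = pka,
    water_solubility = water_solubility,
    melting_point = melting_point,
    vapor_pressure = vapor_pressure,
    papp_ab = papp_ab,
    papp_ba = papp_ba,
    peff = peff,
    fu_plasma = fu_plasma,
    blood_plasma_ratio = blood_plasma_ratio,
    clint_hepatocytes = clint_hepatocytes,
    renal_clearance = renal_clearance,
    skin_first_pass_fraction = skin_first_pass_fraction,
    skin_first_pass_range = skin_first_pass_range %||%
      rep(skin_first_pass_fraction, 2),
    exvivo_delivery_fraction = exvivo_delivery_fraction,
    dermal_delivery_target = dermal_delivery_target
  ), class = "chemical_profile")
}

#' Load a packaged chemical profile
#'
#' Reads one of the structured YAML profiles shipped with the package
#' (`genistein`, `daidzein`) into a [chemical_profile()].
#'
#' @param name chemical name or a path to a YAML profile.
#' @return a `chemical_profile`.
#' @export
load_chemical <- function(name) {
  path <- if (file.exists(name)) name else {
    extdata_path("chemicals", paste0(tolower(name), ".yaml"))
  }
  y <- yaml::read_yaml(path)
  chemical_profile(
    name = y$name,
    molecular_weight = y$molecular_weight,
    log_pow = y$log_pow,
    pka = y$pka %||% list(),
    water_solubility = y$water_solubility,
    melting_point = y$melting_point %||% NA_real_,
    vapor_pressure = y$vapor_pressure %||% NA_real_,
    papp_ab = y$papp_ab,
    papp_ba = y$papp_ba,
    peff = y$peff,
    fu_plasma = y$fu_plasma,
    blood_plasma_ratio = y$blood_plasma_ratio,
    clint_hepatocytes = y$clint_hepatocytes,
    renal_clearance = y$renal_clearance %||% 0,
    skin_first_pass_fraction = y$skin_first_pass_fraction %||% 0,
    skin_first_pass_range = unlist(y$skin_first_pass_range),
    exvivo_delivery_fraction = y$exvivo_delivery_fraction,
    dermal_delivery_target = y$dermal_delivery_target
  )
}

#' @export
print.chemical_profile <- function(x, ...) {
  cat("<chemical_profile>", x$name, "\n")
  cat("  MW", x$molecular_weight, "g/mol | logP", x$log_pow,
      "| Sw", x$water_solubility, "mg/mL\n")
  cat("  pKa:", paste(vapply(x$pka, function(p)
    sprintf("%.2f (%s)", p$value, p$type), ""), collapse = ", "), "\n")
  invisible(x)
}

#' Caco-2 efflux ratio
#'
#' Ratio of basolateral-to-apical over apical-to-basolateral apparent
#' permeability; values near 1 indicate no carrier-mediated efflux.
#'
#' @param papp_ba,papp_ab permeabilities in cm/s (any common unit).
#' @return unitless ratio.
#' @export
efflux_ratio <- function(papp_ba, papp_ab) {
  assert_positive(papp_ba, "papp_ba")
  assert_positive(papp_ab, "papp_ab")
  papp_ba / papp_ab
}

#' Select the unbound plasma fraction for a species
#'
#' Several literature values exist for the fraction unbound; the selection
#' policy is explicit and recorded in the result's attributes.
#'
#' @param profile a [chemical_profile()].
#' @param species `"rat"` or `"human"`.
#' @param strategy `"primary"` (the profile's selected value, default),
#'   `"mean"` of all candidates, or `"max"` (worst-case, least bound).
#' @return fraction unbound with attributes `strategy` and `candidates`.
#' @export
select_fu <- function(profile, species, strategy = c("primary", "mean", "max")) {
  strategy <- match.arg(strategy)
  fu <- profile$fu_plasma[[species]]
  if (is.null(fu) || length(fu$candidates) < 1L) {
    stop_domain("no fu candidates for species '", species, "'")
  }
  cand <- unlist(fu$candidates)
  val <- switch(strategy,
    primary = fu$selected,
    mean = mean(cand),
    max = max(cand)
  )
  structure(val, strategy = strategy, candidates = cand)
}
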