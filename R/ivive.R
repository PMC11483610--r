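#' In vitro to in vivo extrapolation of clearance and permeability
#'
#' Scales hepatocyte intrinsic clearance to the whole liver, applies the
#' well-stirred liver model, and maps Caco-2 apparent permeability to
#' effective intestinal permeability through a configurable log-affine
#' correlation.
#'
#' @name ivive
NULL

#' Scale hepatocyte intrinsic clearance to the whole liver
#'
#' Converts a cellular intrinsic clearance (uL/min/10^6 cells) to a
#' whole-liver intrinsic clearance in L/h using liver mass and
#' hepatocellularity. By convention the cellular rate is additionally
#' multiplied by the liver intracellular volume fraction (67%) when the
#' correction is enabled; the applied convention is recorded in the result's
#' `correction` attribute.
#'
#' @param clint_cellular uL/min/10^6 cells.
#' @param liver_mass g.
#' @param hepatocellularity cells/g (default 110e6).
#' @param intracellular_fraction fraction of liver volume that is
#'   intracellular (default 0.67).
#' @param intracellular_correction apply the intracellular-fraction factor?
#' @return whole-liver intrinsic clearance, L/h.
#' @export
scale_clint <- function(clint_cellular, liver_mass,
                        hepatocellularity = HEPATOCELLULARITY,
                        intracellular_fraction = LIVER_INTRACELLULAR,
                        intracellular_correction = TRUE) {
  if (clint_cellular < 0) stop_domain("clint_cellular must be >= 0")
  assert_positive(liver_mass, "liver_mass")
  assert_positive(hepatocellularity, "hepatocellularity")
  # uL/min/1e6 cells * cells/g / 1e6 * g -> uL/min; * 60 min/h * 1e-9 L/uL
  cl <- clint_cellular * (hepatocellularity / 1e6) * liver_mass * 60 * 1e-9 * 1e3
  if (intracellular_correction) cl <- cl * intracellular_fraction
  structure(cl, correction = if (intracellular_correction)
    intracellular_fraction else 1)
}

#' Well-stirred hepatic clearance
#'
#' CL_h = Q_h * fu_B * CLint / (Q_h + fu_B * CLint), with fu_B the
#' blood-referenced unbound fraction (fu_plasma / blood:plasma ratio).
#'
#' @param clint_whole_liver L/h.
#' @param fu_blood unbound fraction referenced to whole blood.
#' @param hepatic_blood_flow L/h.
#' @return hepatic clearance, L/h (blood-referenced), bounded above by Q_h.
#' @export
well_stirred_clearance <- function(clint_whole_liver, fu_blood,
                                   hepatic_blood_flow) {
  if (clint_whole_liver < 0) stop_domain("clint must be >= 0")
  assert_positive(hepatic_blood_flow, "hepatic_blood_flow")
  if (fu_blood <= 0) stop_domain("fu_blood must be > 0")
  fucl <- fu_blood * clint_whole_liver
  hepatic_blood_flow * fucl / (hepatic_blood_flow + fucl)
}

#' Default Papp -> Peff correlation coefficients
#'
#' The correlation used to derive effective intestinal permeability from
#' Caco-2 Papp is proprietary; the packaged default is the log-affine map
#' `log10(Peff) = a + b * log10(Papp)` fitted exactly through the two
#' published anchor pairs (genistein 3.31e-5 -> 1.01e-4 cm/s; daidzein
#' 2.03e-5 -> 6.61e-5 cm/s).
#'
#' @return list with elements `a` and `b`.
#' @export
peff_correlation_default <- function() {
  p1 <- c(papp = 3.31e-5, peff = 1.01e-4)
  p2 <- c(papp = 2.03e-5, peff = 6.61e-5)
  b <- (log10(p1["peff"]) - log10(p2["peff"])) /
    (log10(p1["papp"]) - log10(p2["papp"]))
  a <- log10(p1["peff"]) - b * log10(p1["papp"])
  list(a = unname(a), b = unname(b))
}

#' Effective intestinal permeability from Caco-2 Papp
#'
#' @param papp_ab apical-to-basolateral Papp, cm/s.
#' @param correlation list with log-affine coefficients `a`, `b`
#'   (`log10 Peff = a + b log10 Papp`); defaults to
#'   [peff_correlation_default()]. `list(a = 0, b = 1)` is the identity.
#' @return Peff in cm/s.
#' @export
papp_to_peff <- function(papp_ab, correlation = peff_correlation_default()) {
  assert_positive(papp_ab, "papp_ab")
  if (is.null(correlation$a) || is.null(correlation$b)) {
    stop_domain("Papp->Peff correlation coefficients 'a' and 'b' are required")
  }
  10^(correlation$a + correlation$b * log10(papp_ab))
}

#' Derive whole-body clearance parameters for a chemical and individual
#'
#' Bundles the IVIVE chain: cellular intrinsic clearance -> whole-liver
#' intrinsic clearance -> well-stirred hepatic clearance; renal clearance is
#' carried through unchanged (0 L/h for these chemicals).
#'
#' @param profile a [chemical_profile()].
#' @param physiology a `species_physiology` individual.
#' @param fu optional plasma fu override (e.g. a sampled candidate).
#' @param clint_cellular optional cellular CLint override (uL/min/10^6 cells).
#' @param intracellular_correction see [scale_clint()].
#' @return object of class `clearance_parameters`.
#' @export
clearance_parameters <- function(profile, physiology, fu = NULL,
                                 clint_cellular = NULL,
                                 intracellular_correction = TRUE) {
  sp <- physiology$species
  fu <- fu %||% as.numeric(select_fu(profile, sp))
  clint_cell <- clint_cellular %||% profile$clint_hepatocytes[[sp]]
  bp <- profile$blood_plasma_ratio[[sp]]
  organs <- physiology$organs
  liver_mass <- organs$volume_L[organs$organ == "liver"] * 1e3  # g
  q_liver <- sum(organs$flow_Lh[organs$organ == "liver" | organs$portal == 1])
  clint_whole <- scale_clint(clint_cell, liver_mass,
                             physiology$liver_hepatocellularity,
                             physiology$liver_intracellular_fraction,
                             intracellular_correction)
  fu_blood <- fu / bp
  structure(list(
    clint_cellular = clint_cell,
    clint_whole_liver = as.numeric(clint_whole),
    fu_plasma = fu,
    fu_blood = fu_blood,
    hepatic_blood_flow = q_liver,
    hepatic_clearance = well_stirred_clearance(clint_whole, fu_blood, q_liver),
    renal_clearance = profile$renal_clearance,
    intracellular_correction = attr(clint_whole, "correction")
  ), class = "clearance_parameters")
}
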