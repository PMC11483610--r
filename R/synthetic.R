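#' Synthetic study data
#'
#' Generators for the two external data sets the original study consumed:
#' legacy in vivo rat PK observations (steady-state Cmax at several oral
#' doses with inter-animal noise) used for model qualification, and ex vivo
#' human-skin penetration/metabolism experiments used for dermal
#' calibration. Both store their generating ground truth so recovery can be
#' checked exactly. Noise is lognormal throughout (concentrations are
#' positive; variability is reported as a CV, default 30%).
#'
#' @name synthetic_data
NULL

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))  # mean-1 multiplicative noise
}

#' Generate pseudo-observed rat PK data
#'
#' Per-animal steady-state Cmax values at each dose level:
#' truth(dose) x perturbation x lognormal(1, cv).
#'
#' @param truth function(dose) returning the true Cmax (nM); typically a
#'   wrapper around the rat PBPK model, or an analytic stand-in in tests.
#' @param doses mg/kg dose levels (defaults to the legacy-study levels
#'   2.59, 6.46, 12.82).
#' @param perturbation multiplier applied to the truth (systematic model
#'   misspecification; 1 = none).
#' @param cv lognormal coefficient of variation between animals.
#' @param n_per_dose animals per dose group.
#' @param seed integer seed.
#' @return object of class `pseudo_observed_pk`: data.frame with `dose`,
#'   `animal`, `cmax`, plus the generating metadata.
#' @export
generate_observed_pk <- function(truth, doses = c(2.59, 6.46, 12.82),
                                 perturbation = 1, cv = 0.3, n_per_dose = 6,
                                 seed = 1L) {
  if (cv < 0) stop_domain("cv must be >= 0")
  set.seed(seed)
  truth_cmax <- vapply(doses, truth, numeric(1))
  obs <- do.call(rbind, lapply(seq_along(doses), function(i) {
    data.frame(dose = doses[i], animal = seq_len(n_per_dose),
               cmax = truth_cmax[i] * perturbation *
                 lognormal_noise(n_per_dose, cv))
  }))
  structure(list(observations = obs,
                 ground_truth = data.frame(dose = doses, cmax = truth_cmax),
                 perturbation = perturbation, cv = cv, seed = seed),
            class = "pseudo_observed_pk")
}

#' Generate pseudo ex vivo skin penetration/metabolism data
#'
#' Replicate delivered and metabolised fractions across an applied-dose
#' series, emulating the observed conjugation pattern: sulfate formation is
#' strictly linear in dose, glucuronide formation saturates above the
#' stated threshold (UDP-glucuronosyltransferase saturation at
#' >= 30 nmol/cm^2), so its per-dose yield declines.
#'
#' @param truth list with `delivered_fraction` and `metabolized_fraction`
#'   (fractions of applied dose at 24 h from the truth skin model).
#' @param doses applied doses, nmol/cm^2.
#' @param cv replicate-level lognormal CV.
#' @param n_replicates replicates per dose (>= 3).
#' @param seed integer seed.
#' @param saturation_threshold nmol/cm^2 above which glucuronidation
#'   saturates (incremental capacity drops to 30%).
#' @param sulfate_share share of metabolised chemical conjugated to sulfate.
#' @return object of class `pseudo_exvivo`: replicate table plus metadata.
#' @export
generate_exvivo <- function(truth, doses, cv = 0.3, n_replicates = 3,
                            seed = 1L, saturation_threshold = 30,
                            sulfate_share = 0.4) {
  assert_positive(doses, "doses")
  if (n_replicates < 3L) stop_domain("need >= 3 replicates")
  set.seed(seed)
  met_sat <- function(dose) {
    # glucuronide capacity saturates above the threshold
    pmin(dose, saturation_threshold) +
      0.3 * pmax(dose - saturation_threshold, 0)
  }
  rows <- do.call(rbind, lapply(doses, function(d) {
    sulfate <- truth$metabolized_fraction * sulfate_share * d
    gluc <- truth$metabolized_fraction * (1 - sulfate_share) * met_sat(d)
    data.frame(
      dose = d, replicate = seq_len(n_replicates),
      delivered_fraction = pmin(truth$delivered_fraction *
                                  lognormal_noise(n_replicates, cv), 1),
      metabolized_fraction = pmin((sulfate + gluc) / d *
                                    lognormal_noise(n_replicates, cv), 1),
      sulfate_nmol_cm2 = sulfate * lognormal_noise(n_replicates, cv),
      glucuronide_nmol_cm2 = gluc * lognormal_noise(n_replicates, cv))
  }))
  structure(list(replicates = rows, ground_truth = truth, cv = cv,
                 seed = seed, saturation_threshold = saturation_threshold),
            class = "pseudo_exvivo")
}
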