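#' Species physiology and virtual individuals
#'
#' Reference anatomies/physiologies for the rat and the European adult human,
#' assembled from packaged organ tables (volume fractions of body weight,
#' blood-flow fractions of cardiac output). Cardiac output follows the
#' allometric relation CO = 14.1 * BW^0.75 L/h, which reproduces both the
#' ~80 mL/min of a 0.23 kg rat and the ~5 L/min of a 60 kg adult.
#'
#' @name physiology
NULL

CO_ALLOMETRIC_LH_KG <- 14.1   # L/h per kg^0.75
HEPATOCELLULARITY <- 110e6    # cells per g liver
LIVER_INTRACELLULAR <- 0.67   # fraction of liver that is intracellular space

# gut geometry / transit used by the single-lumen oral absorption model
GUT_CONSTANTS <- list(
  rat = list(si_radius_cm = 0.18, si_transit_h = 1.5),
  human = list(si_radius_cm = 1.25, si_transit_h = 3.3)
)

build_physiology <- function(species, body_weight, age, height = NA_real_,
                             gfr, hematocrit, organ_file) {
  organs <- read_ref_csv("physiology", organ_file)
  co <- CO_ALLOMETRIC_LH_KG * body_weight^0.75
  organs$volume_L <- organs$volume_fraction * body_weight  # density ~ 1 kg/L
  organs$flow_Lh <- organs$flow_fraction * co
  blood_volume <- switch(species, rat = 0.074, human = 0.0771) * body_weight
  structure(list(
    species = species,
    body_weight = body_weight,
    age = age,
    height = height,
    gfr = gfr,
    cardiac_output = co,
    hematocrit = hematocrit,
    blood_volume = blood_volume,
    organs = organs,
    liver_hepatocellularity = HEPATOCELLULARITY,
    liver_intracellular_fraction = LIVER_INTRACELLULAR,
    gut = GUT_CONSTANTS[[species]]
  ), class = "species_physiology")
}

#' Reference rat physiology
#'
#' The mean Sprague-Dawley rat used throughout: body weight 0.23 kg, age 40
#' weeks, GFR 57 mL/min/100 g kidney.
#' @return a `species_physiology`.
#' @export
reference_rat <- function() {
  build_physiology("rat", body_weight = 0.23, age = 40, gfr = 57,
                   hematocrit = 0.46, organ_file = "rat_organs.csv")
}

#' Reference human physiology
#'
#' The European mean individual: age 30 y, body weight 60 kg, height 163 cm
#' (BMI 22.58 kg/m^2), body surface area 1.65 m^2, GFR 107.44 mL/min.
#' @return a `species_physiology`.
#' @export
reference_human <- function() {
  phys <- build_physiology("human", body_weight = 60, age = 30, height = 163,
                           gfr = 107.44, hematocrit = 0.45,
                           organ_file = "human_organs.csv")
  phys$body_surface_area <- 1.65  # m^2
  phys
}

#' @export
print.species_physiology <- function(x, ...) {
  cat("<species_physiology>", x$species,
      sprintf("BW %.3g kg, CO %.3g L/h, %d organs\n",
              x$body_weight, x$cardiac_output, nrow(x$organs)))
  invisible(x)
}

#' Population specification
#'
#' @param n number of individuals (>= 1).
#' @param weight_range length-2 numeric, kg.
#' @param age_range length-2 numeric (years; human only), or NULL.
#' @param seed integer seed making the sample reproducible.
#' @param scaling exponent policy: organ volumes scale linearly with body
#'   weight, flows/cardiac output/GFR with BW^`flow_exponent`.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n, weight_range, age_range = NULL, seed = 1L,
                            scaling = list(flow_exponent = 0.75)) {
  if (n < 1L) stop_domain("population size must be >= 1")
  if (n > 1L && diff(range(weight_range)) <= 0) {
    stop_domain("weight_range must be non-degenerate for n > 1")
  }
  structure(list(n = as.integer(n), weight_range = weight_range,
                 age_range = age_range, seed = as.integer(seed),
                 scaling = scaling), class = "population_spec")
}

#' Rescale a reference physiology to a given body weight
#'
#' Dependent scaling: organ volumes in proportion to body weight (constant
#' fractions); cardiac output, organ blood flows and GFR allometrically with
#' BW^0.75 by default.
#'
#' @param base reference `species_physiology`.
#' @param body_weight kg.
#' @param age optional age to record on the individual.
#' @param flow_exponent allometric exponent for flows (default 0.75).
#' @return a scaled `species_physiology`.
#' @export
scale_individual <- function(base, body_weight, age = base$age,
                             flow_exponent = 0.75) {
  assert_positive(body_weight, "body_weight")
  ind <- base
  wr <- body_weight / base$body_weight
  ind$body_weight <- body_weight
  ind$age <- age
  ind$organs$volume_L <- base$organs$volume_L * wr
  ind$blood_volume <- base$blood_volume * wr
  ind$cardiac_output <- base$cardiac_output * wr^flow_exponent
  ind$organs$flow_Lh <- base$organs$flow_Lh * wr^flow_exponent
  ind$gfr <- base$gfr * wr^flow_exponent
  ind
}

#' Sample a virtual population
#'
#' Body weight (and, for humans, age) are drawn uniformly within the stated
#' ranges -- the study design states only ranges -- and all dependent
#' anatomy/physiology is rescaled per [scale_individual()]. With `n = 1` the
#' base mean individual is returned unchanged.
#'
#' @param spec a [population_spec()].
#' @param base reference `species_physiology`.
#' @return list of `species_physiology` individuals.
#' @export
sample_population <- function(spec, base) {
  if (spec$n == 1L) return(list(base))
  set.seed(spec$seed)
  bw <- stats::runif(spec$n, spec$weight_range[1], spec$weight_range[2])
  ages <- if (!is.null(spec$age_range)) {
    stats::runif(spec$n, spec$age_range[1], spec$age_range[2])
  } else rep(base$age, spec$n)
  lapply(seq_len(spec$n), function(i) {
    scale_individual(base, bw[i], age = ages[i],
                     flow_exponent = spec$scaling$flow_exponent %||% 0.75)
  })
}
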