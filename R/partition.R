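#' Mechanistic tissue:plasma partition coefficients
#'
#' Implements the published Rodgers & Rowland scheme for acids, very weak
#' bases and neutrals, in which tissue affinity is the sum of distribution
#' into tissue water (with a Henderson-Hasselbalch ionisation correction
#' between intracellular pH 7.0 and plasma pH 7.4), partitioning of the
#' neutral species into neutral lipids and neutral phospholipids, and
#' association with extracellular albumin estimated from the plasma unbound
#' fraction. The tissue composition table is shipped as packaged reference
#' data (see `inst/extdata/physiology/tissue_composition.csv`).
#'
#' @param profile a [chemical_profile()].
#' @param physiology a [species_physiology] object providing the organ list.
#' @param species `"rat"` or `"human"` (selects fu and blood:plasma ratio).
#' @param fu optional override of the plasma unbound fraction (defaults to
#'   the profile's selected value for `species`).
#' @return object of class `partition_set` with one Kp per organ.
#' @export
tissue_partitions <- function(profile, physiology, species, fu = NULL) {
  comp <- tissue_composition_table()
  fu <- fu %||% as.numeric(select_fu(profile, species))
  assert_fraction(fu, "fu", open_lower = TRUE)
  bp <- profile$blood_plasma_ratio[[species]]
  organs <- physiology$organs$organ
  missing <- setdiff(organs, comp$tissue)
  if (length(missing)) {
    stop_domain("no tissue composition data for organ(s): ",
                paste(missing, collapse = ", "))
  }

  P <- 10^profile$log_pow
  Y <- ionisation_factor(profile$pka, ph = 7.4)  # plasma
  X <- ionisation_factor(profile$pka, ph = 7.0)  # intracellular water

  pl <- comp[comp$tissue == "plasma", ]
  lip_p <- (P * pl$f_nl + (0.3 * P + 0.7) * pl$f_np) / Y
  ka_pr_p <- max(0, 1 / fu - 1 - lip_p)  # albumin association, plasma

  kp <- vapply(organs, function(org) {
    tc <- comp[comp$tissue == org, ]
    kpu <- tc$f_ew + (X / Y) * tc$f_iw +
      (P * tc$f_nl + (0.3 * P + 0.7) * tc$f_np) / Y +
      ka_pr_p * tc$alb_ratio
    kpu * fu
  }, numeric(1))

  structure(list(
    chemical = profile$name,
    species = species,
    fu = fu,
    blood_plasma_ratio = bp,
    kp_by_organ = stats::setNames(kp, organs)
  ), class = "partition_set")
}

# Ionisation factor 1 + sum of charged-species ratios at a given pH.
# Handles neutrals (empty pka), mono-/diprotic acids and monoprotic bases.
ionisation_factor <- function(pka, ph) {
  if (length(pka) == 0L) return(1)
  types <- vapply(pka, function(p) p$type, "")
  vals <- vapply(pka, function(p) as.numeric(p$value), numeric(1))
  acids <- sort(vals[types == "acid"])
  bases <- sort(vals[types == "base"], decreasing = TRUE)
  f <- 1
  if (length(acids) >= 1L) f <- f + 10^(ph - acids[1])
  if (length(acids) >= 2L) f <- f + 10^(2 * ph - acids[1] - acids[2])
  if (length(bases) >= 1L) f <- f + 10^(bases[1] - ph)
  if (length(bases) >= 2L) f <- f + 10^(bases[1] + bases[2] - 2 * ph)
  f
}

tissue_composition_table <- function() {
  read_ref_csv("physiology", "tissue_composition.csv")
}

#' @export
print.partition_set <- function(x, ...) {
  cat("<partition_set>", x$chemical, "/", x$species,
      sprintf("(fu %.4f, B:P %.2f)\n", x$fu, x$blood_plasma_ratio))
  print(round(x$kp_by_organ, 3))
  invisible(x)
}
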