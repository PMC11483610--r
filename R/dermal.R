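#' Discretised multilayer skin slab
#'
#' One-dimensional finite-volume grid over stratum corneum, viable epidermis
#' and dermis, with a well-mixed vehicle film on top and a receptor/blood
#' sink below. Each layer carries its own diffusivity and layer:water
#' partition coefficient; interface conditions impose continuity of the
#' aqueous-phase activity (concentration-ratio jumps) and of flux.
#'
#' Transfer into the systemic circulation occurs from all viable sub-layers
#' (epidermis + dermis) as a permeability-limited capillary uptake acting on
#' the local aqueous (unbound) concentration, plus the diffusive flux across
#' the bottom boundary.
#'
#' @param thickness_um named numeric: layer thicknesses in um
#'   (defaults 43 / 60 / 1400 for SC, viable epidermis, dermis).
#' @param nodes named integer: finite-volume cells per layer (>= 20 in SC).
#' @param diffusivity named numeric, cm^2/h, per layer (effective, referenced
#'   to the layer-phase concentration).
#' @param partition named numeric, layer:water partition coefficients.
#' @param sc_scale multiplier on the SC diffusivity (the delivery-calibration
#'   handle; 1 = uncalibrated).
#' @param capillary_exchange first-order capillary uptake coefficient on the
#'   aqueous concentration in viable layers, 1/h.
#' @param temperature_C,wind_cm_s surface conditions retained for fidelity;
#'   no evaporative loss is modelled for these non-volatile chemicals.
#' @return object of class `skin_grid`.
#' @export
skin_grid <- function(thickness_um = c(sc = 43, ve = 60, de = 1400),
                      nodes = c(sc = 22L, ve = 12L, de = 30L),
                      diffusivity = c(sc = 3.6e-6, ve = 1e-4, de = 1e-4),
                      partition = c(sc = 100, ve = 30, de = 30),
                      sc_scale = 1,
                      capillary_exchange = 1.0,
                      temperature_C = 30, wind_cm_s = 16.8) {
  stopifnot(all(thickness_um > 0), all(nodes >= 1L))
  if (nodes[["sc"]] < 20L) {
    stop_domain("the stratum corneum must be resolved with >= 20 nodes")
  }
  assert_positive(diffusivity, "diffusivity")
  assert_positive(partition, "partition")
  nodes <- stats::setNames(as.integer(nodes), names(nodes))
  structure(list(thickness_um = thickness_um, nodes = nodes,
                 diffusivity = diffusivity, partition = partition,
                 sc_scale = sc_scale, capillary_exchange = capillary_exchange,
                 temperature_C = temperature_C, wind_cm_s = wind_cm_s),
            class = "skin_grid")
}

#' Default skin grid for a chemical
#'
#' Initial-guess transport parameters from the chemical's physicochemistry:
#' SC:water partitioning from lipophilicity (K = 10^(0.69 logP)), an
#' MW-scaled SC diffusivity, and viable-layer properties from aqueous
#' diffusion retarded by tissue binding (the Rodgers-Rowland skin affinity).
#' Final SC transport always comes from calibration against the ex vivo
#' delivery target ([calibrate_delivery()]).
#'
#' @param chemical a [chemical_profile()].
#' @param species species for the binding estimate (default human).
#' @param ... overrides passed on to [skin_grid()].
#' @return a `skin_grid`.
#' @export
default_skin_grid <- function(chemical, species = "human", ...) {
  k_sc <- 10^(0.69 * chemical$log_pow)
  # aqueous diffusivity ~ 8.6e-5 MW^-1/3 cm^2/h, tortuosity ~ 1/3 in tissue
  d_aq <- 8.6e-5 * chemical$molecular_weight^(-1 / 3) * 3600 / 3
  kpu_skin <- skin_affinity(chemical, species)
  d_visc <- d_aq / kpu_skin  # effective, total-concentration basis
  d_sc <- 3.6e-6 * exp(-0.005 * (chemical$molecular_weight - 250))
  skin_grid(diffusivity = c(sc = d_sc, ve = d_visc, de = d_visc),
            partition = c(sc = k_sc, ve = kpu_skin, de = kpu_skin), ...)
}

# Tissue:water affinity of skin (unbound-referenced Kpu from the
# Rodgers-Rowland scheme); used as the viable-layer partition coefficient.
skin_affinity <- function(chemical, species = "human") {
  fu <- as.numeric(select_fu(chemical, species))
  phys <- if (species == "human") reference_human() else reference_rat()
  ps <- tissue_partitions(chemical, phys, species, fu = fu)
  unname(ps$kp_by_organ["skin"] / fu)
}

#' First-pass metabolism specification for the viable skin layers
#'
#' @param target_metabolized_fraction fraction of dermally penetrated dose
#'   metabolised before reaching the circulation (genistein 0.70, daidzein
#'   0.36).
#' @param k_met calibrated first-order rate (1/h) applied homogeneously in
#'   viable epidermis + dermis.
#' @return object of class `first_pass_spec`.
#' @export
first_pass_spec <- function(target_metabolized_fraction, k_met = 0) {
  if (target_metabolized_fraction < 0 || target_metabolized_fraction >= 1) {
    stop_domain("target_metabolized_fraction must be in [0, 1)")
  }
  if (k_met < 0) stop_domain("k_met must be >= 0")
  structure(list(target_metabolized_fraction = target_metabolized_fraction,
                 k_met = k_met), class = "first_pass_spec")
}

#' Maximum steady-state flux across the stratum corneum
#'
#' Jmax = (D / h) * K_SC/w * C_w,sat: the Fickian maximum flux from a
#' saturated aqueous vehicle. Unit chain: D [cm^2/h] / h [um -> cm, x 1e-4]
#' gives cm/h; times K [unitless] and C_w,sat [mg/mL = mg/cm^3] gives
#' mg/cm^2/h; x 1e6 converts to ng/cm^2/h.
#'
#' @param D SC diffusivity, cm^2/h.
#' @param h SC thickness, um.
#' @param k_sc_w SC:water partition coefficient.
#' @param c_w_sat aqueous solubility, mg/mL.
#' @return maximum flux, ng/cm^2/h.
#' @export
jmax <- function(D, h, k_sc_w, c_w_sat) {
  assert_positive(D, "D"); assert_positive(h, "h")
  assert_positive(k_sc_w, "k_sc_w"); assert_positive(c_w_sat, "c_w_sat")
  (D / (h * 1e-4)) * k_sc_w * c_w_sat * 1e6
}

# Assemble the constant linear operator dM/dt = A M for the discretised
# skin system. State ordering: [vehicle, node_1..node_n, cum_sys, cum_met].
# Columns of A sum to zero, so the scheme conserves mass to round-off.
skin_operator <- function(grid, first_pass, vehicle_thickness_cm,
                          vehicle_partition = 1) {
  th_cm <- grid$thickness_um * 1e-4
  nn <- grid$nodes
  layer <- rep(names(nn), nn)
  dx <- rep(th_cm / nn, nn)
  D <- rep(grid$diffusivity, nn)
  D[layer == "sc"] <- D[layer == "sc"] * grid$sc_scale
  K <- rep(grid$partition, nn)
  n <- length(dx)

  w <- dx * K                      # cell capacity: M = w * a
  w_v <- vehicle_thickness_cm * vehicle_partition
  dk <- D * K                      # conductivity on activity gradient

  # inter-cell conductances (harmonic); vehicle side is well mixed
  g <- 1 / (dx[-n] / (2 * dk[-n]) + dx[-1] / (2 * dk[-1]))
  g_v <- 2 * dk[1] / dx[1]
  g_b <- 2 * dk[n] / dx[n]

  viable <- layer %in% c("ve", "de")
  k_b <- ifelse(viable, grid$capillary_exchange / K, 0)
  k_m <- ifelse(viable, first_pass$k_met, 0)

  nstate <- n + 3L
  A <- matrix(0, nstate, nstate)
  iv <- 1L; isk <- 2L:(n + 1L); isys <- n + 2L; imet <- n + 3L
  wa <- c(w_v, w)  # capacities for [vehicle, nodes]

  add_exchange <- function(A, i, j, gij) {
    # flux j -> i proportional to (a_j - a_i)
    A[i, j] <- A[i, j] + gij / wa[j]
    A[i, i] <- A[i, i] - gij / wa[i]
    A[j, i] <- A[j, i] + gij / wa[i]
    A[j, j] <- A[j, j] - gij / wa[j]
    A
  }
  A <- add_exchange(A, iv, isk[1], g_v)
  for (j in seq_len(n - 1)) A <- add_exchange(A, isk[j], isk[j + 1], g[j])

  # bottom boundary: diffusive flux to the receptor/blood sink (a = 0)
  A[isk[n], isk[n]] <- A[isk[n], isk[n]] - g_b / wa[isk[n]]
  A[isys, isk[n]] <- A[isys, isk[n]] + g_b / wa[isk[n]]

  # distributed capillary uptake and first-order metabolism (viable layers)
  for (j in which(k_b > 0)) {
    A[isk[j], isk[j]] <- A[isk[j], isk[j]] - k_b[j]
    A[isys, isk[j]] <- A[isys, isk[j]] + k_b[j]
  }
  for (j in which(k_m > 0)) {
    A[isk[j], isk[j]] <- A[isk[j], isk[j]] - k_m[j]
    A[imet, isk[j]] <- A[imet, isk[j]] + k_m[j]
  }

  list(A = A, n = n, layer = layer, dx = dx, K = K, wa = wa,
       iv = iv, isk = isk, isys = isys, imet = imet,
       g_b = g_b, k_b = k_b)
}

#' Solve the skin diffusion-metabolism system
#'
#' Crank-Nicolson time stepping (implicit, unconditionally stable,
#' second-order) of the finite-volume system, with once-daily vehicle
#' replenishment for multi-day exposures. Mass balance (vehicle + skin +
#' systemic + metabolised = applied) holds to round-off by construction of
#' the conservative operator and is verified on output.
#'
#' @param grid a [skin_grid()].
#' @param exposure a [dermal_scenario()].
#' @param first_pass a [first_pass_spec()].
#' @param duration_h simulated time, h (default 24 x scenario days).
#' @param dt_h time step, h.
#' @param out_every_h output sampling interval, h.
#' @param washoff remove the residual vehicle film and the stratum-corneum
#'   reservoir at each reapplication? Default TRUE: daily washing removes
#'   leftover product and the surface reservoir (chemical remaining in the
#'   SC at the end of an exposure window is conventionally counted as
#'   unabsorbed); chemical in the viable layers is unaffected.
#' @return object of class `skin_result`: time series of vehicle/layer
#'   contents (ug/cm^2), cumulative systemic and metabolised amounts, the
#'   systemic influx rate (ug/cm^2/h), and the mass-balance error.
#' @export
solve_skin <- function(grid, exposure, first_pass, duration_h = NULL,
                       dt_h = 0.01, out_every_h = 0.1, washoff = TRUE) {
  duration_h <- duration_h %||% (24 * exposure$duration_days)
  # vehicle film thickness from the applied product (density ~ 1 g/cm^3)
  vehicle_g_cm2 <- exposure$product_amount / exposure$area
  h_v <- max(vehicle_g_cm2, 1e-6)  # cm
  op <- skin_operator(grid, first_pass, h_v)
  ns <- nrow(op$A)

  nstep_out <- max(1L, round(out_every_h / dt_h))
  nt <- ceiling(duration_h / dt_h)
  dt_h <- duration_h / nt

  ident <- diag(ns)
  prop_lhs <- solve(ident - dt_h / 2 * op$A)
  prop <- prop_lhs %*% (ident + dt_h / 2 * op$A)

  load <- exposure$chemical_load  # ug/cm^2 per application
  m <- numeric(ns)
  m[op$iv] <- load
  applied <- load

  keep <- unique(c(seq(0L, nt, by = nstep_out), nt))
  times <- numeric(length(keep))
  states <- matrix(0, length(keep), ns)
  states[1, ] <- m
  applied_t <- numeric(length(keep))
  applied_t[1] <- applied
  washed <- 0
  washed_t <- numeric(length(keep))
  ki <- 2L

  reapply <- 24 * seq_len(max(0, exposure$duration_days - 1))
  for (s in seq_len(nt)) {
    t_now <- s * dt_h
    m <- drop(prop %*% m)
    if (length(reapply) && any(abs(reapply - t_now) < dt_h / 2)) {
      if (washoff) {
        i_sc <- op$isk[op$layer == "sc"]
        washed <- washed + m[op$iv] + sum(m[i_sc])
        m[i_sc] <- 0
        m[op$iv] <- load
      } else {
        m[op$iv] <- m[op$iv] + load
      }
      applied <- applied + load
    }
    if (s %% nstep_out == 0L || s == nt) {
      times[ki] <- t_now
      states[ki, ] <- m
      applied_t[ki] <- applied
      washed_t[ki] <- washed
      ki <- ki + 1L
    }
  }

  sc_mass <- rowSums(states[, op$isk[op$layer == "sc"], drop = FALSE])
  ve_mass <- rowSums(states[, op$isk[op$layer == "ve"], drop = FALSE])
  de_mass <- rowSums(states[, op$isk[op$layer == "de"], drop = FALSE])
  a_nodes <- sweep(states[, op$isk, drop = FALSE], 2, op$wa[op$isk], "/")
  influx <- a_nodes %*% ifelse(op$k_b > 0, op$k_b * op$wa[op$isk], 0) +
    a_nodes[, op$n] * op$g_b
  total <- rowSums(states) + washed_t
  mb_err <- max(abs(total - applied_t) / pmax(applied_t, 1e-12))
  if (mb_err > 1e-6) {
    stop("skin mass balance violated (", signif(mb_err, 3), ")", call. = FALSE)
  }

  structure(list(
    time = times, vehicle = states[, op$iv],
    sc = sc_mass, epidermis = ve_mass, dermis = de_mass,
    systemic = states[, op$isys], metabolized = states[, op$imet],
    influx = drop(influx),               # ug/cm^2/h into the circulation
    washed_off = washed_t,
    applied = applied_t, node_states = states, operator = op,
    mass_balance_error = mb_err
  ), class = "skin_result")
}

#' Dermal delivery as percent of the applied dose
#'
#' The delivery definition used for calibration and reporting: the fraction
#' of applied dose recovered in the viable epidermis, dermis and receptor
#' (systemic) compartments at the stated time -- stratum corneum content and
#' metabolised chemical are excluded.
#'
#' @param result a [solve_skin()] result.
#' @param at_time_h evaluation time (default 24 h).
#' @return percent of applied dose.
#' @export
dermal_delivery_fraction <- function(result, at_time_h = 24) {
  i <- which.min(abs(result$time - at_time_h))
  if (result$applied[i] <= 0) return(0)
  100 * (result$epidermis[i] + result$dermis[i] + result$systemic[i]) /
    result$applied[i]
}

#' Calibrate the cutaneous first-pass metabolism rate
#'
#' Monotone bisection on k_met so that the cumulative metabolised fraction of
#' penetrated chemical, metabolised / (metabolised + systemic) at 24 h,
#' matches the target within 1% absolute.
#'
#' @param grid a [skin_grid()].
#' @param exposure a [dermal_scenario()].
#' @param target a [first_pass_spec()] holding the target fraction.
#' @param tol absolute tolerance on the achieved fraction.
#' @param bracket search interval for k_met, 1/h.
#' @param dt_h time step passed to the solver.
#' @return calibrated k_met (1/h) with attribute `achieved`.
#' @export
calibrate_first_pass <- function(grid, exposure, target, tol = 0.005,
                                 bracket = c(1e-6, 1e3), dt_h = 0.02) {
  tgt <- target$target_metabolized_fraction
  if (tgt == 0) return(structure(0, achieved = 0))
  met_frac <- function(k) {
    res <- solve_skin(grid, exposure, first_pass_spec(tgt, k_met = k),
                      duration_h = 24, dt_h = dt_h)
    i <- length(res$time)
    pen <- res$metabolized[i] + res$systemic[i]
    if (pen <= 0) return(0)
    res$metabolized[i] / pen
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- met_frac(lo); f_hi <- met_frac(hi)
  if (tgt < f_lo || tgt > f_hi) {
    stop("first-pass target ", tgt, " outside achievable range [",
         signif(f_lo, 3), ", ", signif(f_hi, 3), "]", call. = FALSE)
  }
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    f_mid <- met_frac(mid)
    if (abs(f_mid - tgt) < tol) {
      return(structure(mid, achieved = f_mid))
    }
    if (f_mid < tgt) lo <- mid else hi <- mid
  }
  structure(mid, achieved = f_mid)
}

#' Calibrate the stratum-corneum transport to an observed delivery
#'
#' Scales the SC diffusivity (log-space bisection) so that the 24-h dermal
#' delivery fraction matches the target within the stated absolute
#' tolerance. The scaling factor lumps the SC transport proper and the
#' thermodynamic activity of the chemical in the formulation vehicle.
#'
#' @param grid a [skin_grid()].
#' @param exposure a [dermal_scenario()].
#' @param target_fraction target delivered fraction of applied dose (0-1).
#' @param first_pass a [first_pass_spec()] applied during calibration.
#' @param tol absolute tolerance on the delivered fraction.
#' @param bracket search interval for the SC scaling factor.
#' @param dt_h solver time step.
#' @return calibrated `skin_grid` with attributes `sc_scale` and `achieved`.
#' @export
calibrate_delivery <- function(grid, exposure, target_fraction, first_pass,
                               tol = 0.002, bracket = c(1e-8, 1e4),
                               dt_h = 0.02) {
  assert_fraction(target_fraction, "target_fraction")
  delivered <- function(scale) {
    g <- grid; g$sc_scale <- grid$sc_scale * scale
    res <- solve_skin(g, exposure, first_pass, duration_h = 24, dt_h = dt_h)
    dermal_delivery_fraction(res) / 100
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- delivered(lo); f_hi <- delivered(hi)
  if (target_fraction < f_lo || target_fraction > f_hi) {
    stop("delivery target ", target_fraction, " outside achievable range [",
         signif(f_lo, 3), ", ", signif(f_hi, 3), "]", call. = FALSE)
  }
  scale <- NA_real_
  for (it in 1:60) {
    scale <- sqrt(lo * hi)
    f <- delivered(scale)
    if (abs(f - target_fraction) < tol) break
    if (f < target_fraction) lo <- scale else hi <- scale
  }
  out <- grid
  out$sc_scale <- grid$sc_scale * scale
  attr(out, "scale_factor") <- scale
  attr(out, "achieved") <- f
  out
}

#' Jointly calibrate a chemical's dermal module
#'
#' Alternates delivery calibration (SC transport) and first-pass calibration
#' (k_met) until both 24-h endpoints are met; the two couple only weakly
#' (metabolism removes mass from the viable layers), so a few rounds
#' suffice.
#'
#' @param chemical a [chemical_profile()].
#' @param exposure a [dermal_scenario()].
#' @param delivery_target delivered fraction target; defaults to the
#'   profile's packaged `dermal_delivery_target`.
#' @param rounds alternation rounds.
#' @param dt_h solver time step used during calibration.
#' @return list with the calibrated `grid` and `first_pass` objects plus the
#'   achieved endpoints.
#' @export
calibrate_dermal_module <- function(chemical, exposure,
                                    delivery_target =
                                      chemical$dermal_delivery_target,
                                    rounds = 3, dt_h = 0.02) {
  grid <- default_skin_grid(chemical)
  fp_target <- chemical$skin_first_pass_fraction
  fp <- first_pass_spec(fp_target, k_met = 0)
  for (r in seq_len(rounds)) {
    grid <- calibrate_delivery(grid, exposure, delivery_target, fp,
                               dt_h = dt_h)
    if (fp_target > 0) {
      k <- calibrate_first_pass(grid, exposure,
                                first_pass_spec(fp_target), dt_h = dt_h)
      fp <- first_pass_spec(fp_target, k_met = as.numeric(k))
    }
  }
  final <- solve_skin(grid, exposure, fp, duration_h = 24, dt_h = dt_h)
  i <- length(final$time)
  pen <- final$metabolized[i] + final$systemic[i]
  list(grid = grid, first_pass = fp,
       delivery_pct = dermal_delivery_fraction(final),
       metabolized_fraction = if (pen > 0) final$metabolized[i] / pen else 0)
}

#' Systemic influx forcing from a solved skin module
#'
#' Converts the per-area influx of a [solve_skin()] result into a whole-body
#' molar influx function of time for [build_model()].
#'
#' @param skin_result a [solve_skin()] result.
#' @param area exposed area, cm^2.
#' @param molecular_weight g/mol.
#' @return function(t_h) returning umol/h.
#' @export
build_dermal_influx <- function(skin_result, area, molecular_weight) {
  rate_umol_h <- skin_result$influx * area / molecular_weight  # ug/h / (ug/umol)
  f <- stats::approxfun(skin_result$time, rate_umol_h, rule = 2)
  function(t) f(t)
}
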