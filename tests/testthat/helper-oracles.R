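# Independent oracles used across the suite. These deliberately re-derive
# results through separate code paths (scalar arithmetic, closed forms)
# rather than calling the package internals they check.

# --- Rodgers-Rowland partitioning, scalar re-implementation ----------------
# Kpu = f_EW + (X/Y) f_IW + (P f_NL + (0.3P + 0.7) f_NP)/Y + KaPR * alb_ratio
# for a monoprotic or diprotic acid (or neutral); Kp = Kpu * fu.
oracle_rr_kp <- function(tissue_row, plasma_row, log_p, pka_acids, fu) {
  P <- 10^log_p
  ion <- function(ph) {
    f <- 1
    if (length(pka_acids) >= 1) f <- f + 10^(ph - pka_acids[1])
    if (length(pka_acids) >= 2) f <- f + 10^(2 * ph - pka_acids[1] - pka_acids[2])
    f
  }
  Y <- ion(7.4); X <- ion(7.0)
  lip <- function(r) (P * r$f_nl + (0.3 * P + 0.7) * r$f_np) / Y
  ka_pr <- max(0, 1 / fu - 1 - lip(plasma_row))
  kpu <- tissue_row$f_ew + (X / Y) * tissue_row$f_iw + lip(tissue_row) +
    ka_pr * tissue_row$alb_ratio
  kpu * fu
}

rr_composition <- function() {
  read.csv(system.file("extdata", "physiology", "tissue_composition.csv",
                       package = "isopbpk"), comment.char = "#")
}

# --- one-compartment oral disposition ---------------------------------------
# Closed-form concentration for the linear chain
# undissolved -k1-> dissolved -ka-> body -ke-> out (distinct rates).
oracle_one_compartment <- function(t, dose, V, ka, CL, k_diss = Inf) {
  ke <- CL / V
  if (!is.finite(k_diss)) {
    return(dose / V * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t)))
  }
  lam <- c(k_diss, ka, ke)
  terms <- sapply(seq_along(lam), function(i) {
    exp(-lam[i] * t) / prod(lam[-i] - lam[i])
  })
  dose / V * k_diss * ka * rowSums(terms)
}

# --- steady-state flux across a homogeneous membrane -----------------------
oracle_slab_flux <- function(D, K, a_donor, L) D * K * a_donor / L

# --- shared fixtures -------------------------------------------------------
genistein <- load_chemical("genistein")
daidzein <- load_chemical("daidzein")
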