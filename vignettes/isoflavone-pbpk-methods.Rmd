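---
title: "Bottom-up PBPK models for genistein and daidzein: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up PBPK models for genistein and daidzein: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`isopbpk` implements a bottom-up, animal-free workflow for estimating
internal exposure to the isoflavones genistein and daidzein: a rat oral
whole-body PBPK model parameterised purely from in vitro ADME measurements,
its read-across conversion to daidzein, human conversion with a dermal
absorption module for body-lotion exposure, virtual-population simulation,
and the decision-layer calculations (sensitivity, margin of internal
exposure, reverse dosimetry) used in next-generation risk assessment (NGRA).
This vignette explains the model, its assumptions, the parameters that
matter, and the design choices made where the problem was genuinely open.

## Whole-body model

The body is a set of perfusion-limited compartments — adipose, bone, brain,
gut, heart, kidney, liver, lung, muscle, skin, spleen, plus arterial and
venous blood — linked by blood flow. Each organ obeys

$$\frac{dA_i}{dt} = Q_i\left(C_{art} - \frac{A_i/V_i}{K_{p,i}/BP}\right),$$

with $K_{p,i}$ the tissue:plasma partition coefficient and $BP$ the
blood:plasma ratio. The lung sits in series with the total cardiac output;
gut and spleen drain portally into the liver; cardiac output not assigned to
a named organ returns through an arteriovenous shunt, so flows always sum to
the cardiac output exactly. Organ volume fractions and flow fractions are
packaged reference tables (Brown et al. 1997-style compilations for the rat;
ICRP-style values scaled to the 60 kg European adult), and cardiac output
follows $CO = 14.1\,BW^{0.75}$ L/h, which reproduces both the ~80 mL/min of
a 0.23 kg rat and the ~5 L/min of a 60 kg adult.

Unbound plasma concentration is $f_u \times$ total (linear binding); there is
no saturable plasma binding, no transporter kinetics (the measured Caco-2
efflux ratio is 1.02, i.e. no active efflux), no enterohepatic
recirculation, and no metabolite kinetics — conjugation is an elimination
sink, which is appropriate because the measured endpoints are parent-only.

## Tissue partitioning

`tissue_partitions()` implements the published Rodgers & Rowland scheme for
acids, very weak bases and neutrals. For a monoprotic weak acid (genistein,
pKa 7.25) or diprotic acid (daidzein, pKa 7.51 and 9.47):

$$K_{pu} = f_{EW} + \frac{X}{Y} f_{IW}
  + \frac{P f_{NL} + (0.3P + 0.7) f_{NP}}{Y}
  + K_A[PR]_P \cdot r_{alb},$$

where $X$ and $Y$ are the Henderson–Hasselbalch ionisation factors at
intracellular pH 7.0 and plasma pH 7.4, $P = 10^{\log P_{ow}}$, and the
albumin association constant is recovered from the measured plasma unbound
fraction. $K_p = K_{pu} f_u$. The tissue-composition fractions
($f_{EW}, f_{IW}, f_{NL}, f_{NP}$, albumin ratios) ship as a packaged CSV
transcribed from the published compilations; the same fractional composition
is used for rat and human, the usual practice where species-specific
fractions are unavailable. The test suite checks the implementation against
an independent scalar re-derivation and against closed-form limits (a fully
unbound, non-ionised, lipid-free probe partitions near unity into watery
tissues; adipose affinity is monotone in log P).

## IVIVE of hepatic clearance

Hepatocyte intrinsic clearance (µL/min/10⁶ cells) is scaled to the whole
liver with hepatocellularity 110·10⁶ cells/g and the liver mass of the
individual, then combined with hepatic blood flow and blood-referenced
unbound fraction ($f_{u,B} = f_u / BP$) in the well-stirred model:

$$CL_h = \frac{Q_h \, f_{u,B} \, CL_{int}}{Q_h + f_{u,B} \, CL_{int}}.$$

The role of the liver's 67% intracellular volume fraction in the scaling is
a documented convention rather than a published formula: by default the
cellular rate is multiplied by 0.67 when forming the whole-liver intrinsic
clearance, with an explicit switch (`intracellular_correction`) and the
applied factor recorded on the result, so the ambiguity is exposed rather
than buried. Renal clearance is fixed at 0 L/h for both chemicals and
species (the parent compounds are not renally excreted in the data the
models are built on). Effective intestinal permeability comes from Caco-2
Papp through a two-parameter log-affine hook whose packaged coefficients
reproduce the two known (Papp, Peff) anchor pairs exactly; the underlying
regression is proprietary, so only its observable anchors are claimed.

## Oral absorption

The oral dose enters a single gut-lumen compartment as undissolved
suspension. Dissolution follows a Weibull profile (default t50 = 250 min,
shape 0.92, no lag) implemented as its time-varying hazard, with the clock
restarting at each daily dose (carry-over of undissolved material across
doses is negligible at these transit rates). The hazard is capped at 50/h —
sub-minute dissolution is treated as instantaneous — which removes the
integrable singularity of the shape < 1 hazard at the dosing instant and
keeps the ODE system benign. Dissolved drug is absorbed into the portal
inflow at $k_a = 2 P_{eff} / r$ (plug-flow relation; packaged rat
small-intestine radius 0.18 cm), and both dissolved and undissolved material
leave the absorptive segment with a first-order transit rate corresponding
to the 1.5 h rat small-intestinal transit time. There is no segmented GI
tract: the single-lumen structure is the simplest one consistent with a
Peff-level description of absorption. With the default dissolution and
transit constants about 15–20% of a dose is absorbed, which is the dominant
driver of oral bioavailability here; the absorptive-window constants are
reference values, not fitted quantities.

## Dermal module

The exposed skin is a one-dimensional three-layer slab — stratum corneum
(43 µm, 22 nodes), viable epidermis (60 µm, 12 nodes), dermis (1400 µm, 30
nodes) — beneath a well-mixed vehicle film whose thickness follows from the
applied product (0.5 mg/cm² of lotion ≈ 5 µm). Within each layer transport
is Fickian; at interfaces the aqueous-phase activity $a = C/K$ is
continuous (a concentration-ratio jump) and flux is conserved, implemented
with finite-volume harmonic conductances. The discrete operator is linear
and conservative by construction (its columns sum to zero across the
vehicle, nodes, cumulative-systemic and cumulative-metabolised states), so
mass balance holds to round-off; time stepping is Crank–Nicolson (implicit,
unconditionally stable, second order) with the propagator factorised once
per solve. Surface temperature (30 °C) and wind speed (16.8 cm/s) are
retained as scenario metadata but drive no loss term: both chemicals have
vapor pressures around 10⁻⁹–10⁻¹⁰ mmHg, so evaporation is a no-op.

Three processes remove chemical from the viable layers:

* **diffusion to the basal boundary**, a receptor/blood sink;
* **capillary uptake**, first-order in the local aqueous (unbound)
  concentration with exchange coefficient `capillary_exchange` = 1.0/h.
  This represents permeability-limited transfer across the dermal capillary
  wall (PS on the order of 1 mL/h per mL tissue). The stratum corneum is
  avascular and carries no uptake term. This coefficient is the one
  structural dermal parameter with no measured anchor; it is a packaged
  default, applied identically to both chemicals;
* **first-pass metabolism**, first-order with rate $k_{met}$ homogeneous
  over viable epidermis + dermis, representing cutaneous sulfation and
  glucuronidation (linearised — the conjugating enzymes are unsaturated at
  the 1 µg/cm² use concentration; saturation of glucuronidation is only
  emulated by the synthetic ex vivo generator, above 30 nmol/cm²).

Two scalar calibrations anchor the module to fresh-skin ex vivo
measurements, alternated until both endpoints are met
(`calibrate_dermal_module()`):

1. a multiplier on the SC diffusivity such that the 24-h *dermal delivery*
   — the fraction of applied dose recovered in viable epidermis + dermis +
   systemic circulation, excluding SC content and metabolised chemical —
   matches the target (12% genistein, 20% daidzein; these sit within one
   SD of the ex vivo means of 7.2% and 13.5%, and are the packaged default
   targets). The factor lumps SC transport proper with the thermodynamic
   activity of the chemical in the lotion vehicle, which is why the vehicle
   partition coefficient can be left at 1;
2. $k_{met}$ such that metabolised/(metabolised + systemic) over 24 h
   equals the first-pass fraction (70% genistein, 36% daidzein; the ex vivo
   range for genistein extends to 90% and is exposed to the uncertainty
   analysis).

Both calibrations are monotone scalar searches (log-space bisection) with
stated absolute tolerances, and parameter-recovery on synthetic targets is
part of the test suite.

The maximum-flux convenience `jmax()` uses the Fickian form
$J_{max} = (D/h) K_{SC/w} C_{w}^{sat}$ — the product of the SC permeability
coefficient and the saturated aqueous concentration. (A literal product
$D\,h\,K\,C$ is dimensionally not a flux; the division by the SC thickness
is the standard reading.)

At each daily reapplication the residual vehicle film *and* the SC
reservoir are removed and a fresh dose applied (`washoff = TRUE`). This is
the consumer-use reading of repeated application: product is washed off or
rubbed away between applications, and chemical still residing in the SC at
the end of an exposure window is conventionally counted as not
systemically available (the same convention under which the delivery
endpoint excludes SC content). Without it the SC reservoir — which holds
most of each finite dose — would feed the viable skin indefinitely and
repeated-dose plasma levels would grow without bound, contrary to the
near-identical single- and repeated-dose maxima this exposure scenario is
known to produce. Chemical already in the viable layers is untouched by
washing, so a genuine viable-skin depot still accumulates modestly across
days.

The skin module is coupled to the whole-body model one-way: the solved
systemic influx (distributed capillary uptake + basal flux, scaled by the
exposed area) forces the venous blood compartment. Back-diffusion from
blood into skin is negligible here — plasma concentrations are in the nM
range against µM-scale skin-depot concentrations — and one-way coupling
keeps the PDE solve independent of the individual, so a population run
shares a single calibrated skin solution.

## Virtual populations and uncertainty

Populations sample body weight uniformly within the stated design ranges
(rat 0.185–0.275 kg; human 45–100 kg with ages 16–70), since only ranges
are stated. Organ volumes scale linearly with body weight; cardiac output,
organ flows and GFR scale with $BW^{0.75}$. Chemical-specific uncertainty
is sampled per individual: the plasma unbound fraction from the candidate
literature values (four candidates for rat genistein — which of them the
original modelling used is not stated, so the default is the first-listed
measured value, 2.7%, and the uncertainty analysis ranges over all four),
and intrinsic clearance and the Weibull formulation parameters from normal
distributions with a 30% CV truncated at 20% of the mean. All draws derive
from a single seed taken up front, so population results are bit-identical
across runs. Population summaries report the arithmetic mean, geometric
mean and empirical 5th/95th percentiles; the geometric mean is the central
estimate quoted for population maxima, matching the statistic used for the
population concentration profiles this design emulates (the reference
population interval 12.4–61.5 nM around a centre of 24.1 nM is
geometrically, not arithmetically, centred).

Local sensitivity (`local_sensitivity()`) uses normalised coefficients
$S = (\Delta PK/PK)/(\Delta p/p)$ averaged over ±10/20/30% perturbations,
classified high (|S| ≥ 0.5), medium (0.2–0.5), low (0.1–0.2) or negligible.
Parameter-uncertainty spreads are categorised high/medium/low at factor
bands of ≥2, 0.3–2 and ≤0.3.

## Reverse dosimetry and the decision layer

`loec_to_noec()` derives the in vitro point of departure by dividing the
LOEC by 3. `reverse_dosimetry()` inverts the exposure model by log-space
bisection on the external dose after verifying monotonicity, to 1% relative
tolerance on the achieved Cmax, and returns the forward-simulated Cmax for a
roundtrip check. The internal dose metric defaults to the *unbound* Cmax —
the unbound fraction is the biologically active species, and the in vitro
PoD is a free concentration in medium — with the total-Cmax alternative one
flag away; both are reported because which metric produced the published
external dose is not stated. `moie()` reports the margin of internal
exposure both ways (exposure/PoD and PoD/exposure).

## Synthetic study data

`generate_observed_pk()` emulates the legacy steady-state rat PK
observations used for qualification: per-animal Cmax values at 2.59, 6.46
and 12.82 mg/kg, formed as truth × systematic perturbation × lognormal
noise (default CV 30%; lognormal because concentrations are positive and
variability is reported as CVs). `generate_exvivo()` emulates the fresh-skin
experiments: replicate delivered/metabolised fractions across an
applied-dose series with strictly linear sulfation and glucuronidation that
saturates above 30 nmol/cm². Both store their generating ground truth so
recovery is checkable exactly. What passing these loops shows is that the
estimators (qualification statistics, dermal calibration) recover known
truth under the assumed noise structure — not that the models reproduce any
particular animal study; real observations carry analytical error,
conjugate-hydrolysis artefacts and between-study heterogeneity the
generators deliberately do not emulate.

## Numerical choices

* ODE integration: `deSolve::lsoda`, rtol 1e-6, atol 1e-10; repeated doses
  as solver events; 5-min output grid with quadratic refinement of the peak.
* Mass balance is asserted at every output time (tolerance 0.1%; achieved
  ~1e-13 for the ODE system and round-off for the skin PDE).
* Skin PDE: Crank–Nicolson, dt 0.01–0.02 h; halving node spacing and time
  step moves the 24-h delivered fraction by well under 0.5%.
* Bisections run to stated absolute tolerances with hard iteration caps and
  raise errors reporting the achievable range when a target is outside the
  bracket.
* Problem sizes used in the shipped analyses: populations of 100
  individuals (the study design size); qualification uses 30 individuals
  per dose, which is ample for a mean with physiological variability only.

## Known limitations

* The original models were built in a commercial whole-body platform whose
  internal physiology database, GI tract model and IVIVE conventions are
  not fully published. With the documented reference physiology and the
  standard fu-based well-stirred IVIVE, the rat oral models predict higher
  plasma maxima than the platform models did from the same printed inputs
  (the gap corresponds to roughly four-fold more effective hepatic
  clearance in the platform than any standard convention yields here);
  route-to-route and PoD conversions that divide out this scale (dermal
  delivery, reverse dosimetry, ratios) agree much more closely.
* Repeated-dose dermal predictions conserve mass: everything calibrated to
  penetrate daily either metabolises, stays in skin, or reaches blood.
  With a 20%/day delivered fraction and 36% first-pass, steady-state
  plasma levels necessarily exceed what a non-accumulating reading of the
  same calibration endpoints would suggest; the conservative (higher)
  prediction is reported.
* No follicular/shunt pathways, no vehicle evaporation, no frozen-skin
  parameterisation (fresh-skin data are the calibration basis by design),
  no pediatric or pregnancy physiology, no global sensitivity analysis.
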