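# Chemical profile: genistein (source chemical)
# Units are stated per field. Values are the measured/predicted constants used as
# model inputs; candidate lists retain alternative literature values.
name: genistein
molecular_weight: 270.24        # g/mol
log_pow: 3.04                   # octanol:water, unitless
pka:                            # ionisable groups at 25 C
  - value: 7.25
    type: acid
water_solubility: 0.12          # mg/mL
melting_point: 301.5            # degC
vapor_pressure: 1.33e-9         # mmHg (non-volatile; no evaporation term)
papp_ab: 3.31e-5                # cm/s, Caco-2 apical->basolateral
papp_ba: 3.37e-5                # cm/s, Caco-2 basolateral->apical
peff: 1.01e-4                   # cm/s, effective intestinal permeability (from Papp correlation)
fu_plasma:                      # fraction unbound in plasma, per species
  human:
    selected: 0.037
    candidates: [0.037, 0.0243]
  rat:
    selected: 0.027
    candidates: [0.027, 0.0085, 0.07, 0.032]
blood_plasma_ratio:             # unitless
  human: 0.73
  rat: 0.73
clint_hepatocytes:              # uL/min/10^6 cells, suspension hepatocytes
  human: 18.71
  rat: 68
renal_clearance: 0              # L/h, both species (parent not renally cleared)
skin_first_pass_fraction: 0.70  # fraction of dermally penetrated dose metabolised
skin_first_pass_range: [0.70, 0.90]
exvivo_delivery_fraction:       # fresh human skin, 24 h, fraction of applied dose
  mean: 0.072
  sd: 0.054
dermal_delivery_target: 0.12    # default calibration target for the skin module (24 h)
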