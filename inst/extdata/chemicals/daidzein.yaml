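# Chemical profile: daidzein (target chemical, read-across from genistein)
name: daidzein
molecular_weight: 254.23        # g/mol
log_pow: 3.24
pka:
  - value: 7.51
    type: acid
  - value: 9.47
    type: acid
water_solubility: 0.053         # mg/mL
melting_point: 290
vapor_pressure: 3.46e-10        # mmHg
papp_ab: 2.03e-5                # cm/s, Caco-2 apical->basolateral
papp_ba: null                   # not available; efflux assumed absent (read-across)
peff: 6.61e-5                   # cm/s
fu_plasma:
  human:
    selected: 0.032
    candidates: [0.032, 0.0553]
  rat:
    selected: 0.0315
    candidates: [0.0315]
blood_plasma_ratio:
  human: 1.08
  rat: 1.08
clint_hepatocytes:              # uL/min/10^6 cells
  human: 15.4
  rat: 31.8
renal_clearance: 0              # L/h
skin_first_pass_fraction: 0.36
skin_first_pass_range: [0.36, 0.36]
exvivo_delivery_fraction:
  mean: 0.135
  sd: 0.070
dermal_delivery_target: 0.20
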