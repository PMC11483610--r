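# Reference rat organ volumes and blood flows (Brown et al. 1997-style compilation,
# Toxicol Ind Health 13:407-484). volume_fraction: fraction of body weight (density ~1);
# flow_fraction: fraction of cardiac output. The liver row is the hepatic artery only;
# portal inflow is the summed outflow of gut and spleen. Lung receives the entire
# cardiac output in series and is excluded from the flow sum. The unassigned flow
# fraction is routed as an arteriovenous shunt.
organ,volume_fraction,flow_fraction,portal
adipose,0.0761,0.070,0
bone,0.0739,0.122,0
brain,0.0057,0.020,0
gut,0.0270,0.153,1
heart,0.0033,0.049,0
kidney,0.0073,0.141,0
liver,0.0366,0.021,0
lung,0.0050,0.000,0
muscle,0.4043,0.278,0
skin,0.1903,0.058,0
spleen,0.0020,0.010,1
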