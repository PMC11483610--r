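# Reference adult human organ volumes and blood flows (ICRP 89 / Brown et al. 1997-style
# compilation, scaled to the 60 kg European mean individual). Conventions as in
# rat_organs.csv (liver = hepatic artery; gut+spleen drain portally; lung in series).
organ,volume_fraction,flow_fraction,portal
adipose,0.2140,0.050,0
bone,0.0856,0.050,0
brain,0.0200,0.114,0
gut,0.0171,0.160,1
heart,0.0047,0.040,0
kidney,0.0044,0.190,0
liver,0.0257,0.065,0
lung,0.0076,0.000,0
muscle,0.4000,0.170,0
skin,0.0371,0.050,0
spleen,0.0026,0.020,1
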