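# Tissue composition fractions for mechanistic tissue:plasma partitioning,
# transcribed from the Rodgers & Rowland compilations (J Pharm Sci 2006, 95:1238-1257;
# J Pharm Sci 2007, 96:3153-3154 erratum/companion tables).
# f_ew/f_iw: extracellular/intracellular water, fraction of tissue volume
# f_nl/f_np: neutral lipid / neutral phospholipid, fraction of tissue volume
# alb_ratio: tissue:plasma albumin concentration ratio (binding-protein surrogate for acids)
# The 'plasma' row carries plasma water and lipid fractions (f_ew = plasma water).
# The same fractional composition is applied to rat and human tissues.
tissue,f_ew,f_iw,f_nl,f_np,alb_ratio
adipose,0.135,0.017,0.853,0.0016,0.049
bone,0.100,0.346,0.0174,0.0016,0.100
brain,0.162,0.620,0.0391,0.0015,0.048
gut,0.282,0.475,0.0487,0.0163,0.158
heart,0.320,0.456,0.0115,0.0166,0.157
kidney,0.273,0.483,0.0207,0.0162,0.130
liver,0.161,0.573,0.0348,0.0252,0.086
lung,0.336,0.446,0.0219,0.0128,0.212
muscle,0.118,0.630,0.0100,0.0072,0.064
skin,0.382,0.291,0.0603,0.0044,0.277
spleen,0.207,0.579,0.0201,0.0198,0.097
plasma,0.945,0.000,0.00147,0.00083,1.000
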