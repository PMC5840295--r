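construct	total_yfp_positive	n_without	n_spheres	n_large_spheres	reported_percent
WT	373	373	0	0	0
dRRM1	318	318	0	0	0
dRRM2	197	107	77	13	47
dZnF1	182	182	0	0	0
dZnF2	80	80	0	0	0
S85C	167	167	0	0	0
S85C_dRRM2	196	141	55	0	28
F115C	138	138	0	0	0
F115C_dRRM2	101	17	81	3	83
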