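species	dG0f_kJ_mol	dH0f_kJ_mol	charge
NH4	-79.45	-133.26	1
NO2	-32.22	-104.60	-1
NO3	-110.91	-206.85	-1
N2	18.18	-10.44	0
H2O	-237.18	-285.88	0
H	0.00	0.00	1
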