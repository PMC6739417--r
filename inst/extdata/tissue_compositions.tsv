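# Breast tissue elemental compositions (mass fractions) and densities,
# after Hammerstein et al. (H, C, N, O + residual 'ash'); densities as
# used by Boone & Chavez. The ash residual (0.1% adipose / 0.5% glandular)
# is split equally over the five mineral elements Na, P, S, Cl, K.
tissue	element	mass_fraction	density_g_cm3
adipose	H	0.112	0.93
adipose	C	0.619	0.93
adipose	N	0.017	0.93
adipose	O	0.251	0.93
adipose	Na	2e-04	0.93
adipose	P	2e-04	0.93
adipose	S	2e-04	0.93
adipose	Cl	2e-04	0.93
adipose	K	2e-04	0.93
glandular	H	0.102	1.04
glandular	C	0.184	1.04
glandular	N	0.032	1.04
glandular	O	0.677	1.04
glandular	Na	0.001	1.04
glandular	P	0.001	1.04
glandular	S	0.001	1.04
glandular	Cl	0.001	1.04
glandular	K	0.001	1.04
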