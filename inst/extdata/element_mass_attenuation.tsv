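# Elemental mass attenuation coefficients mu/rho (cm^2/g), 10-80 keV.
# H, C, N, O: transcribed from the NIST standard reference tabulation
# (Hubbell & Seltzer); validated against independently transcribed
# water / air / PMMA composite tables via the mixture rule (<=0.5%).
# Na, P, S, Cl, K: Klein-Nishina closed form plus per-atom photoelectric
# power-law interpolation in Z anchored on transcribed O/Al/Fe values
# (estimated accuracy a few %; these elements carry <=0.5% of tissue mass).
# Intended use: log-log interpolation in the 10-50 keV imaging band.
element	energy_keV	mu_over_rho_cm2_g
H	10	0.3854
H	15	0.3764
H	20	0.3695
H	30	0.357
H	40	0.3458
H	50	0.3355
H	60	0.326
H	80	0.3091
C	10	2.373
C	15	0.8071
C	20	0.442
C	30	0.2562
C	40	0.2076
C	50	0.1871
C	60	0.1753
C	80	0.161
N	10	3.879
N	15	1.236
N	20	0.6178
N	30	0.3066
N	40	0.2288
N	50	0.198
N	60	0.1817
N	80	0.1639
O	10	5.952
O	15	1.836
O	20	0.8651
O	30	0.3779
O	40	0.2585
O	50	0.2132
O	60	0.1907
O	80	0.1678
Na	10	15.378
Na	15	4.649
Na	20	2.0417
Na	30	0.7169
Na	40	0.39643
Na	50	0.28034
Na	60	0.2269
Na	80	0.17975
P	10	39.04
P	15	12.051
P	20	5.2285
P	30	1.6734
P	40	0.80189
P	50	0.48897
P	60	0.34865
P	80	0.23269
S	10	48.038
S	15	14.956
S	20	6.5063
S	30	2.0688
S	40	0.97412
S	50	0.58033
S	60	0.4039
S	80	0.25894
Cl	10	54.531
Cl	15	17.121
Cl	20	7.4707
Cl	30	2.3657
Cl	40	1.0985
Cl	50	0.64181
Cl	60	0.43726
Cl	80	0.2699
K	10	75.045
K	15	23.941
K	20	10.517
K	30	3.3185
K	40	1.5112
K	50	0.85686
K	60	0.56371
K	80	0.32516
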