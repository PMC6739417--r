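# Elemental mass energy-absorption coefficients mu_en/rho (cm^2/g), 10-80 keV.
# O, C, N: transcribed NIST values (validated against water/air composites).
# H: Klein-Nishina energy-transfer closed form (photoelectric negligible).
# Na, P, S, Cl, K: photoelectric power-law estimate + Klein-Nishina transfer.
# Intended use: log-log interpolation in the 10-50 keV imaging band.
element	energy_keV	mu_en_over_rho_cm2_g
H	10	0.0071797
H	15	0.010363
H	20	0.01331
H	30	0.018576
H	40	0.023125
H	50	0.027075
H	60	0.030521
H	80	0.036198
C	10	2.078
C	15	0.5627
C	20	0.2238
C	30	0.06614
C	40	0.03343
C	50	0.02397
C	60	0.02098
C	80	0.01968
N	10	3.626
N	15	0.99487
N	20	0.39517
N	30	0.11139
N	40	0.050617
N	50	0.031962
N	60	0.025203
N	80	0.021869
O	10	5.565
O	15	1.545
O	20	0.6179
O	30	0.1729
O	40	0.0753
O	50	0.04414
O	60	0.03207
O	80	0.02468
Na	10	14.133
Na	15	4.1601
Na	20	1.7396
Na	30	0.51557
Na	40	0.22474
Na	50	0.1233
Na	60	0.079527
Na	80	0.046008
P	10	36.137
P	15	11.042
P	20	4.7014
P	30	1.4032
P	40	0.60008
P	50	0.31567
P	60	0.19115
P	80	0.093769
S	10	44.5
S	15	13.739
S	20	5.8849
S	30	1.7664
S	40	0.75581
S	50	0.39638
S	60	0.23848
S	80	0.11444
Cl	10	50.546
Cl	15	15.759
Cl	20	6.7882
Cl	30	2.0486
Cl	40	0.87739
Cl	50	0.45916
Cl	60	0.27486
Cl	80	0.12957
K	10	69.621
K	15	22.099
K	20	9.6188
K	30	2.9327
K	40	1.2592
K	50	0.65732
K	60	0.3907
K	80	0.17934
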