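# Dry air (near sea level) mass attenuation and mass energy-absorption
# coefficients (cm^2/g), transcribed from the NIST standard reference
# tabulation (Hubbell & Seltzer). Density 1.205e-3 g/cm^3 at 20 C.
# Intended use: log-log interpolation in the 10-50 keV imaging band.
energy_keV	mu_over_rho_cm2_g	mu_en_over_rho_cm2_g
10	5.12	4.742
15	1.614	1.334
20	0.7779	0.5389
30	0.3538	0.1537
40	0.2485	0.06833
50	0.208	0.04098
60	0.1875	0.03041
80	0.1662	0.02407
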