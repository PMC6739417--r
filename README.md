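# bctsim — energy optimization for monochromatic parallel-beam breast CT

Breast computed tomography with a monochromatic, parallel synchrotron beam
must pick one photon energy before scanning. Too low, and almost nothing
traverses the breast; too high, and glandular/adipose contrast vanishes.
`bctsim` answers the design question *which energy maximizes the
contrast-to-noise ratio (CNR) at fixed mean glandular dose (MGD)* for a
cylindrical breast of diameter *d* (8–16 cm) and glandularity *G* (0–1),
imaged with an ideal photon-counting detector over 180°.

It is written for medical-imaging physicists designing or simulating
monochromatic breast-CT acquisitions (synchrotron beamlines, bench studies)
who need reproducible dose-normalized image-quality estimates and a
reusable acquisition/reconstruction simulator.

## The model

At the core is the closed-form CNR of a filtered back-projection (FBP)
reconstruction at fixed dose:

    MGD_t = K · DgN_CT                      (dose -> isocenter air kerma)
    K     = (mu_en/rho)_air · E · phi       (kerma -> fluence)
    N_ph  = phi · dx^2                      (fluence -> photons per pixel)

    sigma_center^2 = beta / (N_ph · e^(-mu_phantom(G,E)·d) · e^(-mu_air(E)·ODD))

    CNR_an(E) = (mu_glandular(E) - mu_adipose(E)) / sigma_center(E)

where `beta` is obtained by integrating the noise power spectrum of the
FBP reconstruction (digital ramp filter with aliased replicas, optional
Hamming window, squared linear-interpolation transfer function):
`beta = 26.50 mm^-2` (Ram-Lak) and `4.41 mm^-2` (Hamming) at `dx = 0.12 mm`.
`DgN_CT(E, d, G)` — the mean glandular dose per unit isocenter air kerma —
is computed by an in-package Monte-Carlo photon transport (photoelectric,
Klein–Nishina incoherent, optional coherent) in the homogeneous cylinder,
with glandular-dose weighting by the mass energy-absorption ratio of the
tissues. A full simulator (analytic forward projection of a
concentric-disc phantom, Poisson sampling, FBP/SART/SIRT reconstruction,
photon-starvation correction, ROI-based `CNR_sim`) cross-validates the
analytic curve.

## Worked example

```r
library(bctsim)

# analytic CNR versus energy for an average breast: d = 10 cm, G = 0.143,
# MGD = 20 mGy, 0.12 mm pixels, Ram-Lak FBP
curve <- energy_scan(d = 10, G = 0.143, mgd = 20, dx = 0.12,
                     filter = "ramlak", n_photons = 1e6, seed = 1)
find_optimum(curve)
#> $E_opt
#> [1] 28
#>
#> $cnr_max
#> [1] 0.9686086

subset(as.data.frame(curve), E_keV %in% c(24, 26, 28, 30, 32),
       select = c(E_keV, dgn, cnr, cnr_normalized))
#>    E_keV       dgn       cnr cnr_normalized
#> 15    24 0.4730989 0.9257369      0.9557388
#> 17    26 0.5543120 0.9616570      0.9928231
#> 19    28 0.6350359 0.9686086      1.0000000
#> 21    30 0.7130922 0.9549508      0.9858996
#> 23    32 0.7732525 0.9272794      0.9573313
```

The curve peaks at 28 keV with CNR ≈ 0.97: at this dose a 10 cm breast of
average glandularity is imaged best around 28 keV, and the maximum is broad
— within 5% of its peak from 24 to 32 keV. `dgn` is the Monte-Carlo
`DgN_CT` (mGy per mGy of isocenter air kerma) used at each energy.

A single simulated acquisition, reconstructed and measured:

```r
cfg <- scan_config(d = 10, G = 0.143, mgd = 20, E = 28, dx = 0.12,
                   n_proj = 1200, algorithm = "fbp", filter = "hamming",
                   seed = 7)
sim <- simulate_slice(cfg)
cnr_sim(sim$slice)
#> <bct_cnr> CNR = 2.351 (detail 0.4239, ring 0.3084, sd 0.04910)
```

(The Hamming window trades resolution for noise, so `CNR_sim` exceeds the
Ram-Lak analytic value; with matched filters the two agree within
replicate error bars — see the methods vignette.) The detail and ring
means reconstruct the glandular and adipose attenuation coefficients at
28 keV in 1/cm.

The command-line front end exposes the same studies:

```sh
Rscript inst/scripts/bct table1 --mgd 20 --pixel 0.12 --filter ramlak --out out/
Rscript inst/scripts/bct dose-series --d 16 --G 0.143 --energy 28 --out out/
```

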