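# Free-electron Compton cross sections and electron densities, used to
# split the tabulated total attenuation into interaction channels for the
# photon-transport engine.

.ELECTRON_REST_KEV <- 510.99895
.CLASSICAL_E_RADIUS_CM <- 2.8179403262e-13
.AVOGADRO <- 6.02214076e23
.KEV_TO_J <- 1.602176634e-16

.element_Z <- c(H = 1, C = 6, N = 7, O = 8, Na = 11, P = 15, S = 16,
                Cl = 17, K = 19)
.element_A <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, Na = 22.990,
                P = 30.974, S = 32.06, Cl = 35.45, K = 39.098)

# Klein-Nishina total cross section per electron (cm^2), closed form
.kn_total <- function(E_keV) {
  e <- E_keV / .ELECTRON_REST_KEV
  2 * pi * .CLASSICAL_E_RADIUS_CM^2 *
    ((1 + e) / e^2 * (2 * (1 + e) / (1 + 2 * e) - log(1 + 2 * e) / e) +
       log(1 + 2 * e) / (2 * e) - (1 + 3 * e) / (1 + 2 * e)^2)
}

# Klein-Nishina energy-transfer cross section per electron (cm^2):
# total minus the scatter cross section (KN weighted by E'/E), the latter
# by dense numerical quadrature over the scattering angle.
.kn_transfer <- function(E_keV) {
  ct <- seq(-1, 1, length.out = 4001)
  vapply(E_keV, function(Ek) {
    e <- Ek / .ELECTRON_REST_KEV
    k <- 1 / (1 + e * (1 - ct))
    ds <- pi * .CLASSICAL_E_RADIUS_CM^2 * k^2 * (k + 1 / k - (1 - ct^2))
    scat <- sum((ds[-1] * k[-1] + ds[-length(ds)] * k[-length(k)]) / 2 *
                  diff(ct))
    .kn_total(Ek) - scat
  }, numeric(1))
}

# electrons per gram of a material
.electrons_per_gram <- function(material) {
  comp <- material$composition
  sum(comp$mass_fractions * .element_Z[comp$elements] /
        .element_A[comp$elements]) * .AVOGADRO
}

# log-log interpolation that extrapolates below the grid with the slope of
# the first segment (photon energies degraded below 10 keV during transport)
.loglog_extrap <- function(E, grid, values) {
  lx <- log(grid); ly <- log(values)
  lo <- E < grid[1]
  out <- numeric(length(E))
  if (any(!lo))
    out[!lo] <- .loglog_interp(E[!lo], grid, values)
  if (any(lo)) {
    slope <- (ly[2] - ly[1]) / (lx[2] - lx[1])
    out[lo] <- exp(ly[1] + slope * (log(E[lo]) - lx[1]))
  }
  out
}

# mixture mass coefficient with low-energy extrapolation (internal, for the
# transport grid only; user-facing accessors enforce the tabulated range)
.mixture_coef_extrap <- function(material, E, which) {
  tab <- xray_tables()[[which]]
  comp <- material$composition
  per_el <- vapply(comp$elements, function(el)
    .loglog_extrap(E, tab$energy, tab$coef[el, ]), numeric(length(E)))
  as.numeric(per_el %*% comp$mass_fractions)
}
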