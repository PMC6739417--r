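# Shared test fixtures: independently transcribed NIST reference values
# (used as oracles against the packaged element tables) and small helper
# constructors for fast simulator configurations.

# Water mass attenuation / mass energy-absorption (cm^2/g), transcribed
# from the NIST standard tabulation independently of the element tables.
water_reference <- data.frame(
  E = c(15, 20, 30, 40, 50),
  mu = c(1.673, 0.8096, 0.3756, 0.2683, 0.2269),
  mu_en = c(1.374, 0.5503, 0.1557, 0.06947, 0.04223)
)
water_mass_fractions <- c(H = 0.111894, O = 0.888106)

# Air mass energy-absorption reference points (cm^2/g)
air_en_reference <- data.frame(E = c(20, 30, 40),
                               mu_en = c(0.5389, 0.1537, 0.06833))

# mixture-rule mu/rho of a composition from the packaged element tables
mixture_mu_rho <- function(fractions, E, which = "attenuation") {
  tab <- bctsim:::xray_tables()[[which]]
  vapply(E, function(e) {
    sum(fractions * vapply(names(fractions), function(el)
      bctsim:::.loglog_interp(e, tab$energy, tab$coef[el, ]), numeric(1)))
  }, numeric(1))
}

# a small, fast acquisition configuration for simulator tests
small_config <- function(...) {
  args <- utils::modifyList(list(d = 8, G = 0.143, mgd = 20, E = 28,
                                 dx = 0.48, n_proj = 200, n_photons = 1e5),
                            list(...))
  do.call(scan_config, args)
}

# noiseless line integrals of a phantom at modest resolution
noiseless_projections <- function(d = 4, G = 0.143, E = 28, dx = 0.24,
                                  n_proj = 240, N_ph = 1e6, odd_cm = 0) {
  ph <- concentric_phantom(d, G)
  to_line_integrals(expected_sinogram(ph, E, N_ph, n_proj, dx, odd_cm))
}
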