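test_that("kerma, fluence and photon counts obey the linear chain", {
  dgn <- 0.5
  expect_equal(kerma_from_mgd(0, dgn), 0)
  expect_equal(kerma_from_mgd(40, dgn), 2 * kerma_from_mgd(20, dgn))
  # round trip MGD = K * DgN
  K <- kerma_from_mgd(17.3, dgn)
  expect_equal(K * dgn, 17.3)
  expect_error(kerma_from_mgd(10, -1), "positive")

  expect_equal(fluence_from_kerma(0, 25), 0)
  expect_equal(fluence_from_kerma(6, 25), 3 * fluence_from_kerma(2, 25))
  # inverse: K = phi * E * (mu_en/rho)_air in consistent units
  phi <- fluence_from_kerma(2.5, 30)
  K_back <- phi * (air_mass_energy_absorption(30) * 1e5) * 30 *
    bctsim:::.KEV_TO_J * 1e3
  expect_equal(K_back, 2.5, tolerance = 1e-12)

  n1 <- photons_per_pixel(10, 0.2, 20, 0.12, 28, dgn)
  expect_equal(photons_per_pixel(10, 0.2, 20, 0.06, 28, dgn), n1 / 4)
  expect_equal(photons_per_pixel(10, 0.2, 10, 0.12, 28, dgn), n1 / 2)
  # Eq. 5 rearranged: N_ph * E * (mu_en/rho)_air / dx^2 constant in E
  inv <- vapply(c(15, 25, 35, 45), function(E)
    photons_per_pixel(10, 0.2, 20, 0.12, E, dgn) * E *
      air_mass_energy_absorption(E), numeric(1))
  expect_equal(max(inv) / min(inv), 1, tolerance = 1e-12)
})

test_that("Monte-Carlo DgN is deterministic and seed-consistent", {
  a <- dgn_ct_monte_carlo(10, 0.25, 28, n_photons = 5e4, seed = 11)
  b <- dgn_ct_monte_carlo(10, 0.25, 28, n_photons = 5e4, seed = 11)
  expect_identical(a$value, b$value)
  c2 <- dgn_ct_monte_carlo(10, 0.25, 28, n_photons = 5e4, seed = 99)
  expect_false(identical(a$value, c2$value))
  # two independent runs agree within 3 combined standard errors
  expect_lt(abs(a$value - c2$value), 3 * sqrt(a$stderr^2 + c2$stderr^2))
  expect_gt(a$value, 0)
  expect_gt(a$stderr, 0)
  expect_error(dgn_ct_monte_carlo(10, 0.25, 28, n_photons = 100), "1e4")
})

test_that("thin-cylinder limit matches the first-interaction closed form", {
  # optically thin: dose = fluence * E * (mu_en/rho) and the glandular
  # weighting reduces DgN to (mu_en/rho)_glandular / (mu_en/rho)_air,
  # independent of G
  for (case in list(c(0.5, 28), c(0, 20))) {
    mc <- dgn_ct_monte_carlo(0.1, case[1], case[2], n_photons = 2e5,
                             seed = 4)
    oracle <- mass_energy_absorption(mixture_composition(1), case[2]) /
      air_mass_energy_absorption(case[2])
    expect_equal(mc$value, oracle, tolerance = 0.02)
  }
})

test_that("self-attenuation lowers DgN for larger breasts", {
  small <- dgn_ct(8, 0.25, 28, n_photons = 2e5, seed = 2)
  large <- dgn_ct(16, 0.25, 28, n_photons = 2e5, seed = 2)
  expect_gt(small$value, large$value + 3 * (small$stderr + large$stderr))
})

test_that("DgN is smooth in energy", {
  v <- vapply(27:29, function(E)
    dgn_ct(12, 0.143, E, n_photons = 2e5, seed = 3)$value, numeric(1))
  expect_true(all(abs(diff(v) / v[-1]) < 0.10))
})

test_that("geometry modes are validated and affect the coefficient", {
  expect_error(beam_geometry(odd_cm = -1), ">= 0")
  expect_error(dgn_ct_monte_carlo(10, 0.2, 28,
                                  beam_geometry("laminar"), 5e4, 1),
               "finite cylinder height")
  lam <- dgn_ct_monte_carlo(10, 0.2, 28,
                            beam_geometry("laminar", H_cm = 10), 1e5, 1)
  full <- dgn_ct_monte_carlo(10, 0.2, 28, beam_geometry("full"), 1e5, 1)
  # a thin laminar beam dilutes the dose over the whole breast
  expect_lt(lam$value, full$value)
})

test_that("the DgN cache reuses coefficients and round-trips through disk", {
  dgn_cache_clear()
  a <- dgn_ct(9, 0.3, 31, n_photons = 5e4, seed = 5)
  b <- dgn_ct(9, 0.3, 31, n_photons = 5e4, seed = 5)
  expect_identical(a$value, b$value)
  path <- tempfile(fileext = ".tsv")
  dgn_cache_write(path)
  dgn_cache_clear()
  dgn_cache_read(path)
  c2 <- dgn_ct(9, 0.3, 31, n_photons = 5e4, seed = 5)
  expect_identical(c2$value, a$value)
})
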