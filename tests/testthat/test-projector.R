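test_that("phantom geometry invariants hold", {
  ph <- concentric_phantom(8, 0.143)
  expect_equal(pi * ph$r_ring_cm^2 - pi * ph$r_detail_cm^2,
               pi * ph$r_detail_cm^2, tolerance = 1e-12)
  expect_error(concentric_phantom(1.5, 0), ">= 2")
})

test_that("chord lengths partition the outer chord", {
  ph <- concentric_phantom(8, 0.143)
  L0 <- path_lengths(ph, 0)
  expect_equal(unname(L0[1, "detail"]), 1)
  expect_equal(unname(L0[1, "ring"]), sqrt(2) - 1)
  expect_equal(unname(sum(L0)), 8)
  # ray misses the phantom
  expect_true(all(path_lengths(ph, 41) == 0))
  # per-material lengths sum to the outer-disc chord everywhere
  set.seed(1)
  s <- runif(1000, -50, 50)
  L <- path_lengths(ph, s)
  chord <- ifelse(abs(s / 10) < 4, 2 * sqrt(pmax(16 - (s / 10)^2, 0)), 0)
  expect_equal(unname(rowSums(L)), chord, tolerance = 1e-12)
})

test_that("expected sinogram matches the closed-form central bin", {
  ph <- concentric_phantom(8, 0.143)
  sino <- expected_sinogram(ph, 28, N_ph = 2.4e6, n_proj = 1200, dx = 0.12,
                            odd_cm = 185)
  # all rows identical by rotational symmetry
  expect_equal(max(abs(sweep(sino$data, 2, sino$data[1, ]))), 0)
  # central bin from hand-coded scalar arithmetic
  mu_g <- linear_attenuation(mixture_composition(1), 28)
  mu_a <- linear_attenuation(mixture_composition(0), 28)
  mu_m <- linear_attenuation(mixture_composition(0.143), 28)
  expect_val <- (2.4e6 / 1200) *
    exp(-(mu_g * 1 + mu_a * (sqrt(2) - 1) + mu_m * (8 - sqrt(2)))) *
    exp(-air_linear_attenuation(28) * 185)
  k_mid <- (ncol(sino$data) + 1) / 2
  expect_equal(sino$data[1, k_mid], expect_val, tolerance = 1e-12)
})

test_that("with zero path length and no air gap bins equal the blank", {
  sino <- expected_sinogram(concentric_phantom(4, 0), 28, 1e5, 100, 0.5,
                            odd_cm = 0)
  edge <- sino$data[1, 1]   # ray grazing outside the phantom: L = 0
  expect_equal(edge, 1e5 / 100)
})

test_that("total expected counts are conserved under angle refinement", {
  ph <- concentric_phantom(4, 0.25)
  s1 <- expected_sinogram(ph, 28, 1e5, 100, 0.5, odd_cm = 0)
  s2 <- expected_sinogram(ph, 28, 1e5, 400, 0.5, odd_cm = 0)
  expect_equal(sum(s1$data), sum(s2$data), tolerance = 1e-12)
})

test_that("homogeneous-phantom sinogram equals the mixture-chord formula", {
  ph <- concentric_phantom(6, 0.3)
  ph$detail <- ph$ring <- ph$background   # no detail or ring
  sino <- expected_sinogram(ph, 25, 1e5, 50, 0.3, odd_cm = 0)
  s <- bctsim:::.detector_s(ncol(sino$data), 0.3) / 10
  mu <- linear_attenuation(mixture_composition(0.3), 25)
  chords <- ifelse(abs(s) < 3, 2 * sqrt(pmax(9 - s^2, 0)), 0)
  expect_equal(sino$data[1, ], (1e5 / 50) * exp(-mu * chords),
               tolerance = 1e-12)
})

test_that("Poisson sampling has correct moments and is reproducible", {
  ph <- concentric_phantom(4, 0)
  sino <- expected_sinogram(ph, 28, 1e5, 130, 0.5, odd_cm = 0)
  sino$data[] <- 100
  s1 <- sample_sinogram(sino, seed = 21)
  s2 <- sample_sinogram(sino, seed = 21)
  expect_identical(s1$data, s2$data)
  n <- length(s1$data)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(s1$data) - 100), 4 * 10 / sqrt(n))
  expect_gt(var(as.numeric(s1$data)) / mean(s1$data), 0.9)
  expect_lt(var(as.numeric(s1$data)) / mean(s1$data), 1.1)
  # zero expectation stays zero
  sino$data[] <- 0
  expect_true(all(sample_sinogram(sino, 5)$data == 0))
})

test_that("log-normalization inverts the attenuation and flags starvation", {
  ph <- concentric_phantom(4, 0.143)
  sino <- expected_sinogram(ph, 28, 1e6, 120, 0.24, odd_cm = 185)
  p <- to_line_integrals(sino)
  # noiseless: p equals the mu-weighted chords; air path divides out
  L <- path_lengths(ph, bctsim:::.detector_s(ncol(sino$data), 0.24))
  mu <- c(linear_attenuation(mixture_composition(0.143), 28),
          linear_attenuation(mixture_composition(0), 28),
          linear_attenuation(mixture_composition(1), 28))
  expect_equal(p$data[1, ], as.numeric(L %*% mu), tolerance = 1e-10)
  # counts equal to flat give p = 0
  sino$data[] <- sino$flat
  expect_true(all(to_line_integrals(sino)$data == 0))
  # zero-count bins are masked and given a finite placeholder
  cs <- sample_sinogram(expected_sinogram(ph, 28, 200, 120, 0.24, 0), 3)
  cs$data[5, 7] <- 0
  p2 <- to_line_integrals(cs)
  expect_true(p2$mask[5, 7])
  expect_true(is.finite(p2$data[5, 7]))
})
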