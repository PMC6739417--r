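test_that("noiseless FBP recovers the phantom attenuation within 1%", {
  p <- noiseless_projections(d = 8, G = 0.143, E = 28, dx = 0.24,
                             n_proj = 700)
  sl <- fbp(p, "ramlak")
  n <- nrow(sl$image)
  c0 <- (n - 1) / 2
  xy <- (seq_len(n) - 1 - c0) * 0.24
  r <- sqrt(outer(xy^2, xy^2, `+`))
  mu_g <- linear_attenuation(mixture_composition(1), 28)
  mu_a <- linear_attenuation(mixture_composition(0), 28)
  expect_equal(mean(sl$image[r <= 0.6 * 5]), mu_g, tolerance = 0.01)
  ring <- r >= 5.4 & r <= 6.7
  expect_equal(mean(sl$image[ring]), mu_a, tolerance = 0.01)
})

test_that("FBP is linear and rejects non-finite input", {
  p <- noiseless_projections(d = 4, n_proj = 180)
  a <- fbp(p, "hamming")$image
  p2 <- p
  p2$data <- 2 * p$data
  expect_equal(fbp(p2, "hamming")$image, 2 * a, tolerance = 1e-10)
  p2$data[1, 1] <- NaN
  expect_error(fbp(p2, "hamming"), "finite")
  expect_error(fbp(bctsim:::.new_sinogram(p$data, "counts", p$angles,
                                          p$dx, p$flat, 0)),
               "line-integral")
})

test_that("noiseless FBP of the symmetric phantom is radially symmetric", {
  p <- noiseless_projections(d = 6, G = 0.25, dx = 0.24, n_proj = 500)
  sl <- fbp(p, "ramlak")
  n <- nrow(sl$image)
  c0 <- (n - 1) / 2
  # sample a circle of radius 40 px at many angles
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  ix <- round(c0 + 40 * cos(th)) + 1
  iy <- round(c0 + 40 * sin(th)) + 1
  vals <- sl$image[cbind(ix, iy)]
  expect_lt(sd(vals) / mean(vals), 0.02)
})

test_that("noiseless FBP preserves the area-weighted mean attenuation", {
  p <- noiseless_projections(d = 6, G = 0.25, dx = 0.24, n_proj = 500)
  sl <- fbp(p, "ramlak")
  n <- nrow(sl$image)
  c0 <- (n - 1) / 2
  xy <- (seq_len(n) - 1 - c0) * 0.24
  r <- sqrt(outer(xy^2, xy^2, `+`)) / 10  # cm
  inside <- r <= 2.8                      # avoid the partial-volume rim
  ph <- concentric_phantom(6, 0.25)
  mu <- c(linear_attenuation(ph$background, 28),
          linear_attenuation(ph$ring, 28),
          linear_attenuation(ph$detail, 28))
  rr <- r[inside]
  truth <- ifelse(rr <= 0.5, mu[3], ifelse(rr <= 0.5 * sqrt(2), mu[2],
                                           mu[1]))
  expect_equal(mean(sl$image[inside]), mean(truth), tolerance = 0.01)
})

test_that("iterative reconstructions descend on noiseless data", {
  p <- noiseless_projections(d = 4, G = 0.5, dx = 0.4, n_proj = 120,
                             N_ph = 1e6)
  n <- ncol(p$data)
  truth_img <- {
    c0 <- (n - 1) / 2
    xy <- (seq_len(n) - 1 - c0) * 0.4 / 10
    r <- sqrt(outer(xy^2, xy^2, `+`))
    mu <- c(linear_attenuation(mixture_composition(0.5), 28),
            linear_attenuation(mixture_composition(0), 28),
            linear_attenuation(mixture_composition(1), 28))
    ifelse(r <= 0.5, mu[3],
           ifelse(r <= 0.5 * sqrt(2), mu[2], ifelse(r <= 2, mu[1], 0)))
  }
  rmse <- function(img) sqrt(mean((img - truth_img)^2))
  # evaluated at full-sweep boundaries; within a sweep the error
  # oscillates as successive angles are visited
  errs <- vapply(c(1, 3, 10) * 120, function(k)
    rmse(sart(p, n_iter = k)$image), numeric(1))
  expect_true(all(diff(errs) < 0))
  errs_sirt <- vapply(c(5, 15, 40), function(k)
    rmse(sirt(p, n_iter = k)$image), numeric(1))
  expect_true(all(diff(errs_sirt) < 0))
  # zero sinogram is a fixed point of the zero-initialized iterations
  p0 <- p
  p0$data[] <- 0
  expect_true(all(sart(p0, n_iter = 30)$image == 0))
  expect_true(all(sirt(p0, n_iter = 5)$image == 0))
})

test_that("FBP, SART and SIRT agree on the noiseless attenuation map", {
  p <- noiseless_projections(d = 4, G = 0.5, dx = 0.4, n_proj = 120,
                             N_ph = 1e6)
  masks <- roi_masks(ncol(p$data), 0.4, erosion_mm = 0.8)
  vals <- vapply(list(fbp(p, "ramlak"),
                      sart(p, n_iter = 30 * 120),
                      sirt(p, n_iter = 400)),
                 function(sl) c(mean(sl$image[masks$detail]),
                                mean(sl$image[masks$ring])), numeric(2))
  expect_lt(max(vals[1, ]) / min(vals[1, ]) - 1, 0.02)
  expect_lt(max(vals[2, ]) / min(vals[2, ]) - 1, 0.02)
})

test_that("starvation correction interpolates zero-count runs", {
  ph <- concentric_phantom(4, 0.143)
  sino <- sample_sinogram(expected_sinogram(ph, 28, 1e6, 60, 0.4, 0), 8)
  # no zeros: identity
  expect_true(all(sino$data > 0))
  expect_identical(starvation_correct(sino)$data, sino$data)
  # single zero between 80 and 120 -> 100; run of zeros -> linear ramp
  sino$data[3, 10] <- 80; sino$data[3, 11] <- 0; sino$data[3, 12] <- 120
  sino$data[7, 20:22] <- 0
  sino$data[7, 19] <- 40; sino$data[7, 23] <- 80
  fixed <- starvation_correct(sino)
  expect_equal(fixed$data[3, 11], 100)
  expect_equal(fixed$data[7, 20:22], c(50, 60, 70))
  expect_true(all(fixed$mask[7, 20:22]))
  # edge zeros take the nearest nonzero value
  sino$data[9, 1:2] <- 0
  expect_equal(starvation_correct(sino)$data[9, 1:2],
               rep(sino$data[9, 3], 2))
  # an entire empty row is unphysical
  sino$data[5, ] <- 0
  expect_error(starvation_correct(sino), "no counts")
})
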