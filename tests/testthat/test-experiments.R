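test_that("scan configurations are validated on construction", {
  expect_s3_class(scan_config(), "bct_config")
  expect_error(scan_config(d = 1), "\\[2, 30\\]")
  expect_error(scan_config(G = 1.2), "\\[0, 1\\]")
  expect_error(scan_config(mgd = 0), "MGD")
  expect_error(scan_config(E = 55), "keV")
  expect_error(scan_config(algorithm = "mlem"), "arg")
})

test_that("the optimum table has one row per (d, G) with sane optima", {
  cfg <- scan_config(filter = "ramlak", n_photons = 5e4, seed = 2)
  grid <- seq(18, 40, by = 2)
  tab <- run_table1(cfg, d_set = c(8, 12), G_set = c(0, 0.5), E_grid = grid)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$E_opt_keV %in% grid))
  # optimum shifts up with d and with G on this mini-grid
  expect_true(with(tab, E_opt_keV[d == 12 & G == 0] >=
                          E_opt_keV[d == 8 & G == 0]))
  expect_true(with(tab, E_opt_keV[d == 8 & G == 0.5] >=
                          E_opt_keV[d == 8 & G == 0]))
  # CNR decreases with both d and G
  expect_true(with(tab, cnr_max[d == 12 & G == 0] < cnr_max[d == 8 & G == 0]))
  expect_true(with(tab, cnr_max[d == 8 & G == 0.5] < cnr_max[d == 8 & G == 0]))
  csv <- tempfile(fileext = ".csv")
  tab2 <- run_table1(cfg, d_set = c(8, 12), G_set = c(0, 0.5), E_grid = grid,
                     out_csv = csv)
  expect_equal(read.csv(csv), tab2)
})

test_that("normalized analysis reports the minimum retained fraction", {
  cfg <- scan_config(filter = "ramlak", n_photons = 5e4, seed = 2)
  grid <- seq(18, 40, by = 2)
  res <- run_normalized_analysis(cfg, d_set = c(8, 12), G_set = c(0, 0.5),
                                 E_ref = 28, E_grid = grid)
  expect_equal(nrow(res$table), 4)
  expect_true(all(res$table$ratio <= 1 & res$table$ratio > 0))
  expect_equal(res$min_ratio, min(res$table$ratio))
  expect_error(run_normalized_analysis(cfg, numeric(0), 0, 28, grid),
               "empty")
  expect_error(run_normalized_analysis(cfg, 8, 0, 27, grid), "grid")
})

test_that("CNR curves round-trip through CSV", {
  cur <- energy_scan(8, 0.25, E_grid = seq(20, 30, 5), n_photons = 5e4,
                     seed = 7)
  path <- tempfile(fileext = ".csv")
  write_cnr_csv(cur, path)
  back <- read_cnr_csv(path)
  expect_equal(back$cnr, cur$cnr)
  expect_equal(back$E_keV, cur$E_keV)
})

test_that("expected zero-count bins follow the Poisson closed form", {
  # scaled-down starvation study: the number of empty bins over the scan
  # is Poisson-binomial with mean sum(exp(-lambda))
  cfg <- small_config(d = 10, mgd = 0.05, n_proj = 250, dx = 0.24)
  dgn <- dgn_ct(cfg$d, cfg$G, cfg$E, cfg$geometry, cfg$n_photons, cfg$seed)
  n_ph <- photons_per_pixel(cfg$d, cfg$G, cfg$mgd, cfg$dx, cfg$E, dgn)
  ex <- expected_sinogram(concentric_phantom(cfg$d, cfg$G), cfg$E, n_ph,
                          cfg$n_proj, cfg$dx, cfg$odd_cm)
  expected_zero <- sum(exp(-ex$data))
  expect_gt(expected_zero, 5)
  obs <- vapply(1:20, function(s) sum(sample_sinogram(ex, s)$mask),
                numeric(1))
  expect_lt(abs(mean(obs) - expected_zero),
            3 * sqrt(expected_zero / 20) + 3 * sd(obs) / sqrt(20))
})

test_that("the dose series shows sqrt(MGD) scaling and starvation repair", {
  cfg <- small_config(d = 12, dx = 0.36, n_proj = 400, seed = 3)
  res <- run_dose_series(cfg, mgd_list = c(5, 20, 200), n_rep = 4)
  expect_equal(nrow(res), 3)
  # high dose: no starved bins at all
  expect_equal(res$starved_bins_mean[res$mgd == 200], 0)
  # sqrt scaling between 5 and 20 mGy within combined replicate error
  r <- res$cnr_corrected[res$mgd == 20] / res$cnr_corrected[res$mgd == 5]
  err <- r * sqrt((res$cnr_corrected_sd[res$mgd == 20] /
                     res$cnr_corrected[res$mgd == 20])^2 +
                  (res$cnr_corrected_sd[res$mgd == 5] /
                     res$cnr_corrected[res$mgd == 5])^2)
  expect_lt(abs(r - 2), 3 * err + 0.2)
})
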