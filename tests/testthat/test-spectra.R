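test_that("background subtraction floors at zero and respects the grid", {
  grid_n <- length(qd_wavelengths())
  s <- emission_spectrum(rep(5, grid_n))
  b <- emission_spectrum(rep(5, grid_n))
  expect_equal(subtract_background(s, b)$intensities, rep(0, grid_n))

  zero <- emission_spectrum(rep(0, grid_n))
  expect_equal(subtract_background(s, zero)$intensities, s$intensities)

  big_bg <- emission_spectrum(rep(10, grid_n))
  expect_true(all(subtract_background(s, big_bg)$intensities == 0))
})

test_that("noiseless simulated spectra unmix back to the true coefficients", {
  truth <- c(2.0, 0.5, 1.0)
  sim <- simulate_spectra(spectra_sim_config(background_level = 3),
                          truth, n_replicates = 1)
  s <- subtract_background(sim$spectra[[1]], sim$background)
  u <- unmix(s, sim$refs)
  expect_equal(unname(u$coefficients), truth, tolerance = 1e-10)
  expect_lt(u$residual_norm, 1e-8)

  # independent oracle: unconstrained least squares agrees when the truth
  # is strictly interior to the nonnegative orthant
  ols <- qr.coef(qr(unclass(sim$refs)), s$intensities)
  expect_equal(unname(ols), truth, tolerance = 1e-10)

  # pure-component identity
  sim1 <- simulate_spectra(true_coefficients = c(3, 0, 0), n_replicates = 1)
  u1 <- unmix(sim1$spectra[[1]], sim1$refs)
  expect_equal(unname(u1$coefficients), c(3, 0, 0), tolerance = 1e-10)
})

test_that("nonnegativity clips components whose free solution is negative", {
  refs <- simulated_reference_library()
  # cyan plus autofluorescence minus a little red, still nonnegative
  # everywhere: the free fit must return exactly -0.02 for red
  y <- unclass(refs) %*% c(1, -0.02, 0.5)
  expect_true(all(y >= 0))
  s <- emission_spectrum(as.numeric(y))
  free <- unmix(s, refs, nonneg = FALSE)
  expect_lt(free$coefficients[["red"]], 0)
  con <- unmix(s, refs, nonneg = TRUE)
  expect_identical(con$coefficients[["red"]], 0)

  # brute-force oracle on the two active components
  grid <- expand.grid(cyan = seq(0.9, 1.1, by = 0.002),
                      auto = seq(0.4, 0.6, by = 0.002))
  rss <- apply(grid, 1, function(g) {
    sum((s$intensities - unclass(refs) %*% c(g[1], 0, g[2]))^2)
  })
  best <- grid[which.min(rss), ]
  expect_equal(con$coefficients[["cyan"]], best$cyan, tolerance = 5e-3)
  expect_equal(con$coefficients[["autofluorescence"]], best$auto,
               tolerance = 5e-3)
})

test_that("collinear reference components are rejected by name", {
  refs <- simulated_reference_library()
  bad <- reference_library(cyan = unclass(refs)[, "cyan"],
                           red = unclass(refs)[, "red"],
                           red2 = 2 * unclass(refs)[, "red"])
  s <- emission_spectrum(unclass(refs)[, "cyan"])
  expect_error(unmix(s, bad), "red2")
})

test_that("adding a truly present component never increases the residual", {
  truth <- c(1.5, 0.7, 0.9)
  sim <- simulate_spectra(spectra_sim_config(noise = "gaussian",
                                             noise_sd = 0.02),
                          truth, n_replicates = 1, seed = 7)
  s <- sim$spectra[[1]]
  full <- unclass(sim$refs)
  two <- reference_library(full[, c("cyan", "red")])
  r2 <- unmix(s, two)$residual_norm
  r3 <- unmix(s, sim$refs)$residual_norm
  expect_lte(r3, r2 + 1e-12)
})

test_that("moving-average smoothing has the stated endpoint behavior", {
  x <- rnorm(50)
  expect_equal(smooth_curve(x, 1), x)
  expect_equal(smooth_curve(rep(4, 30), 5), rep(4, 30))
  imp <- rep(0, 21); imp[11] <- 5
  sm <- smooth_curve(imp, 5)
  expect_equal(sm[9:13], rep(1, 5))   # interior plateau of height 5/5
  expect_equal(sum(sm[1:8], sm[14:21]), 0)
  expect_error(smooth_curve(x, 4), "odd")
})

test_that("photon integration is the grid sum and is linear", {
  n <- length(qd_wavelengths())
  expect_equal(integrate_photons(rep(0, n)), 0)
  expect_equal(integrate_photons(rep(2, n)), 352)
  sim <- simulate_spectra(true_coefficients = c(2, 0, 0), n_replicates = 1)
  u <- unmix(sim$spectra[[1]], sim$refs)
  ref_total <- integrate_photons(unclass(sim$refs)[, "cyan"])
  expect_equal(integrate_photons(u$curves[, "cyan"]), 2 * ref_total,
               tolerance = 1e-10)
})

test_that("calibration fits exactly on noiseless lines and rejects degenerate input", {
  cal <- fit_calibration(c(0, 1, 2, 3), c(0, 2, 4, 6))
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)

  nmol <- seq(0.001, 0.008, by = 0.001)   # eight-point dilution series
  cal8 <- fit_calibration(nmol, 120 + 5500 * nmol)
  expect_equal(cal8$slope, 5500, tolerance = 1e-9)
  expect_equal(cal8$intercept, 120, tolerance = 1e-9)

  expect_error(fit_calibration(rep(2, 5), rnorm(5)), "distinct")
})

test_that("specific uptake inverts the calibration, clips, flags and scales", {
  nmol <- seq(0.001, 0.008, by = 0.001)
  cal <- fit_calibration(nmol, 100 + 2e6 * nmol, detection_limit = 1e-6)
  # photons at the third calibration point, 1 mg
  r <- specific_uptake(100 + 2e6 * nmol[3], cal, 1)
  expect_equal(r$nmol_per_mg, nmol[3], tolerance = 1e-10)
  expect_false(r$below_detection)
  # mass scaling: degree -1
  r2 <- specific_uptake(100 + 2e6 * nmol[3], cal, 2)
  expect_equal(r2$nmol_per_mg, r$nmol_per_mg / 2, tolerance = 1e-12)
  # below-detection flag at 5e-7 nmol/mg
  r3 <- specific_uptake(100 + 2e6 * 5e-7, cal, 1)
  expect_equal(r3$nmol_per_mg, 5e-7, tolerance = 1e-9)
  expect_true(r3$below_detection)
  # photons below the intercept clip to zero, never negative
  r4 <- specific_uptake(50, cal, 1)
  expect_identical(r4$nmol_per_mg, 0)
  expect_true(r4$clipped && r4$below_detection)
})

test_that("subsample aggregation matches brute-force mean and SE", {
  expect_equal(aggregate_subsamples(rep(1, 5)), list(mean = 1, se = 0, n = 5L))
  a <- aggregate_subsamples(c(0, 2))
  expect_equal(a$mean, 1)
  expect_equal(a$se, 1)
  set.seed(9)
  v <- rgamma(5, 3)
  flags <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  z <- aggregate_subsamples(v, flags, below = "zero")
  vz <- replace(v, flags, 0)
  expect_equal(z$mean, mean(vz))
  expect_equal(z$se, sd(vz) / sqrt(5))
  ex <- aggregate_subsamples(v, flags, below = "exclude")
  expect_equal(ex$mean, mean(v[!flags]))
  expect_error(aggregate_subsamples(numeric(0)), "no subsample")
})

test_that("spectra round-trip through CSV", {
  sim <- simulate_spectra(true_coefficients = c(1, 2, 0.5), n_replicates = 2)
  tmp <- tempfile(fileext = ".csv")
  write_spectra_csv(sim$spectra, tmp)
  back <- read_spectra_csv(tmp)
  expect_length(back, 2)
  expect_equal(back[["sim_001"]]$intensities, sim$spectra[[1]]$intensities)
  rtmp <- tempfile(fileext = ".csv")
  write_reference_csv(sim$refs, rtmp)
  expect_equal(unclass(read_reference_csv(rtmp)), unclass(sim$refs),
               ignore_attr = TRUE)
})
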