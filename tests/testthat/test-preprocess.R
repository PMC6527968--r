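test_that("cosmic-ray removal replaces only the flagged cells", {
  base <- peak_spectrum(1300, height = 10)
  set <- noisy_set(base, n = 25, sd = 0.05, seed = 3)
  spiked <- set
  spiked$intensity[200, 7] <- spiked$intensity[200, 7] + 50 * 0.05 * 50
  out <- remove_cosmic_rays(spiked, 5)
  rep_ <- attr(out, "replaced")
  expect_true(any(rep_$channel == 200 & rep_$replicate == 7))
  # replaced value sits within the noise band of its neighbours
  expect_lt(abs(out$intensity[200, 7] -
                  mean(spiked$intensity[c(199, 201), 7])), 1e-12)
  # every untouched cell is bit-identical
  mask <- matrix(TRUE, nrow(set$intensity), ncol(set$intensity))
  mask[cbind(rep_$channel, rep_$replicate)] <- FALSE
  expect_identical(out$intensity[mask], spiked$intensity[mask])
})

test_that("cosmic-ray removal is a no-op on spike-free sets and needs >= 3 replicates", {
  base <- peak_spectrum(1300)
  set <- spectrum_set(base$shift,
                      cbind(base$intensity, base$intensity, base$intensity))
  out <- remove_cosmic_rays(set, 5)
  expect_identical(out$intensity, set$intensity)
  two <- spectrum_set(base$shift, cbind(base$intensity, base$intensity))
  expect_error(remove_cosmic_rays(two, 5), "insufficient replicates")
})

test_that("laser-intensity correction divides by the factor and validates it", {
  s <- raman_spectrum(c(800, 801, 802), c(10, 10, 10))
  expect_equal(correct_laser_intensity(s, 1)$intensity, s$intensity)
  expect_equal(correct_laser_intensity(s, 2)$intensity, c(5, 5, 5))
  expect_error(correct_laser_intensity(s, 0), "invalid correction factor")
  st <- spectrum_set(s$shift, cbind(s$intensity, 2 * s$intensity),
                     laser_factors = c(1, 2))
  cor <- correct_laser_intensity(st)
  expect_equal(cor$intensity[, 1], cor$intensity[, 2])
})

test_that("recalibration finds the N2 apex and applies a rigid shift", {
  axis <- seq(2200, 2450, 2)
  mis <- peak_spectrum(2318, axis = axis)        # apex 12 cm^-1 low
  out <- recalibrate_shift(mis, 2330, 30)
  expect_equal(attr(out, "delta_cm1"), 12, tolerance = 0.05)
  # idempotent within half a channel
  again <- recalibrate_shift(out, 2330, 30)
  expect_lt(abs(attr(again, "delta_cm1")), 1)
  ok <- peak_spectrum(2330, axis = axis)
  expect_lt(abs(attr(recalibrate_shift(ok, 2330, 30), "delta_cm1")), 1)
  cropped <- peak_spectrum(1300)                  # 800-1800 only
  expect_error(recalibrate_shift(cropped, 2330, 30), "N2 region absent")
  flat <- raman_spectrum(axis, rep(1, length(axis)))
  expect_error(recalibrate_shift(flat, 2330, 30), "N2 peak not found")
})

test_that("atmospheric subtraction removes constructed lines and skips absent ones", {
  axis <- seq(1400, 1700, 2)
  o2 <- peak_spectrum(1550, height = 2, axis = axis, baseline = 5)
  out <- subtract_atmospheric(o2, positions = 1550)
  win <- out$shift >= 1525 & out$shift <= 1575
  area_before <- sum(o2$intensity[win] - 5)
  area_after <- sum(abs(out$intensity[win] - 5))
  expect_lt(area_after / area_before, 0.05)

  # no feature present: fitted amplitude ~ 0, output ~ input
  flat <- raman_spectrum(axis, rep(3, length(axis)))
  out2 <- subtract_atmospheric(flat, positions = 1550)
  expect_equal(out2$intensity, flat$intensity, tolerance = 1e-8)

  # both lines removed independently
  axis2 <- seq(1400, 2450, 2)
  both <- raman_spectrum(axis2,
                         2 * duvdecon:::pseudo_voigt(axis2, 2331, 25) +
                           1.5 * duvdecon:::pseudo_voigt(axis2, 1550, 25))
  out3 <- subtract_atmospheric(both, positions = c(2331, 1550))
  expect_lt(max(abs(out3$intensity)), 0.05 * 2)
  fits <- attr(out3, "atmospheric_fits")
  expect_length(fits, 2L)
  expect_equal(sort(vapply(fits, `[[`, 0, "position")), c(1550, 2331))

  # position not covered is skipped with a warning
  expect_warning(subtract_atmospheric(peak_spectrum(1300), positions = 2331),
                 "does not cover")
})

test_that("fingerprint crop keeps the closed interval and errors on no overlap", {
  axis <- seq(400, 2400, 2)
  s <- raman_spectrum(axis, seq_along(axis))
  cr <- crop_fingerprint(s, 800, 1800)
  expect_true(all(cr$shift >= 800 & cr$shift <= 1800))
  expect_equal(range(cr$shift), c(800, 1800))
  wide <- crop_fingerprint(peak_spectrum(1300), 0, 5000)
  expect_equal(wide$shift, fp_axis)
  expect_error(crop_fingerprint(peak_spectrum(1300), 1900, 2000),
               "empty crop")
})

test_that("linear baseline subtraction matches the closed-form OLS oracle", {
  x <- fp_axis
  # pure line is annihilated
  line <- raman_spectrum(x, 2 * x + 7)
  expect_lt(max(abs(subtract_linear_baseline(line)$intensity)), 1e-9)

  # line + Gaussian peak: compare against explicit OLS on the same input
  pk <- peak_spectrum(1300, height = 5)
  y <- 0.3 * x - 100 + pk$intensity
  s <- raman_spectrum(x, y)
  out <- subtract_linear_baseline(s)
  beta <- coef(lm(y ~ x))
  oracle <- y - beta[1] - beta[2] * x
  expect_equal(out$intensity, unname(oracle), tolerance = 1e-10)
  # peak apex preserved within 1% of its height relative to the oracle
  expect_lt(abs(max(out$intensity) - max(oracle)) / 5, 0.01)

  # idempotent
  twice <- subtract_linear_baseline(out)
  expect_equal(twice$intensity, out$intensity, tolerance = 1e-10)
  expect_error(subtract_linear_baseline(raman_spectrum(c(800, 801), c(1, 2))),
               "degenerate baseline")
})

test_that("replicate averaging returns channelwise mean and sd", {
  base <- peak_spectrum(1300)
  same <- spectrum_set(base$shift,
                       cbind(base$intensity, base$intensity, base$intensity))
  avg <- average_replicates(same)
  expect_equal(avg$intensity, base$intensity)
  expect_equal(max(avg$meta$channel_sd), 0)

  two <- spectrum_set(c(800, 801), matrix(c(0, 0, 2, 2), 2))
  avg2 <- average_replicates(two)
  expect_equal(avg2$intensity, c(1, 1))
  expect_equal(avg2$meta$channel_sd, c(sqrt(2), sqrt(2)))

  # noise of the mean shrinks like 1/sqrt(N)
  sd_of_mean <- function(n) {
    set <- noisy_set(raman_spectrum(fp_axis, rep(0, length(fp_axis))),
                     n = n, sd = 1, seed = 11)
    sd(average_replicates(set)$intensity)
  }
  expect_equal(sd_of_mean(25) / sd_of_mean(1), 1 / sqrt(25), tolerance = 0.2)
})

test_that("guanine normalization scales the window statistic to one", {
  s <- peak_spectrum(1460, height = 50)
  out <- normalize_to_guanine(s)
  win <- out$shift >= 1440 & out$shift <= 1480
  expect_equal(max(out$intensity[win]), 1)
  expect_equal(out$meta$norm_factor, 50, tolerance = 1e-6)
  # idempotent
  again <- normalize_to_guanine(out)
  expect_equal(again$intensity, out$intensity, tolerance = 1e-12)
  zero <- raman_spectrum(fp_axis, rep(0, length(fp_axis)))
  expect_error(normalize_to_guanine(zero), "cannot normalize")
  # window-mean convention is selectable
  mean_out <- normalize_to_guanine(s, stat = "mean")
  expect_equal(mean(mean_out$intensity[win]), 1, tolerance = 1e-12)
})

test_that("full pipeline recovers the generator truth within the noise band", {
  for (s in 1:10) {
    cfg <- synthetic_config(seed = 400 + s)
    fx <- end_to_end_fixture(cfg)
    out <- preprocess_spectra(fx$set)
    # reference: the noise-free truth passed through crop + baseline +
    # normalization (the deterministic tail of the pipeline)
    ref <- normalize_to_guanine(subtract_linear_baseline(
      crop_fingerprint(fx$truth$clean)))
    ref_on_out <- resample_to_axis(ref, out$shift)
    tol <- 3 * fx$truth$noise_sd / ref$meta$norm_factor
    expect_lt(max(abs(out$intensity - ref_on_out$intensity)), tol)
  }
})

test_that("pipeline is near-identity on already-processed input and names failing stages", {
  # an already cropped, baseline-subtracted, normalized spectrum passes
  # through the idempotent stages essentially unchanged
  cfg <- synthetic_config(seed = 9, background_fraction = 0.1,
                          cosmic_ray_rate = 0, noise_sigma = 0,
                          axis_offset_cm1 = 0, include_atmospheric = FALSE)
  fx <- end_to_end_fixture(cfg)
  done <- normalize_to_guanine(subtract_linear_baseline(
    crop_fingerprint(fx$truth$clean)))
  set <- spectrum_set(done$shift, cbind(done$intensity, done$intensity,
                                        done$intensity))
  out <- preprocess_spectra(set, preprocess_config(
    recalibrate = FALSE, subtract_atmospheric = FALSE))
  expect_lt(max(abs(out$intensity - done$intensity)), 1e-6)
  log <- attr(out, "log")
  expect_equal(log$cosmic_rays_replaced, 0)

  # full chain on a noise-free raw acquisition stays close to the truth
  cfg2 <- synthetic_config(seed = 9, background_fraction = 0,
                           cosmic_ray_rate = 0, noise_sigma = 0,
                           axis_offset_cm1 = 0, include_atmospheric = TRUE)
  fx2 <- end_to_end_fixture(cfg2)
  out2 <- preprocess_spectra(fx2$set)
  expect_lt(abs(attr(out2, "log")$recalibration_delta_cm1), 1)
  ref <- normalize_to_guanine(subtract_linear_baseline(
    crop_fingerprint(fx2$truth$clean)))
  cmp <- resample_to_axis(ref, out2$shift)
  # limited by the atmospheric O2 estimate in the crowded 1550 region
  expect_lt(max(abs(out2$intensity - cmp$intensity)), 0.03)

  # a set without the N2 region fails at the recalibration stage
  base <- peak_spectrum(1300)
  cropped_set <- noisy_set(base, n = 5, sd = 0.001, seed = 2)
  expect_error(preprocess_spectra(cropped_set), "N2 region absent")
})
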