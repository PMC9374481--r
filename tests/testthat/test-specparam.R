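test_that("baseline PSD localizes a pure baseline oscillation and is zero for zero input", {
  t <- epoch_t()
  X <- matrix(rep(0.8 * sin(2 * pi * 10 * t), each = 4), 4)
  psd <- baseline_psd(tfr_tensor(X))
  # the FIR passband is flat to ~0.1% ripple, so the peak bin can land on a
  # 0.5 Hz neighbour of the tone; the 10 Hz trio must dominate all else
  expect_lte(abs(psd$freqs[which.max(psd$power)] - 10), 0.5)
  trio <- psd$freqs %in% c(9.5, 10, 10.5)
  expect_gt(min(psd$power[trio]), max(psd$power[!trio]))
  expect_length(psd$power, 93)
  expect_true(all(psd$power >= 0))

  psd0 <- baseline_psd(tfr_tensor(matrix(0, 2, 3800)))
  expect_equal(max(psd0$power), 0)
  expect_error(baseline_psd(tfr_tensor(X), window = c(-600, -600)), "at least 2")
})

test_that("white-noise PSD is flat at the calibrated level across 10-40 Hz", {
  set.seed(4)
  X <- matrix(rnorm(300 * 3800), 300, 3800)
  # use all frames for a tight Monte-Carlo estimate of the flat level
  psd <- baseline_psd(tfr_tensor(X), window = c(-600, 3200))
  sel <- psd$freqs >= 10 & psd$freqs <= 40
  level <- mean(psd$power[sel])
  expect_true(all(abs(psd$power[sel] - level) / level < 0.10))
})

test_that("a noise-free power law is recovered exactly with zero peaks", {
  f <- tfr_freqs()
  fit <- fit_spectrum(list(freqs = f, power = 10^(1.0 - 1.5 * log10(f))))
  expect_lt(abs(fit$aperiodic[["offset"]] - 1.0), 1e-3)
  expect_lt(abs(fit$aperiodic[["exponent"]] - 1.5), 1e-3)
  expect_equal(nrow(fit$peaks), 0)
  expect_gt(fit$r_squared, 0.999)
  expect_error(fit_spectrum(list(freqs = f, power = c(-1, rep(1, 92)))),
               "positive")
})

test_that("a planted Gaussian peak is recovered and matches an independent joint-fit oracle", {
  f <- tfr_freqs()
  ly <- (1.0 - 1.5 * log10(f)) + 0.4 * exp(-(f - 15)^2 / (2 * 1.5^2))
  fit <- fit_spectrum(list(freqs = f, power = 10^ly))
  expect_equal(nrow(fit$peaks), 1)
  expect_lt(abs(fit$peaks$cf - 15), 0.25)
  expect_lt(abs(fit$peaks$pw - 0.4) / 0.4, 0.15)
  expect_true(fit$peaks$bw >= 1 && fit$peaks$bw <= 15)

  orc <- oracle_specfit(f, ly, n_peaks = 1)
  expect_lt(abs(fit$aperiodic[["offset"]] - orc$offset), 0.02)
  expect_lt(abs(fit$aperiodic[["exponent"]] - orc$exponent), 0.02)
  expect_lt(abs(fit$peaks$cf - orc$peaks$cf[1]), 0.1)
  expect_lt(abs(fit$peaks$pw - orc$peaks$pw[1]), 0.05)
})

test_that("fits agree with the oracle across a noisy fixture set", {
  set.seed(19)
  f <- tfr_freqs()
  cases <- list(c(b = 0.5, chi = 1.0, cf = 10, pw = 0.6, sd = 1.2),
                c(b = -0.5, chi = 1.8, cf = 22, pw = 0.45, sd = 2.0),
                c(b = 1.2, chi = 0.8, cf = 33, pw = 0.5, sd = 1.6))
  for (cs in cases) {
    ly <- cs["b"] - cs["chi"] * log10(f) +
      cs["pw"] * exp(-(f - cs["cf"])^2 / (2 * cs["sd"]^2)) +
      rnorm(length(f), 0, 0.02)
    fit <- fit_spectrum(list(freqs = f, power = 10^ly))
    orc <- oracle_specfit(f, ly, n_peaks = 1)
    expect_lt(abs(fit$aperiodic[["exponent"]] - orc$exponent), 0.05)
    main <- fit$peaks[which.max(fit$peaks$pw), ]
    expect_lt(abs(main$cf - orc$peaks$cf[1]), 0.25)
  }
})

test_that("model components are additive and band values respect the decomposition", {
  f <- tfr_freqs()
  ly <- (0.2 - 1.2 * log10(f)) + 0.4 * exp(-(f - 15)^2 / (2 * 1.5^2))
  fit <- fit_spectrum(list(freqs = f, power = 10^ly))
  # model additivity at every bin
  expect_equal(fit$model, fit$ap_model + megentrain:::peaks_model(f, fit$peaks),
               tolerance = 1e-12)
  full <- component_band_value(fit, component = "full")
  ap <- component_band_value(fit, component = "aperiodic")
  per <- component_band_value(fit, component = "periodic")
  expect_equal(full, ap + per, tolerance = 1e-9)
  # periodic band value ~ planted peak height averaged over the band bins
  planted <- mean(0.4 * exp(-(c(14.5, 15, 15.5) - 15)^2 / (2 * 1.5^2)))
  expect_equal(per, planted, tolerance = 0.02)
  expect_error(component_band_value(fit, band = c(55, 60)), "outside")

  # no-peak spectrum: periodic band value is numerically zero
  fit0 <- fit_spectrum(list(freqs = f, power = 10^(0.2 - 1.2 * log10(f))))
  expect_lt(abs(component_band_value(fit0, component = "periodic")), 1e-6)
})

test_that("exponent recovery holds over 100 noisy spectra", {
  set.seed(23)
  f <- tfr_freqs()
  errs <- t(sapply(1:100, function(i) {
    b <- runif(1, -1.5, 1.5); chi <- runif(1, 0.5, 2)
    cf <- runif(1, 8, 30); pw <- runif(1, 0.3, 0.8); bw <- runif(1, 1.5, 4)
    ly <- b - chi * log10(f) + pw * exp(-(f - cf)^2 / (2 * (bw / 2)^2)) +
      rnorm(length(f), 0, 0.02)
    fit <- fit_spectrum(list(freqs = f, power = 10^ly))
    main <- fit$peaks[which.max(fit$peaks$pw), ]
    c(dchi = abs(fit$aperiodic[["exponent"]] - chi),
      dcf = if (nrow(fit$peaks)) abs(main$cf - cf) else NA_real_)
  }))
  expect_lt(median(errs[, "dchi"]), 0.05)
  expect_lt(median(errs[, "dcf"], na.rm = TRUE), 0.25)
})
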