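test_that("band envelope of a pure tone is constant at the band-attenuated amplitude", {
  A <- 1.7
  tt <- tfr_tensor(matrix(A * sin(2 * pi * 15 * epoch_t()), nrow = 1))
  env <- band_envelope(tt)
  interior <- which(env$times >= 0 & env$times <= 2600)
  # band bins at +-0.5 Hz sit in the FIR passband, so attenuation ~ 1
  expect_true(all(abs(env$mean[interior] - A) / A < 0.02))
})

test_that("band envelope errors on empty input and wrong band", {
  tt0 <- tfr_tensor(matrix(numeric(0), nrow = 0, ncol = 3800))
  expect_error(band_envelope(tt0), "no trials")
  tt <- tfr_tensor(matrix(rnorm(3800), nrow = 1))
  expect_error(band_envelope(tt, band = c(60, 70)), "band outside")
})

test_that("trial-average of per-trial envelopes matches a direct recompute", {
  set.seed(9)
  X <- matrix(rnorm(5 * 3800), 5, 3800)
  tt <- tfr_tensor(X)
  env <- band_envelope(tt)
  fi <- which(tt$freqs >= 14.5 & tt$freqs <= 15.5)
  brute <- colMeans(apply(Mod(tt$coeffs[, fi, , drop = FALSE]), c(1, 3), mean))
  expect_equal(env$mean, brute)
  # and equals the mean of per-trial rows by definition
  expect_equal(env$mean, colMeans(env$trial))
})

test_that("ITPL: identical trials give 1, evenly spaced phases give 0", {
  co <- array(complex(modulus = 1, argument = 0.7), c(8, 1, 1))
  tt1 <- manual_tensor(co, freqs = 15, times = 1000)
  expect_equal(as.numeric(itpl(tt1)), 1)

  n <- 12
  co2 <- array(exp(2i * pi * (0:(n - 1)) / n), c(n, 1, 1))
  tt2 <- manual_tensor(co2, freqs = 15, times = 1000)
  expect_lt(as.numeric(itpl(tt2)), 1e-12)
})

test_that("ITPL of von Mises phases matches the Bessel-ratio expectation", {
  set.seed(77)
  n <- 10000
  # von Mises(kappa = 1) sampler (Best-Fisher rejection)
  rvm <- function(n, kappa) {
    out <- numeric(n); i <- 0
    a <- 1 + sqrt(1 + 4 * kappa^2); b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    while (i < n) {
      u <- runif(3)
      z <- cos(pi * u[1]); f <- (1 + r * z) / (r + z); c <- kappa * (r - f)
      if (c * (2 - c) - u[2] > 0 || log(c / u[2]) + 1 - c >= 0) {
        i <- i + 1
        out[i] <- sign(u[3] - 0.5) * acos(f)
      }
    }
    out
  }
  ph <- rvm(n, 1)
  tt <- manual_tensor(array(exp(1i * ph), c(n, 1, 1)), freqs = 15, times = 1000)
  expected <- besselI(1, 1) / besselI(1, 0)     # ~ 0.4464
  se <- sqrt((1 - expected^2) / n)              # conservative resultant SE
  expect_lt(abs(as.numeric(itpl(tt)) - expected), 3 * se + 0.01)
})

test_that("ITPL is invariant to per-trial amplitude scaling and logs zero coefficients", {
  set.seed(3)
  co <- array(complex(real = rnorm(20 * 2 * 3), imaginary = rnorm(20 * 2 * 3)),
              c(20, 2, 3))
  tt <- manual_tensor(co, freqs = c(14.5, 15), times = c(200, 300, 400))
  scaled <- co * array(rep(runif(20, 0.1, 10), 2 * 3), c(20, 2, 3))
  tts <- manual_tensor(scaled, freqs = c(14.5, 15), times = c(200, 300, 400))
  expect_equal(as.numeric(itpl(tt)), as.numeric(itpl(tts)), tolerance = 1e-12)

  co_z <- co; co_z[3, 1, 2] <- 0 + 0i
  ttz <- manual_tensor(co_z, freqs = c(14.5, 15), times = c(200, 300, 400))
  expect_equal(attr(itpl(ttz), "n_dropped"), 1)
})

test_that("amplitude CV: hand-computed and closed-form lognormal cases", {
  mk <- function(a) manual_tensor(array(complex(modulus = a, argument = 0),
                                        c(length(a), 1, 1)),
                                  freqs = 15, times = 1000)
  expect_equal(amplitude_cv(mk(rep(2, 6))), 0)
  expect_equal(amplitude_cv(mk(c(1, 3))), sqrt(2) / 2, tolerance = 1e-9)

  set.seed(101)
  n <- 1e5
  a <- exp(rnorm(n, 0, 0.5))
  cv_true <- sqrt(exp(0.25) - 1)                 # ~ 0.5329
  se <- cv_true * sqrt((1 + 2 * cv_true^2) / (2 * n))
  expect_lt(abs(amplitude_cv(mk(a)) - cv_true), 3 * se + 0.005)
  expect_error(amplitude_cv(mk(rep(0, 4))), "zero mean")
  expect_error(amplitude_cv(mk(2)), "at least 2")
})

test_that("per-frequency relative response peaks at the entrained bins", {
  lf <- small_leadfield()
  mk <- function(h) synth_config(n_group = c(ADS = 1, HC = 1), n_trials = 12,
                                 n_sensors = 16, sensor_noise_sd = 0.1,
                                 harmonic_gains = h,
                                 artifact_rate = 0, master_seed = 7)
  # 15 Hz entrainment only, over a flat (white-noise) background so the
  # relative profile mirrors the response spectrum itself; over a 1/f
  # background the declining baseline tilts the percent-change profile
  # upward in frequency within the smoothing bandwidth
  cfg0 <- synth_config(n_group = c(ADS = 1, HC = 1), n_trials = 12,
                       n_sensors = 16, sensor_noise_sd = 0.1,
                       harmonic_gains = c(`30` = 0, `45` = 0),
                       B_base = list(ADS = c(mean = 0, sd = 0),
                                     HC = c(mean = 0, sd = 0)),
                       aperiodic = c(offset = -Inf, exponent = 1),
                       artifact_rate = 0, master_seed = 7)
  s <- simulate_subject(cfg0, "ADS", 17, lf)
  best <- which.max(abs(lf$gains[s$ground_truth$true_voxel, ]))
  pf <- per_frequency_relative(tfr_tensor(s$epochs$data[, best, ]))
  expect_length(pf, 93)
  # the profile peaks at the stimulation frequency up to the FIR's spectral
  # smoothing (flat top over ~+-2 Hz), and falls by more than 10x at bins
  # five or more Hz away
  expect_lte(abs(as.numeric(names(which.max(pf))) - 15), 2)
  far <- abs(as.numeric(names(pf)) - 15) >= 5
  expect_gt(pf[["15"]], 10 * max(pf[far]))

  # with harmonics enabled, 30 and 45 Hz are elevated against bins >= 4 Hz away
  s2 <- simulate_subject(mk(c(`30` = 0.4, `45` = 0.2)), "ADS", 17, lf)
  pf2 <- per_frequency_relative(tfr_tensor(s2$epochs$data[, best, ]))
  expect_gt(pf2[["30"]], max(pf2[["25"]], pf2[["35"]]))
  expect_gt(pf2[["45"]], max(pf2[["41"]], pf2[["49"]]))
})

test_that("summary invariant: rel_amp recombines abs_amp and base_amp exactly", {
  set.seed(12)
  X <- matrix(rnorm(6 * 3800, sd = 0.5), 6, 3800) +
    matrix(rep(sin(2 * pi * 15 * epoch_t()), each = 6), 6)
  es <- entrainment_summary(tfr_tensor(X))
  expect_equal(es$rel_amp, 100 * (es$abs_amp - es$base_amp) / es$base_amp,
               tolerance = 1e-9)
  expect_gte(es$itpl, 0); expect_lte(es$itpl, 1)
  expect_gte(es$cv, 0)
  expect_length(es$per_freq_rel, 93)
})
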