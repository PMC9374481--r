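sine_epochs <- function(n_trials, n_sens, amps, f = 15) {
  t <- epoch_t()
  arr <- array(0, c(n_trials, n_sens, length(t)))
  for (i in seq_len(n_trials)) {
    for (s in seq_len(n_sens)) arr[i, s, ] <- amps[s] * sin(2 * pi * f * t)
  }
  sensor_epochs(arr)
}

test_that("CSD of a common sinusoid is rank 1 and Hermitian", {
  ep <- sine_epochs(4, 6, amps = seq(0.5, 3, 0.5))
  csd <- compute_csd(ep, c(14.5, 15.5), c(200, 2000))
  expect_lt(max(Mod(csd$matrix - Conj(t(csd$matrix)))), 1e-10)
  expect_true(all(Im(diag(csd$matrix)) == 0))
  expect_true(all(Re(diag(csd$matrix)) >= 0))
  ev <- eigen(csd$matrix, only.values = TRUE)$values
  expect_lt(Re(ev[2]) / Re(ev[1]), 1e-8)
})

test_that("CSD of white noise is Hermitian and matches an FFT Welch-band oracle", {
  set.seed(33)
  n_sens <- 6
  arr <- array(rnorm(60 * n_sens * 3800), c(60, n_sens, 3800))
  ep <- sensor_epochs(arr)
  csd <- compute_csd(ep, c(14.5, 15.5), c(200, 2000))
  expect_lt(max(Mod(csd$matrix - Conj(t(csd$matrix)))), 1e-10)
  d <- Re(diag(csd$matrix))
  # the demodulation coefficients integrate the flat PSD over the FIR's
  # equivalent noise bandwidth with calibration gain 2, so the predicted
  # diagonal level is 4 * ENBW * S with S the Welch two-sided PSD estimate
  oracle <- welch_band_power(ep, c(10, 20), c(200, 2000)) / 1000
  predicted <- 4 * megentrain:::demod_enbw(1000) * oracle
  expect_equal(mean(d), mean(predicted), tolerance = 0.05)
  # off-diagonal coherence of independent channels stays near zero
  expect_lt(max(Mod(csd$matrix[upper.tri(csd$matrix)])) / mean(d), 0.2)
})

test_that("DICS filters satisfy unit gain and the identity-covariance closed form", {
  lf <- small_leadfield()
  ep <- sine_epochs(3, 16, amps = lf$gains[22, ])
  csd <- compute_csd(ep, c(14.5, 15.5), c(200, 2000))
  fl <- dics_filters(csd, lf)
  expect_lt(max(abs(rowSums(fl$weights * lf$gains) - 1)), 1e-8)

  # C_r = I (lambda = 0): w = l / (l'l)
  csd_i <- csd
  csd_i$matrix <- diag(16) + 0i
  fl_i <- dics_filters(csd_i, lf, lambda_frac = 0)
  expect_equal(fl_i$weights, lf$gains / rowSums(lf$gains^2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pseudo-t maps are zero for equal CSDs, scale invariant, and calibrated", {
  lf <- small_leadfield()
  cfg <- clean_config()
  s <- simulate_subject(cfg, "ADS", 12, lf)
  csd_a <- compute_csd(s$epochs, c(14.5, 15.5), c(200, 2000))
  csd_b <- compute_csd(s$epochs, c(14.5, 15.5), c(-600, 0))
  fl <- dics_filters(csd_a, lf)
  expect_equal(max(abs(source_power_map(fl, csd_a, csd_a)$pseudo_t)), 0)

  # global rescaling of the data leaves the map unchanged
  s2 <- s
  s2$epochs$data <- 3 * s$epochs$data
  csd_a2 <- compute_csd(s2$epochs, c(14.5, 15.5), c(200, 2000))
  csd_b2 <- compute_csd(s2$epochs, c(14.5, 15.5), c(-600, 0))
  fl2 <- dics_filters(csd_a2, lf)
  m1 <- source_power_map(fl, csd_a, csd_b)
  m2 <- source_power_map(fl2, csd_a2, csd_b2)
  expect_equal(m2$pseudo_t, m1$pseudo_t, tolerance = 1e-9)

  # active amplitude sqrt(2) x baseline amplitude -> power ratio 2 -> pseudo-t 1
  t <- epoch_t()
  w_act <- as.numeric(t >= 0.2 & t <= 2.0)
  amp <- 1 + (sqrt(2) - 1) * w_act
  arr <- array(0, c(2, 16, 3800))
  for (i in 1:2) arr[i, , ] <- outer(lf$gains[22, ], amp * sin(2 * pi * 15 * t))
  ep <- sensor_epochs(arr)
  csd_act <- compute_csd(ep, c(14.5, 15.5), c(400, 1800))
  csd_base <- compute_csd(ep, c(14.5, 15.5), c(-400, 0))
  flx <- dics_filters(csd_act, lf)
  mp <- source_power_map(flx, csd_act, csd_base)
  expect_equal(mp$pseudo_t[22], 1.0, tolerance = 0.05)
})

test_that("grand-average peak voxel matches a brute-force scan", {
  m1 <- c(5, 0, 4.9, 0); m2 <- c(0, 5, 4.9, 0)
  got <- find_peak_voxel(list(m1, m2))
  ga <- (m1 + m2) / 2
  brute <- which(ga == max(ga))[1]
  expect_equal(got$peak_voxel, brute)
  expect_equal(got$grand_average, ga)
  expect_equal(got$peak_voxel, 3)      # maximal in neither input map
  expect_equal(find_peak_voxel(list(c(1, 7, 2)))$peak_voxel, 2)
  # ties broken by lowest index
  expect_equal(find_peak_voxel(list(c(3, 1, 3)))$peak_voxel, 1)
  expect_error(find_peak_voxel(list(m1, c(1, 2))), "grids differ")
})

test_that("virtual sensor reconstructs a pure source exactly and is linear", {
  lf <- small_leadfield()
  src <- sin(2 * pi * 15 * epoch_t()) * seq(0, 1, length.out = 3800)
  arr <- array(0, c(2, 16, 3800))
  arr[1, , ] <- outer(lf$gains[22, ], src)
  arr[2, , ] <- outer(lf$gains[22, ], 2 * src)
  ep <- sensor_epochs(arr)
  csd <- compute_csd(ep, c(14.5, 15.5), c(200, 2000))
  fl <- dics_filters(csd, lf)   # unit gain makes reconstruction exact at any lambda
  vs <- virtual_sensor(fl, 22, ep)
  expect_equal(vs[1, ], src, tolerance = 1e-8)
  expect_equal(vs[2, ], 2 * src, tolerance = 1e-8)

  # linearity across epoch mixtures
  arrX <- array(rnorm(2 * 16 * 3800), c(2, 16, 3800))
  arrY <- array(rnorm(2 * 16 * 3800), c(2, 16, 3800))
  epX <- sensor_epochs(arrX); epY <- sensor_epochs(arrY)
  epZ <- sensor_epochs(2 * arrX - 3 * arrY)
  expect_equal(virtual_sensor(fl, 5, epZ),
               2 * virtual_sensor(fl, 5, epX) - 3 * virtual_sensor(fl, 5, epY),
               tolerance = 1e-10)
})

test_that("virtual sensor tracks the true source under noise at default SNR", {
  lf <- small_leadfield()
  mk <- function(noise_sd) synth_config(
    n_group = c(ADS = 1, HC = 1), n_trials = 20, n_sensors = 16,
    sensor_noise_sd = noise_sd, artifact_rate = 0, master_seed = 6)
  s <- simulate_subject(mk(0.1), "ADS", 91, lf)
  s0 <- simulate_subject(mk(0), "ADS", 91, lf)   # same seed: trial 1 source identical
  csd_a <- compute_csd(s$epochs, c(14.5, 15.5), c(200, 2000))
  fl <- dics_filters(csd_a, lf)
  vs <- virtual_sensor(fl, s$ground_truth$true_voxel, s$epochs)
  truth <- virtual_sensor(fl, s0$ground_truth$true_voxel, s0$epochs)
  expect_gt(cor(vs[1, ], truth[1, ]), 0.9)
})
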