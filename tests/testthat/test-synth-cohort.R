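test_that("lead field construction is deterministic, smooth and non-degenerate", {
  lf1 <- build_leadfield(list(dim = c(4, 4, 4), spacing = 20), 16, seed = 9)
  lf2 <- build_leadfield(list(dim = c(4, 4, 4), spacing = 20), 16, seed = 9)
  expect_identical(lf1$gains, lf2$gains)
  expect_true(all(is.finite(lf1$gains)))
  expect_true(all(rowSums(abs(lf1$gains)) > 0))

  # adjacent voxels have more similar gain patterns than distant voxels
  cosim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  co <- lf1$grid_coords
  d <- as.matrix(stats::dist(co))
  adj <- which(d > 0 & d <= 20 + 1e-9, arr.ind = TRUE)
  far <- which(d >= 50, arr.ind = TRUE)
  sim_adj <- mean(apply(adj, 1, function(ij) cosim(lf1$gains[ij[1], ], lf1$gains[ij[2], ])))
  sim_far <- mean(apply(far, 1, function(ij) cosim(lf1$gains[ij[1], ], lf1$gains[ij[2], ])))
  expect_gt(sim_adj, sim_far)

  expect_error(build_leadfield(matrix(0, 10, 3), 16, seed = 1), "duplicate")
  expect_error(build_leadfield(list(dim = c(1, 2, 2), spacing = 20), 16, 1),
               "at least 8 voxels")
})

test_that("noise-free subject reproduces the configured source amplitude at the best sensor", {
  cfg <- clean_config()
  lf <- small_leadfield()
  s <- simulate_subject(cfg, "ADS", 77, lf)
  v <- s$ground_truth$true_voxel
  best <- which.max(abs(lf$gains[v, ]))
  tt <- tfr_tensor(matrix(s$epochs$data[, best, ], nrow = 3), fs = 1000)
  env <- band_envelope(tt)
  # plateau frames clear of the envelope ramp/decay by the FIR half-width
  ti <- which(env$times >= 700 & env$times <= 1000)
  expect_equal(mean(env$mean[ti]), lf$gains[v, best] * 1.0, tolerance = 0.02)
})

test_that("subject generation is deterministic in its seed", {
  cfg <- clean_config()
  lf <- small_leadfield()
  s1 <- simulate_subject(cfg, "HC", 123, lf)
  s2 <- simulate_subject(cfg, "HC", 123, lf)
  expect_identical(s1$epochs$data, s2$epochs$data)
  expect_identical(s1$covariates$score, s2$covariates$score)
})

test_that("per-trial amplitudes honor the configured cross-trial CV", {
  cfg <- synth_config(n_group = c(ADS = 1, HC = 1), n_trials = 120,
                      cv_trial = c(ADS = 0.3, HC = 0.3),
                      sensor_noise_sd = 0, artifact_rate = 0,
                      n_sensors = 16, master_seed = 2)
  lf <- small_leadfield()
  s <- simulate_subject(cfg, "ADS", 31, lf)
  a <- s$ground_truth$a_trials
  cv_hat <- sd(a) / mean(a)
  # SE of a lognormal CV estimate at n = 120
  se <- 0.3 * sqrt((1 + 2 * 0.3^2) / (2 * 120))
  expect_lt(abs(cv_hat - 0.3), 3 * se + 0.3 / sqrt(120))
})

test_that("cohort assembly: counts, configured group differences and score link", {
  cfg <- synth_config(n_group = c(ADS = 6, HC = 5), n_trials = 6,
                      n_sensors = 12, grid_dim = c(2, 2, 2), master_seed = 4)
  ch <- simulate_cohort(cfg)
  expect_length(ch$subjects, 11)
  expect_equal(table(ch$ground_truth$group)[["ADS"]], 6)
  # ADS baseline amplitude configured below HC
  expect_lt(mean(ch$ground_truth$baseline_amplitude[ch$ground_truth$group == "ADS"]),
            mean(ch$ground_truth$baseline_amplitude[ch$ground_truth$group == "HC"]))
  # bit-identical regeneration
  ch2 <- simulate_cohort(cfg)
  expect_identical(ch$subjects[[3]]$epochs$data, ch2$subjects[[3]]$epochs$data)
  expect_identical(ch$ground_truth, ch2$ground_truth)
})

test_that("a positive cognitive link yields a positive sample slope at study size", {
  cfg <- synth_config(n_group = c(ADS = 38, HC = 2), n_trials = 4,
                      n_sensors = 8, grid_dim = c(2, 2, 2), master_seed = 8)
  ch <- simulate_cohort(cfg)
  ads <- ch$ground_truth[ch$ground_truth$group == "ADS", ]
  # normal-equation slope of score on true mean amplitude
  x <- ads$a_mean - mean(ads$a_mean)
  slope <- sum(x * ads$score) / sum(x^2)
  expect_gt(slope, 0)
})

test_that("scaling all amplitudes and noise by c scales sensor data by c", {
  lf <- small_leadfield()
  c0 <- 2.5
  base <- list(A = 1, Asd = 0.2, B = 0.3, Bsd = 0.05, noise = 0.4, off = -1)
  mk <- function(k) synth_config(
    n_group = c(ADS = 1, HC = 1), n_trials = 4, n_sensors = 16,
    A_abs = list(ADS = c(mean = k * base$A, sd = k * base$Asd),
                 HC = c(mean = k * base$A, sd = k * base$Asd)),
    B_base = list(ADS = c(mean = k * base$B, sd = k * base$Bsd),
                  HC = c(mean = k * base$B, sd = k * base$Bsd)),
    sensor_noise_sd = k * base$noise,
    aperiodic = c(offset = base$off + 2 * log10(k), exponent = 1),
    artifact_rate = 0.5, master_seed = 3)
  s1 <- simulate_subject(mk(1), "ADS", 55, lf)
  s2 <- simulate_subject(mk(c0), "ADS", 55, lf)
  expect_equal(s2$epochs$data, c0 * s1$epochs$data, tolerance = 1e-12)
})

test_that("invalid generator settings are rejected", {
  expect_error(synth_config(sensor_noise_sd = -1), ">= 0")
  expect_error(synth_config(cv_trial = c(ADS = -0.1, HC = 0.3)), "cv_trial")
  expect_error(synth_config(n_group = c(A = 3, B = 4)), "ADS and HC")
  expect_error(simulate_subject(clean_config(), "XX", 1, small_leadfield()))
})
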