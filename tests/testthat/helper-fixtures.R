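# Shared fixtures and independent oracles, all built in code at test time.

.fixture_env <- new.env()

# One demo-scale pipeline run shared across test files (expensive stages run
# once; determinism tests re-run explicitly).
demo_pipeline_result <- function(seed = 3) {
  key <- paste0("run_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- run_pipeline(default_config(master_seed = seed))
  }
  .fixture_env[[key]]
}

# Small lead field shared by beamformer tests.
small_leadfield <- function(seed = 9, n_sensors = 16) {
  key <- paste0("lf_", seed, "_", n_sensors)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- build_leadfield(list(dim = c(4, 4, 4), spacing = 20),
                                           n_sensors, seed = seed)
  }
  .fixture_env[[key]]
}

# A clean one-subject configuration: deterministic source, no noise, no
# harmonics, no baseline rhythm, no artifacts.
clean_config <- function(...) {
  synth_config(
    n_group = c(ADS = 1, HC = 1), n_trials = 3, sensor_noise_sd = 0,
    cv_trial = c(ADS = 0, HC = 0), artifact_rate = 0,
    harmonic_gains = c(`30` = 0, `45` = 0),
    A_abs = list(ADS = c(mean = 1, sd = 0), HC = c(mean = 1, sd = 0)),
    B_base = list(ADS = c(mean = 0, sd = 0), HC = c(mean = 0, sd = 0)),
    aperiodic = c(offset = -Inf, exponent = 1),
    n_sensors = 16, master_seed = 5, ...)
}

# Hand-built time-frequency tensor (bypasses demodulation) for metric tests.
manual_tensor <- function(coeffs, freqs, times) {
  structure(list(coeffs = coeffs, freqs = freqs, times = times, fs = 1000),
            class = "tfr_tensor")
}

epoch_t <- function() seq(-0.6, 3.1999, by = 1e-3)

# Independent envelope oracle: FFT bandpass around a target frequency plus
# analytic-signal magnitude, sampled at the TFR frame grid.
hilbert_envelope <- function(x, fs, f0, half_bw = 2) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= (f0 - half_bw) & f <= (f0 + half_bw)   # positive side only
  X[!keep] <- 0
  Mod(stats::fft(X, inverse = TRUE)) * 2 / n
}

# Independent Welch-style band power per sensor (FFT periodogram averaged
# over trials and the band).
welch_band_power <- function(epochs, band, window) {
  dat <- epochs$data
  fs <- epochs$fs
  t_ms <- epochs$window[1] + (seq_len(dim(dat)[3]) - 1) * 1000 / fs
  sel <- t_ms >= window[1] & t_ms <= window[2]
  n <- sum(sel)
  f <- (seq_len(n) - 1) * fs / n
  bsel <- f >= band[1] & f <= band[2]
  sapply(seq_len(dim(dat)[2]), function(s) {
    mean(sapply(seq_len(dim(dat)[1]), function(tr) {
      px <- Mod(stats::fft(dat[tr, s, sel]))^2 / n
      mean(px[bsel])
    }))
  })
}

# Independent spectral-parameterization oracle: one-shot joint least squares
# of line + Gaussians on the log10 spectrum (no iterative flattening), with
# the true parameter count supplied.
oracle_specfit <- function(freqs, log_power, n_peaks) {
  lf <- log10(freqs)
  obj <- function(p) {
    m <- p[1] - p[2] * lf
    if (n_peaks > 0) {
      for (i in seq_len(n_peaks)) {
        q <- p[2 + (i - 1) * 3 + 1:3]
        m <- m + q[2] * exp(-(freqs - q[1])^2 / (2 * q[3]^2))
      }
    }
    sum((log_power - m)^2)
  }
  # starts: line from endpoints, peaks at largest residuals
  b0 <- stats::coef(stats::lm(log_power ~ lf))
  start <- c(b0[1], -b0[2])
  res <- log_power - (b0[1] + b0[2] * lf)
  for (i in seq_len(n_peaks)) {
    j <- which.max(res)
    start <- c(start, freqs[j], res[j], 1.5)
    res <- res - res[j] * exp(-(freqs - freqs[j])^2 / (2 * 1.5^2))
  }
  fit <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- fit$par
  peaks <- if (n_peaks > 0) {
    data.frame(cf = p[seq(3, by = 3, length.out = n_peaks)],
               pw = p[seq(4, by = 3, length.out = n_peaks)],
               sd = p[seq(5, by = 3, length.out = n_peaks)])
  } else data.frame()
  list(offset = p[1], exponent = p[2], peaks = peaks)
}
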