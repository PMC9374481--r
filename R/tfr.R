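# Complex-demodulation time-frequency decomposition and the sensor-level
# statistics that select the entrainment window.

#' Default time-frequency analysis grid
#'
#' The analysis grid spans 4--50 Hz in 0.5 Hz steps (93 bins) and the epoch
#' -600..3200 ms in 100 ms frames (39 frames).
#'
#' @param fmin,fmax,fstep Frequency range and step in Hz.
#' @return Numeric vector of bin-centre frequencies.
#' @export
tfr_freqs <- function(fmin = 4, fmax = 50, fstep = 0.5) {
  seq(fmin, fmax, by = fstep)
}

#' @rdname tfr_freqs
#' @param window Epoch window in ms, `c(start, end)`.
#' @param step Frame step in ms.
#' @export
tfr_times <- function(window = c(-600, 3200), step = 100) {
  seq(window[1], window[2], by = step)
}

# Windowed-sinc (Hamming) lowpass FIR used after demodulation.  The
# passband edge sits at `lowpass_hz` (envelope fluctuations up to ~1 Hz pass
# unattenuated, so the +-0.5 Hz neighbour bins of a tone stay calibrated)
# and the stopband starts at `stop_hz` (a tone >= 5 Hz away is suppressed to
# the Hamming stopband floor).  Keeping the transition this wide keeps the
# filter compact (< 1 s), which matters because the 600 ms pre-stimulus
# baseline lies at the epoch edge.
demod_filter <- function(fs = 1000, lowpass_hz = 1, stop_hz = 4.5) {
  transition_hz <- stop_hz - lowpass_hz
  fc <- (lowpass_hz + stop_hz) / 2 / fs
  n_taps <- ceiling(3.3 * fs / transition_hz)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  m <- (n_taps - 1) / 2
  k <- seq(-m, m)
  h <- 2 * fc * sinc(2 * fc * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Equivalent noise bandwidth (Hz, two-sided) of the demodulation lowpass;
# used by the synthetic generator to calibrate 1/f noise so the TFR-derived
# PSD lands on the configured aperiodic parameters.
demod_enbw <- function(fs = 1000, lowpass_hz = 1) {
  h <- demod_filter(fs, lowpass_hz)
  fs * sum(h^2)
}

# Frame-projection matrix: column j holds the FIR taps centred on frame j's
# sample, truncated to the epoch.  Truncated columns are rescaled to the
# noise gain (sum of squared taps) of the full filter, so stationary noise
# has the same expected power at every frame; without this the edge frames
# that make up the pre-stimulus baseline read systematically hot and bias
# every baseline-relative quantity.  The deterministic-signal gain of the
# one or two outermost frames drops slightly below 1 in exchange.
demod_projection <- function(n_samples, frame_samples, h) {
  m <- (length(h) - 1) / 2
  ssq <- sum(h^2)
  H <- matrix(0, n_samples, length(frame_samples))
  for (j in seq_along(frame_samples)) {
    c0 <- frame_samples[j]
    lo <- max(1L, c0 - m)
    hi <- min(n_samples, c0 + m)
    taps <- h[(lo - c0 + m + 1):(hi - c0 + m + 1)]
    H[lo:hi, j] <- taps * sqrt(ssq / sum(taps^2))
  }
  H
}

# Demodulation operator cache.  The combined matrix M[, (f,t)] =
# exp(-i 2 pi f t_n) * H[n, t] turns the whole transform into one matrix
# product per batch of signals; it is expensive to build, so memoize.
.demod_cache <- new.env(parent = emptyenv())

demod_operator <- function(fs, freqs, times_ms, epoch_start_ms, n_samples,
                           lowpass_hz = 1) {
  key <- paste(fs, lowpass_hz, epoch_start_ms, n_samples,
               paste(c(range(freqs), length(freqs)), collapse = "_"),
               paste(c(range(times_ms), length(times_ms)), collapse = "_"),
               sep = "|")
  if (!is.null(.demod_cache[[key]])) return(.demod_cache[[key]])
  h <- demod_filter(fs, lowpass_hz)
  t_sec <- (epoch_start_ms / 1000) + (seq_len(n_samples) - 1) / fs
  frame_samples <- round((times_ms - epoch_start_ms) / 1000 * fs) + 1L
  frame_samples <- pmin(pmax(frame_samples, 1L), n_samples)
  H <- demod_projection(n_samples, frame_samples, h)
  nf <- length(freqs); nt <- length(times_ms)
  ang <- outer(t_sec, freqs, function(tt, ff) -2 * pi * ff * tt)
  Mre <- matrix(0, n_samples, nf * nt)
  Mim <- matrix(0, n_samples, nf * nt)
  for (i in seq_len(nf)) {
    cols <- ((i - 1) * nt + 1):(i * nt)
    Mre[, cols] <- cos(ang[, i]) * H
    Mim[, cols] <- sin(ang[, i]) * H
  }
  op <- list(Mre = Mre, Mim = Mim, nf = nf, nt = nt,
             freqs = freqs, times = times_ms)
  if (length(.demod_cache) > 4) rm(list = ls(.demod_cache), envir = .demod_cache)
  .demod_cache[[key]] <- op
  op
}

# Core transform: signals (n_series x n_samples) -> complex array
# n_series x n_freq x n_time.  Calibrated so a unit-amplitude sinusoid at a
# bin centre yields envelope 1 in the temporal interior.
demod_transform <- function(X, fs, freqs, times_ms, epoch_start_ms,
                            lowpass_hz = 1) {
  if (any(freqs >= fs / 2)) {
    stop("demodulation frequency at or above Nyquist (fs/2)")
  }
  op <- demod_operator(fs, freqs, times_ms, epoch_start_ms, ncol(X), lowpass_hz)
  Cre <- X %*% op$Mre
  Cim <- X %*% op$Mim
  cx <- 2 * complex(real = Cre, imaginary = Cim)
  array(cx, dim = c(nrow(X), op$nt, op$nf)) |>
    aperm(c(1, 3, 2))
}

#' Complex demodulation of a single signal
#'
#' Shifts each analysis frequency to 0 Hz by complex-exponential
#' multiplication, applies a 1 Hz lowpass FIR (Hamming windowed-sinc,
#' zero-phase by symmetry), and samples the result on the 100 ms frame grid.
#' The output is calibrated so a sinusoid of amplitude A at a bin centre has
#' envelope (modulus) A away from the epoch edges.
#'
#' @param x Numeric vector, one epoch of one channel.
#' @param fs Sampling rate in Hz.
#' @param freqs Analysis frequencies (Hz); must be below `fs/2`.
#' @param times_ms Frame times in ms relative to stimulus onset.
#' @param epoch_start_ms Time of the first sample in ms.
#' @param lowpass_hz Lowpass cutoff of the demodulation FIR.
#' @return Complex matrix, frequency x time.
#' @export
complex_demodulate <- function(x, fs = 1000, freqs = tfr_freqs(),
                               times_ms = tfr_times(), epoch_start_ms = -600,
                               lowpass_hz = 1) {
  h_len <- length(demod_filter(fs, lowpass_hz))
  if (length(x) < h_len) stop("signal shorter than the demodulation FIR")
  cc <- demod_transform(matrix(x, nrow = 1), fs, freqs, times_ms,
                        epoch_start_ms, lowpass_hz)
  out <- cc[1, , , drop = TRUE]
  dim(out) <- c(length(freqs), length(times_ms))
  dimnames(out) <- list(freq = freqs, time = times_ms)
  out
}

#' Trial-resolved time-frequency tensor
#'
#' Applies [complex_demodulate()] to every trial of a single-channel epoch
#' matrix (for example a beamformer virtual sensor) and returns a
#' `tfr_tensor` holding complex coefficients trial x frequency x time.
#'
#' @param trials Numeric matrix, trial x time.
#' @inheritParams complex_demodulate
#' @return An object of class `tfr_tensor` with elements `coeffs`
#'   (complex array trial x freq x time), `freqs`, `times`, `fs`.
#' @export
tfr_tensor <- function(trials, fs = 1000, freqs = tfr_freqs(),
                       times_ms = tfr_times(), epoch_start_ms = -600,
                       lowpass_hz = 1) {
  stopifnot(is.matrix(trials))
  coeffs <- demod_transform(trials, fs, freqs, times_ms, epoch_start_ms,
                            lowpass_hz)
  dimnames(coeffs) <- list(NULL, freq = freqs, time = times_ms)
  structure(list(coeffs = coeffs, freqs = freqs, times = times_ms, fs = fs),
            class = "tfr_tensor")
}

#' @export
print.tfr_tensor <- function(x, ...) {
  cat(sprintf("tfr_tensor: %d trials x %d freqs (%.1f-%.1f Hz) x %d frames (%d..%d ms)\n",
              dim(x$coeffs)[1], length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Baseline normalization of a spectrogram
#'
#' Expresses power at each time-frequency bin as percent change from a
#' frequency-wise reference over the pre-stimulus baseline window.  The
#' reference is the median across baseline frames: the one or two outermost
#' frames of the epoch see a truncated demodulation filter and carry a
#' biased power estimate, and a median reference is insensitive to them
#' where a mean would propagate the bias into every bin of the map.
#'
#' @param power Numeric matrix, frequency x time.
#' @param times Frame times in ms (columns of `power`).
#' @param baseline Baseline window `c(start, end)` in ms; must contain at
#'   least two frames.
#' @return Matrix of percent power change, same shape as `power`.
#' @export
baseline_normalize <- function(power, times, baseline = c(-600, 0)) {
  idx <- which(times >= baseline[1] & times <= baseline[2])
  if (length(idx) < 2) stop("baseline window must contain at least 2 frames")
  base <- apply(power[, idx, drop = FALSE], 1, stats::median)
  if (any(base <= 0)) stop("zero or negative baseline reference power")
  100 * sweep(sweep(power, 1, base, "-"), 1, base, "/")
}

#' Sensor-averaged relative-power spectrogram for one subject
#'
#' Per sensor, trial-averaged power is baseline-normalized; the percent-change
#' maps are then averaged across sensors.  This is the per-participant input
#' to the permutation selection of the entrainment window.
#'
#' @param epochs A `sensor_epochs` object (kept trials are used).
#' @inheritParams complex_demodulate
#' @param baseline Baseline window in ms.
#' @return Matrix, frequency x time, percent power change.
#' @export
sensor_relative_power <- function(epochs, freqs = tfr_freqs(),
                                  times_ms = tfr_times(),
                                  baseline = c(-600, 0), lowpass_hz = 1) {
  dat <- epochs$data[epochs$kept_mask, , , drop = FALSE]
  n_trial <- dim(dat)[1]; n_sens <- dim(dat)[2]; n_samp <- dim(dat)[3]
  if (n_trial == 0) stop("no kept trials")
  X <- matrix(aperm(dat, c(3, 1, 2)), nrow = n_trial * n_sens,
              ncol = n_samp, byrow = TRUE)
  cc <- demod_transform(X, epochs$fs, freqs, times_ms, epochs$window[1],
                        lowpass_hz)
  pow <- Mod(cc)^2
  dim(pow) <- c(n_trial, n_sens, length(freqs), length(times_ms))
  acc <- matrix(0, length(freqs), length(times_ms))
  for (s in seq_len(n_sens)) {
    ps <- apply(pow[, s, , , drop = FALSE], c(3, 4), mean)
    acc <- acc + baseline_normalize(ps, times_ms, baseline)
  }
  out <- acc / n_sens
  dimnames(out) <- list(freq = freqs, time = times_ms)
  out
}

#' Demodulation window support per frame
#'
#' Fraction of the demodulation FIR that falls inside the epoch for each
#' frame of the analysis grid.  Frames near the epoch edges are computed
#' from a truncated window, which widens their effective bandwidth; frames
#' with low support are excluded from sensor-level inference.
#'
#' @param times_ms Frame times in ms.
#' @param epoch Epoch extent in ms.
#' @param fs Sampling rate in Hz.
#' @param lowpass_hz Demodulation lowpass passband edge.
#' @return Numeric vector in (0, 1], one value per frame.
#' @export
tfr_frame_support <- function(times_ms = tfr_times(), epoch = c(-600, 3200),
                              fs = 1000, lowpass_hz = 1) {
  h <- demod_filter(fs, lowpass_hz)
  m <- (length(h) - 1) / 2
  n_samples <- diff(epoch) * fs / 1000
  centers <- pmin(pmax(round((times_ms - epoch[1]) / 1000 * fs) + 1, 1),
                  n_samples)
  lo <- pmax(1, centers - m)
  hi <- pmin(n_samples, centers + m)
  (hi - lo + 1) / length(h)
}

# Connected components (4-connectivity) of a logical matrix; returns an
# integer label matrix, 0 = background.
grid_clusters <- function(exceed) {
  nr <- nrow(exceed); nc <- ncol(exceed)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(exceed)
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      for (nb in c(if (r > 1) p - 1L, if (r < nr) p + 1L,
                   if (cl > 1) p - nr, if (cl < nc) p + nr)) {
        if (exceed[nb] && labels[nb] == 0L) {
          labels[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}

# Max cluster mass of |t| map given a threshold; helper for the permutation
# null distribution.
max_cluster_mass <- function(tmap, crit) {
  exceed <- abs(tmap) > crit
  if (!any(exceed)) return(0)
  labels <- grid_clusters(exceed)
  masses <- tapply(abs(tmap)[exceed], labels[exceed], sum)
  max(masses)
}

#' Permutation selection of the entrainment time-frequency window
#'
#' One-sample cluster-based permutation test of sensor-averaged relative
#' power against zero across participants.  Cluster candidates are formed
#' from bins with two-sided uncorrected p < 0.05; cluster mass (summed |t|)
#' is compared against a max-cluster null built from random sign flips of
#' the participant maps.
#'
#' @param maps List of per-participant frequency x time percent-change
#'   matrices (identical grids), or a 3-D array subject x freq x time.
#' @param alpha Corrected cluster-level alpha (the study used 0.001).
#' @param n_perm Number of sign-flip permutations (>= 200).
#' @param seed Integer seed for the permutation draw.
#' @param freqs,times Grid labels attached to the result.
#' @param valid_frames Optional logical vector over time frames; frames
#'   marked `FALSE` (for example epoch-edge frames with a truncated
#'   demodulation window, see [tfr_frame_support()]) are excluded from the
#'   test and can never enter the mask.
#' @return An object of class `significance_mask`: logical `mask`
#'   (freq x time), data frame `clusters` (id, mass, p), `n_perm`, `alpha`,
#'   `seed`.
#' @export
select_entrainment_window <- function(maps, alpha = 0.001, n_perm = 1000,
                                      seed = 1, freqs = NULL, times = NULL,
                                      valid_frames = NULL) {
  if (is.list(maps)) {
    arr <- simplify2array(maps)        # freq x time x subj
    arr <- aperm(arr, c(3, 1, 2))
  } else arr <- maps
  if (!is.null(valid_frames)) {
    stopifnot(length(valid_frames) == dim(arr)[3])
    full <- list(nt = dim(arr)[3], valid = valid_frames,
                 freqs = freqs, times = times)
    res <- select_entrainment_window(arr[, , valid_frames, drop = FALSE],
                                     alpha, n_perm, seed)
    mask <- matrix(FALSE, dim(arr)[2], full$nt)
    mask[, full$valid] <- res$mask
    tmap <- matrix(NA_real_, dim(arr)[2], full$nt)
    tmap[, full$valid] <- res$t_map
    if (!is.null(full$freqs)) rownames(mask) <- full$freqs
    if (!is.null(full$times)) colnames(mask) <- full$times
    res$mask <- mask
    res$t_map <- tmap
    res$valid_frames <- full$valid
    return(res)
  }
  n_sub <- dim(arr)[1]; nf <- dim(arr)[2]; nt <- dim(arr)[3]
  if (n_sub < 6) stop("need at least 6 participants")
  if (n_perm < 200) stop("n_perm must be >= 200")
  if (1 / (n_perm + 1) > alpha) {
    stop(sprintf("n_perm = %d cannot resolve corrected p < %g", n_perm, alpha))
  }
  X <- matrix(arr, nrow = n_sub)       # subj x (nf*nt)
  ss <- colSums(X^2)
  crit <- stats::qt(0.975, df = n_sub - 1)
  t_of_means <- function(m) {
    v <- (ss - n_sub * m^2) / (n_sub - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n_sub)
  }
  t_obs <- matrix(t_of_means(colMeans(X)), nf, nt)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                  n_perm, n_sub)
  perm_means <- (signs %*% X) / n_sub
  null_max <- vapply(seq_len(n_perm), function(p) {
    max_cluster_mass(matrix(t_of_means(perm_means[p, ]), nf, nt), crit)
  }, numeric(1))

  exceed <- abs(t_obs) > crit
  labels <- grid_clusters(exceed)
  mask <- matrix(FALSE, nf, nt)
  clusters <- data.frame(id = integer(), mass = numeric(), p = numeric())
  if (any(exceed)) {
    masses <- tapply(abs(t_obs)[exceed], labels[exceed], sum)
    for (cl in names(masses)) {
      p_corr <- (1 + sum(null_max >= masses[[cl]])) / (n_perm + 1)
      clusters <- rbind(clusters, data.frame(
        id = as.integer(cl), mass = masses[[cl]], p = p_corr))
      if (p_corr < alpha) mask[labels == as.integer(cl)] <- TRUE
    }
  }
  if (!is.null(freqs)) rownames(mask) <- freqs
  if (!is.null(times)) colnames(mask) <- times
  structure(list(mask = mask, clusters = clusters, t_map = t_obs,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf("significance_mask: %d/%d bins selected, %d cluster(s), %d permutations, alpha = %g\n",
              sum(x$mask), length(x$mask), nrow(x$clusters), x$n_perm, x$alpha))
  invisible(x)
}
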