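# Virtual-sensor entrainment read-outs: band amplitude envelopes, absolute
# and baseline-relative response amplitude, inter-trial phase locking,
# cross-trial coefficient of variation and per-frequency specificity.

band_bins <- function(tt, band) {
  idx <- which(tt$freqs >= band[1] & tt$freqs <= band[2])
  if (!length(idx)) stop("band outside the time-frequency grid")
  idx
}

window_frames <- function(tt, window) {
  idx <- which(tt$times >= window[1] & tt$times <= window[2])
  if (!length(idx)) stop("window outside the time-frequency grid")
  idx
}

#' Band amplitude envelope
#'
#' Mean over band bins of the coefficient modulus, per trial and frame;
#' the trial average is taken after the per-trial modulus, so the envelope
#' reflects total (induced plus evoked) activity.
#'
#' @param tt A [tfr_tensor()].
#' @param band Frequency band `c(lo, hi)` in Hz.
#' @return A list: `trial` (matrix, trial x time), `mean` (vector over
#'   time), `times`.
#' @export
band_envelope <- function(tt, band = c(14.5, 15.5)) {
  stopifnot(inherits(tt, "tfr_tensor"))
  if (dim(tt$coeffs)[1] == 0) stop("no trials in tensor")
  fi <- band_bins(tt, band)
  amp <- Mod(tt$coeffs[, fi, , drop = FALSE])
  trial <- apply(amp, c(1, 3), mean)
  if (is.null(dim(trial))) trial <- matrix(trial, nrow = dim(tt$coeffs)[1])
  list(trial = trial, mean = colMeans(trial), times = tt$times)
}

#' Inter-trial phase locking
#'
#' Per time-frequency bin, the modulus of the trial-averaged unit phase
#' vector; the scalar summary is the mean of this resultant over the
#' band x window grid.  Coefficients of exactly zero magnitude carry no
#' phase and are excluded from that bin's average (count reported via the
#' `n_dropped` attribute).
#'
#' @param tt A [tfr_tensor()] with at least 2 trials.
#' @param band Frequency band in Hz.
#' @param window Time window in ms.
#' @return Scalar in `[0, 1]` with attribute `n_dropped`.
#' @export
itpl <- function(tt, band = c(14.5, 15.5), window = c(200, 2000)) {
  stopifnot(inherits(tt, "tfr_tensor"))
  if (dim(tt$coeffs)[1] < 2) stop("need at least 2 trials")
  fi <- band_bins(tt, band)
  ti <- window_frames(tt, window)
  cc <- tt$coeffs[, fi, ti, drop = FALSE]
  m <- Mod(cc)
  ok <- m > 0
  u <- cc
  u[ok] <- cc[ok] / m[ok]
  u[!ok] <- 0 + 0i
  n_ok <- apply(ok, c(2, 3), sum)
  if (any(n_ok == 0)) stop("a time-frequency bin has no nonzero coefficients")
  R <- Mod(apply(u, c(2, 3), sum)) / n_ok
  structure(mean(R), n_dropped = sum(!ok))
}

#' Cross-trial amplitude coefficient of variation
#'
#' Each trial's response is summarized as the mean amplitude over the
#' band x window grid; the CV is the sample SD over trials divided by the
#' mean.
#'
#' @inheritParams itpl
#' @return Scalar CV (>= 0).
#' @export
amplitude_cv <- function(tt, band = c(14.5, 15.5), window = c(200, 2000)) {
  stopifnot(inherits(tt, "tfr_tensor"))
  if (dim(tt$coeffs)[1] < 2) stop("need at least 2 trials")
  fi <- band_bins(tt, band)
  ti <- window_frames(tt, window)
  a <- apply(Mod(tt$coeffs[, fi, ti, drop = FALSE]), 1, mean)
  if (mean(a) <= 0) stop("zero mean trial amplitude")
  stats::sd(a) / mean(a)
}

#' Per-frequency baseline-relative response
#'
#' For every frequency bin, the percent change of the trial-averaged
#' amplitude in the response window relative to the bin's baseline mean.
#' Bins with zero baseline are returned as `NA`.
#'
#' @param tt A [tfr_tensor()] on the full analysis grid.
#' @param window Response window in ms.
#' @param baseline Baseline window in ms.
#' @return Named numeric vector, one value per frequency bin.
#' @export
per_frequency_relative <- function(tt, window = c(200, 2000),
                                   baseline = c(-600, 0)) {
  stopifnot(inherits(tt, "tfr_tensor"))
  ti <- window_frames(tt, window)
  bi <- window_frames(tt, baseline)
  amp <- apply(Mod(tt$coeffs), c(2, 3), mean)   # freq x time, trial-averaged
  base <- rowMeans(amp[, bi, drop = FALSE])
  act <- rowMeans(amp[, ti, drop = FALSE])
  out <- ifelse(base > 0, 100 * (act - base) / base, NA_real_)
  names(out) <- tt$freqs
  out
}

#' Subject-level entrainment summary
#'
#' Computes the full set of virtual-sensor read-outs: mean absolute band
#' amplitude over the response window (`abs_amp`), mean baseline amplitude
#' (`base_amp`), baseline-relative response in percent (`rel_amp`, equal to
#' `100 * (abs_amp - base_amp) / base_amp`), ITPL, cross-trial CV and the
#' per-frequency relative response vector.
#'
#' @param tt A [tfr_tensor()] of virtual-sensor trials on the full grid.
#' @param band Analysis band in Hz.
#' @param window Response window in ms.
#' @param baseline Baseline window in ms.
#' @return A list of class `entrainment_summary`.
#' @export
entrainment_summary <- function(tt, band = c(14.5, 15.5),
                                window = c(200, 2000),
                                baseline = c(-600, 0)) {
  env <- band_envelope(tt, band)
  ti <- which(env$times >= window[1] & env$times <= window[2])
  bi <- which(env$times >= baseline[1] & env$times <= baseline[2])
  abs_amp <- mean(env$mean[ti])
  base_amp <- mean(env$mean[bi])
  if (base_amp <= 0) stop("zero baseline amplitude")
  structure(list(
    abs_amp = abs_amp,
    base_amp = base_amp,
    rel_amp = 100 * (abs_amp - base_amp) / base_amp,
    itpl = as.numeric(itpl(tt, band, window)),
    cv = amplitude_cv(tt, band, window),
    per_freq_rel = per_frequency_relative(tt, window, baseline)),
    class = "entrainment_summary")
}

#' @export
print.entrainment_summary <- function(x, ...) {
  cat(sprintf("entrainment_summary: abs %.3f, base %.3f, rel %.1f%%, ITPL %.3f, CV %.3f\n",
              x$abs_amp, x$base_amp, x$rel_amp, x$itpl, x$cv))
  invisible(x)
}
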