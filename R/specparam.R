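# Baseline PSD construction and periodic/aperiodic spectral
# parameterization: an iterative fit in log10 space separating a 1/f-like
# aperiodic component (offset, exponent) from Gaussian oscillatory peaks.

#' Baseline power spectral density from a time-frequency tensor
#'
#' Per frequency bin, the mean over trials and baseline frames of the
#' squared coefficient modulus (amplitude^2 units).
#'
#' @param tt A [tfr_tensor()].
#' @param window Baseline window in ms (must contain >= 2 frames).
#' @return A list of class `baseline_psd`: `freqs`, `power`.
#' @export
baseline_psd <- function(tt, window = c(-600, 0)) {
  stopifnot(inherits(tt, "tfr_tensor"))
  bi <- which(tt$times >= window[1] & tt$times <= window[2])
  if (length(bi) < 2) stop("baseline window must contain at least 2 frames")
  pow <- apply(Mod(tt$coeffs[, , bi, drop = FALSE])^2, 2, mean)
  structure(list(freqs = tt$freqs, power = pow), class = "baseline_psd")
}

#' Spectral parameterization settings
#'
#' Defaults mirror standard practice for fixed-mode fitting: unlimited
#' peaks, minimum peak height 0, peak threshold 2 SD of the flattened
#' residual, and peak bandwidth limited to 1--15 Hz.
#'
#' @param max_n_peaks Maximum number of peaks (default unlimited).
#' @param min_peak_height Minimum peak height in log10 power units.
#' @param peak_threshold Residual-SD multiple a candidate peak must exceed.
#' @param peak_width_limits Bandwidth limits in Hz (bandwidth = 2 * Gaussian
#'   SD).
#' @return A list of settings.
#' @export
spectrum_settings <- function(max_n_peaks = Inf, min_peak_height = 0,
                              peak_threshold = 2,
                              peak_width_limits = c(1, 15)) {
  list(max_n_peaks = max_n_peaks, min_peak_height = min_peak_height,
       peak_threshold = peak_threshold,
       peak_width_limits = peak_width_limits)
}

gaussian_log <- function(f, cf, pw, sd) pw * exp(-(f - cf)^2 / (2 * sd^2))

peaks_model <- function(f, peaks) {
  y <- numeric(length(f))
  if (nrow(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      y <- y + gaussian_log(f, peaks$cf[i], peaks$pw[i], peaks$bw[i] / 2)
    }
  }
  y
}

# Aperiodic fit in log-log space.  Robust variant: ordinary fit, then
# discard top-quartile positive residuals (peak regions) and refit.
aperiodic_fit <- function(lf, ly, robust = TRUE) {
  fit <- stats::lm.fit(cbind(1, lf), ly)
  if (robust) {
    res <- fit$residuals
    cut <- stats::quantile(res, 0.75)
    keep <- !(res > 0 & res > cut)
    if (sum(keep) >= 3) fit <- stats::lm.fit(cbind(1, lf[keep]), ly[keep])
  }
  c(offset = fit$coefficients[[1]], exponent = -fit$coefficients[[2]])
}

aperiodic_model <- function(lf, ap) ap[["offset"]] - ap[["exponent"]] * lf

#' Fit periodic and aperiodic spectral components
#'
#' Iterative fit in log10 power space: (1) robust linear aperiodic fit in
#' log-log coordinates; (2) Gaussian peaks extracted one at a time from the
#' flattened residual while the maximum exceeds `peak_threshold` SD of the
#' residual (and `min_peak_height`), each peak width clipped to the
#' configured limits; (3) joint least-squares refinement of all Gaussians on
#' the flattened spectrum; (4) final aperiodic refit on the peak-subtracted
#' spectrum.  R^2 is the squared correlation between the full model and the
#' log10 PSD.
#'
#' @param psd A [baseline_psd()] or a list with `freqs` and `power`
#'   (all power values must be positive).
#' @param settings A [spectrum_settings()] list.
#' @return An object of class `spectrum_fit`: `aperiodic`
#'   (offset, exponent), `peaks` (data frame cf/pw/bw), `r_squared`,
#'   `freqs`, `log_power`, `ap_model`, `model`, `settings`, `converged`.
#' @export
fit_spectrum <- function(psd, settings = spectrum_settings()) {
  f <- psd$freqs
  pw <- psd$power
  if (any(pw <= 0)) stop("all power values must be positive to fit in log space")
  lf <- log10(f)
  ly <- log10(pw)
  bw_lim <- settings$peak_width_limits
  sd_lim <- bw_lim / 2

  ap <- aperiodic_fit(lf, ly)
  flat <- ly - aperiodic_model(lf, ap)

  peaks <- data.frame(cf = numeric(), pw = numeric(), bw = numeric())
  resid <- flat
  max_iter <- if (is.finite(settings$max_n_peaks)) settings$max_n_peaks else 16
  converged <- TRUE
  for (k in seq_len(max_iter)) {
    thr <- settings$peak_threshold * stats::sd(resid)
    i_max <- which.max(resid)
    # 1e-9 log10-power floor keeps numerical jitter from spawning peaks
    if (resid[i_max] <= max(thr, settings$min_peak_height, 1e-9)) break
    guess_cf <- f[i_max]
    guess_pw <- resid[i_max]
    # half-width at half maximum from the residual around the peak
    half <- guess_pw / 2
    lo <- i_max; while (lo > 1 && resid[lo] > half) lo <- lo - 1
    hi <- i_max; while (hi < length(f) && resid[hi] > half) hi <- hi + 1
    fwhm <- max(f[hi] - f[lo], diff(f)[1])
    guess_sd <- min(max(fwhm / 2.355, sd_lim[1]), sd_lim[2])
    one <- stats::optim(
      c(guess_cf, guess_pw, guess_sd),
      function(p) sum((resid - gaussian_log(f, p[1], p[2], p[3]))^2),
      method = "L-BFGS-B",
      lower = c(min(f), 0, sd_lim[1]), upper = c(max(f), Inf, sd_lim[2]))
    peaks <- rbind(peaks, data.frame(cf = one$par[1], pw = one$par[2],
                                     bw = 2 * one$par[3]))
    resid <- resid - gaussian_log(f, one$par[1], one$par[2], one$par[3])
    if (k == max_iter && !is.finite(settings$max_n_peaks)) converged <- FALSE
  }

  if (nrow(peaks)) {
    par0 <- as.vector(t(as.matrix(transform(peaks, bw = bw / 2))))
    joint <- stats::optim(
      par0,
      function(p) {
        P <- matrix(p, ncol = 3, byrow = TRUE)
        m <- numeric(length(f))
        for (i in seq_len(nrow(P))) m <- m + gaussian_log(f, P[i, 1], P[i, 2], P[i, 3])
        sum((flat - m)^2)
      },
      method = "L-BFGS-B",
      lower = rep(c(min(f), 0, sd_lim[1]), nrow(peaks)),
      upper = rep(c(max(f), Inf, sd_lim[2]), nrow(peaks)))
    P <- matrix(joint$par, ncol = 3, byrow = TRUE)
    peaks <- data.frame(cf = P[, 1], pw = P[, 2], bw = 2 * P[, 3])
    if (joint$convergence != 0) converged <- FALSE
  }

  pk_model <- peaks_model(f, peaks)
  ap <- aperiodic_fit(lf, ly - pk_model, robust = FALSE)
  ap_model <- aperiodic_model(lf, ap)
  model <- ap_model + pk_model
  r2 <- if (stats::sd(ly) > 0) stats::cor(model, ly)^2 else 1
  peaks <- peaks[order(peaks$cf), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(aperiodic = ap, peaks = peaks, r_squared = r2,
                 freqs = f, log_power = ly, ap_model = ap_model,
                 model = model, settings = settings, converged = converged),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("spectrum_fit: offset %.3f, exponent %.3f, %d peak(s), R^2 = %.4f\n",
              x$aperiodic[["offset"]], x$aperiodic[["exponent"]],
              nrow(x$peaks), x$r_squared))
  if (nrow(x$peaks)) print(round(x$peaks, 3))
  invisible(x)
}

#' Band summary of a spectral component
#'
#' Averages a fitted spectrum's components over a frequency band in log10
#' power units: `full` is the mean log10 PSD (the unparameterized signal),
#' `aperiodic` the mean of the fitted aperiodic model, and `periodic` the
#' mean flattened spectrum (full minus aperiodic), so
#' full = aperiodic + periodic holds exactly.
#'
#' @param fit A [fit_spectrum()] result.
#' @param band Frequency band `c(lo, hi)` in Hz.
#' @param component `"full"`, `"aperiodic"` or `"periodic"`.
#' @return Scalar band value (log10 power units).
#' @export
component_band_value <- function(fit, band = c(14.5, 15.5),
                                 component = c("full", "aperiodic", "periodic")) {
  component <- match.arg(component)
  if (band[1] < min(fit$freqs) || band[2] > max(fit$freqs)) {
    stop("band outside the fitted range")
  }
  idx <- which(fit$freqs >= band[1] & fit$freqs <= band[2])
  switch(component,
         full = mean(fit$log_power[idx]),
         aperiodic = mean(fit$ap_model[idx]),
         periodic = mean(fit$log_power[idx]) - mean(fit$ap_model[idx]))
}
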