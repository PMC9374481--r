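# Epoch container and individualized-threshold artifact rejection.

#' Epoched multi-sensor recording
#'
#' @param data Numeric array, trial x sensor x time.
#' @param fs Sampling rate in Hz.
#' @param window Epoch extent in ms, `c(start, end)`; stimulus onset is 0 ms.
#' @param kept_mask Logical per-trial inclusion mask (default all kept).
#' @return An object of class `sensor_epochs` with `data`, `fs`, `window`,
#'   `t0_index` (sample index of 0 ms) and `kept_mask`.
#' @export
sensor_epochs <- function(data, fs = 1000, window = c(-600, 3200),
                          kept_mask = NULL) {
  stopifnot(length(dim(data)) == 3)
  n_expected <- diff(window) * fs / 1000
  if (dim(data)[3] != n_expected) {
    stop(sprintf("time axis has %d samples; window implies %d",
                 dim(data)[3], n_expected))
  }
  if (is.null(kept_mask)) kept_mask <- rep(TRUE, dim(data)[1])
  stopifnot(length(kept_mask) == dim(data)[1])
  structure(list(data = data, fs = fs, window = window,
                 t0_index = as.integer(-window[1] * fs / 1000) + 1L,
                 kept_mask = kept_mask),
            class = "sensor_epochs")
}

#' @export
print.sensor_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("sensor_epochs: %d trials (%d kept) x %d sensors x %d samples @ %g Hz, %d..%d ms\n",
              d[1], sum(x$kept_mask), d[2], d[3], x$fs,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Individualized-threshold artifact rejection
#'
#' Computes, per trial, the peak absolute amplitude across all sensors and
#' samples, and the peak absolute first-difference gradient (amplitude units
#' per second).  A trial is rejected when either peak strictly exceeds the
#' subject's own threshold, mean + k * SD of the respective trial-peak
#' distribution.  This adapts the cutoff to each subject's overall signal
#' scale, as sensor-level amplitude depends strongly on head-to-sensor
#' distance.
#'
#' @param epochs A [sensor_epochs()] object with at least 2 trials.
#' @param k_amp,k_grad SD multipliers for the amplitude and gradient
#'   thresholds (both default 3, must be > 0).
#' @return A list: `epochs` (with updated `kept_mask`) and `report`
#'   (class `rejection_report`: thresholds, peak vectors, counts).
#' @export
reject_artifacts <- function(epochs, k_amp = 3, k_grad = 3) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  n_trials <- dim(epochs$data)[1]
  if (n_trials < 2) stop("need at least 2 trials")
  if (k_amp <= 0 || k_grad <= 0) stop("k_amp and k_grad must be > 0")

  peak_amp <- apply(epochs$data, 1, function(tr) max(abs(tr)))
  peak_grad <- apply(epochs$data, 1, function(tr) {
    max(abs(tr[, -1, drop = FALSE] - tr[, -ncol(tr), drop = FALSE])) * epochs$fs
  })
  amp_thr <- mean(peak_amp) + k_amp * stats::sd(peak_amp)
  grad_thr <- mean(peak_grad) + k_grad * stats::sd(peak_grad)
  reject <- peak_amp > amp_thr | peak_grad > grad_thr
  if (all(reject)) {
    stop("all trials rejected; review thresholds (k_amp/k_grad) for this subject")
  }
  epochs$kept_mask <- epochs$kept_mask & !reject
  report <- structure(list(
    amp_threshold = amp_thr, grad_threshold = grad_thr,
    peak_amp = peak_amp, peak_grad = peak_grad,
    rejected_amp = peak_amp > amp_thr, rejected_grad = peak_grad > grad_thr,
    n_kept = sum(!reject), n_rejected = sum(reject)),
    class = "rejection_report")
  list(epochs = epochs, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("rejection_report: %d kept / %d rejected (amp thr %.3g, grad thr %.3g)\n",
              x$n_kept, x$n_rejected, x$amp_threshold, x$grad_threshold))
  invisible(x)
}
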