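# Frequency-domain DICS beamforming: band-limited cross-spectral density,
# unit-gain spatial filters, pseudo-t source maps, peak-voxel selection and
# virtual-sensor extraction.

#' Band-limited cross-spectral density
#'
#' Trial-averaged outer products of complex-demodulation coefficient vectors
#' over the requested frequency band and time window, averaged across
#' trials, band bins and frames.  Hermitian by construction.
#'
#' @param epochs A [sensor_epochs()] object; kept trials are used.
#' @param band Frequency band `c(lo, hi)` in Hz (bins at 0.5 Hz spacing).
#' @param window Time window `c(start, end)` in ms (frames at 100 ms).
#' @param freq_step Bin spacing in Hz.
#' @return An object of class `csd`: complex `matrix` (sensor x sensor),
#'   `band`, `window`, `n_trials`.
#' @export
compute_csd <- function(epochs, band = c(14.5, 15.5), window = c(200, 2000),
                        freq_step = 0.5) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  if (band[1] > band[2] || window[1] > window[2]) stop("empty window or band")
  if (window[1] < epochs$window[1] || window[2] > epochs$window[2]) {
    stop("window outside epoch")
  }
  freqs <- seq(band[1], band[2], by = freq_step)
  times <- tfr_times()
  frames <- times[times >= window[1] & times <= window[2]]
  if (!length(freqs) || !length(frames)) stop("empty window or band")

  dat <- epochs$data[epochs$kept_mask, , , drop = FALSE]
  n_trial <- dim(dat)[1]; n_sens <- dim(dat)[2]; n_samp <- dim(dat)[3]
  if (n_trial == 0) stop("no kept trials")
  X <- matrix(aperm(dat, c(3, 1, 2)), nrow = n_trial * n_sens,
              ncol = n_samp, byrow = TRUE)
  cc <- demod_transform(X, epochs$fs, freqs, frames, epochs$window[1])
  dim(cc) <- c(n_trial, n_sens, length(freqs), length(frames))

  C <- matrix(0 + 0i, n_sens, n_sens)
  n_obs <- 0L
  for (f in seq_along(freqs)) {
    for (tt in seq_along(frames)) {
      V <- cc[, , f, tt, drop = TRUE]       # trial x sensor
      if (is.null(dim(V))) V <- matrix(V, nrow = n_trial)
      C <- C + crossprod(Conj(V), V)        # sum over trials of conj(v) v^T
      n_obs <- n_obs + n_trial
    }
  }
  C <- C / n_obs
  C <- (C + Conj(t(C))) / 2                 # enforce exact Hermitian symmetry
  structure(list(matrix = C, band = band, window = window,
                 n_trials = n_trial),
            class = "csd")
}

#' @export
print.csd <- function(x, ...) {
  cat(sprintf("csd: %d x %d sensors, %.1f-%.1f Hz, %d-%d ms, %d trials\n",
              nrow(x$matrix), ncol(x$matrix), x$band[1], x$band[2],
              x$window[1], x$window[2], x$n_trials))
  invisible(x)
}

#' DICS spatial filters
#'
#' For each voxel with gain vector l, the unit-gain spatial filter is
#' w = (C_r + lambda I)^-1 l / (l' (C_r + lambda I)^-1 l), where C_r is the
#' real part of the cross-spectral density (the power-mapping DICS variant)
#' and lambda = `lambda_frac` times the mean sensor power.
#'
#' @param csd A [compute_csd()] result.
#' @param leadfield A [build_leadfield()] result with matching sensor count.
#' @param lambda_frac Regularization as a fraction of mean diagonal power.
#' @return An object of class `spatial_filters`: `weights`
#'   (voxel x sensor), `lambda`, `band`, `window`.
#' @export
dics_filters <- function(csd, leadfield, lambda_frac = 0.05) {
  Cr <- Re(csd$matrix)
  n_sens <- ncol(Cr)
  if (ncol(leadfield$gains) != n_sens) {
    stop("lead field and CSD sensor counts differ")
  }
  lambda <- lambda_frac * mean(diag(Cr))
  Creg <- Cr + diag(lambda, n_sens)
  Ci <- tryCatch(solve(Creg),
                 error = function(e) stop("regularized CSD is singular; increase lambda_frac"))
  L <- leadfield$gains                       # voxel x sensor
  num <- L %*% Ci                            # voxel x sensor
  denom <- rowSums(num * L)                  # l' Ci l per voxel
  if (any(denom <= 0)) stop("non-positive filter denominator")
  W <- num / denom
  structure(list(weights = W, lambda = lambda, lambda_frac = lambda_frac,
                 band = csd$band, window = csd$window,
                 leadfield = leadfield),
            class = "spatial_filters")
}

#' @export
print.spatial_filters <- function(x, ...) {
  cat(sprintf("spatial_filters: %d voxels x %d sensors, lambda = %.3g\n",
              nrow(x$weights), ncol(x$weights), x$lambda))
  invisible(x)
}

#' Pseudo-t source power map
#'
#' Projects active- and baseline-window cross-spectral densities through the
#' spatial filters and normalizes per voxel:
#' pseudo_t(v) = (P_active - P_baseline) / P_baseline.  The map is invariant
#' under global rescaling of the data.
#'
#' @param filters A [dics_filters()] result.
#' @param csd_active,csd_baseline [compute_csd()] results sharing the band.
#' @return An object of class `source_map`: `pseudo_t`, `p_active`,
#'   `p_baseline` (one value per voxel).
#' @export
source_power_map <- function(filters, csd_active, csd_baseline) {
  if (!isTRUE(all.equal(csd_active$band, csd_baseline$band))) {
    stop("active and baseline CSDs must share the frequency band")
  }
  W <- filters$weights
  p_act <- rowSums((W %*% Re(csd_active$matrix)) * W)
  p_base <- rowSums((W %*% Re(csd_baseline$matrix)) * W)
  if (any(p_base <= 0)) stop("non-positive baseline power")
  structure(list(pseudo_t = (p_act - p_base) / p_base,
                 p_active = p_act, p_baseline = p_base),
            class = "source_map")
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("source_map: %d voxels, peak pseudo-t %.3f at voxel %d\n",
              length(x$pseudo_t), max(x$pseudo_t), which.max(x$pseudo_t)))
  invisible(x)
}

#' Grand-average peak voxel
#'
#' Averages per-subject pseudo-t maps and returns the voxel with the largest
#' grand-average value (ties broken by lowest index).
#'
#' @param maps List of [source_power_map()] results (or numeric vectors) on
#'   identical grids.
#' @return A list: `peak_voxel`, `grand_average` (numeric vector).
#' @export
find_peak_voxel <- function(maps) {
  if (!length(maps)) stop("need at least one map")
  vecs <- lapply(maps, function(m) if (inherits(m, "source_map")) m$pseudo_t else m)
  n <- unique(vapply(vecs, length, integer(1)))
  if (length(n) != 1) stop("source grids differ across maps")
  ga <- Reduce(`+`, vecs) / length(vecs)
  list(peak_voxel = which.max(ga), grand_average = ga)
}

#' Virtual sensor extraction
#'
#' Applies a voxel's beamformer weight vector to the sensor data at every
#' sample, yielding a trial x time source-space series.
#'
#' @param filters A [dics_filters()] result.
#' @param voxel Voxel index.
#' @param epochs A [sensor_epochs()] object; kept trials are used.
#' @return Numeric matrix, kept-trial x time.
#' @export
virtual_sensor <- function(filters, voxel, epochs) {
  w <- filters$weights[voxel, ]
  dat <- epochs$data[epochs$kept_mask, , , drop = FALSE]
  if (dim(dat)[2] != length(w)) stop("sensor count mismatch")
  n_trial <- dim(dat)[1]; n_samp <- dim(dat)[3]
  out <- matrix(0, n_trial, n_samp)
  for (i in seq_len(n_trial)) out[i, ] <- w %*% dat[i, , ]
  out
}
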