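# Synthetic two-group cohort generator with full ground truth.  Emulates a
# 15 Hz flicker-entrainment MEG study: a phase-locked steady-state source
# with 30/45 Hz harmonics, a non-phase-locked baseline 15 Hz rhythm, 1/f
# background, trial-amplitude variability, occasional high-amplitude
# artifacts, and a cognitive score linked to entrainment amplitude.

#' Synthetic cohort configuration
#'
#' Returns the full parameter set of the generator.  Defaults reproduce the
#' study design: two groups (ADS n = 38, HC n = 20), 120 trials of 3800 ms
#' epochs at 1 kHz (-600..3200 ms), a 15 Hz stimulus flickering 0--1500 ms
#' with the neural response spanning roughly 200--2000 ms, and
#' group-dependent baseline 15 Hz amplitude and cross-trial variability.
#'
#' @param n_group Named counts per group, `c(ADS = , HC = )`.
#' @param n_trials Trials per subject.
#' @param fs Sampling rate (Hz).
#' @param epoch_window Epoch extent in ms.
#' @param stim_window Stimulus on/off in ms.
#' @param response_window Extent of the entrained response in ms.
#' @param f0 Entrainment frequency (Hz).
#' @param harmonic_gains Amplitudes of the 30/45 Hz harmonics relative to f0.
#' @param A_abs Per-group mean/sd of the subject-level entrainment source
#'   amplitude (arbitrary units).
#' @param cv_trial Per-group cross-trial coefficient of variation of the
#'   single-trial source amplitude.
#' @param B_base Per-group mean/sd of the sustained baseline 15 Hz
#'   oscillation amplitude.
#' @param aperiodic `c(offset, exponent)` of the 1/f source background,
#'   expressed on the scale of the TFR-derived PSD
#'   (log10 power = offset - exponent * log10 f).
#' @param sensor_noise_sd White sensor noise SD.
#' @param artifact_rate Per-trial probability of a high-amplitude transient.
#' @param artifact_gain Transient amplitude as a multiple of the typical
#'   sensor-level signal amplitude.
#' @param mmse_link `c(intercept, slope, sd)` linking the MMSE-like
#'   cognitive score to the subject's mean source amplitude.
#' @param n_sensors Virtual gradiometer count.
#' @param grid_dim,grid_spacing Source grid layout (voxels per axis, mm).
#' @param master_seed Integer master seed; every random draw in the cohort
#'   derives from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_group = c(ADS = 38, HC = 20),
                         n_trials = 120,
                         fs = 1000,
                         epoch_window = c(-600, 3200),
                         stim_window = c(0, 1500),
                         response_window = c(200, 2000),
                         f0 = 15,
                         harmonic_gains = c(`30` = 0.4, `45` = 0.2),
                         A_abs = list(ADS = c(mean = 1.0, sd = 0.2),
                                      HC  = c(mean = 1.0, sd = 0.2)),
                         cv_trial = c(ADS = 0.25, HC = 0.40),
                         B_base = list(ADS = c(mean = 0.25, sd = 0.06),
                                       HC  = c(mean = 0.45, sd = 0.06)),
                         aperiodic = c(offset = -1.0, exponent = 1.0),
                         sensor_noise_sd = 0.1,
                         artifact_rate = 0.02,
                         artifact_gain = 10,
                         mmse_link = c(intercept = 18, slope = 8, sd = 2),
                         n_sensors = 32,
                         grid_dim = c(4, 4, 4),
                         grid_spacing = 20,
                         master_seed = 1) {
  cfg <- list(n_group = n_group, n_trials = n_trials, fs = fs,
              epoch_window = epoch_window, stim_window = stim_window,
              response_window = response_window, f0 = f0,
              harmonic_gains = harmonic_gains, A_abs = A_abs,
              cv_trial = cv_trial, B_base = B_base, aperiodic = aperiodic,
              sensor_noise_sd = sensor_noise_sd,
              artifact_rate = artifact_rate, artifact_gain = artifact_gain,
              mmse_link = mmse_link, n_sensors = n_sensors,
              grid_dim = grid_dim, grid_spacing = grid_spacing,
              master_seed = master_seed)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (!all(c("ADS", "HC") %in% names(cfg$n_group))) {
    stop("groups must be labeled ADS and HC")
  }
  n_samples <- diff(cfg$epoch_window) * cfg$fs / 1000
  if (cfg$fs == 1000 && n_samples != 3800) {
    stop("epoch grid must be exactly 3800 samples at 1 kHz")
  }
  amps <- c(unlist(cfg$A_abs), unlist(cfg$B_base), cfg$harmonic_gains)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  if (any(cfg$cv_trial < 0)) stop("cv_trial must be >= 0")
  if (cfg$sensor_noise_sd < 0) stop("sensor_noise_sd must be >= 0")
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1) {
    stop("artifact_rate must be in [0, 1]")
  }
  invisible(cfg)
}

# Deterministic per-subject seed stream below 2^31.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + index * 16807) %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parametric lead field for a virtual sensor array
#'
#' Stands in for a physical forward solution: each voxel's sensor gain
#' pattern is a smooth Gaussian falloff of sensitivity with distance to
#' sensors arranged on a virtual helmet hemisphere above the source grid,
#' with a small seeded per-entry modulation so patterns are correlated but
#' not identical.  Deterministic in its seed.
#'
#' @param grid_spec Either a numeric matrix of voxel coordinates (voxel x 3,
#'   mm) or a list with `dim` (voxels per axis) and `spacing` (mm).
#' @param n_sensors Number of sensors (>= 8).
#' @param seed Integer seed.
#' @return An object of class `leadfield` with `grid_coords` (voxel x 3),
#'   `gains` (voxel x sensor), `sensor_coords`, `n_sensors`, `seed`.
#' @export
build_leadfield <- function(grid_spec, n_sensors, seed) {
  if (is.list(grid_spec) && !is.matrix(grid_spec)) {
    dm <- grid_spec$dim; sp <- grid_spec$spacing
    coords <- as.matrix(expand.grid(
      x = (seq_len(dm[1]) - (dm[1] + 1) / 2) * sp,
      y = (seq_len(dm[2]) - (dm[2] + 1) / 2) * sp,
      z = (seq_len(dm[3]) - (dm[3] + 1) / 2) * sp))
  } else {
    coords <- as.matrix(grid_spec)
  }
  if (nrow(coords) < 8) stop("grid must have at least 8 voxels")
  if (n_sensors < 8) stop("need at least 8 sensors")
  if (anyDuplicated(coords)) stop("degenerate grid: duplicate voxel coordinates")

  extent <- max(apply(coords, 2, function(v) diff(range(v))))
  radius <- extent + 40
  with_seed(seed, {
    # jittered Fibonacci hemisphere above the grid centroid
    i <- seq_len(n_sensors)
    phi <- (1 + sqrt(5)) / 2
    theta <- 2 * pi * i / phi
    zfrac <- i / (n_sensors + 1)
    jitter <- matrix(stats::runif(n_sensors * 2, -0.05, 0.05), ncol = 2)
    az <- theta + jitter[, 1]
    el <- asin(zfrac) + jitter[, 2]
    ctr <- colMeans(coords)
    sens <- cbind(ctr[1] + radius * cos(el) * cos(az),
                  ctr[2] + radius * cos(el) * sin(az),
                  ctr[3] + radius * sin(el))
    sigma <- 0.35 * extent + 10
    d2 <- outer(rowSums(coords^2), rowSums(sens^2), "+") -
      2 * coords %*% t(sens)
    gains <- exp(-d2 / (2 * sigma^2))
    mod <- matrix(stats::runif(length(gains), 0.9, 1.1), nrow(gains))
    gains <- gains * mod
    # unit-norm rows: every voxel couples to the array with the same total
    # sensitivity, so depth differences do not inflate beamformer filter
    # norms (|w| >= 1/|l|); voxels still differ by pattern direction
    gains <- gains / sqrt(rowSums(gains^2))
  })
  if (!all(is.finite(gains))) stop("non-finite gains")
  if (any(apply(gains, 1, function(r) all(r == 0)))) {
    stop("lead field has an all-zero gain row")
  }
  structure(list(grid_coords = coords, gains = gains, sensor_coords = sens,
                 n_sensors = n_sensors, seed = seed),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("leadfield: %d voxels x %d sensors (seed %d)\n",
              nrow(x$gains), ncol(x$gains), x$seed))
  invisible(x)
}

# Response envelope: linear ramp 0 -> 1 over 150-250 ms, plateau through
# stimulus offset (1500 ms), linear decay to 0 by 2000 ms.
response_envelope <- function(t_ms, ramp = c(150, 250), plateau_end = 1500,
                              decay_end = 2000) {
  w <- numeric(length(t_ms))
  up <- t_ms >= ramp[1] & t_ms < ramp[2]
  w[up] <- (t_ms[up] - ramp[1]) / diff(ramp)
  w[t_ms >= ramp[2] & t_ms <= plateau_end] <- 1
  down <- t_ms > plateau_end & t_ms < decay_end
  w[down] <- 1 - (t_ms[down] - plateau_end) / (decay_end - plateau_end)
  w
}

# 1/f noise via spectral shaping of white noise, calibrated so the
# TFR-derived PSD (calibrated envelope squared) has expectation
# 10^offset * f^-exponent.
onef_noise <- function(n, fs, offset, exponent, enbw) {
  if (!is.finite(offset)) return(numeric(n))
  half <- floor(n / 2)
  fk <- (1:half) * fs / n
  s2 <- 10^offset * fk^(-exponent) / (4 * enbw)
  amp <- sqrt(n * fs * s2 / 2)
  z <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) * amp
  spec <- complex(real = numeric(n))
  spec[2:(half + 1)] <- z
  spec[n:(n - half + 2)] <- Conj(z[1:(half - 1)])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Simulate one subject
#'
#' Builds a trial x sensor x time epoch array for one subject: per-trial
#' source time course (ramped 15 Hz steady-state response plus harmonics,
#' phase-locked across trials; a sustained baseline 15 Hz oscillation with
#' random per-trial phase; 1/f background) projected through the source
#' voxel's gain row, plus white sensor noise and occasional half-sine
#' artifact transients.
#'
#' @param config A [synth_config()].
#' @param group `"ADS"` or `"HC"`.
#' @param subject_seed Integer seed for this subject's draws.
#' @param leadfield A [build_leadfield()] result.
#' @param source_voxel Index of the true source voxel (default: the voxel
#'   nearest the grid centroid).
#' @return A list of class `subject_record`: `subject_id`, `group`,
#'   `epochs` (a `sensor_epochs`), `ground_truth` (true voxel, per-trial
#'   source amplitudes, baseline amplitude, aperiodic parameters, artifact
#'   trials), `covariates` (cognitive score).
#' @export
simulate_subject <- function(config, group, subject_seed, leadfield,
                             source_voxel = NULL) {
  stopifnot(group %in% c("ADS", "HC"))
  validate_synth_config(config)
  if (is.null(source_voxel)) {
    ctr <- colMeans(leadfield$grid_coords)
    source_voxel <- which.min(colSums((t(leadfield$grid_coords) - ctr)^2))
  }
  fs <- config$fs
  n_samples <- as.integer(diff(config$epoch_window) * fs / 1000)
  t_ms <- config$epoch_window[1] + (seq_len(n_samples) - 1) * 1000 / fs
  t_sec <- t_ms / 1000
  w <- response_envelope(t_ms,
                         ramp = c(config$response_window[1] - 50,
                                  config$response_window[1] + 50),
                         plateau_end = config$stim_window[2],
                         decay_end = config$response_window[2])
  gain_row <- leadfield$gains[source_voxel, ]
  n_sens <- length(gain_row)
  n_trials <- config$n_trials
  enbw <- demod_enbw(fs)

  rec <- with_seed(subject_seed, {
    a_par <- config$A_abs[[group]]
    a_subj <- max(a_par["mean"] + a_par["sd"] * stats::rnorm(1), 0)
    cv <- config$cv_trial[[group]]
    if (cv > 0) {
      s2 <- log(1 + cv^2)
      a_trials <- a_subj * exp(sqrt(s2) * stats::rnorm(n_trials) - s2 / 2)
    } else {
      a_trials <- rep(a_subj, n_trials)
    }
    b_par <- config$B_base[[group]]
    b_subj <- max(b_par["mean"] + b_par["sd"] * stats::rnorm(1), 0)
    phi <- stats::runif(1, 0, 2 * pi)          # phase-locked SSVEP phase
    phi_b <- stats::runif(n_trials, 0, 2 * pi) # baseline phase, per trial

    harm_f <- as.numeric(names(config$harmonic_gains))
    ssvep_shape <- w * sin(2 * pi * config$f0 * t_sec + phi)
    for (k in seq_along(harm_f)) {
      ssvep_shape <- ssvep_shape +
        config$harmonic_gains[k] * w * sin(2 * pi * harm_f[k] * t_sec + phi)
    }

    dat <- array(0, dim = c(n_trials, n_sens, n_samples))
    artifact_trials <- logical(n_trials)
    art_amp <- config$artifact_gain * a_par[["mean"]] * max(abs(gain_row))
    for (i in seq_len(n_trials)) {
      src <- a_trials[i] * ssvep_shape +
        b_subj * sin(2 * pi * config$f0 * t_sec + phi_b[i]) +
        onef_noise(n_samples, fs, config$aperiodic[["offset"]],
                   config$aperiodic[["exponent"]], enbw)
      tr <- outer(gain_row, src)
      if (config$sensor_noise_sd > 0) {
        tr <- tr + config$sensor_noise_sd *
          matrix(stats::rnorm(n_sens * n_samples), n_sens, n_samples)
      }
      if (config$artifact_rate > 0 && stats::runif(1) < config$artifact_rate) {
        artifact_trials[i] <- TRUE
        dur <- round(0.1 * fs)
        onset <- sample.int(n_samples - dur, 1)
        hit <- sample.int(n_sens, max(1, round(n_sens / 4)))
        pulse <- art_amp * sin(pi * seq_len(dur) / dur)
        tr[hit, onset:(onset + dur - 1)] <-
          tr[hit, onset:(onset + dur - 1)] + rep(pulse, each = length(hit))
      }
      dat[i, , ] <- tr
    }
    score <- config$mmse_link[["intercept"]] +
      config$mmse_link[["slope"]] * mean(a_trials) +
      config$mmse_link[["sd"]] * stats::rnorm(1)
    list(dat = dat, a_trials = a_trials, b_subj = b_subj, score = score,
         artifact_trials = artifact_trials)
  })

  epochs <- sensor_epochs(rec$dat, fs = fs, window = config$epoch_window)
  structure(list(
    subject_id = sprintf("%s_%08d", group, subject_seed %% 1e8),
    group = group,
    epochs = epochs,
    ground_truth = list(
      true_voxel = source_voxel,
      a_trials = rec$a_trials,
      baseline_amplitude = rec$b_subj,
      aperiodic = config$aperiodic,
      cv_target = config$cv_trial[[group]],
      artifact_trials = rec$artifact_trials),
    covariates = list(score = rec$score)),
    class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("subject_record %s (%s): %d trials, %d sensors\n",
              x$subject_id, x$group, dim(x$epochs$data)[1],
              dim(x$epochs$data)[2]))
  invisible(x)
}

#' Simulate a full two-group cohort
#'
#' Generates every subject with seeds derived deterministically from the
#' master seed, together with a cohort-level ground-truth table.
#'
#' @param config A [synth_config()].
#' @param leadfield Optional precomputed [build_leadfield()]; by default one
#'   is built from the config's grid specification with a seed derived from
#'   the master seed.
#' @return A list of class `synth_cohort`: `subjects` (list of
#'   `subject_record`), `ground_truth` (data frame), `leadfield`, `config`,
#'   `source_voxel`.
#' @export
simulate_cohort <- function(config, leadfield = NULL) {
  validate_synth_config(config)
  if (is.null(leadfield)) {
    leadfield <- build_leadfield(
      list(dim = config$grid_dim, spacing = config$grid_spacing),
      config$n_sensors, seed = derive_seed(config$master_seed, 0L))
  }
  ctr <- colMeans(leadfield$grid_coords)
  source_voxel <- which.min(colSums((t(leadfield$grid_coords) - ctr)^2))
  groups <- rep(c("ADS", "HC"), times = config$n_group[c("ADS", "HC")])
  subjects <- vector("list", length(groups))
  gt <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    seed_i <- derive_seed(config$master_seed, i)
    subjects[[i]] <- simulate_subject(config, groups[i], seed_i, leadfield,
                                      source_voxel)
    s <- subjects[[i]]
    a <- s$ground_truth$a_trials
    gt[[i]] <- data.frame(
      subject = s$subject_id, group = s$group,
      true_voxel = s$ground_truth$true_voxel,
      a_mean = mean(a),
      cv_target = s$ground_truth$cv_target,
      cv_empirical = stats::sd(a) / mean(a),
      baseline_amplitude = s$ground_truth$baseline_amplitude,
      ap_offset = config$aperiodic[["offset"]],
      ap_exponent = config$aperiodic[["exponent"]],
      n_artifact_trials = sum(s$ground_truth$artifact_trials),
      score = s$covariates$score)
  }
  structure(list(subjects = subjects, ground_truth = do.call(rbind, gt),
                 leadfield = leadfield, config = config,
                 source_voxel = source_voxel),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("synth_cohort: %d subjects (%s), %d trials each, %d sensors, %d voxels\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(table(x$ground_truth$group)),
                            table(x$ground_truth$group)), collapse = ", "),
              x$config$n_trials, x$config$n_sensors,
              nrow(x$leadfield$gains)))
  invisible(x)
}
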