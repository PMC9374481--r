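---
title: "Methods: visual entrainment analysis for MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visual entrainment analysis for MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megentrain)
```

# The analysis problem

A steady-state visual evoked response (SSVEP) study flickers a stimulus at
15 Hz for 1.5 s per trial and records MEG while two groups — patients on
the Alzheimer's disease spectrum (ADS) and healthy controls (HC) — fixate
it. The neural questions are quantitative: how strongly does primary
visual cortex entrain to the flicker (absolute amplitude), how strongly
relative to its own pre-stimulus baseline (relative amplitude), how
consistent is the response across trials in phase (inter-trial phase
locking, ITPL) and in amplitude (coefficient of variation, CV), and how
much sustained 15 Hz rhythm and 1/f background does the baseline itself
contain (periodic/aperiodic parameterization). `megentrain` implements
this analysis chain end-to-end and pairs it with a synthetic cohort
generator whose ground truth exposes every quantity the pipeline
estimates, so each stage can be validated by recovery rather than by
eyeballing.

# Pipeline stages and their models

## Epochs and artifact rejection

Epochs span −600..3200 ms around stimulus onset at 1 kHz (3800 samples);
the pre-stimulus baseline is −600..0 ms. Trials are rejected by an
individualized threshold: for each trial the peak absolute amplitude over
all sensors and the peak absolute gradient (first difference × sampling
rate) are computed, and a trial is dropped when either peak strictly
exceeds the subject's own mean + k·SD of the respective trial-peak
distribution (k = 3 for both criteria by default). Thresholding on the
subject's own signal distribution absorbs the large between-subject
differences in absolute field strength that head-to-sensor distance
induces. The rule is a single pass, so raising k can only keep more
trials, and it is equivariant under trial reordering.

## Complex demodulation

The time–frequency transform multiplies the signal by
$e^{-i 2\pi f t}$ for each analysis frequency (4–50 Hz in 0.5 Hz steps, 93
bins), lowpass-filters the product, and samples the result on a 100 ms
frame grid (−600..3200 ms, 39 frames). Coefficients are calibrated so a
sinusoid of amplitude $A$ at a bin centre has modulus $A$; its phase is
the sinusoid's phase (constant over frames).

The lowpass FIR is a Hamming windowed sinc with its passband edge at 1 Hz
and its stopband from 4.5 Hz (943 taps at 1 kHz). Two constraints pin this
design. First, the stimulation band is analysed as the mean over the
14.5/15.0/15.5 Hz bins, so the response at ±0.5 Hz from a tone must pass
essentially unattenuated (measured H(0.5 Hz) ≈ 1.001). Second, a tone must
contribute less than 5% of its envelope to bins 5 Hz away (measured
H(5 Hz) ≈ 0.001). A much longer filter with a ~1 Hz transition band would
sharpen frequency resolution further, but its ±1.6 s support would exceed
the 600 ms baseline: every baseline frame would become a truncated-window
estimate and the response envelope would smear far beyond the true
200–2000 ms extent. The compact design keeps temporal smearing to about
one 500 ms half-width, which is the price of ±2 Hz spectral smoothing
around each bin.

### Epoch-edge frames

Frames closer to an epoch edge than the filter half-width are computed
from a truncated window. No scalar rescaling can make such frames
simultaneously correct for deterministic signals and for noise: matching
the DC gain inflates their noise power up to two-fold, matching the noise
gain deflates sustained oscillations. For 1/f noise the truncation also
doubles the effective bandwidth, which biases power upward regardless of
scaling. The package therefore (1) rescales truncated projection columns
to the full filter's noise gain, so stationary noise reads flat across the
whole frame grid; (2) uses the *median* across baseline frames as the
baseline reference in `baseline_normalize()`, which is insensitive to the
two to three distorted outermost frames where a mean would propagate their
bias into every bin of the map; and (3) reports per-frame filter support
via `tfr_frame_support()` and excludes frames below 80% support from
sensor-level inference. Virtual-sensor summary metrics keep the plain mean
over baseline frames (the small common droop cancels in group contrasts
and in the rel/abs/base identity).

## Window selection by cluster permutation

Each subject contributes a sensor-averaged baseline-relative power map
(percent change). A one-sample t statistic against zero is computed per
time–frequency bin across subjects; bins with two-sided uncorrected
p < 0.05 form 4-connected cluster candidates scored by summed |t|; the
null distribution of the maximum cluster mass is built by random sign
flips of the subject maps, and clusters with corrected p below α (0.001
by default) enter the selection mask. Sign flipping is exact for a
symmetric null of baseline-relative change. Two practical notes: the
smallest achievable corrected p is about $2^{-n}$ for n subjects (16
subjects are needed to clear α = 0.001), and on synthetic cohorts the
mask legitimately includes the 30/45 Hz harmonic rows and a broadband
stimulus-onset transient in addition to the 15 Hz row — the latter spans
approximately 200–2000 ms, widened by up to one filter half-width.

## DICS beamforming

The cross-spectral density (CSD) is the trial-, bin- and frame-averaged
outer product of the demodulation coefficient vectors over the analysis
band (14.5–15.5 Hz) and window, Hermitian by construction. Spatial
filters use the real-part (power-mapping) DICS form
$w_v = (C_r + \lambda I)^{-1} l_v \,/\, (l_v^\top (C_r + \lambda I)^{-1} l_v)$
with λ = 5% of mean sensor power, giving exact unit gain
$w_v^\top l_v = 1$. Source maps are pseudo-t values
$(P_\mathrm{act} - P_\mathrm{base}) / P_\mathrm{base}$ per voxel, computed
from active-window (200–2000 ms) and baseline-window (−600..0 ms) CSDs of
equal bandwidth; because CSDs are averages, the unequal window durations
affect only estimator variance, not expectation, so no further duration
correction is applied. The map is invariant under global rescaling of the
data. The peak voxel of the grand-average map across all subjects (ties
to the lowest index) defines the virtual sensor: the weight vector applied
to the sensor time series sample by sample.

## Entrainment metrics

All virtual-sensor metrics work on the trial-resolved TFR tensor.
Amplitude (|coefficient|) is used for envelopes and CV; power
(|coefficient|²) for sensor spectrograms, beamforming and the baseline
PSD. The band envelope averages |coefficients| over the three band bins,
per trial, before trial averaging (induced + evoked). `abs_amp` is the
mean envelope over 200–2000 ms, `base_amp` over −600..0 ms, and
`rel_amp` = 100·(abs − base)/base exactly. ITPL computes, per bin, the
modulus of the trial-averaged unit phase vector, then averages the
resultant over the band × window grid (pointwise-then-mean order is a
declared choice; zero-magnitude coefficients are excluded per bin and
counted). CV summarizes each trial by its band × window mean amplitude
and reports sample SD/mean. The per-frequency profile is the
baseline-relative percent change per bin averaged over the response
window; note that over a 1/f background this profile tilts upward in
frequency within the smoothing bandwidth, and the harmonics' relative
responses can exceed the fundamental's because their baselines are
smaller.

## Baseline spectral parameterization

The baseline PSD is the mean squared coefficient modulus over trials and
baseline frames, per bin. The fit separates it, in log₁₀ power space,
into an aperiodic line $b - \chi \log_{10} f$ and Gaussian peaks
(centre CF, height PW in log₁₀ units, bandwidth BW = 2 SD clipped to
1–15 Hz): a robust line fit (discard top-quartile positive residuals,
refit) is followed by iterative peak extraction while the maximum
flattened residual exceeds 2 SD of the residual (minimum height 0, with a
1e-9 numerical floor so exact model-class inputs yield zero peaks), a
joint least-squares refinement of all Gaussians, and a final aperiodic
refit on the peak-subtracted spectrum. R² is the squared correlation
between model and log₁₀ PSD. Band summaries average over the
14.5–15.5 Hz bins in log space: `full` is the data, `aperiodic` the
fitted line, and `periodic` their difference (the flattened data), so
full = aperiodic + periodic holds exactly. Fitting in log space
throughout, and defining the periodic band value from the flattened data
rather than the fitted Gaussians, are declared choices.

## Group statistics

Each metric is tested after per-group outlier exclusion (|value − group
mean| > 2.5 group SD, single pass, sample SD). Group contrasts use the
pooled-variance Student t (df = n₁ + n₂ − 2 — the convention implied by
the published degrees of freedom), Cohen's d = |t|·√(1/n₁ + 1/n₂), and
the JZS Bayes factor with a zero-centred Cauchy prior of scale 0.707 on
the standardized effect size, evaluated by adaptive quadrature of the
noncentral-t prior-predictive integral; BF₀₁ > 1 favors the null.
Regression of the cognitive score on entrainment amplitude uses OLS with
F = (R²/1)/((1−R²)/(n−2)) and partial η² = F/(F + df₂). A regression
Bayes factor is reported as supporting information using the
Zellner–Siow g-prior with scale √2/4; published regression Bayes factors
depend on software conventions that are not uniquely recoverable, so this
value is best-effort and is not used as a validation target.

# The synthetic cohort generator

Each subject's source time course per trial is
$A_i\, w(t) \left[\sin(2\pi f_0 t + \varphi) + \textstyle\sum_h g_h \sin(2\pi f_h t + \varphi)\right] + B \sin(2\pi f_0 t + \varphi_{b,i}) + n_{1/f}(t)$
projected through the source voxel's lead-field row, plus white sensor
noise, with occasional half-sine artifact transients (10× the typical
sensor amplitude, on a quarter of the sensors, triggering both rejection
criteria). The envelope $w(t)$ ramps 0→1 over 150–250 ms, holds 1 until
stimulus offset at 1500 ms and decays to 0 by 2000 ms, matching a
response extent of roughly 200–2000 ms. The SSVEP phase φ is fixed across
trials (phase-locked, so ITPL is high during stimulation); the baseline
oscillation phase is redrawn per trial (non-phase-locked, so it survives
trial-averaged power but not evoked averaging). Per-trial amplitudes
$A_i$ are lognormal with the configured cross-trial CV. The 1/f
background is spectrally shaped white noise calibrated against the
demodulation filter's equivalent noise bandwidth so that the TFR-derived
PSD has expectation $10^{b} f^{-\chi}$ in the package's amplitude² units.
The cognitive score is α + β·(subject mean $A_i$) + Gaussian noise,
emulating an MMSE-like 0–30 scale.

The lead field is a parametric stand-in for a forward solution: sensors
on a jittered Fibonacci hemisphere above a cubic voxel grid, Gaussian
falloff of sensitivity with distance, a small seeded multiplicative
modulation so patterns are correlated but never identical, and rows
normalized to unit norm. Row normalization removes depth bias: the
unit-gain constraint forces $|w_v| \ge 1/|l_v|$, so a weakly coupled deep
voxel would otherwise amplify sensor noise into its virtual sensor by
orders of magnitude. Beamformer algebra is agnostic to the physical
forward model, and localization tests need only a consistent
generator/estimator pair, so no Maxwell-equation gradiometer physics is
modelled.

Default study-scale parameters are 38 ADS / 20 HC subjects, 120 trials,
and a group effect pattern that mirrors the study's ground truth: equal
mean source amplitude in both groups, lower baseline 15 Hz amplitude in
ADS (0.25 vs 0.45), lower cross-trial CV in ADS (0.25 vs 0.40), a 1/f
background with offset −1 and exponent 1, and a positive
amplitude-to-cognition slope (score = 18 + 8·Ā ± 2). Lower baseline with
equal absolute amplitude mechanically produces the study's signature
dissociation — higher *relative* entrainment in ADS without an absolute
difference. Source amplitude 1.0 with sensor noise SD 0.1 was chosen so
that desk-scale recovery is clean (peak-voxel recovery ≥ 95%,
virtual-sensor/source correlation > 0.9); no real-data SNR is available
to match, so defaults prioritize recovery, and the noise level is a
config knob for harder regimes. Determinism is strict: every draw
derives from the master seed through a fixed per-subject seed stream,
and regenerating a cohort is bit-identical. Scaling all amplitudes and
the noise by a constant c scales the sensor data by exactly c (the
aperiodic offset shifts by 2·log₁₀ c since it is a power).

What the generator does not emulate: head motion, tSSS residuals,
cardiac/ocular artifact morphology, realistic anatomy, nonstationary
background power, or between-subject heterogeneity of estimator noise.
Passing tests on this generator therefore demonstrate algorithmic
correctness and recovery under the modelled signal structure, not
robustness to everything real recordings contain. One consequence is
visible in the window-selection stage: synthetic cohorts are so
homogeneous across subjects that percent-level systematic estimator
effects (epoch-edge frames, onset-transient smearing) reach significance
that real between-subject variability would swamp; the edge-frame
handling above addresses the estimator side of this.

# Problem sizes and numerical choices

The demonstration configuration used by the analysis scripts and the
end-to-end tests is 8 subjects per group, 40 trials, 16 sensors and a
4×4×4 voxel grid at 20 mm spacing — large enough for every effect in the
pattern to be detected, small enough that the full pipeline runs in well
under a minute. Recovery suites use 50 single-source simulations for
localization, 100 simulated spectra (noise SD 0.02 log₁₀ units) for
parameterization, and 200 repetitions of a reduced null cohort (8
subjects, 20×15 grid, 250 permutations) for the family-wise error rate
of the window selection, compared against the binomial confidence
interval at α = 0.05. The JZS quadrature uses `integrate()` split at
zero with rel.tol 1e-9; its Monte-Carlo cross-check uses 10⁶ prior
draws. Peak fitting bounds Gaussian SDs to [0.5, 7.5] Hz (BW 1–15 Hz)
and caps extraction at 16 peaks when the configured maximum is infinite,
flagging the fit if the cap binds. Ties in peak-voxel selection break to
the lowest linear index. Degenerate inputs error early: zero pooled
variance, constant regressors, non-positive spectra, empty bands or
windows, all-rejected trial sets.

# Reproducing the workflow

```{r, eval = FALSE}
res <- run_pipeline(default_config(master_seed = 1), out_dir = "results")
res$report
```

The numbered scripts under `analysis/` run the same stages one at a time
(simulate, preprocess, sensor TFR + window selection, beamform, metrics +
parameterization, statistics), caching intermediates and writing tables
under `results/`. Rerunning any script with the same upstream cache
reproduces its outputs exactly.

# Known limitations

Spectral resolution is ±2 Hz by design, so the 0.5 Hz bin grid
oversamples the spectrum and neighbouring bins are strongly correlated;
per-frequency contrasts should be read accordingly. The aperiodic
exponent recovered *through the full pipeline* is mildly flattened
(≈ 0.92–0.98 for a true exponent of 1) because narrowband estimation
convolves the PSD with the filter's response — parameter recovery tests
on directly simulated spectra are unaffected. The regression Bayes
factor convention is declared, not validated against published values.
Mixed-sign cluster candidates are not split; with a symmetric threshold
this is immaterial for the cohorts considered here.
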