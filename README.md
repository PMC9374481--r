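# megentrain

Visual entrainment analysis for MEG recordings.

When a stimulus flickers at a fixed rate, visual cortex synchronizes to
it, producing a steady-state visual evoked response (SSVEP) at the flicker
frequency and its harmonics. In studies of the Alzheimer's disease
spectrum this response is a candidate functional marker: groups can
differ in how strongly they entrain relative to their own pre-stimulus
baseline, in how consistent the response is across trials, and in how
much spontaneous rhythm the baseline itself contains. `megentrain`
implements the full analysis chain for such a study, for researchers who
want a tested, reproducible reference implementation of each stage:

- **Artifact rejection** with individualized amplitude/gradient
  thresholds (mean + k·SD of trial peaks per subject).
- **Complex demodulation** time–frequency decomposition on a 4–50 Hz
  (0.5 Hz step) × −600..3200 ms (100 ms step) grid, calibrated so a
  sinusoid of amplitude A has envelope A.
- **Baseline normalization** (percent power change) and **cluster-based
  sign-flip permutation selection** of the entrainment time–frequency
  window across participants.
- **DICS beamforming**: band-limited cross-spectral density, unit-gain
  spatial filters w = (C_r + λI)⁻¹l / (lᵀ(C_r + λI)⁻¹l), pseudo-t maps
  (P_act − P_base)/P_base, grand-average peak voxel, and virtual-sensor
  time series.
- **Entrainment metrics**: absolute and baseline-relative band
  amplitude, inter-trial phase locking R(f,t) = |⟨c/|c|⟩_trials|,
  cross-trial coefficient of variation, per-frequency specificity.
- **Spectral parameterization** of the baseline PSD into an aperiodic
  component (log₁₀P = b − χ·log₁₀f) plus Gaussian peaks, with band
  summaries of the full/aperiodic/periodic components.
- **Group statistics**: per-group 2.5 SD outlier exclusion, pooled
  Student t with Cohen's d = |t|·√(1/n₁+1/n₂), JZS Bayes factors
  (Cauchy prior, scale 0.707), and OLS regression with partial η².
- A **synthetic two-group cohort generator** with complete ground truth
  (source location, trial amplitudes, baseline rhythm, 1/f parameters,
  cognitive link) so every estimate has a recovery test.

## Worked example

The end-to-end pipeline on the demonstration cohort (8 subjects per
group, 40 trials, 16 sensors, 64 voxels) with the study-style effect
pattern in the ground truth — equal absolute source amplitude, lower
baseline 15 Hz rhythm and lower cross-trial variability in the ADS
group:

```r
library(megentrain)
res <- run_pipeline(default_config(master_seed = 1), out_dir = "results")
print(res)
#> pipeline_result: 16 subjects, peak voxel 22 (true 22), 1094 mask bins
#> cohort_report
#>
#> Group contrasts (ADS vs HC):
#>           metric n_ads n_hc      t     p cohen_d  bf01
#> 1        rel_amp     8    8  3.018 0.009   1.509 0.181
#> 2        abs_amp     8    8 -1.043 0.315   0.521 1.629
#> 3           itpl     8    8  4.026 0.001   2.013 0.041
#> 4             cv     8    8 -5.406 0.000   2.703 0.005
#> 5      base_full     8    8 -4.710 0.000   2.355 0.014
#> 6 base_aperiodic     8    8 -4.108 0.001   2.054 0.036
#> 7  base_periodic     8    8 -4.535 0.000   2.267 0.019
#> 8      r_squared     8    8 -2.204 0.045   1.102 0.531
#>
#> Regressions of cognitive score (ADS):
#>   predictor n     f     p eta2p slope  bf01
#> 1   abs_amp 8 2.699 0.152  0.31 4.529 0.961
#> 2   rel_amp 8 0.253 0.633  0.04 0.002 1.772
```

Reading the output: the beamformer localized the planted source exactly
(peak voxel 22 = true voxel 22). Relative entrainment is higher in the
ADS group (t = 3.02, p = 0.009; BF₀₁ = 0.18 favors a difference) while
absolute amplitude does not differ (p = 0.32) — the study's signature
dissociation, produced here by the lower ADS baseline. The cross-trial
CV is lower in ADS (t = −5.41: more consistent response amplitudes), and
the periodic 15 Hz component of the parameterized baseline is reduced
(t = −4.54). The regression slope of the MMSE-like score on absolute
amplitude is positive (4.53), matching the configured cognitive link.
`results/` receives the metrics, spectrum-fit, significance-mask,
source-map and statistics tables as CSV plus a JSON manifest.

The same stages can be run one at a time with the numbered scripts under
`analysis/` (simulate → preprocess → sensor TFR and window selection →
beamform → metrics and parameterization → statistics), which cache
intermediates and narrate what each stage found.

## Documentation

The methods vignette (`vignettes/entrainment-methods.Rmd`) describes the
models, the filter design and its epoch-edge handling, the generator's
assumptions and what passing tests do and do not establish, and all
numerical choices.
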