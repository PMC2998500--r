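# cardiogate

Cardiac gating of cardiovascular magnetic resonance (CMR) acquisitions
depends on reliably detecting the onset of each cardiac cycle. At
ultrahigh field (7.0 T) the conventional vector ECG is corrupted by the
magneto-hydrodynamic (MHD) effect — blood flowing in the static field
induces a voltage superimposed on the T wave, reaching or exceeding the
R-wave amplitude — causing frequent R-wave mis-registration. Two
alternatives are gating from the finger pulse-oximetry (POX) waveform,
which is clean but delayed by pulse transit time (~350 ms) and jittered
by beat-to-beat pulse-shape scatter, and acoustic cardiac triggering
(ACT), which gates from the phonocardiogram's first heart tone (S1),
arriving ~30 ms after the R wave and immune to electromagnetic and MHD
interference.

`cardiogate` implements, for researchers working on physiological
gating and waveform quality control:

* **The ACT signal chain** — microphone SPL calibration against a
  pistonphone reference tone, Hann short-time SPL spectrograms,
  band-limited acoustic SNR, a third-order inverse Chebyshev (Chebyshev
  type II) low-pass with stopband edge f_c = 105 Hz and ≥ 30 dB stopband
  attenuation that separates heart sounds (1–100 Hz) from
  gradient-switching noise lines at k/TR and 1/TE, and S1 trigger
  detection (envelope, adaptive threshold, Gaussian-envelope onset
  refinement).
* **A synthetic session generator** — multi-rate physiological logs
  (ECG 400 Hz, POX 50 Hz, ACT 200 Hz, respiration 50 Hz, microphone)
  with R-R intervals N(μ, σ), R-to-S1 delay N(29.65, 4.43) ms, POX
  pulses peaking N(350, 8) ms after R with amplitude/width scatter,
  MHD T-wave elevation scaling linearly with field strength
  (0.3 / 1.0 / 7.0 T table positions), breath-hold schedules, and
  gradient noise calibrated to a 120 dB SPL peak third-octave band.
* **The trigger-fidelity pipeline** — breath-hold gating from the
  respiratory trace, cross-correlation R-R segmentation and temporal
  realignment, trigger tickmark reassignment, and per-modality interval
  mean/SD, trigger offset mean/SD, peak-to-peak jitter, and
  mis-registration (failure) rate.
* **Agreement statistics** — Bland-Altman bias and 1.96 SD limits of
  agreement, an exact Wilcoxon matched-pairs signed-rank test
  (midranks for ties, zero differences dropped, full-distribution
  enumeration for n ≤ 15), paired t, and image-quality score
  summaries.

## Worked example

Simulate a 200-cycle gated session at the home table position and run
the complete fidelity analysis:

```r
library(cardiogate)

cfg  <- simulation_config(n_cycles = 200, seed = 11)
log  <- simulate_session(cfg)
analyze_triggers(log)
#>   modality n_cycles n_triggers interval_mean interval_sd offset_mean offset_sd
#> 1      ECG      117        124           897        49.0      -0.144     0.812
#> 2      POX      117        116           930       181.2     315.869    12.750
#> 3      ACT      117        124           897        48.9      28.745     4.605
#>   jitter failure_rate
#> 1   2.68       0.0000
#> 2  73.46       0.0427
#> 3  26.95       0.0000
```

Reading the table: 117 complete cycles fall inside breath-holds; both
ECG and ACT recover the configured 900 ± 50 ms R-R distribution; the
ACT trigger offset distribution (28.7 ± 4.6 ms) recovers the generated
R-to-S1 delay (29.65 ± 4.43 ms); the POX trigger arrives ~316 ms after
R with an emergent peak-to-peak jitter of 73 ms — the scatter that
makes POX gating marginal at high temporal resolution — while the ECG
detector at the home position is accurate and failure-free.

The heart-sound filter and the score statistics:

```r
spec <- design_heart_sound_filter(rate = 2000, cutoff = 105)
spec
#> <filter_spec: order-3 inverse Chebyshev low-pass, stopband edge 105 Hz @ -30 dB, fs=2000>
-20 * log10(Mod(filter_response(spec, 250)))   # single-pass, dB
#> 30.5

t2 <- cg_table2()                      # bundled consensus score table
wilcoxon_matched_pairs(t2$act_ed, t2$ecg_ed)
#> <wilcoxon_matched_pairs: statistic 40.000, p = 0.04 (n=9)>
```

A command-line interface covering simulation, filter design, S1
detection, session analysis and reporting is installed at
`system.file("exec", "cardiogate", package = "cardiogate")`.

## Documentation

See the methods vignette (`vignettes/acoustic-cardiac-gating.Rmd`) for
the models, the detector internals, the numerical choices and the known
limitations of the synthetic generator.
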