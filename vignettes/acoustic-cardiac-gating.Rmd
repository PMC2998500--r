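---
title: "Acoustic cardiac gating: models, detectors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic cardiac gating: models, detectors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiogate)
```

# The problem

Gated cardiovascular MR sorts continuously acquired k-space data into
cardiac phases using a per-cycle trigger. Whatever emits that trigger
determines image quality: a trigger that fires at a variable phase of
the cycle (jitter) or at the wrong phase altogether (mis-registration)
mixes data from different contraction states into one reconstructed
phase and blurs the myocardial border. At 7.0 T the vector ECG suffers
from magneto-hydrodynamic (MHD) voltages superimposed near the T wave
that can match or exceed the R-wave amplitude, so a threshold-type QRS
detector intermittently locks onto the wrong waveform feature.
Pulse-oximetry (POX) gating is electrically clean but delayed by pulse
transit time and jittered by pulse-shape scatter. Acoustic cardiac
triggering (ACT) gates from the first heart tone (S1) of the
phonocardiogram, which follows the R wave by a short, stable
electromechanical delay.

`cardiogate` reimplements this comparison as a fully synthetic,
testable pipeline: a session generator with known ground truth, the
acoustic signal chain, the trigger-fidelity statistics, and the
agreement statistics used on image-quality scores.

# The synthetic session

`simulation_config()` holds every generator parameter. The defaults
are the stated conditions of the emulated study where given, and a
typical resting adult otherwise:

| parameter | default | unit | origin |
|---|---|---|---|
| `rr_mean`, `rr_sd` | 900, 50 | ms | resting heart rate ~67 bpm; per-subject values (e.g. 869 ± 89) can be set directly |
| `r_to_s1_mean`, `r_to_s1_sd` | 29.65, 4.43 | ms | reported R-to-S1 electromechanical delay |
| `pox_latency_mean`, `pox_latency_sd` | 350, 8 | ms | reported POX peak latency; beat-to-beat transit-time variability chosen physiologically |
| `pox_amp_cv`, `pox_width_cv` | 0.15, 0.15 | – | pulse amplitude/width scatter; tuned once so the *emergent* POX trigger jitter falls in the reported 60–80 ms band |
| `mhd_gain_at_7T` | 1.2 | × R amplitude | MHD elevation "same order or larger than the R wave" at isocenter |
| `mhd_amp_cv` | 0.3 | – | beat-to-beat flow-dependent MHD scatter; the source of intermittent mis-registration |
| `tr_s`, `te_s` | 0.004, 0.002 | s | CINE FLASH sequence timing (gradient lines at 250/500/750 Hz) |
| `peak_spl_db` | 120 | dB SPL | loudest third-octave band of the gradient noise |
| `snr_cardiac_db` | 30 | dB | cardiac-to-noise band SNR in 10–50 Hz |

Channel rates mirror the scanner log: ECG 400 Hz, ACT 200 Hz, POX and
respiration 50 Hz; the microphone channel defaults to 2000 Hz so that
the 750 Hz gradient line is representable.

Model components, and what they deliberately simplify:

* **ECG**: five-Gaussian PQRST template (R = 1 mV, σ = 8 ms; T at
  0.40 · RR). The MHD effect is a single additive Gaussian bump
  sharing the T-wave window with amplitude
  `mhd_gain_at_7T · (B/7) · R` and beat-to-beat scatter. Linear
  scaling in B and the absence of flow physics are assumptions, not
  physiology.
* **Phonocardiogram**: S1 is a Gaussian-enveloped 35 Hz oscillation of
  80 ms total duration (envelope truncated at ±3σ so the onset is a
  true zero), S2 a smaller 55 Hz burst at 0.35 · RR. Over 95 % of S1
  energy lies below 100 Hz, matching the premise of the 105 Hz
  low-pass.
* **POX**: one asymmetric pulse per cycle — fast rise (σ ≈ 60 ms),
  broad top, slow decay (σ ≈ 250 ms) with a C∞ width blend so the peak
  has continuous curvature and interpolating peak-pickers are
  unbiased. Trigger jitter is *not* injected; it emerges from the
  amplitude/width scatter interacting with the threshold detector.
* **Gradient noise**: phase-locked sinusoids at 1/TR, 2/TR, 3/TR and
  1/TE (coincident lines add coherently; for TR = 2 TE the 500 Hz line
  carries both) over a white floor 40 dB below the loudest line,
  globally scaled so the loudest third-octave band reads
  `peak_spl_db`. The microphone mixture rescales the heart-sound level
  so the 10–50 Hz band SNR between cardiac and noise-only windows
  equals `snr_cardiac_db`; that calibration uses a direct FFT band-mask
  power estimate, deliberately a different code path from the Hann
  spectrogram estimator that is later tested against it.
* **Respiration**: 0.25 Hz quasi-sinusoid frozen to a plateau during
  scheduled breath-holds (default: 15 s holds, 8 s gaps). Gradient
  noise in the session microphone channel runs only during holds,
  mirroring breath-held CINE acquisition.

Determinism: every stochastic component draws from a seed derived from
`config$seed` plus a fixed per-component offset, so single components
are reproducible in isolation and a full session is bit-identical for
equal configurations. The previous RNG state is always restored.

What a green test on this generator does **not** establish: real heart
sounds have multi-component, subject-dependent morphology; real MHD
distortion is flow-waveform-shaped rather than Gaussian; electrode,
motion and muscle noise are absent; POX misses in real scanners depend
on perfusion, not on a Gaussian amplitude tail. The pipeline's accuracy
numbers are therefore upper bounds on real-data performance.

# The acoustic chain

**SPL calibration.** `calibrate_spl()` returns c with
20·log10(c·RMS/20 µPa) equal to the reference level (94 dB pistonphone
convention), so calibration is a similarity: scaling pressure by k
shifts every reading by exactly 20·log10 k. **Spectrograms** use Hann
windows with cell powers normalized so the sum over frequency bins
equals the window's mean-square pressure (Parseval with window-power
correction); band sums are therefore calibrated band powers, and
`band_spl()`/`acoustic_snr()` are simple band/window aggregations of
the same grid. Zero-energy cells are floored at −150 dB.

**Filter.** The "cut-off" f_c = 105 Hz is interpreted as the
*stopband edge* of the inverse Chebyshev design — the first frequency
at which attenuation reaches the 30 dB specification, beyond which the
equiripple stopband keeps it there. This pairing (f_c directly with
"at least 30 dB") is the only reading under which a third-order design
has both quoted properties at once. The design path is the classical
one: analog type II prototype, low-pass scaling with bilinear
pre-warping, bilinear transform; coefficients were verified against an
independent reference implementation and are frozen in the test suite.
The filter is applied zero-phase (forward–backward, scipy-style
padding and companion-matrix initial conditions), replacing the analog
real-time realization: offline analysis permits it, and it removes
group-delay bias from every timing statistic. A causal single-pass
variant remains available (`apply_filter(..., zero_phase = FALSE)`).
Note one consequence of the shallow passband of a 3rd-order/30 dB
type II design: its −3 dB point sits near f_c/2, so the S1 band is
mildly and asymmetrically shaped — which is why the detector below
self-calibrates.

At the ACT logging rate of 200 Hz the 105 Hz edge exceeds Nyquist;
`detect_s1_triggers()` then designs the filter at
min(105, 0.45 · rate) Hz. For a trace that is already band-limited by
the logging chain this changes nothing material; it keeps the
operation well-posed.

**S1 detection.** Chain: zero-phase low-pass → envelope (rectified +
25 ms moving average) → adaptive threshold at 60 % of the running peak
over the trailing 3 s, floored at half the global envelope maximum
(the offline analogue of a detector training period) → rising edges
with a 300 ms refractory. Each detected burst is then refined: the
analytic (Hilbert) envelope's peak is interpolated parabolically, the
full width at half maximum gives a Gaussian width estimate σ̂, and the
onset is t_peak − 3σ̂ (the generator-independent statement "a heart
tone lasts about six envelope sigmas"). Because the filter broadens
and shifts a narrowband burst envelope, the estimator calibrates
itself: it synthesizes a probe burst matching the measured carrier
frequency and width, passes it through its own chain, measures the
onset error it makes on the probe, and subtracts it. Finally trigger
times are quantized to the trace's sampling grid — the residual
per-cycle error is the ±half-sample quantization the source data
rate imposes, which is what bounds ACT jitter at 5 ms for a 200 Hz
log.

# The fidelity pipeline

**Breath holds** are maximal intervals where the 2 s rolling SD of the
respiratory trace falls below 10 % of the whole-trace SD, dilated by
the half-window (undoing the rolling blur) and filtered at a 5 s
minimum.

**Segmentation.** R waves come from the threshold detector refined to
parabolic peaks; cycles are consecutive R–R pairs inside holds; the
reference is the first complete cycle of the first hold (the method
needs *a* reference and no principled choice is stated — first is
reproducible). Every other cycle receives the integer-sample shift
(±150 ms) maximizing Pearson correlation with the reference window,
ties preferring the smallest |shift|. Two deliberate choices here:

* The correlation window is the leading 0.25 s of the interval (QRS
  and early ST), not the whole R-R interval. Correlating whole
  intervals lets the position of the *following* R wave — pure R-R
  variability — drag the maximizer away from R alignment by several
  ms, which is precisely the bias realignment is meant to remove.
* The reference window is anchored at the reference's sub-sample R
  peak time (interpolated), not at its sampling-grid position;
  otherwise the reference's grid phase (±1.25 ms at 400 Hz) becomes a
  constant bias inherited by every shift and every offset statistic.

**Reassignment.** A tickmark belongs to the cycle containing it, with
a 25 ms lead guard on both boundaries (`[R_i − g, R_{i+1} − g)`): a
trigger that marks the R wave itself, quantized to its channel's grid,
must not round into the previous cycle. The earliest tickmark per
cycle is kept, surplus ones are counted as doubles, cycles without one
are missed. Offsets are `tick − R + shift` in ms.

**Statistics.** Interval mean/SD are sample statistics (n−1) of
successive trigger differences, never spanning a gap between holds.
Jitter is the peak-to-peak offset range — the reported "two cardiac
phases" equivalence (~2 × 33 ms) matches a range, not an SD. The
failure rate is the fraction of offsets farther than 100 ms from the
modal offset of a 20 ms-binned histogram, missed cycles counting as
failures; the 100 ms tolerance operationalizes "mis-registration at
other cardiac phases", for which no numeric criterion is stated.

The emulated monitoring unit reports R-peak times for ECG (vendor QRS
detectors mark the apex), raw threshold crossings for POX (so jitter
emerges from pulse-shape scatter, as observed), and the full S1 chain
for ACT. At isocenter the ECG failure mechanism is: the running peak —
hence the threshold — follows the scattered MHD bumps; cycles whose R
wave falls below it are triggered on the MHD bump instead. The failure
rate therefore rises with MHD gain and saturates once the MHD bump
dominates the running peak for every cycle; the monotonicity property
is asserted on a seed-averaged gain sweep because inside the
saturation regime individual seeds wiggle by Monte-Carlo noise.

# Agreement statistics

The Wilcoxon matched-pairs test drops zero differences (Wilcoxon's
original treatment), assigns midranks to tied absolute differences,
and for n ≤ 15 computes the exact two-sided p over all 2^n sign
assignments of the tied rank multiset (dynamic programming over
doubled ranks; the test suite checks it against a literal 2^n
enumeration, and against the exact base-R test in the tie-free case).
Above n = 15 a normal approximation with tie correction is used. On
the bundled consensus-score table this reproduces the published
ACT-vs-ECG end-diastole comparison (p = 20/512 ≈ 0.039 → 0.04).
Bland-Altman limits are bias ± 1.96 sample SD of the differences.
Score summaries round half-up to one decimal, the print precision of
the source tables.

# Numerical choices and degenerate inputs

* Text logs store samples at nine significant digits and trigger times
  at millisecond precision; parsing is locale-independent.
* FFT-based helpers zero-pad to 2-3-5-smooth lengths (mixed-radix FFT
  cost, not correctness).
* Constant ECG → degenerate-correlation error; fewer than two cycles →
  insufficient-data error; empty traces give empty trigger trains, not
  errors; silent calibration tones are errors.
* Tie-breaks: correlation ties prefer the smallest absolute shift,
  then the negative one; modal-bin ties in the failure rate prefer the
  lowest bin.
* `summarize_scores` uses half-up rounding (`floor(x·10 + 0.5)/10`),
  not banker's rounding.

# Known discrepancies surfaced, not resolved

* The acoustic SNR band is quoted as 10–50 Hz in the text and 10–70 Hz
  in a figure caption of the source material; the 10–50 Hz band is
  used throughout.
* The printed offset-SD columns with the "SD_ECG ≥ 4 · SD_ACT" rule
  yield five qualifying subjects (subject 5: 56 vs exactly 4 × 14)
  while the accompanying text says four; `flag_sd_ratio()` exposes
  both the non-strict (5) and strict (4) counts and asserts neither as
  intent.
* The printed POX end-diastole column averages to 1.9 after half-up
  rounding; the source text reports 2.0. The package reports the
  recomputed value.
* A stated design bound of 35 ms maximum trigger latency alongside a
  29.65 ± 4.43 ms mean delay is ambiguous (processing-only vs total)
  and is not modeled as a constraint.

# Limitations

No real-time triggering loop, no MR image simulation or
reconstruction, no hemodynamic or acoustic-propagation modeling, no
vendor log dialects, and no second-heart-tone gating. The generator's
defaults describe one stated world; conclusions about detector
performance on real scanner logs require real scanner logs.
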