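---
title: "Event-related cross-frequency coupling of the auditory steady-state response"
author: "assrpac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-related cross-frequency coupling of the auditory steady-state response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assrpac)
```

## The problem

Periodic auditory stimulation — a click train at 40, 30 or 20 Hz — entrains
an oscillatory response in auditory cortex, the auditory steady-state
response (ASSR). Beyond the entrained rhythm itself, slow cortical
oscillations (theta/alpha, 4–12 Hz) are thought to modulate the excitability
of the circuits that generate gamma activity (13–60 Hz), so that gamma
amplitude waxes and wanes with the phase of the slow rhythm. This
phase-amplitude coupling (PAC) is a candidate marker of local
excitation-inhibition balance, and comparing PAC between the entrained
(stimulation) period and the pre-stimulus baseline asks whether entrainment
reorganizes that slow-phase gating.

`assrpac` implements the full analysis chain for epoched single-source (or
single-channel) recordings: epoch conditioning, Morlet wavelet
time-frequency and inter-trial phase coherence (ITC) estimation,
across-trials mean-vector-length (MVL) PAC with surrogate z-scoring over an
fP × fA comodulogram, a stimulus-versus-baseline cluster-based permutation
test across subjects, and a rise–decay waveform-shape control. Because
suitable public MEG data are rarely available, the package also contains a
first-class synthetic session generator with known ground truth; every stage
of the pipeline is validated against it.

## The synthetic session generator

`synthesize_trial()` builds each epoch (−1.5 to +1.5 s around stimulus
onset) from four components:

1. a low-frequency oscillation at `phase_freq_hz` with a fresh uniform phase
   every trial (slow rhythms are not reset by the click train), amplitude
   `phase_amp_ratio` relative to the gamma carrier (default 3, reflecting
   the 1/f dominance of slow activity), optionally skewed into a
   non-sinusoidal shape by `waveform_asymmetry`;
2. a gamma carrier at `amp_freq_hz` whose envelope is
   `1 + m * w_low(t)` inside the coupling window (`modulation_depth` m, so
   m = 1 drives the envelope to zero at the slow-wave trough). The carrier
   is given a finite spectral linewidth (`gamma_bandwidth_hz`, default 2 Hz,
   implemented as phase diffusion): cortical gamma is not a coherent tone,
   and an infinitely coherent carrier would lock into a fixed per-trial
   phase relation with the entrained response, producing static
   interference that partially inverts the measurable modulation;
3. an entrained sinusoid at the stimulation frequency, phase-locked across
   trials (ITC ≈ 1 by default; `itc_jitter_rad` degrades it continuously),
   active over the click train with 150 ms raised-cosine ramps — a hard
   onset step would inject a phase-locked broadband transient that
   contaminates low-frequency phase estimates and produces spurious
   "evoked" coupling;
4. additive 1/f^β noise (`one_over_f_exponent`, default β = 1; `noise_sd`
   default 1), generated by spectral shaping of white noise, independent
   across trials.

By default the slow phase modulates the gain of the *total* gamma-band
activity, entrained response included (`modulate_entrained = TRUE`): if slow
oscillations modulate cortical excitability, the entrained gamma passes
through the same gain. Setting it to `FALSE` confines the modulation to the
endogenous carrier, in which case carrier–ASSR interference substantially
dilutes measurable coupling — a useful worst-case configuration.

The oddball task structure (100 trials in 10 blocks, 15 oddball trials
placed uniformly at random, oddballs excluded from analysis) is reproduced
by `generate_session_plan()` / `synthesize_session()`; oddball trials differ
only in their tag, since at source level the deviant tone carrier does not
change the generative law. `generate_cohort(..., null_cohort = TRUE)`
produces stationary ensembles (no coupling, no entrained response) whose
stimulus and baseline windows are draws from the identical process — the
exchangeable null used to calibrate the cluster test.

What the generator does *not* emulate: volume conduction and sensor mixing,
non-stationary artifact (blinks, cardiac), drifting alpha rhythms, or any
between-subject variance structure beyond independent noise. Passing tests
therefore certify the estimators and their null calibration, not robustness
to every property of recorded MEG.

## Time-frequency analysis

`morlet_transform()` convolves every trial with complex Morlet kernels
`exp(2πi f t) exp(−t²/2σ²)`, `σ = n_cycles/(2πf)`, with `n_cycles = 10` at
all frequencies to favor frequency resolution (spectral sd `σ_f = f/10`).
Numerical choices:

* kernels truncated at ±5σ (Gaussian tail < 1e−5) and scaled so a
  unit-amplitude sinusoid at the kernel frequency has coefficient modulus 1
  — amplitude maps are in units of equivalent sinusoid amplitude;
* FFT-based linear convolution with zero padding (verified against naive
  time-domain convolution to 1e−10);
* a per-frequency validity mask flags samples within 2σ(f) of either epoch
  edge. At 4 Hz, σ ≈ 0.40 s, so parts of the standard windows are flagged;
  the computation proceeds and the mask is surfaced rather than silently
  trimmed.

`tf_amplitude()` baseline-corrects the trial-averaged amplitude map by
subtracting the mean over −1.3 to −0.5 s (per-trial correction available);
`itc()` returns the modulus of the across-trials mean unit phase vector.
All windows in the package are half-open `[start, end)` to avoid
double-counting boundary samples.

## Phase-amplitude coupling

For each comodulogram cell (fP from 4–12 Hz, fA from 13–60 Hz), the fA
amplitude envelope of every trial is min–max normalized to [0, 1] over
−1.3 to +1.3 s (per trial and per frequency, damping trial-wise amplitude
bias), and the across-trials MVL is computed at every sample of the
analysis window, then averaged over the window:

$$\mathrm{MVL}(\tau) = \Bigl|\tfrac1n \sum_{t=1}^{n} a_{t,\tau}
e^{i\varphi_{t,\tau}}\Bigr|.$$

The statistic is z-scored against surrogate data: each surrogate cuts every
trial's raw time series at a random interior point (excluding a margin of
one wavelet σ at the lowest fP at both ends, so no surrogate is a
near-identity swap), swaps the two segments, re-runs the fP wavelet
transform on the shuffled signal, and recomputes the MVL against the
*unshuffled* normalized amplitudes. z uses the sample standard deviation
(n − 1) of the surrogate distribution. Stimulus (0.2–1.0 s) and baseline
(−1.3 to −0.5 s) windows use identical machinery and, when requested
together, share transforms and surrogate draws.

Two properties of this estimator deserve emphasis, because they shape what
recovery tests can demand:

* **Surrogate cuts must be per-trial.** A cut common to all trials shifts
  every trial's slow phase by the same amount; for a near-sinusoidal
  modulator that is a common phase *rotation*, and the MVL is invariant to
  common rotations — such surrogates preserve the very coupling they are
  meant to destroy. We verified this empirically (recovery collapses) and
  default to independent per-trial cuts (`surrogate_mode = "per_trial"`).
* **fA localization is bounded by the wavelet bandwidth.** Amplitude
  modulation of a carrier at fA by a modulator at fP places sidebands at
  fA ± fP. With 10 cycles, σ_f = fA/10 is smaller than fP over most of the
  grid, so no single wavelet passes the carrier and both sidebands; detected
  coupling peaks where a wavelet best straddles the carrier and the upper
  sideband — typically fP/2 to fP *above* the true carrier, with a ridge
  spanning roughly fA ± fP. The package's recovery tests therefore evaluate
  the comodulogram argmax at 8-Hz fA bins (about twice the spectral sd at
  40 Hz); finer claims would overstate the method's resolution.
* **Chance phase clustering inflates single-ensemble tails.** The
  across-trial resultant of 85 independent phases is not zero but
  Rayleigh-distributed, and its window mean has heavy tails across
  ensembles (few independent samples per window). Surrogates condition on
  the observed phase streams and under-cover that variance, so a small
  fraction of null ensembles shows an elevated z *row* across all fA.
  Group-level inference with the baseline contrast absorbs this; it is the
  main reason single-subject comodulograms should not be over-read.

## Cluster-based permutation inference

`cluster_permutation_test()` compares per-subject stimulus and baseline
comodulograms with a one-tailed (stimulus > baseline) paired t map,
thresholds it at the t quantile of the cluster-forming p (default 0.01,
df = subjects − 1), groups supra-threshold cells under 4-adjacency (8
optional), and scores each cluster by its mass (sum of t values). The null
is the distribution of the maximum cluster mass over label sign-flips
(stimulus/baseline exchange within subject); corrected p-values use the
`(1 + #{perm ≥ obs}) / (1 + n_perm)` estimator, so they are never exactly
zero. Defaults follow the configuration the pipeline is built around:
5000 permutations, cluster-forming p = 0.01, and a familywise cluster
threshold configurable between the strict 1% used for calibration and the
conventional 0.05 used for reporting.

`null_fwer_simulation()` re-derives the familywise error rate from scratch
by running the entire pipeline on stationary null cohorts. Because the
baseline window sits closer to the epoch edge than the stimulus window,
per-cell stimulus–baseline differences at 4–8 Hz are not perfectly
symmetric under the null (edge effects survive z-scoring only as small
asymmetries), and the realized familywise rate can sit slightly above the
nominal level; the acceptance bound used throughout is the nominal level
plus two binomial standard errors of the simulation size.

## Waveform-shape control

Non-sinusoidal slow waveforms can masquerade as PAC. `rise_decay_ratio()`
measures the mean trough→peak over peak→trough duration on a
harmonic-preserving narrowband reconstruction: the sum of the real parts of
wavelet transforms at fP, 2fP and 3fP. A single 10-cycle band at fP alone
(bandwidth fP/10) would strip the harmonics that carry the asymmetry and
force every ratio to 1; three harmonics keep the cycle shape while
rejecting broadband noise. Extrema are detected as slope sign changes with
alternation enforced (the more extreme of two same-type neighbors wins).
`compare_rise_decay()` runs the Bonferroni-corrected paired t-test between
stimulation and baseline ratios. On the generator's warped waveform with
the rise compressed to 30% of the cycle, the exact ratio is 3/7; the
harmonic-limited reconstruction recovers ≈ 0.55–0.65 of the way towards it
(truncation pulls estimates towards symmetry), monotonically in the
asymmetry parameter — sufficient for its role as a stimulus-versus-baseline
*contrast*, which is how it is used.

## Reporting

`run_study()` chains generator → preprocessing → time-frequency → PAC →
cluster test → waveshape → per-subject tables, seeded end to end, and
`write_study()` emits `subjects.csv`, `clusters.csv`, `waveshape.csv`,
per-subject comodulogram CSVs and a `manifest.json` with every parameter
and seed, so each number is recomputable. Group-level inferential models
(ANCOVA and friends) are deliberately left to standard statistics tools;
`amplitude_confound_correlation()` provides the Spearman check of PAC
against band amplitude that guards the coupling results.

## Problem sizes used by the test-suite

The validation suite runs the study conditions (85 analyzed trials, the
standard windows and grids) with simulation sizes chosen for a desk
machine: 250 Hz sampling and 40 surrogates for single-ensemble calibration
and recovery checks (50 seeded runs each); 200 Hz, 12 trials and 16
surrogates per subject for the familywise-error calibration (200 null
cohorts of 12 subjects on a 5 × 12 grid with 1000 permutations). These
scales only thin the grids and surrogate counts; they do not alter the
estimators, windows, or thresholds.

## Known limitations

* Single-source analysis only: no forward modeling, source localization or
  channel-level artifact correction; recorded data must arrive cleaned and
  epoched (CSV adapter).
* The MVL comodulogram inherits the resolution and clustering caveats
  described above; cluster-level, baseline-contrasted inference is the
  intended readout.
* Surrogate z-scores assume the segment-swap null preserves everything but
  phase-amplitude alignment; strongly non-stationary backgrounds (drifting
  artifacts) would violate this.
* The 4-Hz row of the comodulogram overlaps epoch-edge-contaminated samples
  in the baseline window (flagged by `valid_mask`, not corrected), which is
  also where the null calibration shows its small anticonservative drift.
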