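---
title: "Methods: simulating and analysing dual-modality n-back EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing dual-modality n-back EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vwmeeg` implements a complete analysis chain for a dual-modality verbal
working-memory (VWM) experiment in children: an n-back letter task presented
both auditorily and visually at three memory loads (0/1/2-back), with
concurrent 20-channel EEG at 256 Hz. Because no public recordings exist for
this design, the package also ships a synthetic cohort generator with known
ground truth, so that every stage — preprocessing, spectral analysis,
behavioural scoring, statistics — is testable end to end.

## The task protocol

Stimuli are the seven consonants c, g, k, p, q, t, v (vowels are excluded to
discourage chunking strategies). Each stimulus lasts 500 ms; the
interstimulus interval is offset-to-next-onset, 2500 ms for auditory and
3000 ms for visual presentation, so the onset asynchrony is 3000 ms and
3500 ms respectively. A session opens with a closed-eyes rest segment (60 s,
used for alpha-peak estimation), then a 21-item baseline block (each
consonant three times, randomized, 3000 ms ISI, no task), then six task
blocks — two per load level — in randomized order. Task blocks hold 21
randomized stimuli. The nominal 30% target rate of a 21-item block is not an
integer count; the generator fixes 6 targets per block (28.6%), the closest
integer below 30%, so blocks are comparable. In the 0-back condition the
probe letter "X" is the target; in 1-/2-back a letter is a target when it
matches the one presented 1 or 2 positions earlier. "X" never appears in
1-/2-back blocks, since it is defined only as the 0-back probe. For level L
the first L positions can never be targets.

Target placement in 1-/2-back blocks copies the letter from position
i − L at six seed-chosen admissible positions; remaining positions are
filled avoiding accidental matches, which guarantees the exact target count.

Responses are two-alternative forced choice (target / non-target) on every
trial; unanswered trials are scored as errors. Reaction times are measured
from stimulus offset. Per condition the package reports accuracy (ACC, over
targets and non-targets jointly), mean correct RT, the proportion of errors
PE = 1 − ACC, and the inverse efficiency score IES = RT / (1 − PE), a
speed-accuracy composite in ms.

## The synthetic cohort

`cohort_config()` fixes the study conditions: 11 subjects, both modalities,
the block structure above, and 20 channels (Fpz, Fz, F3, F4, F7, F8, Cz, C3,
C4, T7, T8, Pz, P3, P4, P7, P8, Cp5, Cp6, O1, O2) at 256 Hz in microvolts,
earlobe-referenced by assumption (the simulated data are reference-free).

Each subject draws a profile around population means: an individual alpha
frequency (IAF) from N(10, 0.8) Hz clipped to [8, 12] (a child-typical
alpha peak), oscillation amplitudes, and behavioural parameters. Signals are
additive:

- **Background**: Gaussian 1/f^β noise (β = 1 by default, 8 µV RMS) plus
  optional white sensor noise (2 µV). The 1/f noise is synthesized
  spectrally, normalized analytically so its expected variance is exact;
  channels are generated in quadrature pairs (each inverse FFT yields two
  real series), which leaves same-lag cross-channel correlation at zero.
- **Oscillations**: amplitude-modulated sinusoids (20% AM depth, slow random
  phase) with fixed scalp topographies — the simplest process with
  controllable band power. Posterior alpha at the subject's IAF is strong
  (12 µV) during closed eyes and mild (4 µV) during the session. Theta
  (IAF − 4 Hz) is fronto-central/midline-weighted and its **power** scales
  as `theta_load_gain^level` (default 1.25 per load step, with 0.08
  between-subject log-SD). Parietal gamma (IAF + 20 Hz) amplitude scales as
  `gamma_modality_gain[modality]^level` (default 0.9 audio, 1.0 video), so
  gamma falls with load under auditory stimulation only. Beta (IAF + 8 Hz)
  power follows a per-block standard-normal engagement latent through
  `exp(ei_beta_gain * e)`. On top of these systematic effects, every task
  oscillation's power is jittered per block by an independent lognormal
  factor (`osc_jitter_sdlog = 0.15`), modelling block-to-block state
  variability. This term matters statistically: without it the normalized
  0-back theta cell would be identically 1 for every subject — a
  zero-variance cell that real band power never shows and that would make
  the within-subject covariance grossly non-spherical.
- **Blinks**: half-cosine pulses (400 ms, ~150 µV at Fpz) at a Poisson rate
  of 8/min, scaled per channel by a fixed anterior-to-posterior gain vector
  — this makes regression-based removal exactly identifiable.
- **Injected artifacts**: with probability 0.03 per epoch, one channel
  receives a supra-threshold spike (100–130 µV), a centred linear ramp
  (42–45 µV/s, kept below the ±80 µV threshold so it tests the trend
  criterion specifically), a flat segment, or a 50–70 µV step. All
  injections are logged as ground truth.

Behaviour: correctness is Bernoulli with per-condition accuracies defaulting
to the reported condition means (97.0/87.6/87.0% audio, 90.9/83.3/74.0%
video for loads 0/1/2); correct-trial RTs are lognormal with mean
`rt_base + 140·level + 130·[audio]` ms (measured from stimulus offset,
sdlog 0.25) multiplied by `exp(-ei_rt_coupling · e)` with the same per-block
engagement latent as the EEG — low-engagement blocks have both lower beta
power and longer RTs. Where the underlying study reports no effect sizes in
band-power units, the default gains were chosen once so that the scaled-down
replication suite has high power (see below); they are not fitted to any
cohort.

All randomness flows from one master seed, split deterministically per
subject, stage and block, so a whole cohort — including its YAML manifest —
is byte-reproducible. What the generator does **not** emulate: volume
conduction from a biophysical head model, non-stationary artifact mixtures,
muscle/cardiac contamination, channel drift, or learning effects across
blocks. Passing tests therefore demonstrate correctness of the analysis
chain under a controlled generative model, not robustness to every feature
of real paediatric EEG.

## Preprocessing

Filtering is zero-phase (forward-backward `filtfilt`), so epoch-relative
timing is preserved: channels are demeaned, notched at 50 Hz (2nd-order
Butterworth band-stop, ±2 Hz), and band-passed 1–45 Hz with a 5th-order
Butterworth. Blink removal is regression-based: blink windows are detected
on Fpz by a matched filter against the blink template thresholded at 3 SD
and gated by a 40 µV minimum raw amplitude (so noise-only recordings pass
through unchanged), then Fpz is regressed out of every other channel within
those windows only. Fpz is kept for quality control but excluded from all
analysis clusters.

Epochs span −500 ms before stimulus onset to 2500 ms after its offset
(3.5 s = 896 samples at 256 Hz); sample values are copied exactly. Three
artifact criteria are evaluated per channel over each epoch, and an epoch is
rejected when **any** analysis channel triggers **any** criterion:

1. **Amplitude**: any sample beyond ±80 µV.
2. **Trend**: ordinary least-squares slope above 40 µV/s; a slope below
   0.3 µV/s is treated as a flat/disconnected-channel guard and flags only
   when the epoch's peak-to-peak range is under 1 µV — a literal "slope below
   0.3 µV/s" rule would reject nearly every ordinary zero-drift epoch.
3. **Jump**: any successive-sample difference above 30 µV. (A threshold of
   30 mV would be unreachable once the ±80 µV criterion holds; 30 µV is the
   internally consistent reading.)

All four constants are configurable via `artifact_criteria()`. Flag sets are
monotone in the criteria: loosening any threshold never flags more epochs.

## Spectral analysis

The IAF is the peak of the channel-averaged Welch spectrum of the
closed-eyes segment (posterior channels O1, O2, Pz by default) in 7–13 Hz,
refined by parabolic interpolation; 2 s windows give 0.5 Hz bins for peak
picking. The peak must be a local maximum and exceed the 1/f background
(log-log fit over 4–20 Hz excluding the search range) by a factor 1.5,
otherwise the canonical 10 Hz is used with a warning. Frequency bands are
anchored to the IAF: theta [IAF−6, IAF−2], low/upper alpha splitting
[IAF−2, IAF+2], beta [IAF+2, IAF+16], gamma [IAF+16, IAF+30] clipped at the
45 Hz filter edge. Band intervals are half-open, so adjacent bands tile
without double counting.

Per-epoch, per-channel PSDs use Welch's method with a 1 s Hanning window,
500 ms overlap and per-segment mean detrending; band power is the integral
of the PSD over each interval (µV²). Task power is normalized per channel
and band by the mean clean-baseline-epoch power (ratio mode by default, dB
selectable); normalization happens **before** cluster averaging, respecting
channel-specific baselines (the two orders commute only when baselines are
channel-constant). Cluster powers are arithmetic means over the frontal
{F3, F4, F7, F8, Fz}, parietal {P3, P4, P7, P8}, occipital {O1, O2}, midline
{Fz, Cz, Pz} and hemisphere sets; the old temporal labels T3/T4/T5/T6 are
aliased to the recorded T7/T8/P7/P8. A variant parietal cluster
{Pz, P3, P7, P8} is selectable, as both definitions are in circulation.

The engagement index EI = Beta / (Alpha + Theta) (alpha being the full
[IAF−2, IAF+2] band) is computed per epoch from **raw** band powers averaged
over the 19-channel set (all channels except Fpz), then averaged within each
condition cell. Raw rather than baseline-normalized powers are used because
EI is itself a ratio; dividing each band by its own baseline would change
its meaning. EI is scale-invariant, so any common gain cancels.

## Statistics

Each outcome (cluster × band power, EI, ACC, RT, IES) enters a balanced
2 × 3 within-subject factorial: modality (audio/video) × load (0/1/2), every
subject contributing all six cells. Effects are tested against their own
subject-interaction error strata (`aov` with
`Error(subject/(modality*level))`), with partial eta squared
SS_effect / (SS_effect + SS_error). Residual normality is gated by
Shapiro–Wilk at α = 0.05; on rejection the values are rank-transformed
(ranks over all observations) and the identical decomposition is rerun —
unlike Friedman-type tests this preserves the factorial structure including
the interaction. Residuals rather than raw cell values are tested because
the ANOVA assumption concerns the errors.

Duncan's multiple range test follows significant effects: means are ordered,
and a pair spanning r ranks is compared against
`qtukey(1 − α_r, r, df_error) · sqrt(MS_error / n)` with Duncan's protection
level α_r = 1 − (1 − α)^(r−1); a pair inside a non-significant span is never
declared significant. Critical ranges are non-decreasing in r. The
engagement-performance relation is summarized by the Pearson correlation
between cell-level EI and mean correct RT across subject × condition cells
(11 × 6 = 66 pairs, df = 64).

## Numerical and design choices

- Ratio baseline normalization is the default (the transform is not uniquely
  determined by convention); dB mode is available.
- The repeated-measures (within-subject) decomposition is the default since
  every subject sees all six cells; a between-subject mode exists for
  comparison.
- Degenerate tables (all values equal) report F = 0, p = 1 rather than NaN.
- An estimated IAF is clipped into [7, 13] before band construction.
- Epoch rejection happens before any band-power aggregation; a session that
  loses all clean baseline epochs aborts the pipeline with a named error.

## Problem sizes used by the replication suite

The test suite validates parameter recovery on Monte Carlo replicates using
`scaled_config()`: 11 subjects and the full 2 × 3 design, but one task block
per level, an 8-channel montage subset (the frontal and midline clusters
plus posterior IAF channels), a 40 s closed-eyes segment, no blink/artifact
injection, no white noise, and the filter stage off — the simulated signals
are band-limited by construction, and filtering and artifact handling are
validated by their own dedicated tests. With the default theta load gain the
load main effect on frontal and midline theta is recovered in essentially
every replicate cohort; with the gain at 1 the rejection rate stays at the
nominal level; and the cell-level EI–RT correlation is negative in nearly
all replicates. The full 20-channel, two-blocks-per-level design runs once
in `scripts/acceptance.R`.

## Limitations

Simulated effect sizes are package defaults, not estimates from any real
cohort; reported F/p values from a given real dataset are not reproduction
targets. The blink remover is a documented regression-based substitute for
proprietary blink-correction algorithms and assumes a common template shape
across blinks. The rank-transform ANOVA is an approximation whose interaction
test can be anticonservative under extreme marginal effects; with the
effect sizes simulated here it stays near nominal level, as the calibration
tests check.
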