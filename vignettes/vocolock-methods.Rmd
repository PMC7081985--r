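---
title: "Methods: vocalization-locked analysis of fronto-striatal field potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vocalization-locked analysis of fronto-striatal field potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vocolock implements an analysis chain that relates low-frequency field
potentials (LFPs) recorded simultaneously in the bat frontal auditory field
(FAF; a 16-channel laminar probe spanning depths of 50–800 µm in 50-µm
steps) and the caudate nucleus (CN; a chronic tetrode) to vocal output.
The animal emits two acoustically distinct call types: echolocation pulses
(short, < 2 ms, downward frequency-modulated, spectral peak above 50 kHz,
typically near 72 kHz) and communication calls (longer, dominant energy
below 50 kHz, peak near 14 kHz). The chain asks, stage by stage: does the
spectral state of the fronto-striatal circuit *before* a call predict
which type of call is about to be produced, and how are the two structures
coordinated around vocal onset?

This vignette documents the models, the parameters that matter, the
synthetic-data generator used to exercise every stage as a
parameter-recovery problem, and the numerical and design choices made
where the procedure left room.

## Vocal processing

Calls are detected on the 250-kHz audio by an envelope detector (rectified
waveform smoothed with a 0.1-ms moving average; threshold =
median + 5 MAD of the envelope; supra-threshold runs merged across gaps
shorter than 1 ms; events shorter than 0.2 ms discarded as noise blips).
Each call's **peak frequency** comes from the de-noised FFT: the magnitude
spectrum of an equal-length noise snippet taken immediately before the
call is subtracted from the call's magnitude spectrum and floored at zero.
Classification: peak above 50 kHz → echolocation; at or below 50 kHz →
communication (the boundary is assigned to communication; ties between
equal spectral peaks break toward the lower frequency). Communication
calls split into LF and LHF: LHF when the power maximum above 50 kHz is at
least half the maximum below 50 kHz (inclusive reading of the rule; both
the boundary and the rule are configurable). Only **isolated** calls — at
least 500 ms without any other vocalization before onset and after offset
— enter the neural analyses; calls with a clean pre-window but another
sound inside the 500-ms post-window form the `contaminated_post` control
set for decoder generalization.

## Signal conditioning

Raw 20-kHz traces are band-passed 1–90 Hz (order-2 Butterworth), cleaned
of line noise (sliding-window least-squares sinusoid fit at 50 Hz plus the
first harmonic, 1-s windows, 0.5-s step, Hann overlap-add), downsampled to
1 kHz (zero-phase anti-alias low-pass at 0.4 × target rate, then
decimation), and z-scored per recording — one pooled mean/SD across all
FAF channels (preserving amplitude relationships across depths) and
per-channel statistics for the CN. All filtering is forward–backward
(zero-phase): the phase-locking and coherence stages downstream cannot
tolerate causal phase lag, so this choice is forced even where unstated.
Z-scoring statistics are computed over the whole recording rather than per
time point across trials; the alternative reading exists, but per-recording
statistics are the only ones that keep the randomization trials and epochs
on a common scale.

Epochs are ±500 ms of LFP around each isolated call onset (1001 samples at
1 kHz; sample 501 is the sample nearest onset). Spikes are multi-unit
threshold events: 300–3,000 Hz band-pass (order-2, zero-phase), negative
crossings of 5 × MAD (MAD with the Gaussian-consistency factor 1/0.6745),
spike time at the trough, 1-ms refractory lockout. Sorting into single
units is out of scope; externally sorted spike-time tables are accepted.
Pure-tone tuning (10–90 kHz in 5-kHz steps) is summarized per channel by
the post-onset sum of instantaneous energy (modulus of the analytic
signal) of the trial-averaged LFP; the argmax stimulus is the best
frequency, with ties toward the lower frequency.

## Randomization trials and effect-size maps

A **randomization trial** is the mean of `k` epochs (default 100; desk
scale 50) drawn uniformly from one call condition; `n_rand` such trials
(default 10,000; desk scale ≤ 1,000) are built per condition. Averaging
suppresses every component that is not time-locked to call onset, which is
exactly why injected bursts with per-trial random phase survive only as
power (not as waveform) in these trials. Sampling is without replacement
within a trial whenever `k` does not exceed the condition's epoch count,
with replacement otherwise (flagged); trials are independent of each other
and the whole construction is seeded.

Each trial's time–frequency power is estimated with a multitaper
spectrogram: 250-ms windows, time–bandwidth product TW = 2, K = 3 Slepian
tapers (±8 Hz bandwidth), FFT zero-padded to at least 1-Hz resolution over
1–90 Hz, window centered on the reported time, edge positions without a
full window dropped. The tapers are computed from Slepian's tridiagonal
eigenproblem. The nominal 0.5-ms step is sub-sample at the 1-kHz LFP rate
and is rounded up to one sample; analyses in this package's tests and
scripts use a 10–25-ms step — the maps are smooth at the 250-ms window
scale, so nothing in the recovered structure depends on the step, and the
computation drops by two orders of magnitude. Problem sizes used by the
shipped checks: `n_rand` = 1,000 and `k` = 50 for recovery maps, 250
trials for null sweeps.

Per (time, frequency) bin, the two conditions' across-trial log₁₀-power
distributions are compared with **Cliff's Delta**,
`d = (#{a > b} − #{a < b}) / (n·m)` ∈ [−1, 1], computed exactly through
the midrank identity `d = 2·U/(n·m) − 1`; positive values mean more power
during echolocation. Effect borders 0.147 / 0.333 / 0.474 mark small /
medium / large effects. `d` is invariant under monotone transforms, so the
log is cosmetic here; it matters for the decoder features.

A property of this construction worth knowing: when the number of distinct
epochs `n` per condition is not much larger than `k`, every randomization
trial is tethered to the finite epoch set's mean waveform, the across-trial
power distributions collapse around condition-specific constants, and `|d|`
saturates even for class-blind data. The across-condition comparison is
calibrated in the pooled regime (`n` of several hundred per condition,
i.e. calls pooled across recording sessions, which is how the original
analyses reached 10,000 trials of 100-epoch averages). The generator's
spectral study conditions therefore default to 600 calls per class for
effect-size maps; at `n = 600`, `k = 50` the class-blind 95th percentile of
`|d|` sits near 0.1, while an injected burst of gain 2 drives the in-band,
in-window mean `d` above 0.8.

## Decoding call type from band power

Features for one channel × band × window: the band-mean log₁₀ power at
each spectrogram time point within the pre-onset ([−0.5, 0) s) or
post-onset window, one row per randomization trial. The classifier is a
binary soft-margin SVM with Gaussian (RBF) kernel, trained once, **without
feature standardization**, box constraint 1 and kernel scale
√(n_features) (γ = 1/n_features) — the toolbox-default convention, since
no values were stated. Evaluation uses a disjoint set of randomization
trials; 10-fold stratified cross-validation of the training set is also
reported. Desk scale is 1,000 + 1,000 trials per class (train + held-out)
against the original 5,000 + 5,000.

The **shuffled-label control** permutes the training labels uniformly at
random and reruns the identical fit. A single permutation is a poor
estimate of chance here: balanced permutations flip the labels of entire
feature clusters coherently, so individual shuffled accuracies are
strongly bimodal (roughly symmetric around 50%, SD ≈ 10–18 points at desk
scale). The package therefore reports the mean over many permutation
seeds (50–100 in the shipped checks); that mean sits at 50% and is the
quantity meaningfully compared with chance. The contaminated-trial set is
scored with the clean-trained model, untouched.

## Inter-areal coherence

Coherence between each FAF depth and the CN channels uses the same
multitaper parameters, with **no randomization averaging**: per-trial
epochs enter directly, and `C(t, f) = |ΣS_ab| / √(ΣS_aa·ΣS_bb)` with
sums over trials and tapers. At least two trials are required; no
small-sample bias correction is applied (none was in the original
procedure), so trial counts are recorded on the map. Significance: a bin
is flagged when it strictly exceeds the 95th percentile of all coherence
values pooled over every map of one condition (pooling across conditions
is exposed as an option; per-condition pooling is the default reading of
"all computed values"). Band–depth profiles average coherence over the
band's frequency bins (theta 4–8, alpha 8–12 Hz) per depth and time.

## Spike–phase locking

Per band (theta, alpha, low/high beta, low/high gamma), epochs are
band-passed (order-2, zero-phase) and Hilbert-transformed; the phase
convention is cosine phase (peak = 0, trough = π). One angle is stored per
spike falling in the **pre-onset window only**; the control pool draws the
same number of phases at uniformly random non-spike sample times (±1 ms
exclusion around each spike). Bootstrap: `n_boot` iterations (default
10,000; desk scale 1,000) each draw m = 100 angles per pool and compute
the vector strength VS (resultant length) and, for the spike side, the
angular mean. `dVS` is the difference of bootstrap-mean VS (spike −
random); positive values mean spiking locked to the LFP phase. An
alternative median-based estimator is exposed through the returned VS
samples. Significance: two-sided Wilcoxon rank-sum on the two VS samples,
Bonferroni-multiplied by the number of channel × band tests in the
comparison family (the family size is logged with every result), at
p < 0.001. The stated ambiguity about angular means entering dVS is
resolved by computing dVS on VS and reporting angular means separately.

Calibration caveat, documented deliberately: the rank-sum test treats
bootstrap resamples as independent, so with small phase pools the
persistent finite-pool difference between two samples of the *same* phase
distribution becomes "significant". Measured at n_boot = 1,000, m = 100,
family 6: false-positive rate ≈ 12% for pools of 1,600 angles, ≈ 2% at
3,200, ≈ 0 at 6,400. The procedure is reproduced bias-included (as
specified); its null behavior is trustworthy only with the pool sizes the
pooled multi-unit data provide (several thousand spikes), and the shipped
null checks run in that regime (80-Hz multi-unit rate, 50 calls per
class). Recovery at κ = 5 coupling yields dVS > 0.5, preferred phase
within ±0.15 rad, and band-specific significance.

## The synthetic-data generator

`generate_session()` emulates the recording structure so that every
analysis stage has a ground truth to recover:

* **Audio**: two spectro-temporal templates — a 1-ms downward FM pulse
  (±11% sweep around a 72-kHz peak) and a 5-ms 14-kHz call, the LHF
  variant adding a 60-kHz component at relative amplitude 0.9 — Hann
  tapered, embedded in low-level noise, normalized to [−1, 1]. The
  reported median call duration of ~0.33 ms in the source material is
  implausibly short for either call type and is treated as a typographic
  artifact; the generator keeps 1 ms / 5 ms.
* **LFP background**: 1/f^α noise (α default 1, flat below 1 Hz) made by
  FFT shaping of white noise — exactly seedable, with the Welch log–log
  slope recovering −α ± 0.2 over 2–80 Hz.
* **Bursts**: Gaussian-windowed sinusoids at a band's center frequency,
  time-locked to the onsets of one class, restricted to a region and depth
  range, with uniform per-trial phase jitter — so randomization averaging
  keeps only their power, as the method assumes.
* **Coherent components**: the same construction with the phase *shared*
  between regions (CN lagged, default 5 ms); defaults place theta
  coherence pre-onset for communication and > 250 ms post-onset for
  echolocation. Each entry carries an explicit time window — without it
  the class-dependent coherence *timing* could not be expressed.
* **Evoked deflection**: a deterministic, phase-locked negative bump
  ~80 ms after onset in FAF channels at or below 500-µm depth.
* **Spikes**: thinned Poisson with intensity
  `base_rate · exp(κ·cos(φ − φ₀))/I₀(κ)` on the channel's own band phase
  (stationary spike-phase law exactly von Mises(φ₀, κ)), rate × (1 +
  evoked_gain) for 250 ms post-onset; optional biphasic waveforms injected
  into the raw trace at 8 × MAD for the spike detector to find.
* **Events**: inter-onset gaps exceed 1 s, so ±500-ms epochs of
  neighboring calls never share samples; a configurable fraction of calls
  receives a trailing distractor pulse 250 ms after offset
  (`contaminated_post` trials). Defaults: 30 calls per class in the
  single-session regime (matching per-recording isolated-call counts of
  ~28–31); pooled-regime analyses use 300–600 per class as noted above.

What the generator does *not* emulate: realistic syllable repertoires
beyond the two templates, biophysical neuron models, volume conduction,
electrode drift, correlated noise across channels, or behaviorally
structured call sequences. Passing recovery tests therefore demonstrates
that the analysis code measures what it claims under the stated
statistical structure — not that real fronto-striatal data contain that
structure.

## Numerical choices and degenerate inputs

* Zero-phase filtering everywhere; filters are order-2 Butterworth except
  the order-4 anti-alias low-pass.
* `stats::mad()` already applies the 1/0.6745 consistency factor used by
  the spike threshold.
* Degenerate inputs are explicit: zero-duration call specs, peak
  frequencies at the Nyquist margin, all-zero signals (undefined phase,
  flagged), exact call/noise cancellation (undefined peak, flagged),
  zero-variance channels (error naming the channel), empty spike pools
  (error), single-trial coherence (error), constant coherence maps (empty
  mask, warned), empty contaminated sets (warned, NA).
* Ties: spectral peaks and best frequencies break toward the lower
  frequency; the 50-kHz class boundary belongs to communication; the LHF
  rule is inclusive (H ≥ L/2); the coherence mask uses strict inequality.
* Seeds: every stochastic stage consumes an explicit seed or a sub-seed
  derived from the pipeline master seed; the global RNG state is restored
  after each call.

## Known limitations

* Threshold multi-unit activity stands in for sorted single units.
* Cliff's Delta maps are only calibrated in the pooled-epoch regime
  (n ≫ k); single-session maps with n ≈ k saturate and should be read
  qualitatively.
* The bootstrap phase-locking test inherits the original procedure's
  anti-conservativity for small phase pools (measurements above).
* The 50-kHz classification uses the global de-noised-FFT peak; whether
  the original boundary was applied to the fundamental or any harmonic is
  not recoverable from the text.
* HDF5/WAV interchange is reduced to a minimal PCM-16 WAV reader/writer
  plus RDS/CSV/JSON artifacts.
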