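---
title: "Detecting and quantifying spike-wave discharges in rodent EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying spike-wave discharges in rodent EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdwave)
```

## The problem

Spike-wave discharges (SWDs) are the EEG hallmark of absence epilepsy:
paroxysmal events in which a slow oscillation — about 8 Hz in rats —
carries a sharp spike phase-locked to every cycle. In chronic rodent
recordings they appear abruptly during quiet wakefulness, last from one
to over ten seconds, and recur tens of times per hour in severely
affected animals. Quantifying them means answering, per session: how
many events, how long, how much accumulated seizure time — and, in
stimulation experiments, whether an acoustic stimulus delivered during
an event terminates it.

`swdwave` implements the complete offline analysis as a tested
pipeline, together with a synthetic session generator that reproduces
the statistical structure this analysis assumes, so that every stage
can be validated end to end without animal data.

## Detection model

The detector operates on a single voltage channel sampled at 1 kHz:

1. **High-pass filtering** at 0.9 Hz, as a 4th-order Butterworth
   applied forward and backward (zero phase). Zero-phase filtering
   matters because event boundaries are read off the filtered trace;
   the order balances roll-off against edge transients.
2. **Decimation to 250 Hz** (polyphase, windowed-sinc anti-aliasing).
   The analysis grid tops out at 80 Hz, so a 125 Hz Nyquist leaves
   ample margin while cutting the transform cost sixteen-fold.
3. **Continuous Morlet wavelet transform** (centre frequency
   $\omega_0 = 6$) on a log-spaced grid, 2–64 Hz at 8 voices per
   octave. Scales map to Fourier frequencies by the standard Morlet
   relation; the normalization preserves signal energy across scales,
   so the band-integrated power of a narrowband oscillation is
   proportional to its amplitude squared regardless of its frequency.
4. **Band-power collapse**: the squared-modulus surface is integrated
   (trapezoidally in Hz) over 5–32 Hz, the interval that contains
   essentially all SWD oscillation power, giving one power trace
   $P(t)$.
5. **Robust threshold**: $\theta = \mathrm{median}(P) + k \cdot 1.4826
   \cdot \mathrm{MAD}(P)$. Median and MAD tolerate contamination of up
   to half the samples, so the threshold barely moves even when a
   session spends several percent of its time in seizure.
6. **Segmentation**: maximal supra-threshold runs become half-open
   candidate intervals; candidates separated by less than 0.3 s are
   merged (one waxing-and-waning discharge should not split), and
   candidates shorter than 1 s are discarded — a spike train lasting
   under one second is not counted as an SWD. The merge gap is
   deliberately shorter than the duration floor, so merging alone can
   never promote two sub-threshold fragments into an event.
7. **Artifact rejection** replaces manual visual screening: an
   interval is rejected when its power integrated over 40–80 Hz
   exceeds its 5–32 Hz power. Mechanical noise (cable taps, chewing)
   is a broadband transient and fails this test; spike-wave events,
   whose harmonics stay below ~32 Hz, pass.
8. **Characterization**: each surviving event gets a Welch spectrum
   (1 s Hann segments, 50% overlap), its dominant frequency in 5–32 Hz,
   the first-harmonic power ratio (power near $2 f_0$ over power near
   $f_0$), and its mean band power.

### Choosing the threshold multiplier

The one genuinely delicate constant is $k$. The background trace is a
*mixture* of vigilance states, and one state — REM sleep — carries a
legitimate narrowband oscillation (theta, ~7 Hz) inside the analysis
band. Because in-band power scales with amplitude squared, the REM
plateau sits only about six robust standard deviations above the
session median under default conditions, while even the weakest SWD
peaks another thirty-fold higher. A small multiplier ($k \approx 6$)
therefore lands *inside* the REM plateau and the false-positive rate
becomes a coin flip on the session's state mix, whereas anything in
the wide zone between REM and SWD power is stable. The default
$k = 35$ places the threshold near the log-midpoint of that zone:
measured across seeds, $\theta$ stays at least 1.9× above the REM
maximum and at least 6.7× below the weakest event peak. The
monotonicity property (raising $k$ never adds events) and exact scale
invariance (rescaling the recording leaves detected intervals
unchanged, since median and MAD scale with the power) hold for any
$k$.

## The synthetic session generator

The generator emulates exactly the features the detector relies on:

- **Vigilance states**: a semi-Markov chain over awake / NREM / REM
  with exponential dwells (means 120 / 180 / 60 s) rounded up to 10 s
  epochs. Sessions start awake; wake is followed by NREM; NREM is
  followed by REM with probability 0.5 (a value we fixed once —
  roughly half of rodent NREM bouts end in a REM transition — and do
  not expose as a headline parameter), REM always returns to wake, and
  REM is entered only from NREM.
- **Backgrounds**: one narrowband oscillator per state — 30 Hz at
  30 µV (awake), 3 Hz at 120 µV (NREM), 7 Hz at 40 µV (REM) — as a
  sinusoid with slow phase diffusion (~0.16 Hz linewidth), cross-faded
  over 1 s at state boundaries, plus a 15 µV RMS pink-noise floor
  shared by all states.
- **SWDs**: a crest-locked harmonic stack
  $A\,w(t)\sum_k d^{\,k-1}\cos(2\pi k f_0 t)$ with $f_0 = 8$ Hz, three
  harmonics, decay $d = 0.5$, amplitude $A = 250$ µV and a 0.25 s
  raised-cosine taper at each edge. Crest alignment is the simplest
  morphology that puts the spike in phase with the slow wave, and it
  produces the prominent 16 Hz first-harmonic peak of a spiky cycle
  shape. Durations follow $1 + \mathrm{LogNormal}(\mu, \sigma)$
  seconds, which guarantees the 1 s floor while keeping the long right
  tail (rare events beyond 10 s). Events are injected only into awake
  time (counts Poisson in the awake hours, starts uniform over awake
  time), and overlaps are resolved by rejection-resampling so the
  duration law is preserved exactly.
- **Artifacts**: broadband white-noise bursts (0.3 s, five times the
  SWD amplitude, ~6 per hour) anywhere in the session, giving the
  rejection stage true positives in every state.

The amplitudes are not published quantities; they were chosen once for
a clearly detectable but non-saturating signal-to-background ratio and
are all exposed in `generator_config()`. What the generator does *not*
model: EMG, electrode drift, amplitude nonstationarity within a state,
circadian structure, or any pharmacokinetics — VPA presets differ only
in their SWD rate and duration-law parameters. Passing tests therefore
demonstrate correctness of the *analysis* under controlled conditions,
not detector performance on real chronic recordings.

## Calibration of presets

Each experimental group is represented by a preset whose three free
parameters (rate, $\mu$, $\sigma$) are solved so that
*simulated-and-detected* sessions reproduce the group's published
summary triple (median duration, events/h, accumulated s/h — per-hour
figures normalized to total recording time). The median pins
$1 + e^\mu$ and the accumulated-to-rate ratio pins the mean
$1 + e^{\mu + \sigma^2/2}$, so $\sigma$ is identified by the
mean/median gap; the closed form seeds a multiplicative fixed-point
iteration through the full round trip, run with common random numbers
across iterations so the iteration is not chasing simulation noise. By
default each iteration simulates two one-hour sessions, and
convergence (all residuals within 5%) typically takes two iterations.

Group targets: wild type 2.1 s / 39 h⁻¹ / 102 s h⁻¹; heterozygote
2.0 / 28 / 86; knockout 2.3 / 61 / 155; VPA-treated wild type
1.9 / 51 / 127. The VPA-treated knockout group has a published median
(3.0 s) and accumulated time (307 s/h) but no printed count; its
preset uses 92 events/h, derived from the accumulated time under the
knockout group's mean-to-median shape. Note the rate of the treated
wild-type preset comes from the VPA experiment's own baseline cohort,
whose untreated rate (73/h) differs from the cross-sectional wild-type
group (39/h) — different animal subsets.

## Stimulus-interruption classification

An event is *stimulated* when at least one stimulus onset falls inside
its half-open interval — tones were triggered on live detection, so
only in-event onsets qualify. The event is Case 1 (interrupted) when
it ends within `window_s` of its first in-event onset and Case 2
(resistant) otherwise; unstimulated events are excluded from the
Case-2 ratio $n_2/(n_1+n_2)$. No interruption latency is published, so
the 1.5 s default window is a declared parameter: shorter than the
median event, yet generous for a readily interrupted response. The
session-half tabulation assigns events by start time relative to the
midpoint.

## Statistics layer

Group contrasts use rank-based tests throughout, pooling events within
a group (per-animal aggregation is available but not the default,
matching how the figures were computed): two-sided Wilcoxon rank-sum
and signed-rank (exact for small tie-free samples — up to 12 pooled
values and up to 15 nonzero differences respectively — otherwise
normal approximations with tie and continuity corrections; ties are
expected since durations are quantized by the sampling grid),
Kruskal–Wallis with tie correction, and a Dunn-type pairwise follow-up
on joint mean ranks. "Fisher's LSD" after a rank-based omnibus is
interpreted as its closest rank analogue: unadjusted pairwise p values
reported only alongside the omnibus H test. Degenerate inputs
(identical samples, all-zero differences) return p = 1 with a note or
a named error rather than propagating NaN.

## Numerical choices and degenerate inputs

- Half-open time convention everywhere: sample $i$ (1-based) covers
  $[(i-1)/r, i/r)$; an onset exactly at an event's end lies outside
  it. No stage emits overlapping intervals.
- EDF I/O is standard 16-bit EDF, one signal, physical dimension µV,
  1 s records; recordings are padded to whole seconds with a warning,
  and round trips are exact up to the 16-bit quantization step.
- The Welch estimator shortens its segment to the signal when the
  signal is briefer than 1 s; event spectra always have ≥ 1 s of data
  by the duration floor.
- A constant band-power trace yields a zero MAD; the threshold then
  equals the median and a warning is emitted.
- Resampling ratios are approximated by continued fractions
  (denominator ≤ 1000) with a message when inexact.
- Calibration refuses target triples whose implied mean falls below
  the median (impossible under the lognormal law) and reports best
  residuals when it cannot converge.

## Problem sizes

The test suite validates on sessions of 0.05–0.5 h (some at reduced
sampling rates for the purely statistical properties), Monte-Carlo
loops of 150–1000 replicates for distributional checks, and the
acceptance script reproduces the published knockout statistics on a
calibrated 2 h session at the full 1 kHz. Two dispersion sources
dominate the per-hour figures of a single 2 h session: Poisson
counting noise (~9% at ~120 events) and, larger, the realized awake
fraction of the state chain — with ~21 sleep–wake cycles in two hours
its coefficient of variation is about 19%, and the event count is
proportional to realized awake time. Calibration is therefore
performed on a per-awake-hour basis against the chain's analytic
awake fraction, so the presets are centered on the targets in
expectation even though any single short session can sit tens of
percent away. Median event duration is insensitive to the state mix
and reproduces to within a few percent per session.

## Known limitations

- The detector is offline and non-causal by design (zero-phase
  filtering, whole-session threshold).
- A purely power-based 5–32 Hz rule cannot separate SWDs from an
  equally *powerful* narrowband oscillation in the same band; under
  the default conditions the separation is wide, but real recordings
  with pathological theta would need the harmonic-ratio
  characterization as a post-hoc screen.
- Detected boundaries are threshold crossings; wavelet temporal
  smearing (~0.1 s at 8 Hz) and the event taper shift them by a few
  tenths of a second relative to ground truth. Calibration absorbs
  this bias, which is why presets are calibrated through the detector
  rather than on the raw duration law.
- State labels are generator ground truth; the package does not score
  sleep stages from the EEG.
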