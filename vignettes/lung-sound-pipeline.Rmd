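---
title: "Simulating and scoring adventitious lung sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring adventitious lung sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auscultr)
```

auscultr studies how well rule-based waveform-morphology criteria recover
crackles and wheezes from digital-stethoscope recordings, and how recording
fidelity (sample rate and bit depth) affects agreement with expert-style
reference tags. Because clinical auscultation audio is rarely shareable, the
package is built around a synthetic cohort generator whose outputs have the
same shape as a paired-device pediatric study: every stage downstream of the
generator — preprocessing, detection, scoring, evaluation — treats the audio
as it would treat real recordings.

## The acoustic event models

**Crackle.** A crackle is a brief, discontinuous transient. The package
models it as a short unidirectional initial deflection (a half-cosine pulse)
followed by an exponentially damped sinusoid at an oscillation frequency
$f$. Two quantities characterize the morphology:

* the *two-cycle duration* (2CD), the time spanned by the first two
  oscillation cycles; by construction $\mathrm{2CD} = 2/f$, so an event
  drawn at $f$ between 150 and 800 Hz has 2CD between 2.5 and 13.3 ms;
* the *total duration*, the width from transient onset to the point where
  the amplitude envelope decays below 10% of its peak. The damping constant
  is chosen as $\tau = (T_{\mathrm{total}} - w_{\mathrm{defl}})/\ln 10$, so
  the 10% point lands exactly at the nominal total duration.

A detected transient is accepted as a crackle iff its measured 2CD is below
20 ms and its measured total duration below 25 ms — strict inequalities.

**Wheeze/rhonchi.** A continuous tonal segment: a sinusoid at a dominant
frequency plus optional weaker harmonics (each at 0.3 times the previous
one), with 10 ms raised-cosine edge ramps. A detected segment counts as a
wheeze iff it lasts longer than 25 ms and its dominant frequency exceeds
100 Hz. Wheezes and rhonchi are pooled as one category.

**Background.** Vesicular breath sound is emulated as Gaussian noise
band-limited to 100–1000 Hz, amplitude-modulated by a squared-sine envelope
with a 3 s period (a typical pediatric respiratory rate of about 20
breaths/min) over a small floor, so the signal never vanishes between
breaths.

## The synthetic cohort

`cohort_config()` defaults describe the study shape: 25 participants in four
groups — normal breath sounds ($n=9$), wheeze only ($n=5$), crackles with or
without wheeze ($n=5$), and cystic-fibrosis clinic attendees with a clear
chest ($n=6$) — with 7 of 25 female; four posterior-thorax quadrants per
participant; a 20-second recording per quadrant from each of two device
profiles; and four aberrant recordings excluded per device, leaving 192
analyzable recordings out of 200.

Each (participant, quadrant) site carries one ground truth: events are drawn
once per site and both device recordings are derived from the same master
render at 44100 Hz — one physical sound, two observations, mirroring a
paired-device design. The high-fidelity profile stores float32 at 44100 Hz;
the low-fidelity profile is produced by zero-phase anti-aliased resampling
to 4000 Hz and 16-bit quantization.

Event densities and loudness are not reported in the kind of study this
emulates, so they are stated assumptions fixed once: crackle counts are
Poisson with mean 6 per 20 s and wheeze counts Poisson with mean 2 in the
groups that carry them (a participant in the crackles group also wheezes
with probability 0.5, decided at the participant level); every event is
mixed at 20 dB event-to-noise ratio over its support; crackle oscillation
frequencies are uniform on 150–800 Hz and total durations at most 22 ms;
wheeze dominant frequencies are uniform on 150–900 Hz with durations of
80–2000 ms. Aberrant recordings are simulated as near-silence (poor chest
contact) or hard clipping at 5% of peak (cable failure).

```{r cohort, eval = FALSE}
config <- cohort_config()
manifest <- cohort_manifest(config, seed = 1)
summary <- cohort_summary(manifest)
summary
```

## Preprocessing

Each recording is peak-normalized to 0.9 (the simplest reading of
"normalization" consistent with amplitude-threshold detection; per recording
rather than per corpus) and band-passed with a 6th-order Butterworth
high-pass at 100 Hz followed by a 4th-order Butterworth low-pass at 1000 Hz.
Both stages run zero-phase (forward–backward), because the analysis is
offline and the crackle criteria measure timing that a causal filter would
skew; the effective magnitude response is therefore the square of the
single-pass response. The filters are realized as cascades of second-order
sections designed from the analog prototype by bilinear transform — a
6th-order direct form at a normalized cutoff of 100/44100 is numerically
fragile — and the implementation matches the analytic Butterworth magnitude
response to well under 0.1 dB at 50, 100, 316 and 1000 Hz. At a 4000 Hz
sample rate the 1000 Hz low-pass is still realizable (Nyquist 2000 Hz); only
below a 2000 Hz sample rate is the low-pass stage skipped, with a warning.

## Detection

The morphology criteria define what a crackle or wheeze *is*, not how to
search for one. The search machinery is therefore fully parameterized in
`detect_control()`; the defaults below were fixed from the signal physics.

**Wheeze segmentation** runs first. A Hann-windowed spectrogram (50 ms
frames, 12.5 ms hop) is scanned for *tonal* frames: the spectral peak must
exceed 6 times the frame's median magnitude, both taken over the 100–1000 Hz
analysis band only (outside the band the band-passed signal is essentially
zero, and a full-axis median would declare every frame tonal). Consecutive
tonal frames whose peak frequency changes by less than 20% merge into runs;
each run's boundaries are refined at sub-frame resolution from the envelope
of the signal band-passed ±20% around the run frequency, with the noise
floor (estimated from the slice margins) removed in quadrature, support
taken above half the local envelope maximum, and sub-80 ms envelope nulls
bridged — two simultaneous wheezes at nearby frequencies beat against each
other, and the nulls must not fragment one sustained segment. The dominant
frequency is then re-estimated from the full periodogram of the refined
slice, which also rejects out-of-band tones whose high-pass skirt would
otherwise masquerade as a peak just above 100 Hz. Segments longer than 25 ms
with dominant frequency above 100 Hz are returned.

**Crackle detection** operates on a tone-suppressed copy of the signal: over
every detected wheeze segment the fundamental and harmonics are removed by
complex demodulation (mix down at the segment frequency, low-pass the
amplitude/phase track at 40 Hz, remix, subtract). A crackle riding on a loud
wheeze is otherwise buried — the sustained tone dominates both the broadband
envelope and its rolling-median baseline — while the crackle itself is
broadband and survives the suppression. Candidates are excursions of the
2 ms RMS envelope above 4 times a 150 ms rolling-median baseline. The median
window must be several times the longest admissible crackle: a 20–25 ms
transient occupying most of a short median window inflates its own baseline
and hides itself (with a 30 ms window a 22 ms crackle produces a ratio of
only ~3.6). Candidates closer than 20 ms collapse onto the larger peak;
surviving neighbours get windows trimmed at peak midpoints. Candidates
within 20 ms of a wheeze-segment boundary are discarded: the residual of
tone suppression concentrates at the onset/offset ramps, and such an edge
click — a brief decaying burst at the tone frequency — is indistinguishable
from a crackle.

**Crackle validation** measures each candidate against the criteria. Onset
is the last point before the envelope peak where the envelope is below a
threshold (10% of peak, floored just above the window's lower-quartile
envelope so it cannot sink under the noise floor). The 2CD runs from onset
to the fifth zero crossing (the first crossing closes the initial
deflection; four more complete two cycles). Total duration is measured on
the per-half-cycle lobe maxima of |x| — for a damped sinusoid these lie
exactly on the decay curve and, unlike a short-window RMS envelope, do not
oscillate when the RMS window is shorter than the period. After quadrature
removal of the noise floor, the log-lobe decay is fitted from the peak lobe
down to 30% of it and the 10% point is extrapolated from the fit: waiting
for the noisy envelope to cross 10% systematically overestimates the width,
while a non-decaying candidate (a sustained tone) extrapolates to an
effectively infinite width and is rejected.

## Scores and labels

Each recording receives a continuous score pair in $[0,1]$ — the analog of
a classifier's per-recording probability output. The mapping is a package
choice, documented and configurable: the crackle score is
$1 - e^{-n/4}$ in the number $n$ of accepted crackles, and the wheeze score
is the fraction of the recording covered by the union of detected wheeze
segments, capped at 1. Both are monotone in detection count/coverage, and a
recording with no detections scores exactly (0, 0). Labels use a strict
inequality: presence is declared only when the score strictly exceeds the
cutoff, so a score of 0 at cutoff 0 is *absent* — the "> 0.00" convention.

## Evaluation

Agreement with the reference tags is reported as positive and negative
percent agreement, PPA $= tp/(tp+fn)$ and NPA $= tn/(tn+fp)$ — the
sensitivity/specificity analogs appropriate when the reference standard is
expert annotation. The applied literature uses "TPR" with more than one
definition; the package reports TPR $=$ PPA by default and exposes the
precision-style $tp/(tp+fp)$ as a configurable alternative, asserting
neither as canonical. Metrics with empty denominators are undefined (`NA`),
never zero.

`roc()` enumerates every achievable operating point of the strict-`>`
labelling rule: one point per distinct score plus a sentinel below the
minimum score (the only way to call everything positive; when the minimum
score is 0 that sentinel cutoff is necessarily below 0).
`optimal_cutoff_interval()` maximizes PPA + NPA (a Youden-style balance of
the two agreements; the "best" criterion is otherwise unspecified in this
literature), breaking ties toward higher NPA and then lower cutoff, and
reports the maximal cutoff interval over which the confusion table is
unchanged — with tied scores and strict labelling, an optimal cutoff is an
interval, not a point. Evaluation is per recording, stratified by device;
excluded recordings never enter.

Cohen's kappa is computed per sound type from the standard
$(p_o - p_e)/(1 - p_e)$ with marginal-product expected agreement; when both
raters assign one identical category throughout, $p_e = 1$ and kappa is 1
by convention (observed agreement is perfect), with a message.

## Problem sizes and reproducibility

The test suite exercises the full default cohort once (200 recordings of
20 s; about two minutes of compute) and reuses it across test files; unit
tests run on 4–5 s renders. The acceptance script re-scores the 20%
participant subset twice (about 40 recordings per pass). Every stochastic
step is seeded: the manifest, event draws, and per-site rendering seeds all
derive from one master seed, and identical (config, seed) pairs produce
byte-identical WAV output.

## What passing tests do and do not show

The generator emulates the *shape* of a clinical study, not its physics.
Real chest-wall acoustics — transmission filtering, heart sounds,
respiratory-phase structure of crackles, fine/coarse crackle subtypes,
friction artifacts, crying — are absent, and synthetic crackles are
textbook-regular damped sinusoids. High recovery rates and near-perfect
PPA/NPA on the synthetic cohort therefore demonstrate that the criteria,
scoring and evaluation machinery are implemented and wired correctly, not
that the detector would match expert tagging on clinical audio. Known
detector limitations, measured on the default cohort: crackles closer than
~20 ms to each other or to a wheeze edge can be lost to candidate collision
or edge masking, and crackles whose oscillation frequency sits near the
100 Hz high-pass corner acquire a filter tail that can push the measured
total duration past 25 ms. Overall injected-event recovery on the default
cohort's event-carrying sites is 92% for crackles and 95% for wheezes (99%
and 100% for isolated events mixed at 20 dB SNR), with every accepted event
satisfying the printed criteria exactly.
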