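---
title: "Detecting muscle fatigue from surface EMG: methods and design notes"
author: "emgfatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting muscle fatigue from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgfatigue)
```

## The problem

A muscle is fatigued when it can no longer sustain the required force.
Detecting that moment *objectively* — from the surface electromyogram
(sEMG) rather than from what the subject reports — matters wherever
over-exertion causes injury: athletic training, rehabilitation after
stroke, ergonomics. Two well-established physiological signatures drive
the detector implemented here:

1. with sustained contraction and progressing fatigue the overall sEMG
   amplitude grows, so the integrated EMG (IEMG) of successive analysis
   windows rises; and
2. the power spectrum migrates downward: energy moves out of the
   high-frequency components (HFC, 80–350 Hz) into the low-frequency
   components (LFC, 25–79 Hz).

`emgfatigue` combines the two into a per-window *double-step binary
classifier* with a scalar *fatigue index*, plus everything needed to
exercise it end to end: signal conditioning, segmentation, feature
extraction, session-level evaluation, and a synthetic sEMG generator.

## The procedure

### Conditioning

A raw recording (sampling rate `fs`, default 2000 Hz) is conditioned by
`preprocess()`:

* DC-offset removal (mean subtraction);
* Butterworth band-pass, 25–350 Hz, design order 2 — the informative
  EMG band;
* Butterworth band-stop, 47–53 Hz, design order 2 — 50 Hz power-line
  suppression.

All filters are applied with zero phase by default so that envelope
timing is preserved when the two sub-bands are later compared sample-for
sample. Zero-phase application is realized *spectrally*: the window's
DFT is multiplied by the squared magnitude of the designed transfer
function, which is the net response of an ideal forward–backward pass.
This choice is deliberate. A time-domain forward–backward pass over a
finite window needs end extensions, and the startup transients of the
narrow-band filters used here (the 47–53 Hz notch rings for over a
second at 2000 Hz) leak ringing into the window that contaminates the
mean spectral amplitudes the classifier is built on — enough to break
the analytic tone oracles in the test suite. The spectral realization
has exactly the designed gains (−3 dB at each corner per pass, −6 dB
net), no transient, no group delay, and treats the window as periodic,
consistent with the rectangular-window periodogram used downstream. A
causal single-pass IIR mode (`zero_phase = FALSE`) is kept for
applications that need strict causality; it is a true `signal::filter`
pass with the filter's inherent group delay.

### Segmentation

`segment_record()` cuts the conditioned record into rectangular windows
of `window_s = 3` s with `overlap_s = 1.5` s (hop 1.5 s). Windows are
half-open sample ranges with starts at `round(i * hop * fs)`, so no
sample is claimed twice by rounding; a trailing stretch shorter than one
window is dropped because every feature normalizes by the fixed window
length. "Rectangular" is taken literally: no taper is applied before
any FFT.

### Step 1 — the contraction gate

For window $i$ with samples $x_0,\dots,x_{N-1}$ the integrated EMG is

$$\mathrm{IEMG}_i = \sum_{n=0}^{N-1} |x_n|.$$

The first window of the session fixes the baseline
$\mathrm{IEMG}_{\mathrm{initial}}$. A window enters step 2 only if its
IEMG *strictly* exceeds that baseline — evidence that the muscle is
actually contracting harder than at the session start. Three
conventions are made explicit because the procedure is ambiguous
without them:

* the gate is evaluated independently per window (no latching once
  passed);
* the comparison is strict (`>`), so the first window can never pass
  its own baseline and is always labeled non-fatigue; and
* gated-out windows carry no sub-band analysis in the report.

### Step 2 — sub-band balance

A window that passes the gate is split by two order-4 Butterworth
band-passes into a low-frequency sub-signal (LFSS, 25–79 Hz) and a
high-frequency sub-signal (HFSS, 80–350 Hz). The 79/80 Hz boundary is
kept exactly as published even though the two roll-offs overlap near
80 Hz; no guard band is inserted. For each sub-signal the
*instantaneous mean amplitude* is the mean magnitude of its full
two-sided DFT,

$$\mathrm{IMA} = \frac{1}{N}\sum_{n=0}^{N-1} |X_n|,$$

and the fatigue index is their difference:

$$\mathrm{FI}_i = \mathrm{IMA}^{\mathrm{LFSS}}_i -
  \mathrm{IMA}^{\mathrm{HFSS}}_i, \qquad
  \mathrm{FI}_i \ge 0 \;\Rightarrow\; \text{fatigue}.$$

Early in a session the high band dominates and the index is negative;
as spectral mass migrates downward the index rises through zero. The
threshold is inclusive (`>= 0`). One-sided IMA variants would differ
only by a constant factor and are not exposed.

### The fatigue report

`detect_fatigue()` assembles the per-window outcomes, in order, into a
`fatigue_report` (print/summary/plot/as.data.frame methods). The onset
time is defined as the *start time of the first fatigue-labeled
window* — the underlying study reports only session-level times, so
this convention is stated rather than inherited. `gate = FALSE` runs
step 2 alone, which exists to demonstrate why the gate is necessary
(below).

### Band-boundary diagnostics

`mnf()` and `mdf()` (power-weighted mean frequency; median frequency)
locate the spectral centre of a window, the classical justification for
the 80 Hz split between the component bands. Two discrete-spectrum
choices are documented: the DC bin is excluded (the offset is removed
upstream, and the moment sums index from the first nonzero bin), and
the median is the smallest bin frequency at which cumulative power
reaches half the total, since exact equality essentially never holds on
discrete bins.

## Session-level evaluation

`confusion_from_labels()` scores a session label table the way the
underlying validation study did: ground truth is that fatigue was
reached exactly at the final window of a fatigue-condition session, so
per muscle only the last two windows contribute — a fatigue label at
the last window is a true positive (else false negative), a non-fatigue
label at the second-to-last is a true negative (else false positive).
`classifier_metrics()` turns the tallies into sensitivity, specificity,
positive predictive value and accuracy. The packaged fixture
`session_labels.csv` transcribes the published 76-muscle session table
(75 usable muscles; one not examined); `session_fatigue_index.csv` and
`session_iemg_slopes.csv` transcribe the published per-session index
pairs and IEMG slopes. One transcription note: the running text of the
source study lists subjects 8, 12, 16, **22** and 32 as those whose
final index stayed negative, while its own tables show subject **25**
(right), not 22; the fixtures follow the tables and the discrepancy is
left documented rather than resolved.

`sample_size()` implements the proportion-estimate formula
$N = 4 z^2 \rho (1-\rho) / D^2$ used to size the validation cohort
(with $z = 1.96$, $\rho = 0.89$, $D = 0.2$ it returns 37.6, i.e. 38
subjects), returning both the raw value and its ceiling.
`iemg_slope()` (OLS slope of IEMG against window number) and
`paired_t_test()` support the contraction-trend analysis. Recomputing
the paired test from the transcribed slope table gives a *p*-value far
smaller than the study's printed 0.035 — the fatigue-condition slopes
in the table are one to three orders of magnitude larger than the
non-fatigue ones, which makes the paired *t* statistic large. The
printed table is rounded to two significant figures, so exact
reproduction is not expected; the package treats this as a diagnostic
and the tests assert only the significance decision (*p* < 0.05) and
the sign pattern.

## The synthetic sEMG generator

Real validation recordings are not published, so the generator exists
to make the whole pipeline testable with known ground truth. It
emulates exactly the statistical structure the classifier senses, and
nothing more:

$$x(t) = a(t)\,\bigl[w_l(t)\,s_L(t) + w_h(t)\,s_H(t)\bigr] +
  \phi\, s_0(t)$$

* $s_L, s_H$ are stationary band-limited surrogates for the two
  component bands: a dense random-phase harmonic series at every
  integer frequency in the band (80% of the power) plus
  band-pass-filtered white Gaussian noise (20%, `noise_mix`). The
  harmonic component pins the spectral envelope so the designed
  crossover is sharply identifiable; the noise component keeps genuine
  seed-to-seed variability. Pure filtered noise was rejected after an
  error-budget analysis: the one-periodogram IMA of a 54 Hz-wide band
  over a 3 s window fluctuates by ~3% per window, which alone puts the
  onset-recovery jitter near one hop.
* $w_l$ rises and $w_h$ falls linearly, with independent rates set by
  `w_l0`, `w_h0` and `w_cross` (their common value at the crossover),
  crossing at `crossover_s`. The defaults
  (`w_l0 = 0.1`, `w_h0 = 2.2`, `w_cross = 0.25`) encode a rapid
  high-band collapse against a modest low-band rise — the asymmetry
  observed in real fatigue sessions — and give the index a slope at
  the crossover steep enough that window-level spectral noise moves
  the detected onset by less than one hop.
* $a(t) = a_0(1 + g\,t)$ grows linearly (`amp_growth`, default
  0.06/s), driving the rising IEMG the gate requires.
* $s_0$ is a broadband 25–350 Hz noise floor at weight
  `noise_floor = 0.02`.

Three calibrations make the designed crossover a *well-defined* ground
truth rather than a nominal one. First, each band surrogate is scaled
so one unit of band weight contributes one unit of *net* fatigue index
through the full analysis pipeline (conditioning plus sub-band
extraction) — "net" because the order-4 sub-band filters adjoin at
79/80 Hz and each surrogate leaks a little into the other band's IMA.
Second, the pair is jointly refined so that an equal-weight mixture
measures exactly zero index through the pipeline; this absorbs the
small phasor interaction between the two sub-signals in the shared
roll-off bins, and is precisely the operational definition of the
crossover (overall amplitude scales out). Third, the broadband floor
is calibrated to full-band IMA units so `noise_floor` shares the band
weights' scale. All three are measured per realization, so they adapt
to any configuration.

One scheduling convention: the classifier judges a window by its mean
content but reports its *start* time. The weight trajectories therefore
run on window-start time (delayed by half a window), so that
`crossover_s` is the start of the first window whose mean spectral
balance favours the low band. The expected detected onset is then one
segmentation grid step (+1.5 s hop) after `crossover_s`, and the
recovery tests compare with a ±1 hop tolerance.

The relaxed-muscle mode (`relaxed_semg()`) produces the counter-example
that motivates the gate: a low-amplitude recording with the two bands
in balance, as from a muscle at rest. Its index hovers around zero and
flips sign window to window, so step 2 alone raises false positives.
The spec-level description of this mode as strictly stationary is
internally inconsistent with a strict `>` gate — a stationary record
exceeds its first-window IEMG roughly half the time by chance alone, so
the full classifier could never stay silent on it. The mode therefore
applies a gentle exponential amplitude settling
($a(t) = a_0 e^{-0.05 t}$), emulating residual activity dying away
after the posture is assumed; the IEMG then never exceeds its initial
value and the two-step classifier produces no positives while
step-2-only still fluctuates into false alarms.

### What the generator does not emulate

No motor-unit recruitment structure, no firing-rate modulation, no
electrode or movement artifacts, no nonstationarity beyond the linear
amplitude and weight trends, and no subject-to-subject variability in
band boundaries. Passing tests on this generator therefore show that
the *pipeline implements its definitions correctly* and recovers onsets
whose ground truth is spectral-balance migration; they do not show
field performance on real recordings, which is what the transcribed
session tables (75 muscles) anchor instead.

## Problem sizes and runtime choices

The test and acceptance runs use the study's acquisition geometry
(2000 Hz, 3 s / 1.5 s windows) with 80 s fatigue sessions, a 20-seed
Monte-Carlo for onset recovery, a 52-window non-fatigue control and a
20-window relaxed-muscle session. These sizes were chosen so the full
statistical contract is exercised at desk scale; every quantity is
recomputed from scratch at run time.

## Known limitations

* Single-channel only; no multi-muscle fusion.
* The gate compares against the session's first window; sessions that
  begin mid-contraction inherit a high baseline.
* Band boundaries are fixed (25/79/80/350 Hz); no per-subject
  adaptation.
* The onset convention (start of first fatigue-labeled window) is
  resolution-limited by the 1.5 s hop.
* The causal filtering mode shifts sub-band envelopes by the filters'
  group delay; the fatigue index is then conservative near the onset.
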