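---
title: "The iinfb engine: signal model, controller mechanics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The iinfb engine: signal model, controller mechanics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`iinfb` implements a real-time imagined-imitation (combined action
observation + motor imagery) EEG neurofeedback engine and its offline
analysis pipeline, together with a closed-loop virtual subject so that every
stage — from raw microvolts to the difficulty level reached at the end of a
session — can be exercised and tested without recorded human data. This
vignette documents the science the package encodes, the parameters that
matter, and the choices made where the design was genuinely open.

## The feedback metric

Sensorimotor engagement is quantified by event-related desynchronization
(ERD) of the mu rhythm, scored in a 7.5–14.5 Hz window on four channels over
left (C3, CP3) and right (C4, CP4) sensorimotor cortex. Data arrive in
500-ms ticks at 1000 Hz. Each tick's per-channel mu power is the sum of the
rectangular-window periodogram bins whose centers fall inside the band; at
500 samples the bins sit on a 2 Hz grid, so the band covers the 8, 10, 12
and 14 Hz bins. Powers are smoothed with a running average over the most
recent 6 ticks (3 s) and referenced to a fixed 15-s resting baseline
recorded before the first feedback block.

The single feedback quantity is the hemisphere-weighted score

```
score = rw * log2(C4/C4b + CP4/CP4b) - lw * log2(C3/C3b + CP3/CP3b)
```

where each term is the log2 of the **sum** of the two channel
power-to-baseline ratios for that hemisphere, `lw = 1` always, and `rw`
rises with difficulty (0 at levels ≤ 4, +0.1 per level over 5–13, 1 at
14–15). Contralateral (left) ERD raises the score; ipsilateral (right)
synchronization raises it once `rw > 0`.

Because each hemisphere term sums two unit ratios at rest, the resting
expectation of a term is `log2(2) = 1` and the resting score is `rw - lw`
(−1 at low difficulty). The engine implements the sum form exactly as
specified for the original system and documents the offset rather than
"correcting" it; `compute_nfb_score(..., normalize = TRUE)` exposes a
mean-of-ratios variant for exploration, but it is off by default and unused
by the controller. The simulation suite confirms the −1 resting offset
empirically (a null subject's long-run mean score at difficulty 1 is ≈ −1).

## The controller

* **Video score.** The presented feedback is an integer 1–6 (black-and-white
  to full color). Each tick, the current score is compared to the difficulty
  level's `[lower, upper]` thresholds: strictly above the upper threshold
  raises the video score by 1 (capped at 6), strictly below the lower lowers
  it by 1 (floored at 1). Any actual change freezes the score for 2 s
  (4 ticks). The logged/presented value for a tick is the frame shown
  *during* that tick; an update computed from tick *i* is first visible at
  tick *i + 1*, so every trial presents score 1 on its first tick.
* **EMG gate.** Every tick, the full-wave-rectified mean of each forearm EMG
  channel is compared to its baseline mean + 2 SD (per-tick statistics from
  the same 15-s baseline). A strictly greater value on either channel resets
  the video score to 1 and restarts the lockout. Gating dominates the
  lockout (a reset occurs even mid-lockout): safety gating should never be
  maskable by presentation smoothing.
* **Titration.** At the end of each 50-s trial the presented video scores
  from the final 20 s (40 ticks) are averaged: a mean strictly above 4
  raises the difficulty level (cap 15), strictly below 2 lowers it.
  Demotion below level 1 unlocks only after three consecutive completed
  trials at level 1 (the just-completed trial counts toward the streak) and
  bottoms out at −1. Sessions always start at level 1.
* **Level 15** has thresholds `[2, 2]`: a score strictly above 2 increments
  (a no-op at the cap), strictly below 2 decrements, exactly 2 holds.

Boundary conventions are strict everywhere (`> upper`, `< lower`, `> 4`,
`< 2`, `> mean + 2 SD`): boundary values hold the current state.

## Session schedule

Baseline 15 s; then 3 blocks × 10 trials of 50 s imagined imitation + 10 s
rest; then a transfer block of 10 × 20-s motor-imagery trials with rests
drawn uniformly from [8, 12] s (realized on the 500-ms tick grid), plus one
initial rest before the first motor-imagery trial. Markers
(`baseline_start`, `trial_start`/`trial_end`, `rest_start`,
`mi_start`/`mi_end`, `block_start`/`block_end`) are written at sample
resolution, and offline epoching cuts marker-to-marker, so epoch durations
follow the configured schedule exactly.

## Online and offline preprocessing

The online chain is causal: mastoid re-referencing (when reference traces
are supplied; the simulator emits already-referenced data), a 4th-order
Butterworth 1–100 Hz band-pass plus a 2nd-order 60 Hz notch (Q = 30)
applied with explicit filter state so chunked streaming equals one-shot
filtering to machine precision, DC correction from the first 3 s, and
ocular-artifact handling: any EOG excursion beyond ±360 µV marks an event at
its absolute peak (excursions ≥ 500 ms apart are distinct; earliest sample
wins ties), and within −200…+500 ms around each peak the first principal
component of the EEG+EOG channels is projected out. The PCA is *local*
(uncentered SVD of the window itself), which removes a rank-1 artifact
exactly and never touches samples outside the merged windows.

The offline chain differs exactly where the acquisition software differed:
0.5 Hz high-pass (no low-pass), zero-phase application, and a ±200 µV
ocular threshold. Filter order and notch Q are conventional defaults — the
source system names only cutoffs — and are recorded in `preproc_config()`.
The "±360 mV"/"±200 mV" thresholds are interpreted as microvolts;
millivolt-scale EOG is physically implausible.

## The virtual subject

The generator is deliberately the simplest model with exactly controllable
ERD depth:

* **Mu rhythm:** a phase-continuous sinusoid at `mu_freq` (default 10 Hz,
  amplitude 10 µV). During task states the amplitude at each hemisphere's
  channels is multiplied by `sqrt(ratio)`, so band power scales by the
  ratio itself and the programmed log2 ERD is exact in the noise-free case.
* **Background:** 1/f-shaped Gaussian noise (default 2 µV RMS, spectrum
  flattened below 1 Hz so DC stays bounded), independent per channel.
* **Blinks:** 400-ms raised-cosine deflections of 300 µV on the vertical
  EOG pair (mirrored), with 20% bleed into the EEG channels, at a Poisson
  rate of `blink_rate` per minute (default 8).
* **EMG:** 20–450 Hz noise whose per-tick rectified mean is pinned to a
  slow ±5% sinusoidal modulation (5-s period) around `emg_amp` (default
  5 µV). Scheduled bursts scale a whole tick by 5. The amplitude
  stabilization is intentional: it makes the burst-free false-positive rate
  of the 2-SD gate zero by construction, so tests can assert exact
  rejection counts. Real EMG has heavy-tailed amplitude variability that
  this model does not reproduce; the gate's behavior under borderline
  physiological noise is therefore *not* something the test suite can
  certify.
* **Learning:** after each trial whose titration-window mean video score
  exceeds 4, the contralateral ratio is multiplied by
  `1 - responsiveness` (floored at 0.05). This is the minimal model needed
  to exercise titration dynamics; it makes no claim about human learning
  curves.

The generator does not model cortical geometry, volume conduction,
individual alpha-peak variability, or attentional states (the original
baseline had subjects counting backwards; the generator uses plain rest).
Passing tests therefore demonstrate that the *engine mechanics* are correct
and recover programmed effects, not that the system would behave
identically on human EEG.

## Sham yoking

A sham session replays the presented video-score and difficulty streams
verbatim from the yoked real session's tick log; the sham subject's own EMG
is still evaluated and logged but never alters the presented stimulus. The
tick CSV written by `write_session_log()` is byte-stable (full double
precision, fixed dialect) precisely so that yoked replays are bit-identical
across processes and machines; `read_yoke()` validates the tick count
against the schedule before a sham run starts.

## Numerical choices and degenerate inputs

* Rectangular FFT window, closed band interval on bin centers — the
  estimator is then exactly Parseval-consistent and a pure in-band sinusoid
  of amplitude A yields A²/2.
* A zero-power tick would give `log2(0) = -Inf`; the ERD value floors at
  −20 instead so the controller arithmetic stays finite.
* The running average uses however many ticks exist at stream start (1–5)
  before reaching its full 6-tick window.
* Streaming filters are direct-form II transposed with carried state (a
  small compiled kernel), making chunked and whole-signal filtering equal to
  < 1e-9 µV; the linearity and concatenation properties are asserted in the
  tests.
* Overlapping artifact windows are merged before attenuation, so a sample
  is never projected twice.
* EDF export uses a fixed ±3276.7 µV physical range (0.1 µV per 16-bit
  step) and 0.5-s records; recordings must be tick-aligned. CSV export is
  lossless (17 significant digits). Markers travel in a CSV sidecar for
  both formats. All writes are atomic (temp file + rename).

## Open design points, resolved

* **Smoothing target:** the 6-tick running average is applied to the
  channel powers *before* the score (not to the score itself), keeping the
  score's inputs well-defined; the alternative is a near-equivalent linear
  smoothing of an already nonlinear quantity.
* **Offline ERD** uses raw per-tick powers (no 6-tick smoothing): the
  smoothing is a feedback-presentation device, not part of the measurand.
  The offline baselines are task-specific: the last 4 s of the baseline
  block for feedback epochs, the last 4 s of the initial motor-imagery rest
  for MI epochs.
* **The MI epoch-length discrepancy** (a 20-s protocol trial vs. a 25-s
  analysis epoch in the source description) is surfaced as a validation
  warning when epoch durations deviate from the configured schedule;
  epochs are always cut marker-to-marker.
* **Lockout on saturation:** a score pinned at its floor/cap has not
  changed, so no lockout starts; lockouts attach to actual changes (and to
  EMG resets).

## Problem sizes used by the test and acceptance runs

The packaged verification runs use: 100 random segments for the spectral
oracle; 200 task ticks per ratio (a 1-block × 2-trial schedule) for ERD
parameter recovery at ratios {0.25, 0.5, 1, 2}; 20 seeded full-schedule
sessions per arm for the null-vs-strong titration comparison; and one full
session pair for sham-fidelity and EMG-rejection checks. These sizes give
stable means (the recovery tolerance of ±0.2 log2 units is conservative at
200 ticks) while keeping a complete run in the minutes range on one core.

## Known limitations

* The virtual subject's mu is a single deterministic oscillator; real mu is
  bursty and nonstationary, so real-data ERD estimates carry variance the
  simulator does not produce.
* Online artifact attenuation is applied per contiguous chunk; a blink
  whose window crosses a chunk boundary is attenuated only within the
  chunk. The real-time system has the same constraint.
* The inferential statistics applied to ERD/S tables in the original study
  (conditional-inference forests) are intentionally out of scope: the
  pipeline exports tidy long-format tables ready for any such model.
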