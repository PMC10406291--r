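---
title: "Screening task fMRI runs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening task fMRI runs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskfmriqc)
```

## The problem

A task fMRI dataset can be invalidated from two directions at once: the
images (head motion, failed acquisition, preprocessing errors) and the
task (trials never presented, participants who stopped performing it). A
QC procedure that is too cursory misses these; one that is too onerous is
skipped. This package implements a screen of four necessary criteria —
quantitative where an unbiased threshold exists, qualitative where human
judgment is unavoidable — and keeps a complete machine-readable record of
every decision.

QC is performed on the *preprocessed* images and on the confounds a
preprocessing pipeline (fMRIPrep-style) emits, because an error anywhere
in the pipeline surfaces there: a clean preprocessed run implies a clean
raw run, but not conversely.

## Criterion A: excessive motion

Framewise displacement summarizes between-frame head movement as

$$\mathrm{FD}_t = \sum_{i \in \{x,y,z\}} |\Delta d_{i,t}|
  \;+\; r \sum_{i \in \{x,y,z\}} |\Delta \theta_{i,t}|,$$

with translations $d$ in mm, rotations $\theta$ in radians converted to
arc length on a sphere of radius $r$ (default 50 mm, configurable), and
backward differences ($\mathrm{FD}_1 = 0$). This matches the convention
of the confounds generators the package reads from, so FD taken from a
file and FD recomputed from the parameters agree.

Two thresholds apply, both configurable:

* **Censoring**: a frame is censored when FD *strictly exceeds* 0.9 mm
  ("more than 0.9 mm"); a frame at exactly the threshold is kept. 0.9 mm
  is lenient by connectivity-analysis standards but appropriate for task
  designs, where moderate motion is tolerable unless linked to trial
  timing.
* **Run exclusion**: the run fails when the censored fraction is
  *greater than or equal to* 0.20 ("20% or more"). The inclusive reading
  was chosen as the more conservative of the two natural phrasings;
  `evaluate_criterion_a(..., inclusive = FALSE)` gives the strict one.

Censoring is single-frame by default; `censor_before`/`censor_after`
extend it to neighbours for analyses that need it. Because motion outside
trials costs less analyzable data than motion during them,
`trial_censor_overlap()` partitions censored frames into those falling
inside a trial window `[onset, onset + duration)` and those outside. It
is reported, but deliberately not wired into criterion B's usable-trial
count by default — the interaction is real but its correct weighting is
design-specific; the hook (`usable_trials`) accepts an externally derived
count.

## Criterion B: improper task presentation

Consistent estimation across participants requires roughly equal amounts
of data, so a run fails when fewer than half of its expected trials are
usable — strictly: exactly half keeps the run. "Usable" defaults to the
event row being present (the run-truncation model: projector failures and
aborted runs shorten the table). Expected per-type counts cannot be
inferred from data and must come from the study design
(`expected_by_type`); `check_trial_counts()` reports any deviation,
including never-expected trial types, as a finding rather than an error.

## Criterion C: invalid task performance

This criterion distinguishes inattention (asleep, eyes closed) from poor
performance, which is *not* grounds for exclusion. For rapid designs
where every trial requires a button press, no-response trials are the
proxy. A run fails when either:

* the longest streak of consecutive no-response trials is **5 or more**
  (inclusive), or
* **more than 40%** of all trials lack a response (strict).

The two components are computed and reported separately: a long streak
suggests a lapse of attention; the same number of misses scattered evenly
suggests task difficulty. The fraction component is permutation-invariant
over trials; only the streak component is order-sensitive — a property
the test suite checks directly. A "no response" is a missing response
key; a recorded response with unknown correctness still counts as a
response, and accuracy is computed over responded trials only (suppressed
entirely, not zeroed, when no correctness column exists).

Single-button responding is surfaced as a review flag
(`detect_single_button()`, requiring at least 10 responses of evidence),
never an automatic exclusion. Repetitive-sequence detection is
deliberately not automated: any pattern detector would embed assumptions
about the stimulus sequence that the events table does not carry; the
raster figure exists so a human can see such patterns.

## Criterion D: failed acquisition or preprocessing

Per run, the package computes voxelwise temporal **mean**, **sd** and
**tSNR = mean/sd** volumes over the entire run *without censoring* —
censoring would mask exactly the between-run differences review is
looking for. The sd uses the sample (n−1) denominator; `sd_denominator =
"n"` is available for cross-checking against toolchains that use the
population form. Voxels with zero temporal sd get tSNR 0 rather than
Inf/NaN so montages render, and their count is reported so nothing is
hidden. No brain mask is applied: review covers the whole field of view.

Montages take evenly spaced slices after trimming the first and last 10%
of the chosen axis (edge slices are mostly empty), windowed to the 98th
percentile of in-volume nonzero intensities, in neurological convention.
Both choices are conventions of this package, documented rather than
inherited: slice selection and windowing are unspecified in most QC
toolchains' outputs.

`detect_metadata_mismatch()` compares sidecar fields (default
`PhaseEncodingDirection`, `RepetitionTime`) plus spatial shape and voxel
size across runs. The modal value over at least three runs defines the
dataset majority; deviants are listed, and a field with no majority is
reported as "no consensus". This catches the classic mis-acquisition
signature — one participant scanned with the wrong protocol — but it is
*evidence*, not a verdict: criterion D can only fail through
`qc_decision(..., criterion_d = "fail_by_override", override_note = ...)`,
i.e. a recorded human judgment. The constructor enforces the note.

## Reports and the decision record

`build_reports()` mirrors the classic two-document split: an image/motion
report (criteria A and D evidence: realignment traces with trial onsets,
the censoring threshold and censored frames marked, and the censored
count/fraction printed on each plot; summary-volume montages; the
metadata table) and a behavioral report (criteria B and C: the decision
table, notifications, and a raster of trial onsets, responses at onset +
response time, and correctness ticks with per-run margin counts). Every
number printed in a figure annotation is the same field stored in the
JSON record — no recomputation drift. `qc_decisions.json` is
schema-versioned, one object per run, and `excluded` is a pure function
of the four criterion fields, so the flag can be re-derived from the
record alone. Output is byte-identical across reruns unless a timestamp
is explicitly requested.

## The synthetic study emulation

The generators define the conditions every test runs under; they emulate
a rapid two-condition button-press task:

* **Events** (`synth_events`): 64 trials, CONTROL/TASK in equal
  proportion, ~7 trials/min with ±15% uniform ITI jitter, two response
  keys, response times lognormal with median 0.8 s and sdlog 0.3
  (a typical positively skewed RT distribution; nothing in the screened
  statistics depends on this choice), correctness Bernoulli at the spec
  accuracy (default 0.95). Missing-response plans are exact by
  construction: `block(k, start)` plants a streak, `scattered(k)` spreads
  k misses with no two adjacent (so only the fraction component can
  fire), and `decaying(rate)` draws misses with probability
  $1 - e^{-\text{rate}\,(i-1)/(n-1)}$, emulating a participant fading as
  the run progresses.
* **Motion** (`synth_motion`): per-parameter cumulative Gaussian walks
  rescaled to a 0.2 mm peak drift (0.2/50 rad for rotations) — smooth,
  far below censoring thresholds — plus spikes realized as *permanent
  translation steps* with the drift increment zeroed at the spike frame,
  so each spike yields exactly one frame whose FD equals the planted
  magnitude. Signs alternate to keep the trace bounded.
* **Phantom** (`synth_bold`): an ellipsoid brain (default 16×16×10
  volume, semi-axes 6×6×4 voxels, 3 mm isotropic) at baseline 1000 with
  i.i.d. Gaussian temporal noise of sd baseline/tSNR-target inside, and
  exactly zero outside; the optional affine distortion (shear + scale of
  the ellipsoid coordinates) plus a deviant sidecar emulates a
  mis-acquired run.

What the phantoms do **not** emulate: spatial autocorrelation,
physiological noise spectra, task-evoked signal, motion-image coupling,
and task-correlated (apparent) motion — the last is flagged in the field
as an open methodological problem and is intentionally out of scope.
Passing tests therefore demonstrate that the QC arithmetic and decision
logic are correct, not that the thresholds are optimal for any particular
scanner or population.

All generation is seeded and scoped (`withr::with_seed`), so identical
spec + seed give byte-identical artifacts and the caller's RNG stream is
untouched.

## Numerical and degenerate-input choices

* FD of a single-frame run is 0; the first frame's FD is always 0.
* Censoring/exclusion comparisons: censor strict (`>`), run-exclusion
  inclusive (`>=`), streak inclusive (`>=`), fractions strict (`>`),
  usable-data strict (`<`). Each mirrors the wording of its rule and each
  boundary is pinned by a test.
* Empty events tables are an error for streak/criterion computations
  (the quantities are undefined), while count mismatches and metadata
  deviations are findings, not errors.
* An all-zero volume produces an all-zero montage with no numeric
  warnings (the intensity window falls back to 1 when no nonzero voxels
  exist).
* Problem sizes in the test suite (100-frame FD traces, 200 random
  response sequences, a 6×6×3×50 oracle phantom, 200-frame tSNR
  recovery) were chosen as the smallest sizes at which the checked
  properties are non-trivial; the acceptance emulation uses ten 280-frame
  runs, comfortably representative of a ~9-minute acquisition at TR 2 s.

## Known limitations

* Criterion B's usable-trial count does not subtract censored trials by
  default (see above); studies wanting the stricter coupling must pass
  `usable_trials` explicitly.
* The metadata check compares a fixed field list; it cannot notice a
  deviation in a field nobody asked about.
* Surface-based summaries (vertex timecourses), DVARS, registration
  metrics and positive-control GLMs are out of scope; the screen is a
  first pass, not a full QC battery.
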