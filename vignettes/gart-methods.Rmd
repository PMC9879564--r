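---
title: "Gaze-based attention refocusing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-based attention refocusing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gart)
```

# The experiment this package models

`gart` is an offline, hardware-free implementation of a gaze-contingent
attention training experiment for adult ADHD research. A participant seated
in a virtual seminar room performs an 18-minute letter-stream continuous
performance task (CPT) projected on a canvas, while three-minute distractor
phases (DP) and non-distractor phases (NDP) alternate. An eye tracker
classifies, sample by sample, whether the gaze ray hits the canvas
(*task focus*), the collider of a currently playing distractor
(*distractor focus*), or neither (*gaze wandering*, an oculomotor proxy for
mind wandering). Under the *real* feedback policy an audiovisual cue plays
as soon as the gaze has left the canvas for more than 2 s or rested on a
distractor for more than 0.5 s; a *sham* policy delays the cue by a
quasi-random 20--30 s to decouple it from behaviour while matching its
frequency; a *no-feedback* policy stays silent. Each participant performs
all three conditions in counterbalanced order.

The package implements the full measurement battery around that loop: CPT
scoring, dwell-time analysis and a composite distractibility score,
velocity-based saccade/fixation detection, an EEG theta/beta-ratio (TBR)
pipeline at Fz, head actigraphy, experience-sampling and recognition
scoring, and the mixed-ANOVA/correlation statistics, plus a closed-loop
synthetic participant simulator that makes every stage testable without
recorded data.

# Conventions

One session clock per block, in seconds, with t = 0 at block start. All
windows are half-open `[start, end)`, which makes phase slicing a true
partition (no sample is counted twice; a boundary event belongs to the
later phase). Units are seconds, meters and microvolts; all angles are
degrees. Streams of different rates (gaze ~50 Hz, head ~90 Hz, EEG 500 Hz)
are aligned by timestamp filtering only and never resampled implicitly.

# The CPT generator

The task requires a keypress when a "K" follows an "A" and response
withholding otherwise; stimuli last 100 ms with a 1100 ms interstimulus
interval, giving 900 trials per 18-minute block. Because the target is
defined on a two-letter *transition*, the composition (30% targets; 50% of
the remaining transitions pseudo-targets) is defined over the 899
classifiable transitions; trial 0 is an unclassifiable "opener". A
pseudo-target is a transition carrying exactly one target letter in its
defining slot (`A -> non-K` or `non-A -> K`); everything else is a
nontarget.

The generator works in self-closing units -- a target unit emits
`(x -> A)` (a nontarget) followed by `(A -> K)`; a pseudo-target unit emits
`(non-A -> K)`; a nontarget unit emits a neutral letter -- shuffled under
the block seed. Because an "A" is only ever emitted directly before a
scheduled "K", no target can arise by accident, and re-classifying the
emitted letters independently reproduces the requested counts exactly. A
composition is infeasible when targets outnumber nontargets (each target
consumes one nontarget as its "A" carrier), which rejects `p_target`
beyond roughly 0.5.

The response window defaults to one stimulus-onset asynchrony (1.2 s),
the standard CPT convention when no explicit window is reported; it is a
parameter of `score_cpt()`, as is whether mean RT is computed over hits
only (default) or over all responses.

# Gaze classification and dwell metrics

Gaze states are decided by exact ray--collider intersection (axis-aligned
boxes and spheres; slab and quadratic tests). The nearest intersection
wins; ties break canvas-first, which is conservative against false
inattention. Distractor colliders are hittable only during their
activation window plus a 3 s linger that stands in for the unreported
animation durations. Auditory distractors get generous colliders at their
sound-source location, mirroring how auditory events are made "lookable"
in the scene.

Dwell percentages are expressed relative to the total block duration,
including invalid (blink) time, so the four states always close to 100%.
The distractibility score is
`(distractor-focus % + gaze-wandering %) / task-focus %`; it is undefined
(an error, not NaN) when task-focus time is zero. Whether the dwell
denominator should exclude invalid time is not fixed by the protocol; the
total-duration reading was chosen because it keeps the closure property
exact, and the invalid percentage is always reported alongside.

# The feedback controller

The controller is a deterministic per-sample state machine. Two timers
accumulate while the gaze is off the canvas -- the off-canvas timer on any
non-canvas valid sample, the distractor timer only during distractor
fixation. Any task-focus sample resets both; invalid (blink) samples
freeze them, so blinking is never punished. An onset is placed at the first
sample whose accumulated dwell strictly exceeds the threshold (2 s
off-canvas / 0.5 s distractor; while on a distractor both run, so the
0.5 s rule fires first by construction). Events stop at the first
task-focus sample or after 2 s, whichever comes first, and every offset
starts a 5 s refractory period. The visual envelope ramps linearly to 35%
coverage over 0.5 s and holds.

Sham mode schedules the onset at registration plus a uniform 20--30 s
delay and fires regardless of the participant's state at that moment --
the delay exists precisely to decouple feedback from behaviour -- subject
to the refractory rule at firing time. At most one sham is pending; new
registrations while one is pending are ignored, and a pending sham is not
cancelled by recovered attention. Whether the off-canvas timer should be
suspended during feedback presentation is not specified; here timers
restart from zero after each offset, which keeps inter-onset gaps at
least `max_duration + refractory` on adversarial inputs.

# Oculomotor detection

Preprocessing follows the standard binocular pipeline: per-eye linear
interpolation across gaps of at most 75 ms (on direction components,
renormalized), one-eye loss compensated from the other eye, then
binocular averaging. The raw fraction of samples with no valid eye is
reported as the data-loss figure. Interpolation operates on direction
vectors (not gaze points), consistent with treating velocity as angular.

Velocity is the sample-to-sample angular displacement (arccos of the dot
product) over the sample interval, smoothed with a second-order
Savitzky-Golay filter; the window length is not reported for the original
pipeline, so it defaults to 5 samples (~100 ms at 50 Hz) and is
configurable. The peak-velocity threshold is adaptive and data-driven, in
the standard iterative form of that family: starting at 100 deg/s, the
threshold is re-estimated as mean + 6 SD of the samples at or below the
current threshold until it moves by less than 1 deg/s. This form has a
clean fixed point (constant input returns itself) and separates fixation
noise from saccade peaks on bimodal input; its internals cannot be
verified against the original closed-source script, so every constant is
exposed in `detector_params()`.

Supra-threshold runs become saccades, refined outward to adjacent local
velocity minima. Fixation candidates shorter than 60 ms are discarded and
retained fixations separated by gaps of at most 40 ms are merged; a
saccade swallowed by a merge is dropped so events never overlap. At 50 Hz
durations are quantized to 20 ms, which is why the package makes no claim
about microsaccades -- the sampling rate is an order of magnitude below
what that requires.

# EEG and actigraphy

The EEG pipeline detrends per channel, low-pass filters at 35 Hz with a
zero-phase 4th-order Butterworth (the forward-backward pass doubles the
attenuation, >20 dB by 50 Hz), cuts each phase into as many non-overlapping
5 s epochs as fit, subtracts each epoch's mean (the reading of "baseline
corrected" for a continuous-performance epoch with no pre-stimulus
interval), and rejects epochs containing any sample above 100 microvolts in
absolute value. Interactive ICA-based artifact rejection and visual
component selection are deliberately out of scope -- they require expert
judgment and are not reproducible in a deterministic pipeline -- so the
amplitude screen is the documented, testable stand-in.

Time-frequency power at Fz comes from an FFT-based continuous wavelet
transform with an analytic complex Morlet wavelet (width 6 cycles, the
common default where the family is unreported) on 85 log-spaced
frequencies from 0.1 to 35 Hz, evaluated on a 4 ms time grid. The wavelet
is amplitude-normalized per frequency (unit gain at its center
frequency), so a sinusoid contributes the same band power wherever it
falls on the grid -- the property that makes the theta (4--7 Hz) to beta
(13--30 Hz) power ratio meaningful and exactly gain-invariant. Band means
are taken over 0.5--4.5 s of each epoch and averaged across epochs before
the ratio.

Head actigraphy low-pass filters the ~90 Hz 3D head position at 80% of
the target Nyquist (zero-phase), subsamples to ~10 Hz, trims filter edge
transients, and reports the mean Euclidean distance between consecutive
positions -- per 10 Hz step, which is the resolution at which "mean
distance of head position shifts" is best defined. The measure is
invariant to constant offsets and global rotations of the tracking frame.

# The synthetic participant

Latent attention is a continuous-time Markov jump process over
`on_task`, `gaze_wandering`, `distracted` and `blink` with exponential
holding times -- the simplest generative model whose stationary occupancy
maps directly onto dwell percentages. Distractor activations multiply the
distraction hazard during their window, so capture is bottom-up and
DP-locked; wandering is spontaneous and phase-independent, mirroring the
distinction between environmental distraction and mind wandering. Blinks
return to the interrupted state.

The group default profiles in `participant_profile()` were calibrated
once, before the test suite was frozen, so that simulated cohort means
approximate the published group means of the study population (18 + 18
adults): task-focus dwell near 86% vs 92%, distractor dwell near 1.9% vs
0.8%, per-cell omission errors near 2.8 vs 0.9, mean RT near 471 vs
436 ms, and head movement near 1.75 vs 0.80 mm per step for the ADHD and
control profiles respectively. These are *statistical* targets: the
generator reproduces orderings and magnitudes, not individual-level
dynamics, eye-tracker noise spectra, EEG artifact structure, or any
learning across blocks -- so passing recovery tests shows the analysis
battery is sign-correct and well-calibrated on data of this structure,
not that it would reproduce a specific clinical dataset.

Rendering places on-task fixations on the central canvas area with
Poisson relocations (~1.2/s), distracted fixations on the active
distractor's collider, wandering fixations in off-object regions, and
blinks as invalid samples; relocations are rendered as short
high-velocity transitions whose times and amplitudes are stored as ground
truth for the detector. Because feedback has no programmed effect by
default (`feedback_refocus_boost = 1` -- the study found no immediate
effect, so the boost is a knob, not a claim), the recorded feedback
stream is produced by running the real controller on the rendered,
classified gaze trace: a true in-loop composition. When the boost is set
away from 1, a continuous-time replica of the controller runs inside the
jump simulation and multiplies the refocus hazard while feedback is
active; re-sampling holding times at such modifier changes is exact by
memorylessness. The replica ignores blink-freezing of the timers (a
deliberate simplification -- it only shapes hazards, never the recorded
events).

# Statistics

The 2 (Group) x 3 (Feedback Condition) x 2 (Phase) and 2 x 3 mixed
ANOVAs are computed through a multivariate linear model with type-III
tests and sum-to-zero contrasts (`car::Anova`), from which the package
reports F, uncorrected p, partial eta squared, and both
Greenhouse-Geisser and Huynh-Feldt epsilons. The published switching rule
is applied per within-subject effect: Huynh-Feldt when the GG epsilon
exceeds 0.75, Greenhouse-Geisser otherwise ("Huynh field" in the source
protocol is read as the Huynh-Feldt correction). A hand-written
sums-of-squares decomposition oracle in the test suite guards the backend
choice. Post-hocs are Bonferroni-adjusted pairwise t-tests; correlation
matrices (Pearson or Spearman) apply the Benjamini-Hochberg step-up across
the off-diagonal tests of each matrix; all tests are two-sided at
alpha = 0.05.

# Numerical choices and degenerate inputs

Threshold crossings in the controller carry a one-nanosecond guard so
that accumulated floating-point error cannot move an onset by one sample.
The adaptive velocity threshold uses "at or below" in its conditioning
set, which makes a constant velocity input an exact fixed point instead
of an empty-set error. Constant outcome variables yield ANOVA tables of
NAs (reported as such, not zero); constant columns in correlation
matrices yield NA entries with a warning; zero task-focus time makes the
distractibility score an explicit error. Sphericity epsilons that are
inestimable (tiny cohorts) disable the correction rather than producing
NaN p-values.

# Problem sizes used by the test suite

The full study geometry (six 180 s phases, 900 trials, 500 Hz EEG) runs in
the examples and the calibration work, but the routine test suite
exercises the same code paths at reduced sizes chosen for tight feedback
loops: two 60--120 s phases per block for most pipeline tests, cohorts of
8 + 8 over 12 replicates for ordering recovery, and 40 null cohorts of
6 + 6 for the type-I check of the Feedback Condition effect. The
acceptance script regenerates every design-parameter quantity (controller
latencies, refractory gap, sham delay floor, fixation-duration and
merge-gap floors) from scratch on synthetic traces at the native 50 Hz.

# Known limitations

Collision geometry is box/sphere only; there is no vergence or gaze-depth
estimation, no smooth-pursuit class, no pupillometry, no ERP analysis and
no source localization. The simulator does not model learning,
medication, fatigue, or the sham-feedback aggravation the study observed
descriptively. The adaptive-threshold internals follow the standard
published form of the velocity-based family but cannot be verified
against the original analysis script. Dwell percentages use the
total-duration denominator; analyses preferring valid-time denominators
can recompute them from the reported invalid percentage.
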