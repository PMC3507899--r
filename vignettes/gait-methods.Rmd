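---
title: "Quantitative gait analysis for walkway recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative gait analysis for walkway recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousegait)
```

## Scope

`mousegait` implements the quantitative gait-analysis chain used to phenotype
bilaterally lesioned parkinsonian mice on an illuminated glass walkway: a
calibrated kinematic simulator of runway crossings, a paw-print detector for
luminance frame stacks, the full battery of temporal, spatial and
interlimb-coordination gait parameters, an open-field path-length readout,
and the group-comparison and neurochemical-correlation statistics
(one-way ANOVA, Pearson correlations of gait readouts against tyrosine
hydroxylase (TH) protein levels in the substantia nigra, SN). Because no
public dataset of this kind exists, the simulator is a first-class component:
its presets encode the published group statistics of saline-control and
MPTP-lesioned C57BL/6 mice, and the analysis chain is validated by recovering
them end to end.

## The kinematic gait model

A crossing is a sequence of step cycles. Cycle $k$ has duration
$T_k = T(1+e_k)$ with $e_k \sim N(0,\sigma_T^2)$ (truncated at 2.5 sd) and
body speed $v_k = v(1+d_k)$, so the cycle's stride is $v_k T_k$. The speed
multipliers $d_k$ follow an AR(1) process with lag-one correlation 0.65 and
marginal sd `body_speed_cv`: walking speed drifts on the run scale
(accelerations and decelerations), which is the component of "walking-speed
variation" that a cycle-scale statistic sees. Cycles accumulate until the
next stride would overrun the far margin of the 60 cm runway, with a uniform
start-position jitter; a floor keeps every run at or above the validity
minimum of five complete step cycles per paw.

Paw $j$ touches down at phase $\phi_j$ of the cycle and stays down for
`duty_factor` $\times\,T_k$. The phase offsets encode the footfall order; the
presets use the diagonal-couplet structure of the `Ab` alternate sequence
LF-RH-RF-LH: offsets $(0, \delta, 0.5, 0.5+\delta)$ with a small couplet lag
$\delta$. Two jitter terms perturb contact timing: a small onset jitter
(1.5 ms), of the same order as the control couplet lag (so it occasionally
flips the near-simultaneous diagonal touchdown order, a realistic source of
coordination noise) but far below the lesioned preset's lag, and a larger
stance-duration jitter that smears the support-phase boundaries the way
physiological variability does. With probability `pattern_noise` per cycle
one adjacent footfall pair swaps order, degrading the step pattern. The rate
is a per-preset coordination knob calibrated to the *null* finding that
interlimb coordination does not separate the groups: the control preset
(0.10) also loses pattern windows to onset jitter at its tight couplet lag,
while the lesioned preset (0.23, with a wide lag that jitter cannot flip)
loses them only to explicit swaps, leaving the regularity index statistically
indistinguishable between groups (~83% in both). The `Ab` share of classified
windows stays dominant in both (control ~99%, lesioned ~84%, against the
80–95% range typical of intact rodents).

Prints are placed at the body-centre position at touchdown plus a
longitudinal reach (+4.0 cm fore, −3.0 cm hind, a plausible placement span
for a C57BL/6 body) and half the girdle's base of support laterally. The
reach separation is chosen so prints of different paws stay separable on the
glass even when a speed spike stretches a single stride — a hind paw then
never lands on a still-lit fore print — while producing the
fore-ahead/hind-behind geometry the paw labeler relies on. Per-run stride
draws that would overrun the runway once the five-cycle validity floor
applies are compressed just enough to stay on the glass.

With every noise term at zero the model is exactly solvable, and the test
suite asserts the closed forms: stride equals `stride_length_mean`, duty
cycle equals `100 * duty_factor`, base of support equals the `bos` fields,
and the run duration is $D = (n - 1 + \phi_{max} + d)\,T$ for $n$ placements,
so cadence is $4n/D$. Cadence equals the idealised $4/T$ exactly only when
$\phi_{max} + d = 1$; the round-trip test uses such a configuration (a
single-support walk with duty 0.25 and offsets $(0, .25, .5, .75)$), and the
calibrated presets are checked against the full closed form with the
$O(1/n)$ end effect included.

## Support-phase algebra and its oracle

`support_profile()` partitions the run span at every contact boundary and
classifies each sub-interval by the set of paws in contact (zero, single,
diagonal pair, girdle pair, lateral pair, three, four); fractions sum to
exactly 100 by construction. The independent oracle in the test suite is a
1 kHz per-sample counter. Sampling a continuous partition at 1 ms aliases
category boundaries by up to half a sample, which for a 1.7 s run is worth
up to ~0.25 percentage points; the oracle comparison therefore generates
random runs whose event times are aligned to the 1 ms grid, making the
counter exact and the comparison a genuine check of the classification
algebra rather than of grid aliasing.

## Walking-speed variation

The paper-level readout "variation of walking speed" has no published
definition, so the package defines it explicitly and exposes the pieces: the
body centre is the unweighted mean of the centroids of currently active
prints sampled at the frame rate (at frame midpoints, so boundaries cannot
sit on the sampling grid); positions are smoothed with a centred moving
average of one median step cycle; speed is a central difference over half
that window; and the statistic is the population-SD coefficient of variation
in percent. The cycle window cancels the within-cycle staircase of the print
proxy exactly for a periodic gait (a constant-speed run scores 0), while
cycle-scale speed drift passes through with mild attenuation — which is why
the preset `body_speed_cv` values are calibrated through the measurement
rather than set to the printed CVs directly. Start and end transients, where
not all paws have landed, are trimmed.

## Detection and labeling

`render_frames()` emulates the acquisition: during a stance an elliptical
bright region appears at the print position; its pixel area and luminance
ramp from a floor (60% / 70% of maximum) up to the event's maximum at
mid-stance and back. The luminance floor is deliberately above any sensible
threshold so that detected contact intervals match the true ones to within
one frame. `detect_contacts()` thresholds at a fraction of the dynamic
range, labels 8-connected components per frame (EBImage's 4-connected
labeling plus a union-find merge of diagonally touching components), and
links components across consecutive frames when the centroid moves less than
the 1.5 cm gate *and* the pixel masks overlap. The overlap condition matters:
prints are stationary, so a true continuation always overlaps, whereas a paw
lifting in one frame and its girdle partner landing ~1.4 cm away in the next
would otherwise be chained into one event whenever frame quantisation
separates them by exactly one frame. Tracks shorter than 2 frames are
discarded as flicker.

`label_paws()` assigns left/right from the sign of the lateral offset to a
running-mean midline (a local window along the runway holds a balanced mix of
left and right prints, so its mean tracks the body axis; a running *median*
would lock onto one of the four discrete print tracks). Fore/hind is decided
per side: the fore and hind paw leave two distinct lateral tracks (their
bases of support differ), so the side's prints are split at the largest gap
in lateral position and the cluster whose prints lie, on average, ahead of
the concurrent body centre along the travel direction is fore. The
cluster-level decision is the important refinement: a *per-print*
longitudinal offset misclassifies at high walking speed, where the advancing
body overtakes an old fore print during its own stance; averaged over a whole
track the sign is unambiguous. When the two tracks are not separable
(unusually similar bases of support), each print's own offset decides. The
labeled run is validated: per-paw non-overlap, placements advancing along the
travel direction, and at least five complete cycles per paw; violations raise
a classed error, mirroring the exclusion of invalid crossings, and the
cohort-level analysis drops such crossings (about 0.5% at the default
presets) exactly as the experimental protocol discards unusable runs.

## Cohorts and the TH coupling

One latent lesion severity $s$ per animal (group mean 0 for control, 1 for
MPTP, within-group sd 0.2) drives everything: TH levels are linear in $s$
with group endpoints 1.0 → 0.4296 (SN; 57.04% loss) and 1.0 → 0.3868
(striatum; 61.32% loss) plus measurement noise (sd 0.05), and each
generator-parameter *block* (step-cycle timing; stride; posture = duty,
couplet lag, stance jitter; speed variability; base of support) follows its
own copy $s_b = s + \eta_b$. For a configured readout–TH population
correlation $\rho$ the block noise is available in closed form: with
$\sigma_S^2 = 1/4 + \sigma_u^2$ the pooled severity variance of a balanced
two-group cohort and $c$ the TH–severity correlation implied by the TH noise,
$\mathrm{Var}(\eta_b) = \sigma_S^2 (c^2/\rho^2 - 1)$. The correlation's sign
needs no separate mechanism — it follows from the direction in which the
parameter moves from the control to the lesioned preset, which reproduces the
published sign pattern (stride, swing speed, diagonal support and open-field
distance positive; stance, step cycle, duty cycle, dual stances, three- and
four-point support, speed variation and hind base of support negative).

The shipped couplings are one per block (stride 0.759, posture 0.677,
timing −0.463, speed −0.469, base of support −0.569, open field 0.206),
taken from the left-fore / whole-run rows of the published correlation
table; per-paw differences in the real data are treated as sampling noise, as
the generator is bilaterally symmetric. Interpolated per-animal parameters
are clamped to a physiological envelope for walking mice (step cycles
0.12–0.42 s, strides 2.2–9.0 cm, duty factor 0.30–0.80, and so on): the block
noise required to reproduce the weak correlations is substantial, and without
the envelope the severity tails would contain gaits no animal walks, whose
Jensen-type contributions (e.g. E[1/T] against cadence) visibly distort the
cohort group means. A single latent severity cannot
reproduce the published *negative* cadence correlation: cadence falls under
MPTP while TH also falls, so any one-factor mechanism makes their correlation
positive. The package accepts this as a limitation and does not attempt to
match that row's sign.

One published inconsistency is resolved by convention: the replicate-crossing
count is stated as "average 8 (range 4–6)"; the package defaults to 6 runs
per animal and exposes `runs_per_animal`.

## Calibration of the presets

The preset tables are frozen output of a calibration procedure that
adjusts, per group: duty factor, couplet lag and stance jitter against the
three printed support fractions (diagonal 80.52/59.76%, three-point
8.07/25.99%, four-point 1.24/7.33%; SEM-weighted Nelder–Mead followed by
damped Gauss–Newton steps on the support skeleton's Jacobian); step-cycle
mean against printed cadence (19.19/15.18 steps/s); stride mean against
printed run duration (1.708/3.099 s, via the number of cycles that fit the
runway); and `body_speed_cv` against the printed speed-variation CV
(24.44/34.92%), absorbing the window-averaging attenuation. Crucially the
calibration measures *cohort-level group means* — full cohorts with the
latent-severity spread and default couplings in place, on frame-grid
quantised events — not single preset-valued runs: the severity spread shifts
the group means through clamping and the nonlinear parameter-to-readout maps,
and those shifts belong inside the calibration. The frozen values were
verified on fresh seeds, both on the event algebra and through the full
frames → detection → labeling chain. Base-of-support and TH values need no
search (the measurement is unbiased for them), and maximum print area and
intensity are identical across groups, as the published comparison found
them indistinguishable.

The zero-noise support skeleton alone cannot reproduce the control mix:
four-point support requires the duty excess over 0.5 to exceed the couplet
lag, while lateral support requires the opposite, so a deterministic walk
can have one or the other but not both. Stance-duration jitter supplies the
missing mass on both sides of the kink, which is why it is a calibrated
parameter rather than cosmetic noise.

## Statistics

Group summaries are mean ± SEM (SD with $n-1$ over $\sqrt n$). One-way ANOVA
is the standard between/within decomposition (undefined F reported as
missing when both variances vanish). Pearson records carry $r$, the
two-sided $p$ from the $t$ transform with $n-2$ df, and $n$; `stats::cor.test`
supplies the numbers. The correlation table aggregates runs to per-animal
means before correlating — replicate crossings of one animal are not
independent — and pools both groups, which is what induces the correlation
through group separation; both choices are switchable (`groups =` argument).
No multiple-testing correction is applied, matching the raw-p convention of
the reported table. Repeated-measures ANOVA of the open-field time course and
post-hoc tests are out of scope: they apply to the real longitudinal data,
not to anything the simulator emulates.

## Open field

Spontaneous locomotion is a bounded correlated random walk in a 50 × 50 cm
arena: heading diffuses (sd 0.6 rad per 0.1 s step), speed fluctuates around
a per-animal mean, and both position and heading reflect off walls
(reflection preserves step length; the sampled polyline cuts reflection
corners by a negligible amount). The per-animal mean speed interpolates
5 cm/s (control) to 3 cm/s (lesioned) along the latent severity with the
open-field coupling (0.206) — values chosen to give ~3,000 cm vs ~1,800 cm
per 10-minute session, realistic spontaneous activity for intact vs
sub-acutely lesioned mice; the published figures report the direction and
significance of this difference but no usable group means. `path_length()`
sums Euclidean steps, in total and per time bin (default 60 s bins, 10 Hz
sampling, no smoothing).

## Problem sizes and reproducibility

The validation suite uses the sizes at which the checks are statistically
meaningful yet routine on a laptop: 20 replicate 8-per-group cohorts through
the full frames chain for group-statistic recovery (each readout within one
printed SEM, median over replicates); 100 replicate 44-animal cohorts for
correlation recovery (median $r$ within ±0.15 of the configured coupling);
1,000 grid-aligned random runs for the support oracle; 1,000 permutations
for the type-I-error check. All randomness flows from one integer seed
through documented stream splitting (per animal, run and stage), so cohorts
are bitwise reproducible; `run_pipeline()` writes a manifest with the seed
and a hash of the scientific configuration, and identical configurations
give byte-identical outputs.

## Known limitations

The generator emulates the statistical structure of walkway data, not its
physics: luminance is proportional to nothing mechanical (no pressure
model), prints are rigid ellipses, there are no hesitation, grooming or
wall-climbing runs (the published protocol excludes them, so the generator
only emits valid crossings), and bilaterally asymmetric lesions are out of
scope. Passing recovery tests therefore show that the analysis chain is
correct and well calibrated on data with this structure — not that it would
be robust to every artefact of real video. The cadence-correlation sign
issue above is inherent to the single-severity design. Detection assumes
separable prints; at resolutions below 4 px/cm the renderer refuses to
produce stacks rather than emit unseparable data.
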