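---
title: "Methods: downstream gait analysis for markerless motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream gait analysis for markerless motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneegait)
```

## Scope and model of the data

Markerless motion-capture systems built on smartphone video (two cameras,
deep-learning keypoint detection, triangulation, and OpenSim inverse
kinematics) emit two text artefacts per walking trial: a TRC file of 3-D
marker trajectories sampled at a fixed frame rate (typically 60 Hz,
millimetres, vertical axis Y) and a MOT file of joint angles in degrees for
the pelvis, hips, knees, ankles and subtalar joints. `kneegait` implements
everything downstream of those files for a two-group clinical gait study --
the canonical example being medial knee osteoarthritis (KOA) patients
versus healthy controls:

1. strict TRC/MOT readers and writers (`read_trc()`, `read_mot()`, ...);
2. signal conditioning: gap filling, Savitzky-Golay smoothing
   (`fill_gaps()`, `savgol_smooth()`);
3. gait event detection from vertical marker displacement
   (`detect_gait_events()`);
4. cycle segmentation, time normalization to the 101-point percentage
   grid, and quality control (`segment_cycles()`, `time_normalize()`,
   `qc_cycles()`);
5. spatiotemporal parameters and peak joint angles per cycle, averaged
   per participant after a pooled outlier screen (`cycle_parameters()`,
   `peak_angles()`, `participant_summary()`);
6. group statistics in the two conventional report shapes
   (`build_table1()`, `build_table2()`); and
7. phase-wise bootstrap comparison of normalized kinematic curves
   (`bootstrap_band()`, `difference_regions()`).

A synthetic cohort generator (`cohort_spec()`, `generate_cohort()`)
provides ground truth for every stage and is itself first-class, tested
code.

## Signal conditioning

Marker trajectories are smoothed with a Savitzky-Golay filter, window 31
frames, polynomial order 3. The classic filter requires an odd window, so
a requested even width (30 frames is a common published choice at 60 Hz)
is realised as 31. Edges are handled by refitting the polynomial on the
window truncated at the series boundary -- no padding, no artefacts beyond
the fit itself -- and the edge fit drops its order when the truncated
window has too few points. `savgol_smooth()` reproduces any polynomial up
to its order exactly and is linear in its input; both properties are
asserted in the tests against an independent per-point least-squares
oracle.

Kinematic curves get a *shorter* default window (11 frames, order 3). The
reason is quantitative: at a typical 64-frame gait cycle, the 31-frame
window passes the first harmonic at gain 0.98 but attenuates the second to
0.79 and the third to 0.30, which visibly clips joint-angle peaks; the
11-frame window keeps gains above 0.94 through the fourth harmonic. Both
smoothing points are individually switchable in `gait_config()`.

Interior marker gaps up to `max_gap` frames (default 10) are linearly
interpolated; longer gaps and leading/trailing missing samples are never
extrapolated and are reported, so quality control can reject any cycle
crossing an unfillable discontinuity.

## Event detection

Heel strike is defined as a prominent local minimum of the vertical heel
trajectory; toe off as the instant of maximum upward toe-marker velocity
(central difference) within each rise out of the stance plateau. These are
the standard displacement-based definitions when no force plates are
available. Three numerical safeguards matter in practice:

* an adaptive prominence threshold, 0.2 times the trajectory's 5th-95th
  percentile range (with an absolute floor so that float-level wiggles on
  flat signals never count as events);
* a refractory interval (default 0.5 s, bounding cadence at 240
  steps/min), resolved in favour of the deeper minimum / taller peak;
* parabolic sub-frame refinement through the three samples around each
  extremum -- at 60 Hz one frame is 16.7 ms, which is material for
  double-support percentages.

Event timing gets its own conditioning, independent of the spatial
smoothing. The heel-strike landmark is a sharp, locally symmetric height
minimum, which symmetric FIR smoothing leaves in place, so the heel
profile uses the full 31-frame window. The toe-off landmark is a broad
velocity peak whose flanks are asymmetric (rise from a plateau, fall
toward the swing descent); under marker noise a long window drags the
detected peak toward the flatter flank. Calibration sweeps on synthetic
trials with 2 mm marker noise showed toe-off biases of -0.6 frames at a
31-frame window versus |bias| < 0.15 frames and 95th-percentile absolute
errors of about 1.6-2 frames at 19 frames, which is the toe default.
These window choices are method parameters fixed here once, by those
simulations, not per-dataset tuning knobs.

## Cycles, quality control, parameters

A gait cycle runs from one heel strike to the next ipsilateral heel
strike. Curves are cut per cycle and linearly interpolated onto 101 grid
points (0-100%, integer percents at integer indices -- the gait-analysis
convention). Interpolation at native resolution is the identity, and the
operation is idempotent; both are asserted in tests.

Quality control rejects a cycle for exactly one of three reason codes, in
order: `abnormal_timing` (duration outside 0.4-2.5 s, bracketing the
cadences plausible in clinical walking), `marker_discontinuity` (an
unfilled gap overlaps the cycle), `implausible` (any degree of freedom
leaves its joint-family bounds, e.g. knee outside -20..100 degrees). The
"visual inspection" step of manual workflows is replaced by logged
rejections with provenance.

The six spatiotemporal parameters follow the standard event-defined
forms: gait speed as pelvis forward displacement per cycle (steadier than
heel progression; heel-based fallback via `speed_source = "heels"`),
stride and step lengths as forward-projected heel distances at heel
strikes, step width as the lateral heel separation at the bounding
strikes, cadence as 120 over the cycle duration, double support as the
bilateral stance-interval overlap within the cycle, and step-length
asymmetry as `100 |mean L - mean R| / mean`. Forward and lateral axes come
from a per-trial principal-direction fit to the pelvis track, which makes
every parameter invariant to laboratory-frame rotation (tested). Double
support is marked missing when the contralateral stance information cannot
reach the cycle -- in particular when an unpaired leading contralateral
toe-off shows that the stance interval it terminates was never observed.

Peak angles are signed extrema of the normalized curves: flexion-type
peaks are maxima, their antagonists minima, and pelvis degrees of freedom
report a single signed peak. Per-participant representative values are
means over accepted cycles after a single pooled +/-3 SD screen per
parameter (computed once on the full pooled dataset, no iteration).

## Group statistics

Continuous parameters are compared with Welch's unequal-variance t test
(always -- the Shapiro-Wilk and median-centred Levene screens are reported
but never switch the test), categorical ones with Pearson's chi-square
without continuity correction (switchable), and effect sizes are pooled-SD
Cohen's d. The two report shapes are the demographics/spatiotemporal table
(nine rows, step width in cm) and the fifteen-row peak-angle table in
which the control reference is each control participant's bilateral (L/R)
average and the experimental group contributes affected and unaffected
sides separately. The unit of analysis is the participant, never the
cycle; analysing the ~10 cycles per participant as independent
observations would overstate the evidence roughly threefold.

## Phase-wise bootstrap comparison

For each degree of freedom the per-participant mean curve is compared
between groups pointwise over the 101-point grid. Participants (not
cycles) are resampled with replacement, B = 1000 by default; a grid point
is flagged when the bootstrap interval of the group-mean difference
excludes zero; flagged points are merged into runs and runs shorter than
3 grid points are discarded, giving the conventional "X%-Y%" region
notation.

The interval is the *expanded* percentile interval by default. The plain
percentile interval of a mean difference at n = 15 per group is too
narrow: its bootstrap SD underestimates the sampling SD by a factor
sqrt((n-1)/n) per group and its z-style quantiles ignore the t correction,
and in a 200-repetition null simulation it flagged 7.2% of points at a
nominal 5%. The expanded interval widens the percentile level to
`2 * pnorm(-qt(1 - alpha/2, df) / shrink)` with pointwise Satterthwaite
df and the bootstrap-narrowness factor `shrink`; the same simulation then
flags 5.3%. `ci_type = "percentile"` restores the plain variant. Bands
are equivariant under constant shifts and reproducible under a seed
(tested).

For the within-patient contrast (affected vs unaffected side) the two
side-groups are resampled independently, ignoring the pairing; this is
conservative for that contrast and keeps one code path for all three
comparisons.

## The synthetic cohort generator

The generator is the package's ground-truth instrument, and its defaults
encode the group structure of a published KOA-versus-control cohort: 33
patients and 78 controls, three trials each at 60 Hz, group means and SDs
such as gait speed 0.87 +/- 0.44 vs 1.24 +/- 0.37 m/s, step width 13.23
vs 8.87 cm, double support 38.54 vs 22.68% and affected-side peak knee
flexion 37.39 vs 50.60 degrees (`group_targets()`). Four trial cycles per
foot reflect what a ~6 m walkway yields at these stride lengths.

Geometry is idealized but event-exact:

* **Heel height** is a raised cosine per cycle: a unique minimum exactly
  at heel strike, locally even, hence invariant under symmetric
  smoothing. (A literal flat stance plateau would have no unique minimum
  and sub-frame heel-strike recovery would be ill-posed by construction.)
* **Toe height** is a raised-cosine bump whose steepest ascent falls
  exactly at the true toe-off; the toe begins rising slightly before
  terminal contact and lands 8% of a cycle after the next heel strike, as
  real toes do. The late landing keeps the velocity peak locally
  symmetric even at the high stance fractions of severe double support,
  which is what makes unbiased toe-off detection possible there.
* **Forward progression** advances by the drawn step lengths with
  zero-end-slope cosine transitions, so heel positions are stationary at
  the instants where the pipeline samples them; the pelvis advances at
  exactly the drawn speed. Per-participant speed and cadence are drawn
  independently and stride length is derived as speed times cycle
  duration, so the kinematic identity speed = stride/duration holds by
  construction.
* **Double support** is imposed via the stance fraction s = 0.5 + DS/200
  with the contralateral offset fixed at half a cycle, so true DS equals
  2(s - 0.5) x 100 exactly; DS draws are clipped to [5, 49.5]% because
  this symmetric design cannot represent DS above 50%.
* **Joint angles** are truncated Fourier series (K = 6, top two harmonics
  zero) with idealized healthy-walking shapes, calibrated per participant
  by an affine gain/offset so the curve extrema equal the drawn peak
  targets to 1e-6 degrees (`calibrate_template()`). Keeping the waveform
  energy within the first four harmonics bounds the peak loss under the
  11-frame curve smoothing below 0.06 degrees, so zero-noise peak
  recovery is exact to well under 1%. The bundled templates are
  synthetic: they are designed shapes, not measurements of any cohort.

Participant-level draws are *moment matched*: the standardized normal
draws are rescaled so the sample mean and SD equal the configured targets
exactly (the `MASS::mvrnorm(empirical = TRUE)` idea), then clipped at
physical bounds with one re-centring pass. A generator whose finite cohort
only approximates its own targets would confound pipeline error with
sampling noise in every recovery test; moment matching makes "the pipeline
recovers the configured mean" a sharp statement. Clipping still shrinks
the SD where the configured distribution collides with a physical bound
(KOA double support against the 50% ceiling; the very wide printed ankle
peak SDs against the max-above-min requirement, which the generator
enforces with a 3-degree minimum separation).

Noise is white: 2 mm SD on every marker coordinate (the scale of
smartphone keypoint jitter; real markerless noise is autocorrelated and
occlusion-driven, which this deliberately does not model), 0.5 degrees on
angles, 2% CV duration jitter and 3% amplitude jitter per cycle. One
pelvis serves both sides, so per-side pelvis peak targets cannot differ
within a participant; the generator calibrates pelvis waveforms to the
affected-side (or control) target and records that value for both sides.

What passing recovery tests does and does not show: they demonstrate that
the pipeline is unbiased and sub-frame accurate *under this generative
model* -- smooth periodic kinematics, stationary heel landmarks, white
noise. They do not certify behaviour under occlusion dropouts, soft-tissue
artefact, curved walking paths, or pathological waveform shapes outside
the template family.

## Problem sizes and numerical choices

The recovery analyses use the full emulated design (33 + 78 participants,
3 trials, 4 cycles/foot/trial, about 2,700 accepted cycles); event
calibration uses ~500 events at each noise level; the null calibration of
the phase comparison uses 200 repetitions at B = 500, n = 15/15; the
double-support oracle comparison uses 1,000 random event configurations
against brute-force occupancy sampling. Degenerate inputs are decided
explicitly: all-equal samples keep everything in the outlier screen;
zero-variance groups give t = 0, p = 1; a flat trajectory yields no
events plus a warning; one participant is an error for a bootstrap band;
ties in the refractory rule resolve toward the deeper event.

## Known limitations

* Double support above 50% of the cycle is unrepresentable in the
  generator's symmetric-offset design.
* The affected-vs-unaffected phase contrast ignores within-participant
  pairing (conservative).
* The generator's noise model is white; no occlusion bursts.
* Printed group SDs that collide with physical bounds are honoured in
  the mean but shrunk in the SD by clipping.
* Statistical reports assume two groups; multi-group designs are out of
  scope, as are kinetics, muscle activation, and any upstream video
  processing.
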