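---
title: "Validating single-camera muscle-force estimates against marker-based motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating single-camera muscle-force estimates against marker-based motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleval)
```

## The scientific question

Marker-based optoelectronic motion capture driving a musculoskeletal model
is the de-facto reference for estimating individual muscle forces during
exercise, but it needs a laboratory, markers and cleanup. A single RGB
camera with a pose-estimation network produces a much sparser signal — a
handful of 3D joint centres at 30 Hz with centimetre-level, temporally
correlated errors — yet can drive the *same* musculoskeletal machinery.
`muscleval` implements both processing pathways end to end and the
statistics used to quantify their agreement, so that the whole validation
design can be exercised, tested, and stress-tested against synthetic data
whose ground truth is known exactly.

The package deliberately re-implements each stage in simplified, fully
inspectable form rather than wrapping an external simulation platform: a
desk-scale pipeline whose every numerical choice is visible and testable.

## The model

The kinematic chain is a tree rooted at a fixed thorax: thorax → clavicle
(2 rotational coordinates) → scapula (3) → humerus (3: elevation plane,
elevation, axial rotation) → forearm (elbow flexion + pronation) → hand
(rigid wrist). Clavicle and scapula coordinates are *prescribed*: they are
not solved from markers but follow a linear scapulohumeral rhythm
(default 1:2 upward-rotation-to-elevation ratio, configurable), because
scapular skin markers are unreliable in practice. Angles are degrees at
every interface and radians internally; each joint's rotation sequence is
intrinsic about the listed axes (world frame: X lateral toward the
dominant side, Y up, Z anterior).

The muscle registry holds 33 musculotendon actuators of the
thoracoscapular shoulder and elbow with their maximum isometric force,
optimal fiber length, tendon slack length and pennation angle. Muscle
paths are straight-line segments through configurable anatomical anchor
points shipped as an editable JSON asset (`inst/extdata/default_model.json`).
The source model's detailed geometry is not published numerically, so
these anchors are the package's own plausible choices; every force
comparison the package makes is *pathway-internal* (camera stream versus
marker stream through the same geometry), so anchor realism affects face
validity, not the validity of the comparison. Two geometric conventions
are worth noting:

* **Length calibration.** At load, each muscle's path is slid along one
  path leg so its musculotendon length at a mid-range calibration pose
  (45° elevation with rhythm, 60° elbow flexion) equals
  `l_ts + l_opt * cos(alpha)`. Fibers therefore operate near optimal
  length in the middle of each exercise's range, which keeps the published
  maximum-force values meaningful. Elbow-crossing muscles slide their
  origin (preserving the distal lever); all others slide their insertion.
  A via point at the posterior elbow stands in for trochlear wrapping of
  the triceps.
* **Moment arms** are tendon-excursion arms, `-dL/dq` by central finite
  difference (0.1° step, expressed per radian).

Segment masses and inertia default to regression-style proportions for a
75 kg adult and scale with the model.

## The two measurement pathways

The synthetic-data generator produces ground-truth joint kinematics for
two dumbbell exercises — the lateral fly (frontal-plane shoulder
elevation, 15°→90°, 3 kg) and the biceps curl (sagittal-plane elbow
flexion, 10°→130°, 5 kg), by default 3 sets of 5 raised-cosine
repetitions with 30 s rests and a ±5% per-repetition amplitude jitter as
a stand-in for self-selected effort. From one ground truth it renders:

* a **marker stream**: 12 bony landmarks at 400 Hz, isotropic Gaussian
  noise (default 1 mm) and independent per-frame dropout;
* a **camera stream**: 5 joint centres at 30 Hz with AR(1)-correlated
  Gaussian noise — default marginal sd 20 mm in-plane and 40 mm along the
  anterior depth axis with lag-1 correlation 0.9, sized so the mean
  per-joint position error falls in the 23–47 mm range reported for
  single-view pose-estimation networks, with the depth axis degraded most
  as is typical of monocular lifting. With a small per-trial probability
  the whole camera trial collapses to a tiny skeleton, emulating the
  catastrophic pose-estimation failures that quality control must catch.

What the generator does **not** emulate: soft-tissue artifact, marker
relabeling errors, occlusion-structured (pose-dependent) camera error,
lighting effects, or any image formation — the pose network itself is out
of scope and replaced by this statistical error model. Passing tests
therefore demonstrate that the *pipeline machinery* is correct and
well-behaved under a realistic error magnitude, not that a specific
network reaches a specific accuracy on real video.

## Processing chain

1. **Quality control.** Marker trials are excluded when any segment has
   fewer than three visible markers on more than 5% of frames; camera
   trials when median segment lengths leave [0.15 m, 0.6 m] or a centre
   teleports (median speed > 10 m/s). The thresholds are package choices;
   the underlying principles (minimum three markers per segment,
   implausible stick figures) come from the validation protocol.
2. **Joint centres.** Elbow and wrist centres are exact marker midpoints.
   The shoulder centre is the acromion plus a regression offset; the
   default is an affine map of acromion position in the thorax frame,
   calibrated at load against the model's own rhythm, because the
   acromion-to-centre vector rotates with the scapula during elevation (a
   constant offset would drift by centimetres at high elevation). The
   published regression coefficients are not available, so this is a
   documented stand-in with a function hook for replacements.
3. **Scaling.** Static-trial marker-pair distances divided by the generic
   model's distances give per-segment factors. Each measured distance is
   the norm of the *mean relative vector* over the static trial, not the
   mean of per-frame distances: averaging noisy distances is upward-biased
   (the norm is convex), while for a static pose the noise averages out of
   the relative vector before the norm is taken. The dense marker set
   scales thorax height and depth separately; the sparse camera set has a
   single thorax distance and must apply it uniformly to all thorax axes.
   Unmeasurable segments inherit a neighbour's factors. Slow, temporally
   correlated camera noise still leaves a few-percent scale uncertainty
   for short static trials — one of the realistic ways the camera pathway
   is less specific.
4. **Inverse kinematics.** Per-frame damped Gauss–Newton weighted least
   squares over all coordinates: marker terms (default weight 1), a
   prescribed-coordinate tracking term (weight 10 on radian residuals,
   strongly following the rhythm regression), and a weak prior (0.01)
   pulling humeral axial rotation to neutral — that coordinate is
   genuinely unobservable from a joint-centre-only stream at an extended
   elbow, and the prior resolves it identically in both pathways.
   Frames without a warm start probe several starting poses because the
   elevation-plane parametrization is degenerate near a hanging arm, and a
   frame whose fitted marker error exceeds 0.15 m is re-solved from those
   starting poses as well — under heavy camera noise a warm-started solve
   can otherwise follow a wrong branch of the elevation-plane ambiguity
   for the rest of the trial.
   Convergence: 1e-6 m improvement tolerance, 100 iterations cap;
   out-of-range solutions are clamped and flagged rather than hard-
   constrained. The measured humero-thoracic elevation that drives the
   rhythm regression is converted to the glenohumeral elevation
   *coordinate* through a calibrated monotone map (the measured angle
   contains the scapula's own rotation; the map is purely rotational and
   hence scale-invariant).
5. **Inverse dynamics.** Newton–Euler generalized moments at the free
   coordinates from low-pass-filtered coordinates (2nd-order 6 Hz
   zero-phase Butterworth before differentiation — distinct from the 4 Hz
   post-hoc force filter), segment gravity, and the dumbbell modeled as a
   pure downward force `m·g` at the hand's centre of mass (29.4 N and
   49.1 N for the 3 kg and 5 kg dumbbells; dumbbell inertia ignored).
   An `inertial_fraction` diagnostic reports the share of each frame's
   moment vector due to velocity/acceleration terms; for 2 s repetitions
   it stays below 15% at the peak-moment frame.
6. **Static optimization.** Per frame, activations minimize
   `sum(a_i^2) + w * sum(r_j^2)` subject to moment equilibrium
   `sum_i a_i Fhat_i R_ij + r_j = M_j` and `0 ≤ a_i ≤ 1`, with
   `Fhat_i = f_L · F_max · cos(alpha)` (rigid tendon; force–velocity
   omitted for these slow movements). The box-constrained quadratic
   program is solved exactly by an active-set method — important because
   near activation saturation a penalty solved only approximately makes
   the force distribution chatter. Reserve actuators (weight 1000)
   guarantee feasibility and are reported; a frame is flagged infeasible
   when a reserve exceeds `0.01·|M_j| + 0.1 N·m`. Both force–length modes
   (Gaussian of width 0.45, or ideal force) are available; the Gaussian
   mode is the default and is recorded in the output.

   The default constrained set contains only coordinates about which the
   muscle set can generate moment in *both* directions: the three
   shoulder coordinates and elbow flexion. Forearm pronation is excluded —
   with straight-line paths every muscle's pronation arm has the same
   sign, so constraining it forces the reserve to cancel muscle-generated
   pronation moment and distorts the whole distribution. Scapula and
   clavicle coordinates are prescribed and never moment-constrained;
   scapulothoracic muscles therefore carry no force in this model — the
   major, openly stated simplification relative to a full thoracoscapular
   model.

## Validation statistics

Camera forces are cubic-spline up-sampled to the marker rate (a 2 s
window maps 61 samples to 801), synchronized per repetition at the peak
shoulder-elevation (fly) or peak elbow-flexion (curl) instant detected
independently in each pathway, windowed to ±1 s around the peak, and
filtered with a zero-phase 2nd-order 4 Hz Butterworth (zero-phase because
the analysis is offline and phase distortion would bias peak alignment).
Per repetition and report row the package computes RMSD in N, RMSD as a
percentage of the row's (summed-head) maximum isometric force, and
Pearson's r, categorized as weak/moderate/strong/excellent at the
0.35 / 0.67 / 0.90 bounds. Zero-variance windows leave r missing rather
than zero, since correlations are uninformative for near-constant
signals; missing r values are excluded from aggregation but counted.
Aggregation is trial → subject mean → unweighted grand mean with the SD
across subject means as between-subject variation. Peak forces of the
prime movers feed Bland–Altman analysis (bias, bias ± 1.96 × sample SD
limits, per-subject mean differences). Report tables round half away
from zero to 1 decimal (r to 2).

Reconstructing the published percentage column from its Newton column and
the registry reproduces every single-head and summed-head rotator-cuff
row at 1-decimal rounding; the two biceps-curl biceps rows are *not*
reproducible at that rounding (7.1 N over 693 N is 1.0%, not 0.9%;
3.1 N over 485.8 N is 0.6%, not 0.7%) and the package flags rather than
reconciles them.

## Problem sizes used in tests

The generator's defaults are the study conditions (five subjects, 3×5
repetitions, 400/30 Hz, 20 mm correlated camera noise). The test suite
and the acceptance script exercise deliberately smaller instances of the
same machinery — one or two subjects, one to two repetitions per trial,
and reduced sampling rates in unit tests — which keeps the full suite
within a desktop-minutes budget while the acceptance checks still run the
marker stream at its native 400 Hz. The vignette's and README's example
sizes are chosen the same way.

## Known limitations

* Straight-line muscle paths without wrapping surfaces: moment arms are
  only plausible, and degrade at extreme flexion; the comparison between
  pathways remains internally valid because both share the geometry.
* No scapulothoracic gliding constraint; prescribed rhythm instead.
* Rigid tendon, no force–velocity property (slow strength movements).
* The camera error model is stationary AR(1); real pose-estimation error
  is pose- and occlusion-dependent.
* Real-participant results cannot be regenerated: the original videos are
  withheld, so the synthetic study reproduces the *design*, not the
  published table values.
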