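# muscleval

Can a single RGB camera with a pose-estimation network replace
marker-based optoelectronic motion capture for estimating individual
muscle forces during strength exercises? `muscleval` implements the full
validation pipeline needed to study that question at desk scale: a
simplified thoracoscapular shoulder–elbow musculoskeletal model with a
33-muscle parameter registry, a synthetic-data generator that renders
both measurement streams (12 bony landmarks at 400 Hz; 5 joint centres at
30 Hz with correlated, pose-estimation-like noise) from known ground
truth, the processing chain each stream passes through — quality control,
joint-centre estimation, static-pose scaling, weighted least-squares
inverse kinematics with rhythm-prescribed scapula/clavicle coordinates,
inverse dynamics with the dumbbell load at the hand, static optimization
of squared muscle activation — and the agreement statistics that compare
the two pathways.

It is written for movement scientists and biomechanics methodologists who
want an inspectable, fully testable implementation of this validation
design rather than a black-box simulation platform.

## The core computation

Per frame, inverse kinematics solves

```
min_q  Σ_l w_l ‖x_model,l(q) − x_exp,l‖² + w_a Σ_presc (q_c − q̂_c)² + w_r q_rot²
```

(damped Gauss–Newton; prescribed scapula/clavicle targets from a linear
scapulohumeral rhythm). Inverse dynamics yields net joint moments `M_j`
by Newton–Euler recursion with the dumbbell as a pure force `m·g`
(29.4 N / 49.1 N) at the hand's centre of mass. Static optimization then
distributes the moments over muscles:

```
min_a  Σ_i a_i² + w Σ_j r_j²   s.t.   Σ_i a_i F̂_i R_ij + r_j = M_j,  0 ≤ a_i ≤ 1
```

with `F̂_i = f_L(l̃_i) · F_max,i · cos α_i` (rigid tendon, Gaussian
force–length) and tendon-excursion moment arms `R_ij = −∂L_i/∂q_j`,
solved exactly as a box-constrained quadratic program. Agreement between
the camera and marker pathways is quantified per repetition by RMSD (N
and %F_max), Pearson r with the 0.35/0.67/0.90 category bounds, and
Bland–Altman statistics of peak forces, aggregated trial → subject →
grand mean ± between-subject SD.

## Worked example

A one-subject, one-trial lateral-fly comparison with mild camera noise
(10 mm, reduced sampling rates so it runs in about a minute):

```r
library(muscleval)

model <- load_default_model()
model
#> <msk_model> simplified thoracoscapular shoulder-elbow model
#>   segments: thorax, clavicle, scapula, humerus, forearm, hand
#>   coordinates: 10 (5 prescribed)
#>   muscles: 33 entries, 16 muscle groups

group_f_max(model, "Infraspinatus")   # summed heads, N
#> [1] 2004.8

design <- study_design(n_subjects = 1, n_trials = 1, n_reps = 2,
                       exercises = "lateral_fly",
                       noise = noise_model(sigma_xy = 0.01,
                                           failure_prob = 0, seed = 42),
                       marker_rate = 100, camera_rate = 30, seed = 42)
report <- run_study(design, model)
report
#> <validation_report>
#>   trials: 1 generated, 1 included, 0 excluded
#>   per-muscle grand means (RMSD N / %Fmax / r):
#>     lateral_fly  Deltoid anterior               37.9 +-  0.0 N   5.4%  r=0.21 (weak)
#>     lateral_fly  Deltoid middle                103.6 +-  0.0 N   4.0%  r=0.89 (strong)
#>     lateral_fly  Deltoid posterior             130.6 +-  0.0 N   9.9%  r=-0.03 (weak)
#>     lateral_fly  Infraspinatus                   9.0 +-  0.0 N   0.5%  r=0.01 (weak)
#>     lateral_fly  Subscapularis                  49.1 +-  0.0 N   2.5%  r=-0.64 (moderate)
#>     lateral_fly  Supraspinatus                  16.0 +-  0.0 N   1.8%  r=0.48 (moderate)
#>     lateral_fly  Teres minor                     3.8 +-  0.0 N   0.5%  r=NA (-)
#>     ...
```

Reading this: even with mild (10 mm) camera noise the prime mover's
(deltoid middle) force curve is reproduced to 4.0% of the muscle group's
2597.8 N maximum isometric force with a strong correlation (r = 0.89),
while muscles carrying little force correlate weakly — with hardly any
signal to track, r is dominated by noise, and a constant-force window
leaves r missing (`NA`) by design. The between-subject SD column is 0
because this example has a single subject, and a single noisy trial
scatters considerably from draw to draw — the full study design averages
trials within and then across subjects. `tidy(report)`
returns the table as a tibble, `glance(report)` a one-row summary, and
`autoplot(report)` / `autoplot(report$bland_altman[["Deltoid middle"]])`
the standard figures. `run_pathway()`, `solve_ik_trajectory()`,
`compute_net_moments()` and `solve_trajectory_so()` expose the individual
stages; `write_trc()` / `write_sto()` exchange streams with external
biomechanics tools.

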