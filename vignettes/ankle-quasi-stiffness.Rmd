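---
title: "Ankle quasi-stiffness and propulsive work: models, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ankle quasi-stiffness and propulsive work: models, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the moment–angle
model it assumes, what the synthetic-data generator does and does not
emulate, every numerical rule with a tunable constant, and the design
decisions taken where more than one defensible choice existed. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The piecewise-linear loop model

The analysis unit is one stance-phase record of sagittal ankle angle
$\theta$ (rad, dorsiflexion positive) and ankle moment $M$ (N·m,
extensor positive) indexed by percent of the gait cycle. Over the
progression period the loop is treated as three nearly linear limbs
joined at four landmarks:

* **b** — onset of dorsi-flexion: first local minimum of the angle
  after the heel-strike transient;
* **c** — dorsi→dual transition, placed at a fixed percent of the gait
  cycle (default 30%);
* **d** — dual→plantar transition: the moment maximum;
* **e** — toe-off: the post-c angle minimum.

Phase quasi-stiffness is the ordinary-least-squares slope of $M$ on
$\theta$ within a phase; the phase excursion $\Gamma$ is last-minus-
first angle; propulsive work $E$ is the area enclosed by the b..e
samples closed by the chord e→b (shoelace rule). For an idealised loop
with zero moment at b and e,

$$E = \tfrac12\left|M_d(\Gamma_{pf} - \Gamma_{dl})
      - M_c(\Gamma_{df} + \Gamma_{dl})\right|,$$

the area of the quadrilateral through the phase-transition vertices
($M_c$, $M_d$ are the moments at c and d and $\Gamma_{dl}$ is signed).
`work_from_fits()` implements this closed form and `loop_work()` the
shoelace integral; the two agree exactly on noiseless piecewise-linear
loops, which the tests exploit as an oracle.

**Sign conventions.** Dorsiflexion-positive angles and extensor-positive
moments make $K_{df}$ and $K_{pf}$ positive. The dual-flexion excursion
is kept *signed* throughout the regression bases: the dual phase
dorsiflexes below and plantarflexes above a subject-specific singular
speed, so $K_{dl} = (M_d - M_c)/\Gamma_{dl,signed}$ flips sign there
and diverges as the excursion passes through zero. A magnitude-only
convention cannot represent this sign structure, which is why the
package departs from reporting conventions that define $\Gamma$ as a
magnitude (the summary table carries both `Gamma_dl` and
`Gamma_dl_signed`).

**Singularity handling.** A dual excursion below `singular_tol`
(default 1e-4 rad) flags the trial: its $K_{dl}$ is reported non-finite
and the row is excluded from dual-flexion model fitting. The dorsi- and
plantar-phase quantities of such trials remain valid.

## 2. The synthetic-cohort generator

No per-trial data were deposited for this class of study, so the
generator is a first-class, tested module that defines the study
conditions. It emulates a 26-subject, 216-trial cohort pooled from
three lab protocols: 9 subjects at 4 evenly spaced speeds over
0.75–2.0 m/s, 5 subjects at 20 speeds over 1.0–2.6 m/s, and 12
subjects with 5,6,9,7,4,5,7,9,5,4,6,13 trials within ±5% of their
preferred speed. Weight and height are uniform on 46–94 kg and
1.43–1.87 m.

The generative model (all defaults in `gen_coeffs()`):

* transition moments scale with body size and speed,
  $M_c = WH(a_0 + a_1 V)e^{\eta}$ and
  $M_d = WH(b_0 + b_1 V + b_2 V^2)e^{\eta'}$, with log-normal
  multiplicative noise (`moment_cv` = 0.10) so moments stay positive;
* excursions: $\Gamma_{df} \sim N(0.22 - 0.02(V-1.5),\,0.03)$ rad and
  $\Gamma_{pf} \sim N(0.49 + 0.04(V-1.5),\,0.06)$ rad, truncated
  positive; $\Gamma_{dl,signed} = s_0(V_{sing} - V)e^{\eta''}$ with
  $s_0 = 0.08$ rad/(m/s), so its sign flips exactly at the subject's
  singular speed, drawn uniformly on (1, 1.5) times the preferred
  speed;
* each subject's preferred speed comes from the Froude relation of
  section 4.

The moment/excursion coefficients were calibrated — analytically first,
then centred on simulated expectations — so the default cohort's mean
dorsi-flexion stiffness, plantar-flexion stiffness and propulsive work
sit near 246 N·m/rad, 202 N·m/rad and 17.6 J, the field-typical
pooled means this design emulates. Cohort draws at different seeds
scatter a few percent around these centres. Note one consequence of
honouring all three targets jointly: with $K_{pf}\approx 200$ N·m/rad
and $E\approx 17.6$ J the push-off excursion must average roughly
0.5 rad, which is what the default uses.

Rendered trials sample the vertex sequence on an even gait-percent grid
(landmarks at 10/30/48/62% by default, inserted into the grid exactly
so noiseless trials can be re-fit without discretisation error), with a
heel-strike prefix and a post-toe-off tail making b and e genuine local
minima. Measurement noise is i.i.d. Gaussian *on the moment channel
only* (`noise_sd`, default 8 N·m), scaled per phase by (0.4, 1, 1) for
dorsi/dual/plantar. The scaling is the minimal heteroskedastic model
that reproduces field-typical average per-phase linear-fit quality of
about 96% (dorsi), 73% (dual) and 93% (plantar): a single homoskedastic
level cannot hit all three because the phase moment ranges differ by a
factor of about two. The calibration is analytic — a linear ramp of
range $R$ sampled uniformly has variance $R^2/12$, so
$R^2_{phase} \approx (R^2/12)/(R^2/12 + \sigma^2_{phase})$.

**What the generator does not emulate.** Angle-channel noise, within-
phase curvature (real loops are only *nearly* linear), inter-trial
correlation within a session, foot-strike variability, and any
systematic lab-protocol differences. Passing tests therefore show that
the estimators are exact on the idealised loop and robust to calibrated
moment noise — not that they are unbiased on every feature of real
data.

## 3. Segmentation rules

Landmark detection uses a centred 5-sample moving average — for
*detection only*; all fits use raw samples.

* **b**: first local minimum (3-sample window) of the smoothed angle
  after 3% of the cycle and before c, refined to the raw minimum within
  the half-window. The refinement matters because a moving average
  skews a kink extremum sideways when the flanking slopes differ.
* **e**: minimum of the smoothed angle after c, refined likewise. The
  post-c restriction is deliberate: on swing-inclusive or noisy records
  a global angle minimum could fall elsewhere.
* **d**: nominally the moment maximum. Under calibrated noise a raw (or
  smoothed) argmax wanders along the shallow dual-phase limb, so d is
  located as the two-segment least-squares changepoint of the moment
  over c..e — the maximum-likelihood estimate of a slope-break under
  Gaussian noise. It coincides with the argmax on noiseless data. Even
  so, single-sample localisation of d is not statistically achievable
  at the default noise level; the tests assert the honestly measured
  bounds (b exact; d within ±1 sample in at least 70% of trials and
  within ±6 always, over 100 seeded trials).
* **c**: the sample nearest `c_pct` (default 30%, configurable). The
  alternative rule — snapping c to a vertical-GRF local minimum — is a
  documented extension point, not implemented, since trials carry no
  GRF channel.

Slices share endpoint samples (b..c, c..d, d..e) and must each hold at
least 3 samples.

## 4. Model fitting

**Bases.** Each response has a reconstructed monomial basis derived
from the simplified inverse-dynamics form of the transition moments:

* `K_df`: {1, WH/Γ_df, WHV/Γ_df, WH, WHV};
* `K_dl`, `K_pf`: {1, WH/Γ, WHV/Γ, WHV²/Γ, WH, WHV, WHV², V} with the
  phase's excursion (signed for dual);
* `E`: {WHΓ_x V^k : x ∈ {df, dl, pf}, k ∈ {0,1,2}}, nine terms, no
  intercept.

Bases are configuration objects (`basis_spec()`), not code constants,
so alternates can be tested.

**PLS cross-validation.** Collinearity among the basis terms is
screened by partial least squares with leave-one-subject-out folds
(`mixOmics::pls`, regression mode, centred and unit-scaled predictors;
zero-variance columns dropped). The component count maximising pooled
held-out predicted R² is selected; ties within 1e-8 resolve toward
fewer components, and the count is clamped to the numerical rank of the
scaled design. The maximum rule (rather than a one-standard-error rule)
is the deliberate choice; with it, predicted R² never exceeded training
R² in any tested run, and the tests assert that inequality with 1e-9
slack.

**Stepwise selection.** Backward elimination from the full basis:
iteratively drop the largest p-value at or above `alpha` (default
0.05), ties toward the later column, aliased columns first; the
intercept competes like any term. Metrics: training R², externally
studentized residual outliers (threshold 3.0), and mean percent error
excluding outliers. The default `alpha` follows common practice; the
coefficient-recovery tests use `alpha` = 0.001 because at their sample
size (n = 500, 1% multiplicative noise) true-term t-statistics are far
above any reasonable threshold, while at 0.05 the chance that backward
elimination retains at least one spurious term somewhere across the
four bases approaches one half — a test of selection correctness should
not be a coin flip on the null p-value draw.

**Stature reduction.** The Froude relation $V_{opt} =
\sqrt{Fr_{opt}\,g\,c_l H}$ (defaults $Fr_{opt}=0.25$, $c_l=0.53$,
configurable literature constants) and the cohort-mean excursions at
each subject's nearest-preferred trial (ties toward the slower trial)
are substituted symbolically into the retained terms: a monomial
$W^wH^hV^v\Gamma^\gamma$ collapses to $c\,W^wH^{h+v/2}$. The reduced
model's predictions equal the source model's at the substituted
operating point exactly (tested to 1e-9), and the dual-flexion
reduction is flagged low-confidence — the dual stiffness is dominated
by its small excursion, which stature does not predict.

**Work response.** Model fitting uses the raw-loop `E_loop` as the work
response; `E_fit` (the fitted-line vertex polygon, with adjacent phase
lines averaged at shared vertices) is also reported since either
definition is defensible — the two coincide exactly on noiseless loops.

## 5. Inverse-dynamics audit

`foot_moment_full()` implements the standard single-segment
Newton–Euler balance about the ankle,

$$M_A = I\alpha + \omega\times(I\omega) - r_{GA}\times F_G - M_G
        - r_{CA}\times(m g) + r_{CA}\times(m a_{com}),$$

in a lab frame with X anterior, Y up, Z mediolateral. This is a
reconstruction of the generic balance — adopted because it is the
unique standard form that collapses to the GRF-only expression
$-r_{GA}\times F_G$ when foot mass, inertia, angular terms and the
ground reaction moment vanish — and is documented as such rather than
asserted as identical to any particular printed variant.
`assumption_gap()` reports the collected size of the neglected terms
(`eps_z`) and its ratio to the full sagittal moment, flagging the
zero-moment case as degenerate instead of dividing by zero.

## 6. Problem sizes and tolerances

The test suite and acceptance script use: a 26 × 8 noiseless grid
cohort for exact-closure checks (recovery to 1e-6 relative; the
work-area identity to 1e-9 on 1000 random loops); n = 500 rows for
coefficient recovery; n = 200 with 20 subject-folds for PLS rank
selection; 1000 random states for the inverse-dynamics reduction; and
the default 216-trial cohort for calibration and the model-family
error ordering. These sizes keep any single check within seconds on one
CPU while leaving Monte-Carlo margins far from the asserted bounds.
Numeric tolerances not already mentioned: angle-variance tolerance
1e-12 rad² for declaring a locked (singular) phase fit, and 1e-4 rad
on the dual excursion for flagging a trial singular.

## 7. Known limitations

* The regression coefficients shipped by a pipeline run describe the
  *synthetic* cohort; they are not population estimates. Fitting to
  measured data requires only `read_trials()` + `run_pipeline()`, but
  the calibration claims in section 2 do not transfer.
* Single-joint analysis: no biarticular crosstalk, no swing-phase work
  (the ankle is nearly silent there, so stance work approximates the
  stride), level ground only.
* The dual-flexion stiffness is intrinsically hard to predict near the
  singular speed; percent errors on `K_dl` are large for every model
  family and the stature reduction for it should not be used for
  device sizing.
* `c` is snapped to a fixed gait-cycle percent; per-trial GRF-based
  placement is an extension point.
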