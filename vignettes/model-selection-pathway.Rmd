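---
title: "A model-selection pathway for blood-volume response models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A model-selection pathway for blood-volume response models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvselect)
```

## The problem

Physiological closed-loop controlled (PCLC) fluid-resuscitation devices
adjust infusion rates automatically from sensed patient state.  Before
such a device can be evaluated in simulation, the physiological model
standing in for the patient must itself be credible: it must calibrate
well to experimental data, must not overfit, and must predict responses
under conditions it was never calibrated to.  `bvselect` implements a
complete selection pathway between two candidate lumped-parameter models
of the blood-volume (BV) response to hemorrhage and fluid infusion,
exercised end-to-end on a synthetic cohort that emulates a sheep
hemorrhage/resuscitation experiment (a 25 ml/kg primary bleed, two 5
ml/kg re-bleeds, and 150 min of closed-loop crystalloid or colloid
infusion, with serial hematocrit-derived BV measurements).

## The two candidate models

Both models share one mechanism: a fluid perturbation (infusion rate $U$,
loss rate $V$, ml/min) is distributed between the intravascular and
interstitial compartments by an inter-compartmental shift $q$ that a
proportional-integral (PI) law drives so the BV change $\Delta BV$ tracks
a reference $r_{BV}$:

$$q(t) = -K_p\,e_{BV}(t) - K_i \int_0^t e_{BV}(\tau)\,d\tau,
  \qquad e_{BV} = r_{BV} - \Delta BV,$$
$$\dot{\Delta BV}(t) = U(t) - V(t) - q(t).$$

The models differ in the reference.  The **original model** uses the
static steady-state target

$$r_{BV}(t) = \frac{1}{1+\alpha_u}\int_0^t U\,d\tau
            - \frac{1}{1+\alpha_v}\int_0^t V\,d\tau,$$

where $\alpha_u, \alpha_v$ are the interstitial-to-intravascular
distribution ratios under gain and loss: at steady state the
intravascular compartment retains the fraction $1/(1+\alpha_u)$ of the
fluid given.  The **refined model** lets the reference evolve with
first-order dynamics per channel,

$$\dot r_{BV,u} = A_u r_{BV,u} + \frac{U}{1+\alpha_u}, \qquad
  \dot r_{BV,v} = A_v r_{BV,v} - \frac{V}{1+\alpha_v},$$

with state parameters $A_u, A_v \le 0$, so the target itself relaxes over
time (for $A<0$ the whole perturbation is eventually redistributed; $A=0$
recovers the original model exactly).  The original model has $P=4$ free
parameters, the refined $P=6$.

Parameter validity: $1+\alpha_u>0$, $1+\alpha_v>0$ (the retained
fractions must exist and be positive — note that Hextend-like colloids
produce *negative* $\alpha_u$, i.e. recruitment of interstitial fluid),
$K_p>0$, $K_i>0$ (Hurwitz condition on the tracking polynomial
$s^2+K_ps+K_i$), and $A_u,A_v\le 0$.  The sign constraint on $A$ is our
interpretation: it is required for stability of the reference dynamics,
and all group-level estimates reported for these models are negative.

## Numerical realization

We simulate the *structural* form above as a linear time-invariant system
with states $(\Delta BV, \int e_{BV}, r_{BV,u}, r_{BV,v}, \int q)$ rather
than the equivalent third/fourth-order input-output ODE, because the
latter contains $\ddot U$, $\ddot V$, which are impulsive for the
piecewise-constant protocols used here.  Inputs are held constant over
each grid step (left-continuous; the interpolation rule is a convention
we fix, since rates are recorded as step profiles), and each step is
propagated by the matrix exponential of the augmented (state + input)
system — exact for piecewise-constant inputs, so there is no solver
tolerance to tune.  The default grid step is `dt = 0.1` min.  All states
start at zero.

Two independent cross-checks guard this realization:

* `transfer_function()` collects the input-output form over a common
  denominator ($s^3+K_ps^2+K_is$ for the original model; the quartic
  $(s^2+K_ps+K_i)(s-A_u)(s-A_v)$ for the refined, whose integrator pole
  cancels channel-wise against a numerator root at the origin) and
  `simulate_tf()` integrates the controllable canonical realization with
  `Matrix::expm()` — a different realization, a different matrix
  exponential, a different code path.
* the test suite carries a third, plain-R matrix-exponential
  discretization written directly against the model equations.

The three routes agree within $10^{-6}$ ml on random models over the full
protocol.  An early lesson recorded here for maintainers: a companion-form
realization amplifies matrix-exponential error through its ill-scaled
phase states, so the oracle needs an exponential accurate to near machine
precision; `pracma::expm()` (absolute error around $5\times10^{-8}$) was
not good enough and is not used.

### Identifiability maps

`params_to_theta()` maps parameters to the coefficient vector $\Theta$ of
the frequency-domain regression form (7 entries for the original model,
11 for the refined; one entry of each is identically 1).  Uniqueness of
the inverse is what structural identifiability means here, and
`theta_to_params()` realizes the inverse constructively.  For the refined
model the first four entries are (negated) coefficients of the quartic
characteristic polynomial whose roots are $A_u$, $A_v$ and the PI pair;
rather than a multi-start numeric root solve we factor the quartic
exactly (`polyroot`) and enumerate the six pairings of roots, keeping the
assignment whose full 11-entry consistency residual is smallest.  This is
deterministic, exact at machine precision, and handles the $A_u=A_v$ and
$A=0$ boundary cases without special-casing.  Inconsistent coefficient
vectors are rejected with the offending entries named.

## Measurement model

Experimental BV changes are reconstructed from serial hematocrit $H$ and
withdrawal volumes $V_H$ via red-cell bookkeeping:
$RBC(t_k) = BV(0)H(0) - \sum_{i\le k} V_H(t_i)H(t_i)$,
$PV(t_k) = (1-H(t_k))\,RBC(t_k)/H(t_k)$,
$\Delta BV(t_k) = RBC(t_k)+PV(t_k)-BV(0)$.  We implement the recursion
exactly as stated (it is itself a first-order approximation — continuous
red-cell loss within a bleed is collapsed onto the reading at the
withdrawal's timestamp; whether $H$ is read pre- or post-withdrawal is
not specified, and we adopt the same-timestamp convention).  The
generator's inverse `hct_from_bv()` emits hematocrit series that
round-trip through `bv_from_hct()` to machine precision, which is how the
conversion path is tested.

## The synthetic cohort

No experimental data ship with the package, so every downstream stage is
exercised on virtual subjects (`generate_cohort()`).  The defaults *are*
the emulated study conditions and are not tuned per analysis:

* 11 LR (Lactated Ringer's) + 5 HEX (Hextend) subjects;
* protocol: 25 ml/kg hemorrhage over 0–15 min, 5 ml/kg over 50–55 and
  70–75 min, infusion window 30–180 min;
* generating parameters drawn per fluid group from normal priors with the
  group-level means and standard deviations reported for the calibrated
  models (e.g. original-LR $\alpha_u \sim N(1.72, 0.66^2)$, refined-HEX
  $A_u \sim N(-0.004, 0.006^2)$), rejection-truncated to the parameter
  invariants;
* iid Gaussian measurement noise, matching the likelihood assumption, so
  calibration on synthetic subjects is a well-specified recovery
  experiment.

Choices the source experiment does not pin down, made once and recorded
here:

* **Infusion controller.** The experiment's closed-loop controller is not
  specified.  The default synthetic controller is a discrete proportional
  law updated every 5 min inside the infusion window,
  $u = \mathrm{clamp}(-K_c\,\Delta BV,\ 0,\ u_{max})$ with $K_c=0.05$
  /min and $u_{max}=100$ ml/min, closed over the subject's own true
  model.  It produces the decaying resuscitation profile such experiments
  show, is fully deterministic given the subject, and is configurable; a
  fixed piecewise-constant profile is also accepted.
* **Noise scale.** `noise_sd = 50` ml, chosen so synthetic per-subject
  RMSEs have the same order of magnitude as the reported fits (tens of
  ml).  This is a free knob of the generator, not an estimated quantity.
* **Anthropometrics.** Weights uniform on 30–45 kg; baseline blood volume
  60 ml/kg; baseline hematocrit 0.30.  All configurable.
* **Measurement schedule.** Every 5 min, 0–180 min (37 points).  The
  experiment sampled "every 5 or 10 min"; we use the denser end because
  the predictive-capability scenarios require at least four calibration
  points per parameter of the six-parameter model once the transient
  window is held out, which a mixed 5/10-min schedule cannot provide.

What the generator does *not* emulate: urinary output or other unmodelled
losses, endothelial/osmotic dynamics, measurement error correlated over
time, or inter-subject correlation of parameters.  Passing tests on this
cohort therefore demonstrate internal consistency of the pathway — not
that either model is adequate for real sheep, which only real data can
show.

## Calibration

Fitting is penalized maximum likelihood (`fit_mle()`).  With iid Gaussian
residuals the negative log-likelihood is
$(K/2)\ln 2\pi + (K/2)\ln\sigma^2 + RSS/2\sigma^2$; $\sigma$ is profiled
analytically ($\hat\sigma^2 = RSS/K$) at every evaluation, and the
penalized objective

$$-L^*(\theta, \hat\sigma(\theta)) + 2\gamma\,\lVert\theta\rVert_2$$

is minimized over the model parameters within box bounds.  Notes:

* the penalty is the $L_2$ *norm*, as the formula states, not its square
  (`penalty = "squared"` switches, since the prose "penalizes the L2
  norm" admits both readings);
* $\sigma$ is not penalized;
* parameters are penalized on their raw scale — the formulation gives no
  standardization.  This makes the penalty's bite depend on units (it
  mostly bites $\alpha$'s, whose magnitudes dominate); a documented
  limitation, kept for comparability with the reported parameter scales;
* bounds are the per-parameter envelope mean ± 4 sd of the group-level
  calibrated statistics, pooled over the fluid groups, intersected with
  the invariants.  The box also guarantees every evaluated point is a
  valid model, letting the hot loop skip validation;
* optimization runs in box-scaled coordinates ($[0,1]^P$) from 10
  Latin-hypercube starts, using bounded quasi-Newton (L-BFGS-B) with
  finite-difference steps of $10^{-7}$ of each parameter's range.  The
  scaling matters: un-scaled finite differences of $10^{-3}$ are larger
  than $K_i$'s plausible range and destroy convergence.  On noise-free
  subjects the generating parameters are recovered to better than 1%;
* the RSS is floored at $10^{-12}$ so interpolating fits keep a finite
  objective;
* a zero-input, zero-response subject is rejected as uninformative.

**Penalty selection** (`select_penalty()`) mirrors the inner-level
validation: for each $\gamma \in \{1,3,5\}$ fit on the first 120 min,
reproduce the remaining 60 min, and keep the $\gamma$ with the smallest
held-out AIC (held-out residual count, $\sigma$ profiled on the held-out
residuals — the formulation does not say which segment the AIC uses, so
this is configurable via `aic_on`).  Ties break to the smallest penalty.
Selection is per subject and per model variant.

## Assessing calibration

`rmse()`, `aic()` ($-2L^*+2P$; at equal likelihood the refined model pays
exactly 4), and the multi-dimensional measure: four residual features —
bias, residual SD, trend over time, trend over the measured BV range.
The source defines the features only by name; we fix them as the
*absolute* mean residual, the sample SD, and absolute OLS slopes, so that
all features are non-negative and the origin is the ideal point, which
the distance-from-origin reading requires.  "Standard error of residuals"
is taken as the residual SD (not SD$/\sqrt K$); a switch is trivial to
add, and the choice only rescales one axis before normalization.
Features are normalized by their maximum over the *joint* pool of all
subjects and both models — normalizing per model would map each model's
worst subject to 1 and make distances incomparable.  The summary per fit
is the Euclidean distance $U_d \in [0,2]$ of the normalized feature
vector from the origin.

Group comparisons use the field-standard tests: paired t between models
on per-subject metrics, Welch two-sample t between fluid groups on
parameters, and a chi-squared test (no continuity correction) on
within-envelope counts.  No multiple-testing correction is applied,
matching the reporting convention being emulated.

## Practical identifiability (Sobol indices)

`sobol_first_order()` estimates first-order indices
$G_i = V_i/\mathrm{Var}(BV)$ at report times 30, 80, 120, 180 min, with
parameters sampled uniformly and independently over their ranges
(defaults: the min–max of the fitted values across the cohort).  The
estimator is Saltelli pick-and-freeze, $N(P+2)$ model runs at base
$N=1000$, with outputs centered on the pooled mean so indices are exactly
invariant to affine rescaling of the output; small negative estimates
(Monte Carlo noise) are clipped to zero for classification, with raw
values retained.  Thresholds: $G<0.01$ insensitive, $G>0.1$ highly
sensitive; a parameter insensitive at *all* report times is flagged
insignificant.  The claim that first-order effects "add up to 1" holds
only for additive models; these models are not additive, so the package
asserts $\sum_i G_i \le 1$ within Monte Carlo error instead.  The
qualitative pattern reproduces on synthetic cohorts: before infusion
begins (30 min), $\alpha_u$ (and $A_u$) have no pathway to the output and
classify insensitive, while $\alpha_v$ is highly sensitive; once infusion
starts, $\alpha_u$ becomes highly sensitive.

## Predictive capability

Three scenarios, each summarized by a percentile envelope, the interval
score, and the proportion of measurements within the envelope (PM):

* **A — steady-state extrapolation**: 100 fits to random 75% sub-samples
  (without replacement) of the measurements at $t \le 150$ min predict
  the window after 150 min.
* **B — transient interpolation**: the window [45, 80] min (boundaries
  inclusive), containing the second and third bleeds, is held out; fits
  use 75% sub-samples of the rest.
* **C — leave-one-out**: 1000 parameter draws from per-parameter normals
  fitted to the other subjects' estimates, rejection-truncated to the
  donors' min–max range, drawn independently per parameter; the
  infusion-side parameter ($\alpha_u$ original, $A_u$ refined) uses only
  donors of the held-out subject's fluid type, since its dispersion
  differs strongly between fluids.  Zero donor variance degenerates to a
  point mass with a warning.

Conventions fixed here: envelopes are the 2.5th/97.5th percentiles with
the standard linear-interpolation (type-7) quantile rule; boundary
equality counts as inside both for PM and for the width-only branch of
the interval score
$S = (u-l) + \tfrac{2}{\alpha}\max(l-y,0) + \tfrac{2}{\alpha}\max(y-u,0)$
at $\alpha = 0.05$; the baseline point $t=0$ is always retained in every
sub-sample (without it, fits lose their anchor — an addition to the
stated procedure); $\gamma$ is selected once per subject and variant and
reused across replicates; and replicate fits are warm-started from the
full-calibration-set optimum plus one fresh Latin-hypercube start, since
a 75% sub-sample perturbs the objective only mildly and the full
ten-start policy multiplies study cost about five-fold without changing
the envelopes.  Sub-sampling is the default resampling mode;
`replace = TRUE` gives the classical bootstrap.

Score comparisons between models pool per-point scores over all subjects
(paired t), and PM comparisons pool hit counts (chi-squared), so the
effective $n$ is the number of prediction points, not subjects.

## The full study

`run_study()` chains everything — generate, calibrate both variants with
per-subject penalty selection, assess, sensitivity, three scenarios,
group tests — under a single master seed from which every stage derives
child seeds deterministically; re-running a configuration reproduces
every number bit-identically.  Problem sizes of the default study: 16
subjects, 100 sub-sample replicates per scenario, 1000 leave-one-out
draws, Sobol base sample 1000 — a few minutes on one core, with the
compiled zero-order-hold kernel doing the per-fit work.

On cohorts *generated by the refined model*, the study ranks the refined
fit at or above the original on transient-window coverage and at or below
it on transient interval score — the directional self-consistency one
should demand of the pathway.  This is a property of the synthetic
experiment, not a re-derivation of any published table: the original
animal data are not available, and nothing here should be read as
reproducing their numeric values.

## Known limitations

* Linear, time-invariant model class only; no urinary output state, no
  pressure-dependent shifts.
* The raw-scale $L_2$ penalty is unit-dependent (see above).
* Local multi-start optimization carries no global guarantee; the
  identifiability maps and recovery tests are the practical mitigation.
* The leave-one-out donor model ignores parameter correlations (drawn
  independently), consistent with the weak pairwise correlations the
  emulated analysis reports.
* Synthetic-cohort realism ends at the model class; conclusions about
  real physiology require real data.
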