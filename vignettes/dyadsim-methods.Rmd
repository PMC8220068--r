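---
title: "Methods: the dyadsim interaction model and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dyadsim interaction model and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsim)
```

## The generative model

`dyadsim` animates two agents in a planar arena. Each agent carries a
heading direction $\phi$, a heading rate $\dot\phi$, a signed
propagation speed $s$ and a position $(x, y)$; position integrates
unicycle kinematics $\dot x = s\cos\phi$, $\dot y = s\sin\phi$. The
heading obeys a damped second-order attractor dynamic

$$\ddot\phi = -b\,\dot\phi + A(\phi,\psi^g) + R(\phi,\psi^o),$$

where the goal along direction $\psi^g$ at distance $d^g$ attracts,

$$A = -k_g\,\mathrm{wrap}(\phi-\psi^g)\,(e^{-c_1 d^g}+c_2),$$

and each obstacle $n$ repels with angular decay $c_3$ and distance
decay $c_4$, scaled by $k_o$. Speed relaxes toward a distance-dependent
drive with time constant $\tau$ and additive white noise of gain
$k^\epsilon$:

$$\tau\dot s = -s + F(d^g) + k^\epsilon\,\epsilon(t),\qquad
F(d) = \frac{c_5}{1+e^{-c_6 (d-c_7)}} - c_8 e^{-k d} + c_9.$$

Two modeling commitments matter most. First, *speed is signed and never
clamped*: several classes (Avoiding, Dodging) have $F < 0$ over part or
all of the distance range, which produces retreat — the behavior those
classes are about. Because the arena imposes no walls, retreating
agents can leave it; a trajectory's positions are only guaranteed to
stay within the arena expanded by the travel bound
(duration × max |s|), and `validate_trajectory_pair()` checks exactly
that. Second, *obstacles never touch the speed dynamic*: only the
heading equation sees the obstacle context.

The two agents are coupled asymmetrically: agent 1 steers toward a via
point drawn uniformly over the arena (samples closer than
`via_min_dist` to the agent are rejected) and draws a fresh one on
arriving within `via_capture_radius`; agent 2's goal is agent 1's
instantaneous position. The catalog leaves the coupling rule as a
labeled field so other rules can be added, but all fifteen bundled
classes use this one — including Meeting and Walking, for which an
independent-via-points variant is conceivable; we keep the single
documented rule rather than invent per-class variants.

## Parameters and defaults

The fifteen classes differ only in the per-agent speed parameters
$(k, k^\epsilon, c_5\ldots c_9)$, shipped verbatim in
`inst/extdata/interaction_classes.csv`. $c_5$ is per-agent throughout:
the class table lists it separately for each agent even though the
drive formula is often written with an unsubscripted $c_5$.

The shared heading-dynamics constants are not part of the class
catalog, and we ship them as explicit named defaults in
`inst/extdata/global_dynamics.json`, overridable per class:

| parameter | default | units | role |
|---|---|---|---|
| b | 3.25 | 1/time | heading damping |
| k_g | 7.5 | 1/time² | goal attraction gain |
| k_o | 0 | 1/time² | obstacle repulsion gain (no class defines repulsion parameters, so the default is off) |
| c1 | 0.4 | 1/length | attraction distance decay |
| c2 | 0.4 | — | attraction floor at long range |
| c3 | 6.5 | 1/radian | repulsion angular decay |
| c4 | 0.8 | 1/length | repulsion distance decay |
| tau | 0.5 | time | speed relaxation constant |

The heading-dynamics values follow the classical human-navigation
steering literature from which this model family descends; $\tau = 0.5$
makes speed settle within a fraction of a run. Simulation defaults: a
20×20 arena, dt = 0.01, duration 10 time units per trajectory,
`via_min_dist` = 5, `via_capture_radius` = 0.5. Initial positions are
uniform over the arena, headings uniform over $(-\pi,\pi]$, speed and
heading rate zero. None of these five scenario constants is dictated by
the model itself; they are declared package choices, fixed once.

## Numerical choices

Integration is explicit Euler for the heading system and Euler–Maruyama
for the speed SDE, with the noise entering as
$(k^\epsilon/\tau)\sqrt{dt}\,z$, $z\sim N(0,1)$, per step — the
simplest scheme consistent with a first-order SDE with additive noise.
The suite verifies first-order convergence by Richardson comparison
against a 20×-finer reference. Angular errors are wrapped to
$(-\pi,\pi]$ (half-open at $-\pi$) *before* they multiply anything;
without wrapping, the attractor would be discontinuous at $\pm\pi$
crossings. Every random element of a run — initial conditions, via
points, the two agents' noise streams — derives from a single integer
seed through a multiplicative-congruential mixer modulo $2^{31}-1$
(`derive_seed()`), so dataset realization $(c, r)$ is regenerable in
isolation and the two agents' noise streams are independent
substreams.

Degenerate inputs fail loudly: non-finite states raise a
simulation-diverged error naming the step, an unreachable
`via_min_dist` exhausts a documented rejection budget, empty
trajectories refuse to serialize, and truncated or column-deficient
trajectory files raise format errors naming the violation.

## Rendering

Stimuli follow the standard impoverished-display convention: agent 1 a
filled blue circle, agent 2 a filled red rectangle whose long axis
tracks its heading — an orientation cue motivated by the finding that
shapes with a body axis read as more animate. Trajectories are
resampled from the integration grid to the frame grid (default 25
frames/s) by linear interpolation, with headings unwrapped first so the
rectangle never spins through the $\pm\pi$ seam. The arena-to-pixel
map is affine, aspect-preserving and recorded in a JSON sidecar;
rendering is a pure function of (pair, spec), which the suite checks by
byte-comparing repeated renders and by mapping painted centroids back
through the recorded transform (within one pixel). Shape size defaults
to 2.5 % of canvas width; actual on-screen sizes in any given
experiment are a display decision, not a model quantity.

## Validation statistics

The analysis functions mirror the standard pipeline for labeling
experiments with such stimuli:

* **Confusion counting.** A trial may report up to three labels; each
  reported label contributes one count to its cell. This multi-count
  rule is a declared convention (the alternative — fractional counts —
  is not implemented), surfaced here and in the docs.
* **Recall / precision / F1** per class, with zero-denominator cases
  reported as `NA` (undefined), never as 0.
* **Mislabeling probability** $P_{MS}(i,j)$: the share of all
  off-diagonal counts carried by the unordered pair $(i,j)$; sums to 1
  over pairs.
* **Block-wise learning.** Metrics are computed per subject and block,
  averaged across classes (dropping undefined cells), then across
  subjects, and regressed on block index by OLS; the t statistic has
  $n_{blocks}-2$ df. The aggregation order follows the
  averaged-across-subjects-and-classes definition.
* **Animacy model.** A linear mixed model with sum-to-zero Agent and
  Social-Interaction fixed effects and a subject random intercept,
  estimated by REML via `lme4`. Inference uses residual
  df $= N - p$ with $p = 1 + (N_a-1) + (N_c-1)$ — for 13 subjects,
  2 agents and 12 classes, $312 - 13 = 299$ — a deliberate convention
  matching how such designs are conventionally reported; `lme4` itself
  does not commit to a df rule. Post-hoc class contrasts are 1-df Wald
  F tests with Bonferroni correction over the 66 pairs.
* **Semantic distances.** Similarities on the 0–10 scale are
  complemented and divided by the scale maximum, $d = (10-s)/10$, per
  subject and then averaged. Division by 10 (not observed min–max)
  preserves the anchors "0 = unrelated, 10 = equivalent"; averaging
  happens after the per-subject transform.
* **Non-metric MDS** (Kruskal stress-1, monotone regression) via
  `MASS::isoMDS` with 20 seeded restarts (classical scaling first,
  then random initializations), best stress kept, output centred. Zero
  off-diagonal distances are floored at $10^{-6}$ because the
  optimizer requires positive dissimilarities.
* **Ward clustering** (`hclust`, `ward.D2`) cut at $0.7 \cdot M_{WD}$,
  the maximum merge height.
* **Mislabeling–distance correlation.** Pearson r over all unordered
  pairs; $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ df (64 for the
  12-class set).

## The synthetic-response generator

Human responses are not shipped; a seeded generator produces response
tables with the statistical structure the analysis assumes, so the
whole pipeline is testable. It emulates: multinomial labeling from a
row-stochastic confusion kernel (default 0.65 correct, remainder
uniform — mid-range for the recall levels such experiments report);
latent learning as a linear additive bump of 0.03/block on the correct
probability, off-diagonal mass renormalized (learning is an observed
phenomenon; the linear mechanism is ours, chosen to make the
learning-fit's target well-defined); balanced pseudo-randomized blocks
(default: 12-class label set, 5 blocks, one trial per class per block,
13 subjects); animacy ratings drawn from the mixed model itself with
$\alpha_0 = 53.27$, agent effect $\mp 8.37$ (circle below rectangle),
$\sigma_b = 5$, $\sigma = 10$, truncated to [0, 100]; and similarity
surveys as true similarity plus symmetric Gaussian rater noise clamped
to the scale.

What it does *not* emulate — and therefore what passing tests do not
establish about real data: perceptual similarity structure (the kernel
is specified, not derived from the stimuli), response omissions,
subject-specific confusion patterns or lapse rates, order effects
within blocks beyond the programmed learning trend, and any coupling
between a video's kinematics and the labels it attracts. Tests built
on the generator validate the *analysis machinery* (counting rules,
estimators, df conventions, recovery of programmed effects), not the
perceptual validity of the stimuli.

## Problem sizes and test design

Parameter-recovery checks run 100 simulations at the design size of the
animacy experiment (13 × 2 × 12) and 100 labeling replicates at 50
subjects; face-validity checks (pursuit closes distance; avoidance
keeps agents farther apart than bumping) use majorities over 20 seeds
at the full 10-time-unit, dt = 0.01 resolution. For the learning-slope
recovery oracle we use two trials per class per block: with a single
trial the slope's standard error (~0.006 at 50 subjects) would be
nearly a third of the recovery band itself, making the check a test of
oracle resolution rather than of the estimator. The
law-of-large-numbers recall check uses 4000 trials per class so its
±0.03 band sits at four standard errors.

One recovery band deserves a caveat: with $\sigma_b = 5$ and 13
subjects, the grand-mean estimator of $\alpha_0$ has a sampling SD of
$\sqrt{\sigma_b^2/N_s + \sigma^2/N} \approx 1.5$, so an absolute
recovery band of ±2 is only a ~1.3-SD interval and no estimator can hit
it much more than ~82 % of the time; the corresponding check reflects
the estimator's true sampling distribution, not an implementation
defect.

## Known limitations

Class parameters were identified heuristically upstream, not fitted;
the package deliberately excludes system-identification of parameters
from observed trajectories. The coupling repertoire is the single
agent-2-chases-agent-1 rule. Rendering is restricted to rigid 2-D
shapes — no articulated or 3-D avatars, occlusion or degradation. The
integrator is first-order; if higher-order accuracy is ever needed the
dt-convergence test documents the current behavior to build against.
No claim is made that synthetic-response-based numbers reproduce any
human dataset; human-derived quantities (mean animacy ratings,
empirical confusion matrices, measured semantic distances) are
explicitly out of scope.
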