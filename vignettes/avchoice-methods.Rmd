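---
title: "Models and methods in avchoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in avchoice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avchoice)
```

`avchoice` analyses two-alternative forced-choice audiovisual localization
behavior and the neural activity recorded alongside it. This vignette
explains the models the package implements, the assumptions behind them,
the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the numerical choices made where the
design was genuinely open.

## The additive psychometric model

On each trial the subject sees a grating of contrast $V \in [0,1]$ on the
left or right and hears a sound from a left, central, or right speaker,
and reports a side by turning a wheel. If visual and auditory evidence are
conditionally independent given the stimulus side, the posterior log odds
of "right" decompose as a sum of a visual-only function, an auditory-only
function, and a constant prior term. The package's central model commits
to a parametric form of that sum:

$$\log \frac{p(R)}{p(L)} = b + v_R V_R^{\gamma} - v_L V_L^{\gamma}
  + a_R A_R - a_L A_L,$$

with a power law in contrast to capture visual saturation ($\gamma$,
bounded to $(0.01, 3]$) and indicator variables $A_R, A_L$ for the
auditory side. Choices are Bernoulli with $p(R) = \sigma(\cdot)$.

`psych_model()` exposes the rest of the family: a bias-only reference;
unisensory (visual-only, auditory-only) reductions; an
*auditory-dominance* model that zeroes the visual term on conflict trials
(optionally with a free conflict-trial auditory deflator); a *sensory
bias* model with multiplicative deflators on coherent and conflict trials
(the additive model is its special case at zero); an *unconstrained
additive* model with one free weight per signed contrast level (any
function of contrast); a *full* model with one weight per visual-by-
auditory condition cell (27 for the standard 4-contrast, 3-azimuth
design), which drops the additivity constraint altogether; a 5-azimuth
variant; and the *ipsi/contra* reparameterization used for inactivation
data, where sides are defined relative to the inactivated hemisphere.

**Fitting.** The Bernoulli likelihood depends on the data only through the
per-condition counts of left and right choices, so trials are aggregated
to condition cells before optimization; fits then cost the same at
200 or 200,000 trials. The optimizer is bounded L-BFGS-B with 10 restarts
(one deterministic at zero sensitivities, $\gamma = 0.6$), with analytic
gradients for the plain additive and ipsi/contra families; an independent
coarse grid search over $(b, a_R)$ serves as an oracle in the tests. The
full model is fit in closed form — its likelihood separates by cell, so
each weight is the empirical log odds clamped to the bounds; cells never
seen in training predict the bias-only value.

**Model comparison.** `cv_bits_per_trial()` scores a family by 5-fold
cross-validation against a bias-only model refit on every training fold,
reporting the held-out log₂-likelihood gain per trial. Folds are
stratified by condition; a training fold that loses a choice class
triggers a refold under a fresh draw. Bits per trial is zero for the
bias-only model against itself by construction, and converges to the
generative information gain on data simulated from the fitted family (a
property the tests check by enumeration).

**Multi-subject fits.** `combine_subjects()` equalizes each subject's
contribution by subsampling to the smallest subject count before fitting,
repeating 10 times and reporting mean parameters and mean per-condition
choice fractions.

## Behavior extraction

`detect_choice()` reports the side of the first crossing of ±30° of wheel
rotation (threshold and response window are arguments; thresholds vary
across rigs and sessions) within the 1.5 s response window.
`detect_reaction_time()` finds the last time before that crossing at which
the wheel velocity crossed zero after at least 50 ms at zero or moving
opposite to the choice, followed by at least 50 ms above 20% of the
threshold per second; trials with no such time, or with movement within
10 ms of stimulus onset, are flagged rather than assigned an RT. Velocity
is computed by first differences at the native sampling interval with no
smoothing; an epsilon argument (`vel_eps`) controls how strictly "at
zero" is interpreted, since small sensor noise would otherwise never be
exactly zero. Ties at the zero crossing resolve to the later sample — the
rule asks for the *last* such time.

`filter_trials()` flags (never deletes) timeouts, repeats following
incorrect choices, trials outside the first/last run of three consecutive
non-timeout choices in a session, and choices whose RT could not be
extracted. `summarize_behavior()` aggregates session-first: the statistic
is computed within session, averaged over sessions, then over mirrored
presentations; relative reaction times subtract each subject's mean over
stimulus types.

## Inactivation statistics

All inactivation inference is permutation-based. For the per-site choice
shift, trials are first mirrored so stimuli are effectively leftward (the
visual stimulus, on conflict trials), which folds the two hemispheres
together; the observed statistic is the mean over subsample iterations
(each equalizing per-subject laser and control counts) of the difference
in rightward-choice fraction, and the null reassigns laser/control labels
within subject. Rank p values use $(r+1)/(n+1)$, so they are never zero
and are uniform under the null; the tests verify the 5% rejection rate on
null worlds within a binomial confidence interval. Defaults follow the
full design (25,000 subsamples × 10 shuffles); the test suite and the
pipeline's `ci` profile scale these down (25–100 subsamples, hundreds of
null points), which widens the attainable p floor but leaves the
statistic unbiased.

For parameter changes, the additive model is reparameterized
ipsi/contra relative to the inactivated hemisphere; the contrast exponent
is frozen at the control-trial value, and control trials are symmetrized
(each trial plus its mirror image) so the same model applies to data with
no inactivated side. The shuffle null permutes laser/control labels and
refits. The inter-region divergence test compares within-region to
inter-region held-out log likelihood under region-label shuffles; when
several region pairs are tested, Bonferroni-correct the returned p
values. The pulsed-inactivation analysis slides a 70 ms boxcar over laser
onset times and tests each window's laser-vs-control choice split with a
Fisher exact test (implemented by direct hypergeometric enumeration, with
a brute-force oracle in the tests); a window is flagged when it, or both
neighbors, pass the criterion, and sessions with fewer than 75 laser
trials are excluded.

One genuinely open design choice is whether the null reassigns site
labels within or across subjects; the package shuffles within subject,
which protects the test against subject-level imbalances.

## Neural encoding

Firing rates are estimated in 2 ms bins and smoothed with a causal
half-Gaussian of SD 60 ms, normalized to unit mass — causal so that no
rate precedes its spike, unit-mass so spike counts are conserved. The
kernel model decomposes the single-trial rate into six temporal kernels —
grand mean $B(t)$, auditory and visual side effects $a_i A(t)$,
$v_i V(t)$, their interaction $a_i v_i N(t)$ on $-50..400$ ms, and
movement and direction kernels $M, c_i D$ on $-200..700$ ms around
movement onset — and fits them jointly by ridge regression with a single
shared penalty ($\alpha = 10$, applied on the raw Hz scale) on a random
half of trials, with the cross-validated mean-squared error E computed
over 0–400 ms on the held-out half. The additive variant sets $N = 0$; an
8-movement-kernel variant gives each audiovisual condition its own
movement pair; the passive variant drops movement kernels and the penalty
($\alpha = 0$ falls back to a minimum-norm solution if the design is rank
deficient). The design matrix is shared across neurons, so one solve fits
an entire population.

Numerically, the package fits kernels on a configurable lattice; the
examples and tests use 10 ms bins, which keeps the design at a few
hundred columns while leaving the estimator unchanged — at 2 ms the same
code runs but the design grows 25-fold. Movement onsets are snapped to
the lattice. An exact-recovery oracle (noise-free rates from known
kernels, $\alpha \to 0$, movement-free window) pins the implementation to
machine precision, and a design-matrix oracle checks that `X θ` equals
the direct kernel sum pointwise.

## Population and single-neuron statistics

Decoding uses a linear SVM on window-averaged rates with accuracy
reported relative to a spikes-blind baseline that predicts the training
majority class: $(\text{raw} - \text{base})/(1 - \text{base})$. Five
30-neuron subsamples are averaged, and sessions need 25 trials per class;
visual decoding uses high-contrast trials only. Any linear max-margin
classifier passing the chance/separable/rescaling fixtures would do; the
package uses `e1071::svm`, whose internal standardization makes relative
accuracy invariant to per-neuron rate rescaling.

ccCP/ccSP is the fraction of within-condition trial pairs with different
outcomes in which the positive-outcome trial fires more (ties half),
computed via rank sums and checked against brute-force pair enumeration;
with one condition it reduces to the normalized Mann-Whitney U. The
shuffle null permutes outcomes within condition, with significance at the
0.5th/99.5th percentiles. d′ divides the mean difference by the mean of
the SDs. Discrimination time slides a 50 ms window in 5 ms steps,
requires three consecutive Mann-Whitney p < 0.01 windows, reports the
*start* of the first window (window start and window center are both
defensible conventions; start is conservative — at high SNR a window
partially overlapping a response onset can already be significant, so
reported times can lead the true onset by up to one window), and discards
times beyond 300 ms. The Mann-Whitney implementation is exact for small
untied samples and uses a tie-corrected normal approximation otherwise.
For ccSP there is no single convention for balancing choices within
condition cells; the package forms pairs within cells that include
the controlled stimulus and choice, which requires both outcome classes
per cell and drops cells without them.

## The accumulator

Surrogate trials are independent Poisson counts per 10 ms bin with
intensities from the condition PSTH bank on $-100..300$ ms (the bin width
is not dictated by the science; a constant-drift analytic test —
crossing bin $\lceil \theta/\mu \rceil$ — guards correctness across bin
choices). The decision variable integrates from the start of the trace,
including pre-stimulus bins: the training loss penalizes $d(t)^2$ before
stimulus onset, which only makes sense if those bins accumulate. Targets
are the stimulus side, random on conflict trials. Training minimizes the
summed pre-stimulus MSE and post-stimulus hinge loss with Adam
(learning rate 0.01, decay 0.9/0.999, 300 epochs, 70/30 split,
boundaries at ±1); the gradient of the piecewise loss is computed
analytically and verified against finite differences. The
hemisphere-constrained variant projects weights to the feasible signs
(left ≥ 0, right ≤ 0) after every step. Boundaries are then fit by grid
search to per-condition choice probabilities; trials that never cross are
labeled `none`, excluded from the probability MSE, and reported as a
fraction. `evaluate_vs_behavior()` fits the additive model to the
accumulator's choices and compares its log odds to a reference fit, with
a null from refitting after shuffling the trials' condition labels.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure the analyses assume:
the 10/10/5/5/1 trial-type mix with uniform contrasts and random sides;
Bernoulli choices from any model in the family; wheel traces that hold
still, then ramp through threshold (with optional sub-threshold wiggles
exercising the last-zero-crossing rule); spike trains from the kernel
forward model with rectification, Poisson variability on a 1 ms lattice,
and auditory kernels leading visual by a configurable latency
(defaults 30 ms vs 75 ms); a trained regime with lateralized kernels and
a naive regime without them; and scanning inactivation over an 8×8
AP × ML site grid at 75% laser probability, with region effects injected
as additive ipsi/contra parameter shifts. The default grid is the full
64-site product: the experimental grids drop some AP×ML combinations that
the printed coordinate sets do not determine, so the site list is
user-supplied and the shipped default is labelled synthetic. The
reaction-time model (base latency minus auditory advantage of 22 ms minus
a contrast-dependent speedup, Gaussian jitter truncated positive) is
generative plumbing chosen to reproduce the qualitative RT ordering
(coherent < auditory < visual), not a mechanistic claim.

What passing tests on these data do *not* show: real wheels have
biomechanics and sensor noise; real spike trains are non-Poisson and
correlated across neurons; real sessions drift. Tests against the
generators validate the estimators' correctness and calibration, not
their robustness to those features.

## Problem sizes and other fixed choices

Examples and tests run at deliberately modest sizes — 2,000–20,000
behavioral trials, 150–360 trials and 16–200 neurons for neural analyses,
360 surrogate trials per condition and 100 shuffle refits for the
accumulator, and shuffle-test replication reduced to tens of subsamples
and hundreds of null points. The pipeline's `full` profile
restores the full replication counts. Contrast is stored as a fraction in
[0, 1] (not percent), which keeps the $\gamma$ power numerically stable;
rightward is positive everywhere (azimuth, choice, log odds).

## Known limitations

Mixed-effects inference across mice/sessions on decoding accuracies,
kernel errors, or reaction times is out of scope; the package emits the
per-session and per-neuron tables such models consume. The full
psychometric model's unobserved cells fall back to the bias-only value
rather than borrowing strength across cells. Ridge strength is shared
across kernels and applied on the raw rate scale; normalizing rates
before fitting changes the effective penalty. The accumulator is strictly
linear and non-leaky; recurrent or leaky variants are not implemented.
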