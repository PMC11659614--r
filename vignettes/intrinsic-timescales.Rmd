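---
title: "Estimating intrinsic neural timescales and modeling their rest-task flexibility"
author: "intflex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intrinsic neural timescales and modeling their rest-task flexibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intflex)
```

This vignette explains what `intflex` computes, the assumptions behind
each stage, the parameters that matter and why their defaults are what
they are, and where the package makes choices that the underlying
methods leave open. It also states what the synthetic-data generators
do and do not emulate, so that passing tests are interpreted correctly.

## The measurement: windowed intrinsic neural timescales

The intrinsic neural timescale (INT) of a signal is operationalized
through its autocorrelation function (ACF). For a window
$x_1,\dots,x_N$ the package computes the biased-normalization ACF

$$r_l \;=\; \frac{\sum_{t=1}^{N-l}(x_t-\bar x)(x_{t+l}-\bar x)}
                 {\sum_{t=1}^{N}(x_t-\bar x)^2},$$

whose value at lag zero is exactly 1. Two interchangeable
implementations exist — a Wiener–Khinchin FFT route (default) and a
direct double summation — and the test suite asserts their agreement to
$10^{-10}$; the direct form serves as an independent oracle for the
fast one. The window mean is removed (it appears in the estimator
itself); no further detrending is applied.

Two summary measures are derived per window and channel:

* **τ** — least-squares fit of $e^{-l/\tau}$ to the ACF. τ is the lag
  at which the fitted curve reaches $1/e$, reported in seconds.
* **ACW-0** — the first lag at which the ACF reaches zero, linearly
  interpolated between the bracketing integer lags. Windows whose ACF
  never crosses zero within the computed range return `NA` and are
  excluded downstream.

Estimation is windowed: one estimate per channel per non-overlapping
10-s window (`windowedINT()`), with incomplete trailing windows
dropped, or one estimate per behavioral segment when a segment table is
supplied.

### Numerical choices in the τ fit

The exponential model has a single parameter, so the fit is a bounded
one-dimensional least-squares minimization (Brent search), bracketed
around the empirical $1/e$ crossing of the ACF. Windows whose ACF never
decays below $1/e$ within the computed lag range, or whose optimum
sticks to the bracket boundary, are flagged `converged = FALSE` and
excluded by the aggregation functions.

**Fit range.** The ACF is computed out to half the window length (100
lags for 10-s windows at 20 Hz, 500 at 100 Hz, 2500 at 500 Hz), but the
τ fit by default uses only the leading lags up to the first $1/e$
crossing (minimum 3 lags). The reason is statistical, and we consider
it the most consequential numerical choice in the package: in finite
windows the estimated ACF is biased downward by roughly the ratio of
the true timescale to the window length (a consequence of subtracting
the within-window mean), and the bias accumulates in the tail, which a
least-squares fit over the full half-window range then weights heavily.
On Ornstein–Uhlenbeck ground truth with 10-s windows at 20 Hz, the
full-range fit underestimates the median τ by about 27% at τ = 0.4 s
and 32% at τ = 0.5 s, while the truncated fit stays within 25% for
τ ≤ 0.5 s (these recovery numbers are computed by the acceptance test
on estimator recovery). The single-exponential model is a description
of the initial ACF decay, and restricting the fit to that regime is
what keeps the estimator anchored to its definitional quantity — the
lag at which correlation falls to $1/e$. The full-range fit remains
available via the `nLags` argument of `fitTau()`.

The estimator's residual negative bias (10–25% depending on the ratio
of timescale to window length) is shared by any windowed ACF-based
estimate; comparisons between states and correlations across channels,
which are the package's analyses, are unaffected in rank terms because
the bias is monotone in the underlying timescale.

### Band powers

`bandPower()` computes a one-sided periodogram scaled so its integral
over frequency equals the window variance, then integrates it between
band edges by the trapezoid rule with interpolation at the exact edges.
The default edges are theta 1–4, delta 4–7, alpha 8–12, beta 13–30,
gamma 30–40, broadband 1–40 Hz. The labels of the two slowest bands are
deliberately kept as in the analyses this package operationalizes,
where theta denotes 1–4 Hz and delta 4–7 Hz — the reverse of the common
convention; users who prefer conventional names can pass their own
`bands` list, which changes nothing numerically.

## Behavioral segmentation

`segmentBehavior()` turns a wheel-velocity trace into labeled 10-s
windows in two steps. Binarization marks samples with
$|v| > \text{threshold}$ as running, closes rest gaps shorter than
`minGapS`, then suppresses run bouts shorter than `minBoutS`. The
threshold default (0.25 velocity units) is exposed prominently because
no principled universal value exists — it must sit above the rest-noise
floor and below genuine running speeds; the defaults for the two
cleaning windows (1 s each) remove sensor flicker without merging
distinct bouts.

Each run bout with pre-rest duration `preR`, duration `runD` and
post-rest duration `postR` then emits up to five window types:

| state | window | preconditions |
|---|---|---|
| onset | last 5 s rest + first 5 s run | preR ≥ 5, runD ≥ 5 |
| locomotion | 10 s centered on the bout midpoint | runD ≥ 20, preR ≥ 60 |
| offset | last 5 s run + first 5 s rest | runD ≥ 20, postR ≥ 10 |
| initial_rest | first 10 s of rest after the bout | runD ≥ 5, postR ≥ 60 |
| sustained_rest | 10 s starting 40 s after bout end | same as initial_rest |

A bout may emit several states, and the offset and initial-rest windows
of the same bout overlap by construction (they share the first 5 s of
post-bout rest); both are emitted, because the heuristic defines
per-state window extraction rather than an exclusive labeling. Window
midpoints are snapped to the sample grid. Rest before the first
recorded sample is not assumed: pre/post-rest durations are measured
inside the trace, so a bout starting at the very beginning of a
recording cannot qualify for states requiring 60 s of pre-rest.

## Rest–task statistics

The percent change of a measure from rest to a task state is
$((\text{task}-\text{rest})/\text{rest})\times 100$, defined only for
positive rest values. `restTaskSummary()` aggregates a windowed
timescale table into per-channel rest means, task means, and the
across-window SD of the rest values; `variabilityChangeCorrelation()`
then computes the Spearman correlation (average-rank ties, two-sided p
from the t approximation on $n-2$ degrees of freedom) between resting
variability and percent change — the rest–task modulation statistic.

`compareGroups()` implements rank-sum and signed-rank comparisons with
a continuity-corrected, tie-corrected normal z; below 10 observations
per group (and without ties) the p value comes from the exact
distribution instead. Zero paired differences are dropped (Wilcoxon's
original convention), which makes the comparison of a vector with
itself return z = 0, r = 0, p = 1 rather than an error. The default
effect size is the rank-biserial correlation, bounded in $[-1, 1]$,
with complete separation mapping to ±1; a `z/\sqrt{n_\text{min}}`
variant is available via the `effect` argument. We use the bounded
rank-biserial as the default because unbounded biserial variants can
exceed 1, which makes effect sizes incomparable across analyses;
published effect sizes computed with such variants are therefore
matched only qualitatively by this package.

Outlier screening keeps values within $k$ scaled median absolute
deviations of the median (scale 1.4826, $k = 3$ by default); a zero MAD
degenerates to keeping exact-median values, with a warning, rather than
keeping everything. Multiple comparisons use the Holm step-down
(delegated to `stats::p.adjust`).

`cloggCompare()` tests whether the coefficient of a predictor changes
when a covariate is added to the same regression on the same data. For
nested models the restricted estimator is efficient under the null, so
the variance of the coefficient difference is the *difference* of the
sampling variances, $\mathrm{SE}_2^2 - \mathrm{SE}_1^2$, not their sum;
a non-positive difference (which indicates the models are not nested on
identical data) is an error with a diagnostic, except in the exact-tie
case $\beta_1 = \beta_2$ where z = 0 by definition.

## State classification

`nestedCVClassify()` predicts the behavioral state of each window from
the vector of per-channel timescales. The protocol is nested
cross-validation: stratified outer folds partition the samples without
replacement (so the aggregated outer test sets reproduce the whole data
set — the confusion-matrix total equals the sample count), and
hyperparameters are tuned exclusively on stratified inner folds of each
outer training set. Features are z-scored with training-fold statistics
only. Candidates are drawn log-uniformly at random — cost and kernel
scale for the RBF SVM, regularization strength for ridge multinomial
logistic regression — with a default budget of 30 evaluations per outer
fold. Random search is used rather than a Bayesian optimizer because at
this budget their accuracy is comparable and random search is exactly
reproducible under a seed across platforms.

Stratification and standardization are defaults chosen for safety with
imbalanced state counts; both are visible in the report (`fold_params`
records the tuned values per fold). Per-class one-vs-all ROC curves are
computed on each outer test fold and averaged on a fixed 101-point
false-positive-rate grid, with the across-fold SD as the uncertainty
band and the AUC of the mean curve reported; folds whose test set
contains a single class are excluded from the ROC average with a
warning. The permuted-label check in the acceptance suite doubles as a
leakage test: any tuning leak across the outer split inflates accuracy
above chance, and the suite asserts accuracy stays inside the binomial
99% interval around chance.

## The firing-rate model

The network model couples $N$ regions through a nonnegative matrix $W$:

$$\tau\,\frac{dx_i}{dt} = -x_i +
  f\!\Big(\sum_j W_{ij}x_j + b + s + I\Big),
  \qquad f(u) = \frac{1}{1+e^{-ru}},$$

with bias $b = -3$, gain $r = 0.5$, external input $I = 0$ (rest) or
$I = 1$ (stimulation), and $s$ a zero-mean unit-variance Gaussian noise
draw. The diagonal $W_{ii}$ is the recurrent connection strength
(default 1); the off-diagonal block is scaled by a single scalar so
that the mean over rows of $\sum_{j\neq i} W_{ij}$ equals exactly 2,
reflecting interareal input collectively stronger than the recurrent
term. `setRecurrent()` and `scaleOffdiagonal()` manipulate the two
parts independently, and `shuffleEdges()` permutes a chosen fraction of
off-diagonal weights among their positions (preserving the weight
multiset and the diagonal) as a topology null model.

### Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `b` | −3 | — | bias of the sigmoid drive |
| `r` | 0.5 | — | sigmoid gain |
| `tauNode` | 0.05 | s | population time constant (below) |
| `dt` | 0.01 | s | integration step |
| `duration` | 300 | s | per run |
| `discard` | 100 | s | transient removal |
| `noiseSd` | 1 | — | SD of the per-step noise draw |
| `tauI` | 0.05 | s | clamping-controller time constant |

**Node time constant.** The model's defining equations do not pin
$\tau$ to a value, and it is the one parameter the results are
genuinely sensitive to — not because the dynamics change qualitatively
(the rest→stimulation lengthening of the network's effective timescale
holds for any $\tau$), but because the *measurement* does: with 10-s
analysis windows, a 1-s node constant leaves only a handful of
correlation times per window, and the windowed τ estimator is then too
noisy to resolve the rest–stimulation contrast at realistic effect
sizes. The default, $\tau = 50$ ms, is the standard population time
constant of Wilson–Cowan-type firing-rate units (the transfer function
this model adopts); with it, the windowed estimator resolves the
contrast and the recurrent-connection sweep reproduces the expected
pattern — negligible effect without recurrence, a strong positive
effect at the default strength, growth to saturation around
$W_{ii} = 2$, and a sign flip at $W_{ii} = 4$ where the network
saturates at high rates. The parameter is exposed in `modelParams()`.

**Integration.** RK2 (explicit midpoint) in compiled code. The noise
draw $s$ is sampled once per step per region and held fixed across both
stages: the deterministic RK2 scheme is only well-defined for a drift
that is fixed within the step, so the noise enters as a per-step
constant inside $f$, exactly as written in the rate equation — not as a
$\sqrt{dt}$-scaled SDE increment. Both the noise SD and its presence
are configurable; noise-free runs are bit-reproducible without a seed,
noisy runs under a fixed seed (the compiled code draws through R's
RNG). Initial rates are Uniform(0,1) per region; the 100-s discard
makes the initialization immaterial, which the fixed-point tests
assert by converging from different random starts. Non-finite states
abort with the offending step index.

### The clamping controller

Raising $W_{ii}$ also raises mean firing rates, which would confound
any claim that recurrent connections shape timescale change. The
controller removes the confound by giving each region's input its own
dynamics,

$$\tau_I \frac{dI_i}{dt} = \tilde I_i(t) - I_i(t), \qquad
  \tilde I_i(t) = \frac{\mathrm{logit}(\bar x)}{r}
  - \sum_{j\neq i} W_{ij}x_j(t) - W_{ii}\bar x - b,$$

where $\tilde I_i$ is the exact steady-state input for which region
$i$'s sigmoid fixed point equals the target rate $\bar x$ (0.1 at rest,
0.6 under stimulation) given the other regions' current rates.
Substituting $\tilde I_i$ into the transfer function returns $\bar x$
to machine precision — the defining identity, asserted in the tests.
With $\tau_I = 0.05$ s the input tracks its target closely; the
mean-rate error shrinks as $\tau_I$ decreases until the controller
saturates numerical precision, and values of $\tau_I$ below about
$dt/2$ should be avoided (the explicit scheme stops damping the
controller there). The rate equation keeps its noise term in clamped
mode — fluctuations are what windowed timescales are estimated from —
so the achieved mean sits within about 0.01 of the target rather than
exactly on it: the sigmoid's curvature rectifies the noise slightly
upward at $\bar x = 0.1$ and downward at $0.6$. This rectification
offset is a property of the noisy sigmoid, independent of the
recurrent strength, and well inside the ±0.02 band the clamped-rate
check uses.

### Lyapunov spectra

Chaotic dynamics could masquerade as long timescales, so
`lyapunovSpectrum()` checks for chaos directly: Benettin-style repeated
QR re-orthonormalization of a deviation basis propagated through the
tangent dynamics of the noise-free model along its trajectory, with the
analytic Jacobian $J_{ik} = (-\delta_{ik} + f'(u_i)W_{ik})/\tau$. The
per-step propagator is the 4th-order truncated exponential of the
frozen midpoint Jacobian (the 2nd-order version leaves a visible
$\mathcal{O}((dt/\tau)^3)$ bias on the exponents at $dt/\tau = 0.2$). A
basis warm-up (default 200 QR steps before accumulation starts) aligns
the deviation basis with the invariant subspaces so the reported
exponents are insensitive to the initial basis; the leading exponent is
then reproducible across random orthonormal starts to ~$10^{-6}$, while
interior exponents in near-degenerate clusters agree to about 1%,
which is the accuracy the non-chaoticity bound needs. For the
uncoupled network every exponent equals $-1/\tau$ in closed form — the
oracle for the implementation.

## What the synthetic generators emulate — and what they do not

`genOUSeries()` uses the exact AR(1) discretization
$x_{t+1} = \phi x_t + \varepsilon_t$, $\phi = e^{-1/(f_s\tau)}$,
$\mathrm{Var}(\varepsilon) = \sigma^2(1-\phi^2)$, so the generated
autocorrelation and stationary SD are exactly the nominal ones (no
Euler discretization drift); `genStateRecording()` switches the
timescale with the behavioral state while keeping each channel
continuous across switches. `genWheelVelocity()` concatenates
rest/run/rest epochs with Gaussian noise — the simplest trace
satisfying the segmentation heuristic's duration rules, with exactly
computable expected windows. `genConnectome()` draws heavy-tailed
(lognormal by default, $\mu = 0$, $\sigma = 1$) symmetric weights at
full density with a zero diagonal, mimicking dense averaged DTI
matrices; nothing beyond the scaling rule is known about the real
weight distribution, so the lognormal choice is a stand-in, and every
analysis that depends on $W$ only does so through the scaled
off-diagonal sum. `genRestTaskEnsemble()` builds in the
rest–task modulation structure as ground truth: heterogeneous resting
timescales with task change inversely proportional to them, which
(because windowed-τ variability grows with the underlying timescale)
yields all-positive percent changes together with a negative
variability–change correlation.

What passing tests on these inputs show is that the pipeline recovers
known structure of OU-like signals with state-switched timescales; they
do not show robustness to calcium-indicator dynamics, hemodynamic
cross-talk, EEG volume conduction, 1/f backgrounds, oscillatory
components, or artifacts — all of which real recordings contain and the
generators deliberately omit. All generators take explicit integer
seeds and restore the caller's RNG state; with `seed = NULL` they use
the ambient stream.

## Problem sizes used by the checks

The acceptance suite runs at sizes chosen for a single CPU: the
clamped-rate check at 360 regions (4 simulations per state and
recurrent strength); the recurrent sweep and the variability–change
analysis at 90 regions with 10 simulations per state (the off-diagonal
scaling makes the mean-field regime insensitive to the region count);
the Lyapunov sweep at 60 regions, 5000 QR steps per configuration;
estimator recovery on 200 windows per ground-truth timescale; and the
classification checks on 400 samples with full 10×10 nested CV. The
pipeline smoke tests run smaller still. These sizes are stated here so
that anyone scaling the analyses up knows which knobs were reduced and
that none of the qualitative conclusions depends on the reduction.

## Known limitations

* The τ estimator's finite-window bias is not corrected, only
  contained; absolute τ values from 10-s windows underestimate slow
  timescales, and analyses should rely on within-design comparisons.
* The segmentation heuristic is deterministic and threshold-based; it
  has no notion of uncertainty and no smoothing beyond the two cleaning
  windows (probabilistic state inference is out of scope).
* The Clogg test assumes nested models on identical data; applied to
  anything else its variance estimate is invalid (and usually
  negative, which the implementation turns into an informative error).
* The firing-rate model is excitatory-only with homogeneous parameters;
  inhibitory populations, delays and conductance effects are out of
  scope, as is fitting the model to empirical data.
* Exact Wilcoxon p values are used only below 10 observations per
  group and without ties; elsewhere the continuity-corrected normal
  approximation applies.
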