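---
title: "Modelling feeding microstructure as a piecewise deterministic Markov process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling feeding microstructure as a piecewise deterministic Markov process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedPDMP)
```

## The model and its assumptions

Rodent feeding, observed at bout resolution, is a homeostatic behaviour:
the rates at which the animal starts and stops feeding depend on a
continuously varying physiological state. `feedPDMP` represents this as a
piecewise deterministic Markov process with three behavioural states —
feeding bout $F$, short within-meal pause $S$, long intermeal interval $L$
— coupled to a single fullness state $x(t)$ (grams of chow in the stomach
and small intestine).

**Fullness dynamics.** During a bout, fullness rises linearly at the
bout's feeding rate $\rho$; otherwise it empties at a rate proportional to
the square root of its contents, $\dot x = -k\sqrt{x}$, so a finite load
empties completely in finite time $t_{\text{empty}} = 2\sqrt{x_0}/k$. The
default $k = 0.00055\ \mathrm{g^{1/2}\,s^{-1}}$ empties a 4 g load in
roughly two hours, appropriate for an adult rat. Digestion during feeding
is neglected entirely (bouts are far shorter than the pauses in which
digestion happens); this keeps every downstream expression closed-form
rather than approximate. A linear law $\dot x = -kx$ and general power
laws $\dot x = -kx^\gamma$, $\gamma \in (0,1)$, are first-class
alternatives used for robustness checks: all operations accept any
emptying law, falling back from closed forms to quadrature and bracketed
root finding where necessary.

**Stochastic behaviour.** Bout durations are Exponential($\lambda_F$);
per-bout rates $\rho$ are Normal($\mu_F$, $\sigma_F$) truncated below at
zero; within-meal pauses are Exponential($\lambda_S$). After each bout the
meal terminates with the sigmoid probability
$p(x) = 1/(1+e^{-T_1(x-T_2)})$ evaluated at the bout-end fullness, and the
intermeal interval then terminates at the fullness-dependent hazard
$\lambda_L(x) = 1/(L_1 + L_2 x)$ along the emptying trajectory, giving the
interval the exact density
$p(t\mid x_0) = \lambda_L(x(t))\,e^{-\Lambda(t)}$ with
$\Lambda(t) = \int_0^t \lambda_L(x(\tau))\,d\tau$. For the square-root law
$\Lambda$ is an arctangent expression while the gut is emptying and linear
in $t$ afterwards, and it is inverted in closed form, so interval draws
use exact inverse-transform sampling rather than thinning or
discretisation.

## Parameters, units, defaults

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `lambda_F` | 1/s | 1/80 | bout termination rate (mean bout 80 s) |
| `mu_F`, `sigma_F` | g/s | 0.006, 0.0015 | per-bout feeding-rate distribution |
| `lambda_S` | 1/s | 1/40 | short-pause termination rate |
| `T1` | 1/g | 1.5 | termination sharpness |
| `T2` | g | 2 | termination threshold (coin flip at 2 g) |
| `L1` | s | 2000 | fullness-independent interval scale |
| `L2` | s/g | 1500 | fullness-dependent interval scale |
| `k` | g^(1/2)/s | 0.00055 | gut emptying rate |

Time is in seconds and amounts in grams throughout; the printed $k$ is
plausible under exactly this convention. The behavioural defaults were
chosen once to reproduce the meal patterning of an ad-libitum dark-period
rat: roughly 1.4 g meals, ~44 minute intermeal intervals, ~20 g intake
over 12 h, and a meal-termination probability at empty gut several-fold
lower than at typical end-of-meal fullness (with the defaults,
$p(0) \approx 0.05$ against $p \approx 0.5$ at threshold). The termination
scale matters for the sham-feeding experiment: a much steeper sigmoid
would make sham meals essentially unterminated, which real rats do not
show acutely.

`epsilon_empty` ($10^{-9}$ g) makes "fullness reached zero" numerically
well defined; under the linear law, which never reaches zero exactly,
`time_to_empty()` reports the time to reach this floor.

## Likelihood and censoring

`sequence_loglik()` sums exact event-level terms: Exponential log-densities
for complete bout and short-pause durations, the zero-truncated normal
log-density for each realised rate (the same truncation the simulator
uses — mixing conventions here would bias recovery), the log of the
termination probability (or its complement) at each bout-end fullness, and
the interval log-density at the fullness at meal termination. Events cut
by the observation window contribute the matching log-survival instead;
discarding them would bias the interval scales upward, which the test
suite demonstrates by refitting with censored events dropped. Fullness at
every boundary is recomputed from the observed events under the gut model,
never trusted from file metadata. The per-sequence likelihood and its
analytic gradient are implemented in compiled code for the square-root and
linear laws; other laws use the R path with finite-difference gradients.

For ad-libitum recordings the fullness at window start is unknown; fasted
protocols justify the default `x_init = 0`.

## Hierarchical inference

Individuals within a condition group share a multivariate normal prior on
the transformed scale (log10 for the six positive parameters, identity for
$T_1$, $T_2$): $\tilde\theta_j \sim N(\mu, \Sigma)$ with the separation
prior $\Sigma = \mathrm{diag}(\tau)\,\Omega\,\mathrm{diag}(\tau)$,
$\tau_i \sim \mathrm{HalfCauchy}(2.5)$, $\mu \sim N(\mu^*, 2)$, and
$\Omega \sim \mathrm{LKJ}(\eta)$. The LKJ shape is not pinned down by the
source analysis; the default $\eta = 2$ expresses a weak preference for
moderate correlations and is exposed in `hyper_prior()`. The prior mean
$\mu^* = (-3,-3,-3,1,1,-1,3,3)$ follows the parameter order
$(\lambda_F, \mu_F, \sigma_F, \lambda_S, T_1, T_2, L_1, L_2)$; this
ordering is a configuration choice, exposed because reasonable readings
differ.

Sampling uses the non-centred parametrisation
$\tilde\theta_j = \mu + \mathrm{diag}(\tau) L_\Omega z_j$ with
$z_j \sim N(0, I)$ and the correlation Cholesky factor $L_\Omega$ built
from canonical partial correlations through a tanh transform (prior and
Jacobian in closed form, verified against an independent onion-method
sampler). The sampler is a dynamic-trajectory ("no-U-turn") Hamiltonian
Monte Carlo sampler written for this package: multinomial sampling over a
doubling trajectory, dual-averaging step-size adaptation, and a mass
matrix estimated in expanding warmup windows — diagonal first, dense (with
shrinkage toward the diagonal) once enough warmup draws accumulate, which
matters because informative data induce strong linear correlations between
$\mu$ and the $z_j$ in the non-centred geometry. The whole log posterior
and gradient evaluate in one compiled call. Divergences (energy error
above 1000) are counted and the fit fails loudly when they exceed a
configurable fraction. Initialisation jitters a cheap data-informed point
(moment estimates plus a pooled termination logistic per individual)
rather than the prior mean: with a weakly informative prior mean far from
the data, the termination-parameter gradient at the prior mean points
toward the $T_1 = 0$ saddle, where chains can stall; mode-finding
(MAP-style) initialisation is still deliberately avoided.

Diagnostics are split-$\widehat R$ and Geyer initial-monotone effective
sample sizes over all quantities. Posterior predictive simulation
(`posterior_predictive_intake()`) back-transforms per-draw individual
parameters and replays the generative model, yielding intake or next-meal
distributions.

## What the synthetic-data generator emulates — and what it does not

The simulator doubles as the package's data generator: exponential bout
and pause durations, truncated-normal rates, sigmoid termination, and the
fullness-coupled interval hazard are exactly the model's laws, so
recovery and calibration tests verify the inference machinery, not the
realism of the model. Real recordings additionally contain circadian
drift within a photoperiod, day-to-day adaptation, weighing-scale
artefacts (the cleaning rules approximate standard screens: cancelling
pairs, non-positive amounts, configurable amount/rate bounds), and
meal-definition ambiguity (the 300 s labelling threshold is a field
convention, recorded in sequence metadata because interval- and
termination-parameter estimates depend on it). Passing tests therefore
demonstrate correctness of simulation + inference under the stated model,
not that the model captures every feature of real rats.

## Numerical choices

- Stable arctangent differences (`atan((p-q)/(1+pq))`) keep the integrated
  hazard accurate as $L_2 \to 0$; a series branch covers the last decade.
- Interval draws invert $\Lambda$ in closed form (sqrt law) or by
  `uniroot` on the exact bracket $[L_1 E, (L_1+L_2x_0)E]$ (other laws).
- The zero-truncated normal is sampled by inverse CDF (one uniform per
  draw, preserving seed-coupled comparisons across arms).
- Paired experiment designs re-seed per repeat so arms share randomness;
  a zero-strength intervention reproduces its baseline bit-identically.
- Likelihood optimisation runs on the transformed scale with analytic
  gradients (BFGS); out-of-range proposals return a large penalty.

## Problem sizes in the test suite

The suite exercises reference scales chosen to make each check
statistically decisive at desk scale: oracle comparisons over ~110 random
parameter draws at relative tolerance $10^{-8}$; Kolmogorov–Smirnov tests
at $n = 10^4$; likelihood recovery on a ~1300-meal subject (the 5 %
ingestive tolerance then sits about three sampling standard deviations
out); one hierarchical fit of 8 individuals × 7 half-day windows at
500 + 500 draws × 3 chains for convergence diagnostics; a 24-replicate
calibration study at 8 individuals × 4 windows per fit (99 % binomial band
around 90 % nominal coverage); and experiment sweeps at 500 Monte Carlo
repeats. The replication experiment for compensatory meal-termination
changes uses a baseline with strong fullness–interval coupling
($L_1 = 400$ s, $L_2 = 4000$ s/g): the compensation mechanism — a
near-proportional relation between termination fullness and the following
interval — only operates when the fullness-dependent hazard term
dominates, which is the regime reported for the rats that motivated the
experiment. Under the weaker default coupling the same perturbations
enlarge meals but raise daily intake, which the grid search reports
honestly.

## Known limitations

- Single-compartment gut; no hormone kinetics, no drug effects on $k$
  itself (motility changes are studied as an explicit experiment instead).
- No circadian modulation within a run; photoperiods are separate
  parameter groups.
- No learning or adaptation across days (relevant for repeated
  restriction protocols).
- Hierarchical fitting requires the square-root or linear emptying law
  (the compiled fast path); power laws are supported everywhere else.
- The no-U-turn sampler is a purpose-built implementation, not a drop-in
  replacement for a general-purpose probabilistic-programming backend;
  its diagnostics (split-$\widehat R$, ESS, divergence counts) should be
  inspected on every fit, as with any MCMC.
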