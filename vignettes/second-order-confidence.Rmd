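---
title: "Second-order computation of decision confidence: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-order computation of decision confidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaconf)
```

## The generative model and its assumptions

All three observer models share one generative skeleton. A trial has a
binary world state $d \in \{-1, +1\}$ with a flat prior, and a stimulus
strength $\theta \in [0, 1]$. The observer receives two internal samples,
a decision variable $X_{act}$ and a confidence variable $X_{conf}$, drawn
jointly from a bivariate Gaussian with mean $(d\theta, d\theta)$, standard
deviations $(\sigma_{act}, \sigma_{conf})$ and correlation $\rho$. The
choice is a fixed sign rule, $a = +1$ iff $X_{act} > 0$ (a sample of
exactly zero maps to $-1$; this is measure-zero and has no simulation
consequences). Confidence is a posterior probability of success,
$z = P(a = d \mid \text{evidence}, \text{beliefs})$.

The assumptions worth keeping in mind: Gaussian noise with equal variance
across the two world states; a neutral, fixed decision criterion; exactly
two world states; and a single evidence snapshot per trial — no
accumulation dynamics, no response times, no criterion variability.

The three models differ only in what "evidence" enters the posterior:

* **first-order**: $X_{conf} = X_{act}$; the posterior uses the likelihood
  $N(d\theta, \sigma_{act}^2)$ and reduces to a logistic function of
  $2 a \theta X_{conf} / \sigma^2$. Because the action is the sign of the
  same sample, $z \ge 0.5$ always.
* **postdecisional**: $X_{conf} = X_{act} + X_{new}$ with an independent
  extra sample $X_{new} \sim N(d\theta, \sigma_{act}^2)$, giving likelihood
  $N(2 d\theta,\, 2\sigma_{act}^2)$. The summed evidence can contradict the
  action, so $z < 0.5$ (error detection) is possible, but the action itself
  contributes nothing beyond $X_{conf}$.
* **second-order**: the observer only sees $X_{conf}$, and treats the
  decision system as a coupled actor. For each candidate $d$ it weights the
  $X_{conf}$ likelihood by the probability that the observed action would
  have occurred, $P(a \mid X_{conf}, d) = \Phi(a\,\mu_c(d)/\sigma_c)$ with
  $\mu_c(d) = d\theta + \rho \tfrac{\sigma_{act}}{\sigma_{conf}} (X_{conf} - d\theta)$,
  $\sigma_c = \sigma_{act}\sqrt{1 - \rho^2}$,
  then normalizes over $d$ and reports the action-consistent component.
  This is an exact conditioning of the bivariate Gaussian, and it collapses
  to the first-order model when $\rho = 1$ and
  $\sigma_{act} = \sigma_{conf}$.

A separate belief object carries the observer's *assumed* parameter values.
When beliefs match the generative parameters the posterior is calibrated by
construction; mismatches (hyperparameter errors) are the package's model of
metacognitive bias.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `sigma_act` | SD of the decision variable (unitless evidence scale) | 1 | fixes accuracy at $\Phi(\theta/\sigma_{act})$, ~84% correct at $\theta = 1$ |
| `sigma_conf` | SD of the confidence variable | 1 | equal-noise baseline; sweeps cover 0.25–3 |
| `rho` | coupling of the two samples | 0 / 0.6 | 0.6 is the canonical moderate-coupling regime used for worked examples and fixtures |
| `theta` | stimulus strength scaling the sample mean | 1 | full-strength stimulus; grids over $[0,1]$ for strength sweeps |

When the observer does not know the trial's $\theta$ (as in the
stimulus-strength experiments), confidence marginalizes the likelihood over
a discrete prior on $\theta$ before normalizing; the package exposes this
as a `theta_prior` object. A fixed believed $\theta$ is also available.
Marginalization is the default reading for the strength-sweep experiments
because the divergent confidence-by-strength pattern is precisely a
consequence of the observer's ignorance of $\theta$.

## What the simulator emulates — and what it does not

`simulate_trials()` generates the study conditions used throughout:
equiprobable world states, per-trial strengths from a fixed value or a
schedule prior, bivariate-Gaussian internal states (first-order and
postdecisional couplings as special cases), sign-rule actions, and both
post-choice and pre-choice confidence per trial. Experiments that compare
model variants or belief settings reuse one set of internal samples so
contrasts are paired.

The generator deliberately omits several features of real data: sequential
dependencies, lapses, response-time structure, criterion drift or
variability, non-Gaussian noise, and rating-scale distortions. Passing
tests therefore demonstrate the internal coherence of the models and
metrics on data generated under their own assumptions — parameter-recovery
and direction-of-effect claims — not that any of these assumptions hold in
empirical data.

Experiment defaults were chosen once as desk-scale study conditions:
$10^5$ trials per condition where a mean or curve is estimated (calibration
curves use the same), $10^4$ per dataset for meta-d′ sweeps (400 grid
cells), 20-point uniform $\theta$ grids, 25 equal-count internal-state
bins, and 10 equal-width confidence levels for calibration. The test suite
runs the same experiments at smaller sizes chosen for the properties being
asserted.

## Pre-choice confidence: the design choice that was genuinely open

Rating confidence *before* acting (the rate-choose design) needs a
definition of what is being rated. The package defines pre-choice
confidence as the model posterior for the covert response consistent with
the confidence evidence, $z_{pre} = z(X_{conf}, \operatorname{sign}(X_{conf}))$.

The tempting alternative — the posterior over $d$ from the $X_{conf}$
likelihood alone, reported for the maximizing $d$ — turns out to be
incapable of producing an action effect on mean confidence: both it and
post-choice confidence are calibrated success probabilities of their
respective classifiers, so with matched beliefs and
$\sigma_{act} = \sigma_{conf}$ their trial means are identical
($\Phi(\theta/\sigma)$), and for noisier confidence channels the
*post*-choice mean is higher, the opposite of the intended contrast. The
covert-response definition instead dissociates pre from post exactly on
the trials where the two evidence streams disagree: post-choice ratings
there condition on an action at odds with $X_{conf}$ and fall below 0.5,
while pre-choice ratings stay on the $X_{conf}$-consistent side. Averaged
over trials this yields both signatures at once — lower bias and higher
sensitivity after acting — and leaves the first-order model with a null
effect (its covert and overt responses always coincide), which is what the
choose-rate/rate-choose experiment asserts.

A consequence worth noting: at equivocal evidence the covert response
still functions as (self-generated) evidence, so
$z_{pre}(0) = z_{post}(0) \approx 0.69$ at the canonical parameters rather
than 0.5. The action-effect contrast is driven by disagreement trials, not
by the behavior at $X_{conf} = 0$.

## Metacognition metrics

**Type 2 ROC.** Confidence is binned by a rating scheme (default: 4
empirical-quantile bins; equal-width available) and a criterion swept
across ratings, plotting $P(z \ge c \mid \text{correct})$ against
$P(z \ge c \mid \text{error})$; the trapezoid area summarizes sensitivity
and is invariant to monotone transforms of $z$.

**meta-d′.** The maximum-likelihood fit expresses type 2 sensitivity in
type 1 units under an equal-variance Gaussian SDT model: the
metacognitively-ideal observer's $d'$ is `meta_d`, its type 1 criterion is
held at the empirical *relative* criterion $c' = c/d'$ (so the meta-level
criterion is $c' \cdot \text{meta-}d'$), and $2(K-1)$ type 2 criteria are
free, parameterized as ordered log-increment offsets so the optimizer
cannot cross them. The likelihood is multinomial over ratings conditional
on stimulus and response. Every cell is padded with $1/2K$ before
evaluation, which regularizes empty ratings. Optimization is quasi-Newton
(BFGS) from data-derived starting values with a relative tolerance of
$10^{-8}$ on the negative log-likelihood; non-convergence is an error, and
$d' = 0$ reports the ratio as undefined rather than infinite. Quantile
rating bins are the default precisely because equal-width bins on well-
calibrated confidence concentrate mass in the top bin and starve the
likelihood.

**Error detection and calibration.** An error is "detected" when its
post-choice confidence is below 0.5. Calibration curves bin trials into
equal-width confidence levels on $[0,1]$ (matching the accuracy-by-
confidence-level convention) and report accuracy per level; empty levels
carry count 0 and undefined accuracy.

## Numerical choices

* All posteriors are computed in log space and normalized with
  log-sum-exp; samples tens of SDs out do not underflow.
* The degenerate second-order case $|\rho| = 1$ makes the action
  likelihood a step function ($\sigma_c = 0$). The step is implemented
  with a finite log-floor ($-700$) instead of $-\infty$, so a query that
  conditions on a measure-zero action/evidence combination (e.g. $a = +1$
  with $X_{conf} < 0$ at $\rho = 1$) cancels to the likelihood-only
  posterior instead of returning 0/0. Exactly zero conditional means
  contribute $\log \tfrac12$.
* Ties at $X_{act} = 0$ map to $a = -1$ per the decision rule's
  "otherwise" branch.
* Every stochastic stage reseeds from a documented linear-congruential
  fan-out of the root seed (`child_seed(root, stage)`), so each stage is
  reproducible in isolation and whole runs are byte-identical given the
  root seed.
* Quantile rating edges that collapse on degenerate data are nudged by
  machine-scale offsets into a strictly increasing partition rather than
  erroring.

## Known limitations and honest caveats

* The decrease of error detection with increasing $\rho$ holds on the
  $\sigma_{conf} \ge \sigma_{act}$ band, where the $\rho \to 1$ limit
  approaches the first-order case. When the confidence channel is much
  sharper than the decision channel ($\sigma_{conf} \ll \sigma_{act}$),
  detection stays high at large $\rho$ — the first-order reduction
  requires *both* $\rho = 1$ and equal SDs. The error-surface tests
  assert monotonicity in $\rho$ only on that band.
* The action effect on confidence requires
  $\rho\,\sigma_{act}/\sigma_{conf} < 1$ for its usual sign and fades to
  zero for very noisy confidence channels ($\sigma_{conf} \gtrsim 2$ at
  the canonical $\rho$); sweep defaults stay in the informative range.
* Direction-of-miscalibration results (e.g. believing $\sigma_{act}$
  smaller than it is produces overconfidence; believing $\sigma_{conf}$
  smaller produces *under*confidence, because the believed-sharper
  confidence channel downweights the action term) are verified by
  simulation at the fixed generative setting
  $\sigma_{act} = 1.5, \sigma_{conf} = 1, \rho = 0.6$, $\theta = 1$;
  magnitudes elsewhere are not asserted.
* meta-d′ here is the response-conditional ML variant with a fixed
  relative type 1 criterion; hierarchical estimation, criterion
  variability corrections and confidence-RT joint models are out of scope.

## A small end-to-end run

```{r example, eval = FALSE}
gen <- gen_params(sigma_act = 1, sigma_conf = 1, rho = 0.6, theta = 1)
obs <- belief_params("second_order", 1, 1, 0.6)
trials <- simulate_trials(gen, n = 2e4, belief = obs, seed = 42)
summary(trials)
fit_meta_d(trials)
surf <- run_error_surface(n = 1e4, seed = 1)
head(surf)
```
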