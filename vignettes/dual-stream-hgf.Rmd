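---
title: "Dual-stream belief updating under social influence: models, fitting and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stream belief updating under social influence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualhgf)
```

## The task and what the model is for

Participants classify chimeric face/scene images twice: once alone (C1)
and once after seeing the bet of a partner (C2) who is either a
collaborator (they earn money when the partner's bet is correct) or a
competitor (they lose money when it is). The bets are uninformative — in
experiment 1 they are correct on exactly half the trials, in experiment 2
on exactly 75% — so the reward-maximizing strategy is to ignore them.
People do not: classifications drift toward a collaborator's bet and away
from a competitor's, and a C1-to-C2 change in the partner-aligned
direction is scored as a *self-deceptive* response.

The package's perceptual model formalizes the two information sources as
parallel two-level filters: a *social* stream tracking the tendency of the
partner's bets to be correct, and a *non-social* stream tracking the
tendency of the images to be scenes. Each level-2 tendency evolves as a
Gaussian random walk with variance $\omega_s$ or $\omega_{ns}$; each
level-1 prediction is a logistic squash of the previous level-2 mean. The
non-social squash adds a *recency bias* $(p_{t-1} - 50)/50$ carried over
from the previous image's scene percentage $p_{t-1}$: an unambiguous
previous image pulls the next prediction toward its own category, a 50/50
image carries nothing. The social squash of the winning variant is
$\mathrm{logistic}(\eta\,\omega_s\,\mu_{2,s})$, so the walk variance
itself scales the steepness — a volatile bet-tendency belief also
saturates faster.

After every trial each stream's level 2 is updated by its
precision-weighted prediction error. The level-2 update is printed in the
source literature only up to proportionality; this package adopts the
canonical binary-filter closure
$$\hat\pi_2 = \frac{1}{\sigma_2 + \omega},\quad
  \hat\pi_1 = \frac{1}{\hat\mu_1(1-\hat\mu_1)},\quad
  \pi_2 = \hat\pi_2 + \hat\pi_1^{-1},\quad
  \mu_2 \leftarrow \mu_2 + \delta_1/\pi_2,$$
which is the form the adapted open-source toolboxes use; the literal
alternative (multiplying by $\hat\pi_1$) diverges near belief extremes.
Note that $\omega$ here is a *variance on the natural scale* (it is
estimated in log space), not the log-volatility exponent of some
toolboxes.

The streams meet in *bet-agreement space*: the non-social belief is
flipped when the bet is "face" ($a_{ns} = 1-\hat\mu_{1,ns}$), then
combined by level-1 precision weights, and a softmax with inverse decision
noise $\beta$ yields the probability of agreeing with the bet. Choices are
therefore driven by *predictions* — the current image enters the model
only as the input that updates the non-social stream afterwards. The
consequences of this (deliberate, printed-equation-faithful) choice for
synthetic data are discussed below.

## Parameters, transforms and priors

| parameter | meaning | transform | default prior (transformed) |
|---|---|---|---|
| $\omega_s$ | social level-2 walk variance | log | N(-2, 4) |
| $\omega_{ns}$ | non-social walk variance | log | N(-2, 4) |
| $\mu^0_{2,s}$ | initial social mean (prior trust in the bet) | identity | N(0, 1) |
| $\eta$ | social sigmoid scale (winning map) | log | N(0, 1) |
| $\kappa$ | additive exponent bias (map P2) | identity | N(0, 1) |
| scale | free multiplicative exponent (map P3) | log | N(0, 1) |
| $\beta$ | softmax inverse decision noise | log | N(0, 1) |
| $\zeta$ | social stream weight (response R2) | log | N(0, 1) |
| $\alpha_s,\alpha_{ns}$ | Rescorla-Wagner learning rates | logit | N(0, 1) |

$\sigma^0_2$ is fixed at 1 for both streams and $\mu^0_{2,ns}$ at 0 (only
the social prior mean is a quantity of interest). The source article's
exact prior table is not reproduced in its main text, so these weakly
informative defaults — centered on neutral behavior, all configurable via
`model_spec(priors = ...)` — stand in for it.

Inversion is MAP estimation in the transformed space (BFGS from 10
jittered starts by default, objective tolerance 1e-10 relative), with the
log model evidence approximated by Laplace's method at the optimum and a
BIC fallback when the Hessian is not positive definite. A caution: the
Laplace evidence is *not* bounded above by the log joint at the mode — for
flat posteriors the Gaussian volume $(2\pi)^{d/2}/\sqrt{\det H}$ exceeds
one — so no such inequality is asserted anywhere.

## Model space and its identifiability limits

Perceptual families: P1 ($\eta\omega_s$-scaled sigmoid, the winner), P2
(additive exponent bias), P3 (free multiplicative scale), and the
Rescorla-Wagner baseline; response families: R1 (softmax only, the
winner) and R2 ($\zeta$-weighted combination, taken as precision-weighted
with a configurable switch). Random-effects model selection follows the
standard variational Dirichlet scheme (uniform prior $\alpha_0 = 1$,
tolerance 1e-6), exceedance probabilities by seeded Dirichlet Monte Carlo
($10^5$ draws), the Bayes omnibus risk by free-energy comparison against
the equal-frequency null, and PXP $= (1-\mathrm{BOR})\,\mathrm{EP} +
\mathrm{BOR}/K$. Family comparison pools member evidences with
$\mathrm{logsumexp} - \log(\text{family size})$, making it invariant to
duplicating a model within a family.

One structural caveat the tests surfaced and the package documents rather
than hides: P1 and P3 parameterize the *same* likelihood surface (the
product $\eta\omega_s$ plays the role of P3's free scale), so their
evidences differ only through prior geometry. Data generated under P1
favor P1 only when the generating parameters sit where P1's priors expect
them; agents with a generating $\omega_s$ far above the prior center hand
the evidence advantage to P3, whose scale parameter is decoupled from the
walk variance. Model-recovery checks therefore use near-deterministic
responders ($\beta = 20$) with perceptual parameters drawn from the
default priors — the regime in which the social map is actually expressed
in behavior — and under that design the P1 family is recovered with PXP
> 0.99 and the heuristic baseline never wins.

## The synthetic cohort: what it emulates, what it does not

`sample_cohort()` draws, per participant: a paranoia label (high with
probability 0.3; R-GPTS persecution sampled on the matching side of the
clinical cutoff 11, BAI/BDI loosely coupled to it), a condition
(cooperation/competition, balanced), and model parameters
$$\log\omega_{ns} \sim N(-1 + 0.32\,\mathrm{HP},\ 0.8^2),\quad
  \log\omega_s \sim N(0 + 0.32\,\mathrm{HP},\ 0.8^2),$$
$$\mu^0_{2,s} \sim N(-0.2 + 0.4\,\mathrm{COOP},\ 1),\quad
  \log\eta \sim N(0, 0.5^2),\quad \log\beta \sim N(0.7, 0.3^2),$$
so the three published group effects are encoded as ~0.4-SD shifts
(small-to-moderate, chosen once to mirror the reported partial eta squared
magnitudes in spirit): elevated $\omega_{ns}$ and $\omega_s$ with high
paranoia, elevated $\mu^0_{2,s}$ under cooperation. The baseline
$\log\omega_s$ mean of 0 (rather than the fitting prior's $-2$) keeps the
social stream behaviorally expressed so the condition effect is visible
at all; $\log\beta \approx 0.7$ gives a moderately deterministic
responder. All constants are `cohort_config()` arguments.

Every participant sees the same shuffled 80-stimulus sequence (11-level
grid $\{0, 10, \dots, 100\}$, as in the experiment), C2 reuses the C1
image order, and bets are placed per participant so that *exactly*
`round(accuracy * 80)` are correct — a design constraint, not a sampling
rate. Truth at exactly 50/50 is a seeded coin flip, flagged so accuracy
metrics can exclude those trials. C1 choices come from the non-social
stream alone (no bets exist in C1); C2 choices from the full dual-stream
model. Confidence is the minimal monotone construction the CWSD metric
presupposes, `clip(round(1 + 6 * (2|b - 0.5|)^gamma + eps), 1, 7)` with
$\gamma = 1$ and $\epsilon \sim N(0, 0.5)$, using $|\hat\mu_{1,ns}-0.5|$
in C1.

Because the printed response model is prediction-driven, generated
choices are independent of the *current* image. Two realistic features
are therefore absent from synthetic cohorts, and a green test does not
establish them: there is no C1 psychometric curve (simulated C1 accuracy
hovers near chance), and the self-deception-by-ambiguity profile is flat
rather than peaked at 50/50. The metrics that presuppose an
ambiguity-peaked profile are accordingly tested on cohorts constructed
with an explicit ambiguity-linked flip propensity, and the rank-difference
insight metric is exercised on data with a known monotone link rather
than on generator output.

## Numerical choices

Beliefs are clipped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-8}$ to keep level-1 precisions finite; likelihood
probabilities to $10^{-10}$. The softmax is evaluated as
`plogis(beta * qlogis(b))` for stability. The first optimizer start is the
prior mean; the rest jitter it by half a prior SD. Ties in ranks get
average ranks; $\omega_{ns}$ is ranked ascending and C1 accuracy
descending, so a large positive rank difference reads "overly pessimistic
about one's own performance". The raw self-deception denominator is the
number of C2 trials (80), not the number of change-eligible trials, and
the confidence numerator of CWSD uses C2 confidence (the session in which
the deceptive response occurs). All randomness descends from single seeds
through a deterministic child-seed scheme kept inside the 32-bit integer
range; regenerating any artifact with the same seed is byte-identical.

## Known limitations

Parameter recovery is regime-dependent: with decision noise drawn from
its wide prior, many simulated agents respond near-randomly and the
initial social mean recovers only weakly ($r \approx 0.19$ at $n = 100$);
with suppressed decision noise all three headline parameters recover
clearly ($r = 0.82/0.49/0.43$). Recovery of $\omega_{ns}$ is *not*
monotone in series length for prior-drawn agents whose $\omega_{ns}$ is
essentially unidentifiable — longer series can genuinely prefer a
large-$\omega_{ns}$ overfit. The full-circle group-effect check at
$n = 200$ establishes the *direction* of the three encoded effects in the
fitted parameters, not their significance: a 0.4-SD generative shift
attenuated by finite recovery correlations is underpowered for a
significance claim at that size. Three-level (volatility) filters,
response models for reaction times or the 1-7 confidence ratings, and the
covariate batteries of the source analyses are out of scope.
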