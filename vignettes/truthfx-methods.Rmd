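---
title: "Modeling plausibility and the repetition-based truth effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling plausibility and the repetition-based truth effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truthfx)
```

## The model

People judge repeated statements as true more often than new ones. A
long-standing question is whether this repetition-based truth effect is
*moderated* by how plausible a statement already is: does repetition help
mostly ambiguous statements, or all statements equally?

`truthfx` formalizes this question with a latent-variable model. Every
statement $i$ carries a latent plausibility $p_i$. A truth judgment arises by
drawing a latent truth value $y^* \sim \mathrm{Normal}(p_i, \sigma)$ and
responding "true" iff $y^* > 0.5$. Marginally this is a probit model with a
non-standardized link ($\sigma = 0.5$, threshold $0.5$; both fixed constants
of the framework, kept configurable in `link_spec()`):

$$\theta_i^{\text{new}} = \Phi\!\left(\frac{p_i - 0.5}{\sigma}\right), \qquad
  \theta_i^{\text{rep}} = \Phi\!\left(\frac{p_i + f_i - 0.5}{\sigma}\right),$$

where $f_i$ is the additive *fluency shift* caused by repetition. Four
variants encode competing hypotheses about how the shift depends on
plausibility:

| variant | shift $f_i$ | interpretation |
|---|---|---|
| M1 | $m$ | constant shift for all statements |
| M2 | $m\,p_i$ | larger shift for plausible statements |
| M3 | $m\,(1 - p_i)$ | larger shift for implausible statements |
| M4 | $2m\,(0.5 - |p_i - 0.5|)$ | triangular, peaking at $p_i = 0.5$ |

The formulas are applied *literally* for $p_i$ outside $[0, 1]$: nothing in
the model clamps them, and the conventional simulation span $[-1, 2]$
deliberately includes such values. Under M2–M4 the shift is then negative in
part of the range. This choice is consequential for M4 (see *Prior
calibration* below).

A point this package exists to make precise: even when the shift is constant
on the probit scale (M1), the observable effect $\theta^{\text{rep}} -
\theta^{\text{new}}$ is largest for ambiguous statements and vanishes at the
extremes, simply because $\Phi$ compresses differences in its tails. Whether
"repetition × plausibility" shows an interaction depends on the scale:
`transform_scale()` maps response probabilities to the probit or logit scale
so this can be inspected directly. The logit comparison uses the plain
(unscaled) logit; no scaling constant is applied, since the comparison is
qualitative — which interactions appear or disappear — not quantitative.

```{r}
curve <- truth_effect_curve("M1", m = 0.4)
head(curve, 3)
```

## Hierarchical model for trial-level data

For judgments $y_{ij}$ of statement $i$ by participant $j$:

$$y_{ij} \sim \mathrm{Bernoulli}\!\left(\Phi\!\left(\frac{p_i + R_{ij}(f_i + v_i) + u_j - 0.5}{\sigma}\right)\right),$$

with repetition indicator $R_{ij}$, statement plausibilities
$p_i \sim \mathrm{Normal}(\mu_p, \sigma_p)$, item-level residual truth-effect
shifts $v_i \sim \mathrm{Normal}(0, \sigma_v)$ and participant response
biases $u_j \sim \mathrm{Normal}(0, \sigma_u)$. Hyper-priors:
$\mu_p \sim \mathrm{Normal}(0.5, 1)$ (uniform-ish on the probability scale
once the threshold is subtracted), half-normal(1) priors on all three scales,
and a zero-truncated normal prior on $m$ with sd $0.1$ and a
*variant-specific* mean (next section). The participant effect $u_j$ enters
additively inside the probit numerator, on the same scale as $p_i$; that is
the single supported convention. Statements are always modeled
hierarchically when fitting, even if a simulation generated them on a fixed
grid: the fitted model should not be told the generator's secret.

## Prior calibration across variants

The same $m$ implies very different average truth effects under the four
shift functions, so putting the same prior on $m$ in all variants would
covertly favor some of them. `scale_prior_means()` therefore sweeps $m$ over
a grid ($0.01$–$0.50$ in steps of $0.01$), computes the implied average
truth effect per variant, and matches each variant to the grid value whose
implied effect is closest to a common target (ties toward the smaller $m$).
The default target of $.04$ is the average effect size typical of this
paradigm. The implied effect is computed analytically by averaging the
closed-form curve over the plausibility distribution (uniform $[-1,2]$ grid
by default); a simulation mode cross-checks it.

Under this default design the matched values are $0.12/0.32/0.20/0.35$ for
M1–M4. The default prior means used by `prior_spec()` are the conventional
$0.11/0.27/0.19/0.38$; the difference is expected, because matched values
depend on the assumed plausibility distribution and noise model of the
calibration sweep, which the convention does not pin down. One structural
point deserves emphasis: with the literal triangular shift, M4's implied
average effect over $[-1, 2]$ is bounded near $0.016$ — the negative shifts
beyond $[0, 1]$ cancel most of the central hump — so a target of $.04$ is
unreachable for M4 and it is matched to its nearest (maximal-effect) grid
value. Reproducing a matched value of $0.38$ for M4 would require clamping
the triangular shift at zero outside $[0, 1]$, which the model definition
here deliberately does not do. For the same reason M4's implied effect is
*not* monotone in $m$: it peaks near $m \approx 0.35$ and declines as the
out-of-range penalty grows. `scale_prior_means()` errors only when *no*
variant can reach the target, reporting the per-variant achievable maxima.

```{r}
scale_prior_means(0.04)$matched
```

## The sampler

`fit_truth_model()` defaults to a blocked data-augmentation Gibbs sampler
written for exactly this model family. Augmenting each trial with its latent
truth value $y^*$ (a truncated normal given the observed judgment) makes the
model conditionally linear-Gaussian, so the plausibilities, both
random-effect vectors, $\mu_p$ and the zero-truncated $m$ all have exact
conjugate conditionals — for every variant in which the linear predictor is
linear in the block being updated ($p$ under M1–M3; $m$ always). The
remaining blocks use adaptive random-walk Metropolis: the three scales (on
the log scale) and $p$ under M4, whose triangular shift is only piecewise
linear.

Two refinements matter in practice:

* **Interweaving (ASIS).** After the centered scale updates, $\sigma_u$ and
  $\sigma_v$ are redrawn in the non-centered parameterization (effect vector
  divided by its scale), where the likelihood is linear in the scale and the
  conditional is an exact truncated normal. This breaks the scale–vector
  coupling that otherwise makes $\sigma_v$ the slowest-mixing parameter.
* **Marginal refresh of $p$.** Items at the extremes of plausibility answer
  almost deterministically; their latent values live in the far tail and the
  conjugate update then crawls. Each iteration therefore starts with a
  vectorized Metropolis step on $p$ against the *marginal* Bernoulli
  likelihood (valid as a partially collapsed update because it runs before
  $y^*$ is re-imputed).

A non-centered parameterization throughout (the usual remedy for funnel
geometry under gradient-based samplers) is unnecessary here: the conjugate
blocks do not suffer from the funnel, and the two refinements above address
the couplings that do arise. `engine = "jags"` hands the identical model to
JAGS instead; the test suite checks that both engines agree on the posterior
of $m$, which is a useful guard against implementation error in either.

Convergence is never assumed: every fit computes split-$\hat R$ (each chain
split in half) and effective sample sizes for *all* monitored parameters,
and a fit with any $\hat R \ge 1.02$ is flagged with a warning. The
full-scale profile (8 chains × 1,000 warmup × 10,000 draws) is the default
of `mcmc_settings()`; `mcmc_settings_desk()` (4 × 500/1500) is the
reduced profile used in examples.

## Model comparison

Marginal likelihoods come from an iterative optimal-bridge estimator
(`bridge_sampler_core()`): posterior draws are mapped to an unconstrained
scale (log transforms with Jacobians for $m$ and the scales), half of them
moment-match a multivariate-normal proposal, and the Meng–Wong fixed point
is iterated to tolerance $10^{-10}$ (cap 1,000 iterations) on the remaining
half plus fresh proposal draws. The Monte Carlo error estimate uses the
standard asymptotic formula, with the posterior-side term corrected for
autocorrelation through the spectral density at frequency zero. A conjugate
Beta–Bernoulli model, whose log marginal is known in closed form, anchors
the implementation in the tests. A prior-only fit has marginal likelihood
exactly 1 (the prior integrates to one), so its log marginal likelihood is
returned as exactly 0 rather than estimated.

Bayes factors are differences of log marginal likelihoods; posterior model
probabilities are a log-sum-exp-stabilized softmax of
$\text{lml} + \log(\text{prior})$. PSIS-LOO (`loo_elpd()`) smooths the right
tail of each observation's importance weights with a generalized Pareto fit
(Zhang–Stephens estimator) and reports ELPD on the sum-over-observations
scale with per-observation Pareto-$k$ diagnostics; pairwise ELPD differences
carry standard errors computed from the pointwise differences.

## The bootstrap midpoint test and its power

The classic aggregate test regresses the per-statement truth effect $R - N$
on perceived truth and its square, and asks whether the peak of the fitted
inverted U lies at $.50$ — the signature of a constant probit-scale shift.
`bootstrap_peak_ci()` resamples statements with replacement (5,000 resamples
by default) and forms a percentile CI for the peak $-b_1 / (2 b_2)$;
percentile rather than BCa, since nothing more specific is conventional
here. Resamples with $b_2 \ge 0$ have no interior peak: they are excluded
from the percentile computation and counted, because including extrapolated
vertices of upward parabolas explodes the interval; if more than half the
resamples are degenerate the result is flagged unreliable. Proportions of 0
or 1 enter the regression as-is, with no continuity correction. Both x-axis
operationalizations are supported: the traditional $(R+N)/2$ and the
new-only proportion $N$, which avoids conditioning the x-axis on the
manipulation itself.

`power_study()` wraps this in a Monte Carlo loop. Each simulated dataset has
80 statements on the uniform $[-1, 2]$ plausibility grid and *250 binomial
judgments per statement per condition*, with no item or participant residual
variation. The 250 is worth flagging prominently: the per-statement sample
size behind the conventional power figures for this test is not part of the
convention, and rejection rates for the weakly-identified cells (the
triangular model at small $m$) are sensitive to it — more judgments mean
less item noise and more power. With this recipe the constant-shift model
rejects at roughly 4–10% across $m \in \{0.1, 0.2, 0.4\}$ (slightly
anti-conservative, as expected of this bootstrap), the linear-dependence
models reject essentially always, and the triangular model rises from single
digits at $m = 0.1$ to ~100% at $m = 0.4$; its $m = 0.2$ rate (~55–60%
under this recipe) is exactly the kind of quantity that moves by tens of
percentage points under a different per-statement sample size.

## The simulator and what passing tests do not show

`simulate_trials()` emulates the standard repetition paradigm: every
participant judges all statements, a random half repeated, counterbalanced
in complementary pairs so each statement is repeated for half the
participants (±1 when the count is odd). Defaults: 80 statements, 250
participants, $\sigma_u = 0.3$, $\sigma_v = 0.1$ — participant variance in
line with reported participant-intercept variances in this literature
(roughly 0.01–0.08 on the variance scale), item residual variance modest.
The simulator does not emulate: exclusion rules and missingness of real
studies, session/order effects, within-participant fluency drift, or
non-binary response formats. Recovery and model-selection results on
simulated data therefore demonstrate internal consistency of the machinery,
not robustness to those real-data complications.

## Numerical choices

* Success probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ (JAGS:
  $10^{-9}$) before Bernoulli evaluation.
* Analytic identities are tested to $10^{-10}$–$10^{-12}$; normal CDF and
  quantile come from R's own implementations.
* `hdi()` returns the shortest interval containing the requested mass;
  degenerate draws give a zero-width interval.
* Calibration ties break toward the smaller $m$; an unreachable target for a
  single variant matches its nearest grid value, and only a target no
  variant reaches errors.
* Truncated-normal draws use inverse-CDF sampling with probabilities clamped
  to $[10^{-15}, 1 - 10^{-15}]$.
* Bridge sampling reserves the first half of the posterior draws for
  proposal fitting and adds a $10^{-10}$-scaled ridge to the proposal
  covariance; non-PD covariances fall back to their diagonal.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen for a desk-scale run:
parameter recovery at 80 statements × 200 participants (2 chains ×
1,000 warmup + 6,000 draws), model-selection consistency at 16 × 48 with
$m = 0.5$ over ten replicates, power cells at 150–600 datasets × 2,000
bootstrap resamples, and the Monte-Carlo/closed-form equivalence at 100,000
draws with common random numbers across grid points. `scripts/acceptance.R`
runs the power study at its full conventional scale (1,000 datasets × 5,000
resamples per cell).

## Known limitations

* The probit link with $\sigma = 0.5$ and threshold $0.5$ is an assumption,
  not an estimate; the data cannot identify the link's shape, only
  conclusions conditional on it.
* The Gibbs engine's $m$ draws are more autocorrelated than a slice or HMC
  sampler's would be per iteration; the cheap iterations more than
  compensate in wall-clock ESS, but very short chains should not be trusted
  for $m$ without checking its ESS.
* Bridge sampling with a moment-matched normal proposal needs posterior
  draws to outnumber the parameter dimension comfortably; with hundreds of
  random effects, use the full draw budget rather than a minimal one.
* PSIS-LOO treats trials as exchangeable units; leave-one-*statement*-out
  questions would need a grouped variant that is not implemented.
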