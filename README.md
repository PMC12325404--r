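# truthfx

Bayesian modeling of the repetition-based truth effect: how the latent
plausibility of a statement moderates (or does not moderate) the boost in
"true" judgments that repetition produces.

## The problem

Repeated statements are judged true more often than new ones. Empirically
the effect looks biggest for ambiguous statements and small for clearly
plausible or implausible ones — but that observation depends entirely on the
measurement scale. `truthfx` implements a probit latent-variable framework
in which each statement $i$ has a latent plausibility $p_i$, a truth
judgment arises by thresholding $y^* \sim \mathrm{Normal}(p_i, \sigma)$ at
$0.5$ (with the conventional $\sigma = 0.5$), and repetition adds a fluency
shift $f_i$ to the latent value:

$$\theta_i^{\text{new}} = \Phi\!\left(\tfrac{p_i - 0.5}{\sigma}\right),\qquad
  \theta_i^{\text{rep}} = \Phi\!\left(\tfrac{p_i + f_i - 0.5}{\sigma}\right).$$

Four model variants encode rival hypotheses about the shift: constant
($f_i = m$, M1), increasing in plausibility ($m p_i$, M2), decreasing
($m(1-p_i)$, M3), or triangular with a peak at $p_i = 0.5$ (M4). A constant
latent shift *still* produces an inverted-U truth effect on the probability
scale — the core scale-transformation point the package makes testable.

For trial-level data $y_{ij}$ the package fits the hierarchical model
$y_{ij} \sim \mathrm{Bernoulli}\bigl(\Phi((p_i + R_{ij}(f_i + v_i) + u_j -
0.5)/\sigma)\bigr)$ with crossed statement and participant random effects,
compares the four variants by bridge-sampling Bayes factors and posterior
model probabilities (optionally PSIS-LOO), and implements the classic
aggregate alternative: a quadratic-regression bootstrap test of whether the
truth-effect curve peaks at perceived truth $.50$, together with its Monte
Carlo power analysis.

## Worked example

```r
library(truthfx)

# simulate a constant-shift experiment: 60 statements, 120 participants
set.seed(42)
design <- design_spec(n_statements = 60, n_participants = 120)
trials <- simulate_trials(design, draw_parameters(design, "M1", m = 0.3))

fit <- fit_truth_model(trials, "M1",
  settings = mcmc_settings_desk(chains = 2, warmup = 800, draws = 3000, seed = 1))
tidy(fit)
#> # A tibble: 9 x 5
#>   parameter  mean     sd hdi_lo hdi_hi
#> 1 m         0.246 0.0325 0.184   0.311
#> 2 mu_p      0.529 0.122  0.301   0.770
#> 3 sigma_p   0.918 0.0936 0.734   1.09
#> 4 sigma_u   0.276 0.0221 0.235   0.320
#> 5 sigma_v   0.165 0.0328 0.0990  0.227
#> # ... var(u), var(v), sigma_u^2, sigma_v^2
```

The generating shift ($m = 0.3$) lies inside the 95% HDI of `m`. The same
data, seen through the aggregate midpoint test:

```r
set.seed(43)
bootstrap_peak_ci(summarize_items(trials), n_bootstrap = 5000)
#> <peak_test_result> peak = 0.4724, 95% CI [0.4238, 0.5016];
#>   does not reject midpoint 0.50
```

The fitted inverted-U peaks near perceived truth .50, as a constant latent
shift predicts, so the midpoint test (correctly) does not reject. Fitting
all four variants and comparing them by Bayes factors is one call each:

```r
fits <- lapply(setNames(model_variants(), model_variants()),
               function(v) fit_truth_model(trials, v,
                 settings = mcmc_settings_desk(seed = 1)))
compare_models(fits, method = "bridge", seed = 2)   # lmls, BFs, probabilities
```

Analytic truth-effect curves, the prior calibration that matches the
implied average effect across variants, and the power study of the midpoint
test are exposed as `truth_effect_curve()`, `scale_prior_means()` and
`power_study()`; `autoplot()` methods draw each result type. A thin CLI over
the same functions ships in `inst/cli/truthfx`
(`curves | simulate | fit | compare | calibrate | power`).

External datasets enter through `read_trials()` (CSV with columns
`participant_id`, `statement_id`, `repeated`, `judgment`) or, for deposited
data with arbitrary column names, through `reanalysis_pipeline()` with a
user-supplied column mapping.

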