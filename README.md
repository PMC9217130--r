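# painrl

Asymmetric reinforcement-learning models of instrumental pain-avoidance
behavior.

## What this package is for

In a two-option pain-avoidance task, participants choose between two
stimuli whose pain probabilities drift over trials as independent bounded
random walks, and must keep learning from two kinds of feedback: pain
they *received* and pain they *avoided*. `painrl` provides the complete
computational pipeline for such studies, for researchers in computational
psychiatry and decision neuroscience:

- **Task and agent simulation** — bounded random-walk environments with a
  crossing constraint, softmax Q-learning agents, and cohort generation
  with subject parameters drawn from group-level distributions
  (`pal_task()`, `simulate_agent()`, `simulate_cohort()`).
- **Hierarchical Bayesian estimation** of two delta-rule Q-learning model
  variants per treatment group (`pal_fit()`), with split-Rhat diagnostics
  (`check_convergence()`).
- **Model comparison** by WAIC on the deviance scale (`waic()`,
  `grade_evidence()`, `waic_compare()`).
- **Posterior analysis** — highest density intervals, between-group
  difference distributions, strict posterior orderings, per-subject
  summaries (`hdi()`, `pal_contrast()`, `proportion_greater()`,
  `individual_medians()`).
- **Model-independent behavior** — pain counts, outcome-conditioned
  switch rates, paired contrasts, lagged outcome→switch logistic
  regression, group ANOVAs (`switch_rates()`,
  `lagged_switch_regression()`, `group_anova()`).
- **Parameter recovery** pipelines (`run_recovery()`) and export of
  trial-wise expected-pain-probability regressors for fMRI GLMs
  (`pain_regressors()`, `write_pain_regressors()`).

## The model

Outcomes are coded −1 (pain) / 0 (no pain). Each option *s* carries a
value *Q*<sub>s,t</sub> ∈ [−1, 0], initialized at −0.5, so −*Q* is the
option's expected pain probability. After each trial the chosen option is
updated by the delta rule

> *Q*<sub>s,t+1</sub> = *Q*<sub>s,t</sub> + α (*O*<sub>t</sub> − *Q*<sub>s,t</sub>)

with a single learning rate α (Model 1) or separate rates
α<sub>pain</sub> / α<sub>no-pain</sub> for received vs avoided pain
(Model 2). Choice probabilities are softmax in the *Q* values with
inverse temperature β ∈ [0, 20]. Subject-level parameters sit in a
hierarchical Bayesian model per treatment group — unconstrained normals
with N(0, 1) / half-Cauchy(0, 5) hyperpriors, inverse-probit constraining
transforms — sampled by an adaptive Metropolis-within-Gibbs scheme with
interweaved centered updates (4 chains × 5000 iterations, 1000 burn-in,
thinning 5 → 3200 retained draws by default). See the methods vignette
(`vignettes/pain-avoidance-modeling.Rmd`) for the full account.

## Worked example

Simulate a placebo-like cohort (28 subjects, 144 trials), look at its
model-independent behavior, fit both model variants, and compare them:

```r
library(painrl)

coh <- simulate_cohort(28, pal_group_params("placebo"),
                       group_label = "placebo", seed = 7)
coh
#> Simulated cohort 'placebo': 28 subjects x 144 trials (3 walk pair(s))
#>   true constrained parameter means: alpha_pain=0.655, alpha_nopain=0.344, beta=9.566

paired_switch_contrast(switch_summary(coh))
#> Switch after pain 42.7% vs after no pain 8.2% (n = 28)
#>   paired t(27) = 17.21, p = 4.41e-16, Cohen's d = 3.25

fit  <- pal_fit(coh, model = "dual",   chains = 2, iter = 1500,
                warmup = 500, thin = 5, seed = 8)
fit1 <- pal_fit(coh, model = "single", chains = 2, iter = 1500,
                warmup = 500, thin = 5, seed = 9)
fit
#> Hierarchical Q-learning fit (dual-learning-rate model), group 'placebo'
#>   28 subjects, 400 retained draws (2 chains x 1500 iter, burn-in 500, thin 5)
#>   posterior medians of constrained group-level means:
#>   alpha_pain alpha_nopain         beta
#>        0.656        0.315        8.315
#>   max split-Rhat: 1.03

waic_compare(waic(fit1), waic(fit))
#> Model A: WAIC = 3148.4 | Model B: WAIC = 3108.1
#> WAIC difference 40.32: very strong evidence for model b

check_convergence(fit)
#> Convergence: PASS (max split-Rhat = 1.030 at 'sigma_beta', threshold 1.10)
```

Reading the output: participants switch far more often after pain than
after avoided pain (a large paired effect); the fitted group-level
posterior medians recover the generating asymmetry (learning rate ≈ 0.66
after pain vs ≈ 0.32 after avoided pain at β ≈ 8.3); and the
dual-learning-rate model is very strongly preferred by WAIC, as expected
for data generated with asymmetric rates. (This example uses a light
2-chain sampler configuration; analyses of record should use the 4 × 5000
defaults.)

Real data come in through `read_pal_trials()` (CSV/TSV with a declared
column mapping and outcome dialect), and model-derived expectation
regressors go out through `pain_regressors()` +
`write_pain_regressors()`, one file per participant.

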