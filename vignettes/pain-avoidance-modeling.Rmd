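---
title: "Modeling asymmetric learning from received and avoided pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling asymmetric learning from received and avoided pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painrl)
```

## The scientific problem

In a two-option instrumental pain-avoidance task, a participant repeatedly
chooses between two stimuli whose probabilities of delivering a painful
outcome drift slowly and independently over trials. Good performance
requires continually updating an internal estimate of each option's pain
probability from two kinds of feedback: *received* pain and *avoided*
pain. A central question is whether these two teaching signals drive
learning at the same rate, and whether pharmacological manipulations of
the dopaminergic or opioidergic systems shift that balance. `painrl`
implements the computational side of that research program: task
simulation, model fitting, model comparison, posterior contrasts between
treatment groups, model-independent behavioral metrics, and export of
model-derived expectation regressors for neuroimaging analyses.

## The learning and choice model

Each option $s$ carries a value $Q_{s,t}$, the running expectation of its
outcome. Outcomes $O_t$ are coded $-1$ (pain) and $0$ (no pain), both
$Q$ values start at $-0.5$, and after every trial the **chosen** option is
updated by the delta rule

$$Q_{s,t+1} = Q_{s,t} + \alpha\,(O_t - Q_{s,t}),$$

so $Q$ always stays in $[-1, 0]$ (a convex combination of its previous
value and the outcome) and $-Q_{s,t}$ is the expected pain probability of
option $s$. The unchosen option is not updated. Two variants are fit:

* **single**: one learning rate $\alpha$ for all outcomes;
* **dual**: $\alpha_{\text{pain}}$ after received pain, $\alpha_{\text{no-pain}}$
  after avoided pain.

Choices follow a softmax over the current values,

$$P_{s,t} = \frac{e^{\beta Q_{s,t}}}{\sum_{s'} e^{\beta Q_{s',t}}},$$

with inverse temperature $\beta \ge 0$: at $\beta = 0$ both options are
equally likely; as $\beta$ grows, choice concentrates on the option with
the lower expected pain probability.

### Parameters, units, defaults

| parameter | range | role |
|---|---|---|
| $\alpha_{\text{pain}}$, $\alpha_{\text{no-pain}}$ | $[0, 1]$ | fraction of the prediction error incorporated per outcome type |
| $\beta$ | $[0, 20]$ | choice determinism (unitless inverse temperature) |

The $[0,20]$ cap on $\beta$ comes from its constraining transform (below);
at $\beta = 20$ a value difference of 0.25 already yields a ~99% choice
probability, so the cap is not binding in practice.

## Hierarchical estimation

Subject-level parameters are modeled on an unconstrained scale as draws
from group-level normal distributions, one independent model per
treatment group. We use the non-centered form
$\theta_s = \mu + \sigma z_s$, $z_s \sim \mathcal N(0,1)$, with
hyperpriors $\mu \sim \mathcal N(0, 1)$ and
$\sigma \sim \text{half-Cauchy}(0, 5)$, and map unconstrained values to
the working ranges with the inverse-probit transform: rates as
$\Phi(\theta)$, $\beta$ as $20\,\Phi(\theta)$. The reported "group-level
mean" on the constrained scale is $\Phi(\mu)$ (and $20\,\Phi(\mu)$ for
$\beta$), the conventional summary for this model family.

### Sampler

Inference uses an adaptive component-wise Metropolis-within-Gibbs sampler
implemented in compiled code. Design choices that matter:

* **Non-centered parameterization** improves the geometry when the data
  constrain single subjects weakly.
* **Interweaved centered updates.** After each sweep, the subject-level
  unconstrained values $\theta_s$ are held fixed while $\mu$ is redrawn
  from its exact (conjugate normal) conditional and $\log\sigma$ from a
  cheap prior-only Metropolis step, then $z$ is recomputed. Alternating
  the two parameterizations (an ancillarity–sufficiency interweaving
  scheme) decorrelates the hyperparameters from the subject-level
  deviations and is the main reason the hyperparameter chains mix well.
* **Joint subject moves.** Within a subject, learning rates and $\beta$
  are posterior-correlated (the classic $\alpha$/$\beta$ tradeoff), so in
  addition to component-wise updates each subject receives an isotropic
  joint proposal over its deviations.
* **Adaptation only during burn-in.** Proposal scales are tuned toward
  ~44% (component-wise) and ~23% (joint) acceptance in diminishing
  batches during the burn-in phase and frozen afterwards, so retained
  draws target the exact posterior.
* **Sweeps.** Each recorded iteration performs 3 full update sweeps
  (`sweeps = 3`), trading CPU for lower autocorrelation at a fixed
  retained-draw count.

Defaults are 4 chains of 5000 iterations, 1000 burn-in, thinning 5,
giving 3200 retained draws (800 per chain). Per-chain seeds derive
deterministically from one master seed, and chains start from
overdispersed initial values. Convergence is assessed with split-Rhat on
every monitored quantity (group-level means and SDs on both scales, and
all subject-level constrained parameters), with the conventional 1.1
threshold; constant (zero-variance) chains return Rhat 1 by convention
but are a degenerate case the printed diagnostics make visible. The
sampler was validated two ways: against brute-force likelihood
recomputation (the sequence likelihood agrees with an explicit
trial-by-trial oracle to 1e-10), and by prior recovery — with zero-length
data the chains reproduce the $\mathcal N(0,1)$ and half-Cauchy(0,5)
hyperpriors to Monte-Carlo accuracy.

### Model comparison and posterior summaries

Model fit is compared with WAIC on the deviance scale from the
per-subject pointwise log-likelihood matrix (one value per participant
per draw; a per-trial pointwise variant is available via
`waic(fit, pointwise = "trial", data = ...)`):
$\text{lppd} = \sum_i \log \tfrac1D \sum_d e^{\ell_{id}}$ (computed by
log-sum-exp), $p_\text{WAIC} = \sum_i \text{Var}_d(\ell_{id})$,
$\text{WAIC} = -2(\text{lppd} - p_\text{WAIC})$. Differences of 2–6 /
6–10 / >10 are graded positive / strong / very strong evidence.

Group contrasts subtract the constrained group-level mean draws of two
independently fitted groups, paired by draw index (the fits are
independent, so the pairing is a convention; `shuffle = TRUE` confirms
insensitivity). HDIs use the shortest-sorted-window algorithm: the
narrowest window of $\lceil \text{mass} \cdot n \rceil$ consecutive
sorted draws. This assumes unimodality; a clearly bimodal sample (two
pronounced density peaks separated by a deep valley) triggers a warning
rather than a multi-interval result.

## The synthetic task and cohort generator

The generator emulates the study conditions: 144 trials in 4 runs; two
per-option pain-probability series following independent Gaussian random
walks reflected into $[0.1, 0.9]$ (starts 0.35/0.65, per-trial step SD
0.025), rejection-resampled (up to 1000 attempts) until the pair crosses
at least once; three walk pairs per cohort, each administered to about a
third of subjects; Bernoulli outcome delivery; softmax Q-learning agents;
and a 1.2% per-trial lapse rate producing missed responses resolved by a
uniform random choice. The walk start/step/bounds values are package
defaults chosen once to match the published task's qualitative range and
volatility — the original generative walk parameters are not public — and
are all exposed as arguments.

Group-level simulation presets use the reported posterior medians
(placebo 0.72/0.32/8.8; levodopa 0.66/0.66/5.3; naltrexone 0.72/0.76/5.7;
generic "drug" 0.70/0.70/5.5). Between-subject spread on the
unconstrained scale defaults to 0.5, a realistic value for this model
family chosen once and documented here; it is not printed in the source
study.

What the generator does *not* emulate: reaction times and their
dependence on outcome history, skin-site habituation, temperature
calibration (49 vs 50 °C), inter-trial and anticipation timing, and any
within-session drift in engagement. Passing tests on synthetic cohorts
therefore demonstrate the estimation machinery's correctness and the
internal consistency of the analysis pipeline on data that obey the
model; they cannot certify how well the model describes real
participants.

## Parameter recovery and what it shows

`run_recovery()` chains generator → fit → summaries. Two facts about
recovery at the study's scale (28 subjects × 144 trials) are worth
stating plainly:

* The group-level mean of a cohort of 28 subjects drawn with
  unconstrained SD 0.5 has a sampling SE of about $0.5/\sqrt{28} \approx
  0.09$ probit units (≈ 0.75 on the $\beta$ scale near its preset), so a
  recovered median can sit a full unit from the generating value without
  any estimation bias. Recovery across many seeds is unbiased (checked at
  n = 120, where medians land within ~0.02/0.4 of truth), but
  single-cohort errors at n = 28 occasionally reach the edge of the
  package's frozen tolerances (±0.12 for rates, ±2.0 for $\beta$).
* The scientifically load-bearing contrasts are robust: the presence
  (placebo-like) vs absence (drug-like) of the learning asymmetry, and
  the joint recovery of a high no-pain learning rate *with* a low
  $\beta$ in the drug-like scenario (the $\alpha/\beta$ tradeoff is
  disentangled, not an estimation artifact).

The reduced mode (`reduced = TRUE`: 2 chains × 1500 iterations) retains
only 400 draws; its Rhat estimates are correspondingly noisy and its
tolerances looser. Full-scale runs are held to Rhat < 1.1.

## Behavioral metrics

Model-independent measures mirror the study's analyses: per-subject pain
counts; switch rates conditioned on the previous outcome (transitions
involving a missed response are excluded by default, since the recorded
choice was not the participant's own, while pain counts always count all
delivered stimuli); a paired t test with Cohen's d for the after-pain vs
after-no-pain switch-rate difference; a one-way ANOVA with $\eta^2$
across treatment groups; and a per-subject logistic regression of
switching on pain indicators at lags 1–6, aggregated across subjects
(matching subject-wise error-bar reporting). Deterministic policies
(e.g. strict lose-shift) separate perfectly in the logistic regression;
such subjects are retained via a small ridge penalty and flagged rather
than dropped.

## Numerical choices and edge cases

* Softmax and lppd computations use log-sum-exp stabilization.
* Walk reflection is applied repeatedly, so even pathological step sizes
  stay in bounds.
* `update_q` validates $\alpha \in [0,1]$ and $O \in \{-1, 0\}$; the
  convexity of the update is what keeps $Q \in [-1, 0]$ invariant.
* Q values reset to $(-0.5, -0.5)$ only at the start of a participant's
  full sequence, not per run, matching the concatenated-run analysis
  convention.
* Missed trials stay in the likelihood by default (the participant still
  observed the outcome); `include_missed = FALSE` drops them.
* Trial tables accept three outcome dialects (`pain`/`no_pain`, 1/0 with
  1 = pain, −1/0) and arbitrary two-level choice labels; indices are
  1-based in files.
* Ties and degenerate inputs: strict inequalities in
  `proportion_greater` (identical draws give 0), point-mass samples give
  zero-width HDIs, zero-variance log-likelihood draws give
  $p_\text{WAIC} = 0$ exactly.

## Problem sizes used in the shipped checks

The package's own test suite runs the full analysis at the study's scale
where it matters (parameter recovery and the three-group synthetic study
at 26–29 subjects × 144 trials with the default sampler) and uses the
reduced sampler configuration with 10–14 subjects for replicated
properties (model selection across 10 cohorts, behavior equivalence
across 20 cohort pairs), keeping the whole suite to a few minutes of CPU
while exercising every pipeline stage end to end.

## Known limitations

* The sampler is a random-walk scheme; it is validated and well mixed at
  this model's scale but would need gradient-based methods for much
  larger hierarchies.
* WAIC with per-subject pointwise units estimates subject-level
  out-of-sample accuracy; with only ~28 subjects its Monte-Carlo noise is
  several deviance units, so small differences between models should not
  be over-read — the evidence grades encode this.
* The walk parameters are package choices; absolute levels of simulated
  pain counts vary noticeably with the three realized walk pairs of a
  cohort, so cohort-level behavioral statistics carry that extra
  variance.
* No reaction-time model, no single-subject maximum-likelihood mode, and
  no regressor convolution — expectation series are exported raw for
  downstream GLM tooling.
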