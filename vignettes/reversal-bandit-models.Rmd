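---
title: "Latent-state observer models for reversal bandit behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-state observer models for reversal bandit behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revbandit)
library(dplyr)
```

## The task and what the package models

revbandit models behaviour in a two-armed probabilistic reversal task.
Two options deliver reward stochastically; in the *correlated* environment
the two reward probabilities are anti-phased between two latent states
(when one option is good the other is poor, and abrupt reversals exchange
them), while in the *uncorrelated* environment each option's probability
changes independently. An observer that knows only the outcome of each
chosen trial must track the options' values — and, in the correlated task,
the probability that the world has just reversed.

The package contains four layers, all operating on plain tibbles so they
compose with the pipe:

1. a **synthetic task generator** (schedules, trial timing, Bernoulli
   outcomes),
2. two **grid-based Bayesian observers** producing trial-wise estimates,
3. a **switch/stay choice layer** (simulation, maximum-likelihood fitting,
   AIC model comparison, perturbed-policy presets), and
4. **behavioural statistics** (consecutive-error switch rates, per-session
   logistic regressions with two-stage group inference, a two-factor
   ANOVA).

## Reward schedules

`gen_correlated_schedule()` draws 1–7 latent-state reversals per
170-trial session, uniformly over all placements that leave every block
at least `min_block = 15` trials long, so reversal timing is independent
of behaviour. Base reward levels are 0.9 (good option) and 0.05 (poor
option). Real schedules of this kind are strongly but not perfectly
anti-correlated, and we emulate that with two mechanisms:

* each block's levels carry independent Gaussian jitter
  (`level_jitter = 0.08`, clipped to [0, 1]);
* at each reversal the two options change level after independent uniform
  lags of 0–11 trials (`reversal_lag`), so the switch is not exactly
  simultaneous.

The lag is the dominant decorrelator, and the pair (0.08, 11) was
calibrated once, by simulation, so the population mean Pearson
correlation between the two per-trial probability series is close to
−0.8 while every individual schedule remains negatively correlated. A
pure per-block jitter cannot do this: with a single reversal the two
series are affine functions of the block indicator, so their correlation
is exactly ±1, and jitter large enough to move the mean to −0.8 flips
the sign of some schedules.

`gen_uncorrelated_schedule()` toggles each option independently between
its (jittered) high and low levels with probability
`change_rate = 0.02` per trial — about three to four changes per option
per session, comparable to the volatility of the correlated task. Since
a single random draw of two independent step series can still be
substantially correlated by chance, the generator applies a design
criterion, as an experimenter constructing genuinely uncorrelated
schedules would: candidate pairs are redrawn until the realized |r| is
at most `max_abs_r = 0.2` and both options change at least once.

```{r schedule}
sch <- gen_correlated_schedule(seed = 1)
cor(sch$p_left, sch$p_right)
attr(sch, "reversal_trials")
```

### Trial timing

Inter-trial intervals are uniform on [6.5, 7.5] s. The action–outcome
delay is bounded in [0.103, 8.770] s with mean 3.394 s and variance
0.605 s²; only these four numbers are known, so a distribution family
must be chosen. We use a scaled Beta on the stated support with shape
parameters solved from the standard Beta moment equations
(α ≈ 10.72, β ≈ 17.52) — a smooth, unimodal, bounded choice whose sample
moments converge to the targets. The true empirical delay distribution
may of course have had a different shape.

## The two observers

Both observers maintain, for each option separately, a joint probability
mass function over a hypothesis grid with the option's reward
probability `v` on one axis (101 points, 0 to 1 in steps of 0.01) and a
volatility parameter on the other (31 points, 0 to 0.3 in steps of
0.01). Beliefs start uniform.

On every trial the chosen option's belief is multiplied cellwise by the
outcome likelihood (`v` for a reward, `1 − v` for a non-reward) and
renormalized. Then a transition function carries both options' beliefs
into the next trial's priors:

* **Model 2 (latent-state / reversal model).** The auxiliary axis is the
  reversal rate `H`. Within each slice `H = j`, the value distribution
  becomes a mixture of the previous posterior (weight `1 − j`) and a
  uniform distribution (weight `j`), then the joint is renormalized. A
  uniform joint is a fixed point of this leak, and the `H = 0` slice is
  untouched — with all mass at `H = 0` the model reduces exactly to
  Beta-binomial accumulation.
* **Model 1 (drift model).** The auxiliary axis is the standard
  deviation σ of a Gaussian drift kernel. Within each σ slice the value
  marginal is convolved with a discrete Gaussian of that width,
  truncated at the [0, 1] boundary and renormalized per slice so no mass
  escapes the support (a reflecting kernel is the obvious alternative;
  truncation was chosen for simplicity and exact mass conservation).

Because the likelihood is flat across the auxiliary axis while the
transition is not, the marginal over `H` (or σ) is itself updated by the
data: surprising outcomes favour high-volatility slices.

### Trial-wise estimates

At decision time (before the outcome) the observer reports, per option:
the value point estimate — the **mode** of the value marginal for
model 2 and its **mean** for model 1, preserving the asymmetry of the
original analyses (both estimators are available through
`point_estimates()`) — and the 95% credible width (2.5th to 97.5th
centile). Model 2 additionally reports the reversal estimate
(the expected `H` of the chosen option) and the reversal EV (the
expected value of the unchosen option, i.e. the expected worth of
switching). Across each outcome update the Kullback–Leibler divergence
of the `H` marginal (model 2) or of the chosen option's value marginal
(model 1) is recorded as the belief-update signal.

Numerical conventions, all chosen once:

* mode ties break toward the smallest grid value;
* quantiles interpolate the cumulative mass linearly with each grid
  point's mass located at the point; zero-mass points are dropped and
  plotting positions are scaled so the first and last occupied points
  map to 0 and 1 (the weighted analogue of the type-7 sample quantile).
  Under this convention the uniform marginal has width exactly 0.95 and
  a point mass has width 0;
* all computation is in linear space with renormalization each step and
  a 1e-300 floor before normalization; an exactly zero posterior (which
  cannot arise from a uniform start) raises an explicit error.

```{r observer}
ses <- simulate_session(sch, seed = 1)
trace <- run_observer(ses, model = "model2")
trace |>
  select(trial, choice, outcome, chosen_prob, chosen_unc,
         reversal_estimate, reversal_dkl) |>
  head(5)
```

## The choice layer

The study never prints the likelihood behind its per-session AIC
comparison, so the choice model here is a documented **reconstruction**:
a Bernoulli switch/stay policy whose log-odds of abandoning the
previously held option are a linear function of the same regressors the
behavioural analyses use — the chosen-minus-unchosen probability
difference, the uncertainty difference, and (for model 2 policies) the
reversal estimate. It is the minimal policy consistent with those
analyses; model 2 policies have four free parameters, model 1 policies
three, and AIC = 2k − 2·loglik. The first trial of a session has no
previous choice and is excluded from the likelihood; the simulated agent
picks its first side at random.

Fitting uses BFGS from ten random starts (uniform in [−5, 5] per
weight, plus the null start) on the analytic negative log-likelihood;
the problem is convex so the multi-start is belt-and-braces.
Non-convergence is flagged, not thrown.

### Agent presets

The intact ("sham") agent is **environment-adapted**, which mirrors the
animals' knowledge of the task structure: in correlated sessions it runs
the model 2 observer with a reversal-sensitive policy, and in
uncorrelated sessions the model 1 observer with a value/uncertainty
policy and no reversal term (`condition_policy()`). This adaptation is
what produces the observed flip of AIC preference between environments
and the condition difference in the fitted reversal-estimate
coefficient; a single fixed policy in both environments would, by
construction, be described better by its own generating model
everywhere.

The perturbation presets (`tus_preset()`) encode the qualitative
disruption signatures as sign/zero patterns relative to sham: dmPFC —
switching driven only by the held option's value (chosen-value term,
no uncertainty or reversal weights); hippocampus — reversal weight
removed, uncertainty weight increased; thalamus — reversal weight
sign-flipped, uncertainty weight increased. Magnitudes were calibrated
by simulation so cohorts show these patterns alongside realistic switch
rates (overall ~0.15, ~0.4 after a single non-reward); the printed
coefficients of the original study are not targets.

## Behavioural statistics

`consecutive_error_switch()` classifies each trial by the exact number
of consecutive non-rewards for the repeatedly chosen option immediately
before it (a switch or a reward resets the run), so a run surviving to
length three contributes one observation at each of lengths 1, 2 and 3 —
nested observation counts, with the switch rate at each length computed
over those trials.

`build_design()` + `logistic_irls()` implement the per-session switch
regressions. Two variants exist: difference coding (probability
difference, uncertainty difference, reversal estimate) and separate
option terms. Regressors are z-scored within session so coefficients
are comparable across sessions (the emitted scale factors make this
reversible); whether the original per-session fits standardized is not
stated, so this is a package convention. The solver is plain
Newton/IRLS to 1e-8 with standard errors from the inverse observed
information and a coefficient-norm guard (25) that flags perfect
separation instead of failing.

Group inference is deliberately **two-stage**: per-session ML fits, then
one-sample and two-sample tests (t and rank variants) on the
coefficients. Refitting the full random-slope hierarchical models is out
of scope here; the long-format coefficient tables are designed to be
exported for that purpose. No multiple-testing correction is applied by
default; a Holm option exists.

`anova_session_by_errors()` runs the standard two-factor ANOVA (group ×
run length, one observation per session × run length) and reports the
interaction row.

`recover_parameters()` quantifies identifiability: it simulates a
cohort from known weights and reports the pooled (fixed-effects) ML
estimate with its error, alongside the spread of per-session fits. The
pooled fit is the right recovery summary at this scale — individual
170-trial sessions contain only ~25 switch events, so per-session
logistic estimates carry substantial outward small-sample bias, while
the pooled estimate recovers all four sham weights to within a few
percent over 30 sessions.

## What the simulations do and do not show

The synthetic agent reproduces, at desk scale: the schedule correlation
structure; the AIC preference flip between environments; the intact sign
pattern of the switch regressions (negative bias, negative value
difference, positive reversal estimate, larger in correlated sessions);
the perturbation signatures; and higher switching after two or three
consecutive non-rewards in correlated than uncorrelated sessions.

One group-level phenomenon is **not** reproducible within this
architecture, and the corresponding check is expected to fail: the
session-type × error-number interaction in the ANOVA. For any memoryless
logistic policy driven by belief estimates, the aggregate switch-rate
profile across run lengths self-flattens — trials that reach run length
r + 1 are precisely those whose regressors favoured staying at run
length r, and this selection cancels the escalation of the evidence. The
escalating profile seen in real correlated sessions (switching roughly
half again as likely after two errors as after one) requires failures of
the chosen option to also *raise* the estimated value of the unchosen
option. That cross-option inference is a documented extension point of
the observer (an alternative update rule can be plugged into the
observer step) but is intentionally not implemented here.

Other limitations worth keeping in mind: the delay distribution's shape
and the block-length distribution between reversals are package choices
constrained only by printed summaries; the choice likelihood is a
reconstruction, so AIC difference magnitudes are not comparable to the
original figure, only their sign pattern; and simulated agents have no
lapses, session drift, or motor errors, so per-session coefficient
spreads are tighter than real behavioural data.

## Problem sizes

The test-suite simulations use 170-trial sessions throughout, with
cohorts of 40 + 40 sham sessions for the model-comparison and
regression-pattern checks, 24 sham + 3 × 18 perturbed sessions for the
disruption contrasts, 30 sessions for parameter recovery, and 30 + 30
sessions for the consecutive-error analyses; generator calibration
checks use 35–1000 schedules and 100,000 timing draws. These sizes match
or slightly exceed the original study's session counts per condition.
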