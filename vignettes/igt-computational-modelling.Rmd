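---
title: "Computational modelling of Iowa Gambling Task choice data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational modelling of Iowa Gambling Task choice data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igtrl)
library(dplyr)
```

## The task and its payoff structure

The Iowa Gambling Task (IGT) asks a participant to make 100 selections from
four card decks. Decks A and B pay a constant 100 RMB per draw but carry
losses averaging 125 RMB per draw, for a long-run net of **−25 RMB per
card**; decks C and D pay 50 RMB with losses averaging 25 RMB, for **+25 RMB
per card**. Losses arrive with fixed frequencies: deck A loses one of
150/200/250/300/350 with 10% probability each, deck B loses 1250 with 10%
probability, deck C loses 25 (12.5%), 50 (25%) or 75 (12.5%), and deck D
loses 250 with 10% probability. Play starts from a 2000 RMB bankroll, and
the 100 trials are scored in five blocks of 20; the fraction of C/D choices
per block is the classic learning curve.

`igt_schedule()` realises these frequencies *exactly* rather than by
sampling: each deck's card order is built from fixed-length cycles (10 cards
for A, B, D; 8 for C) that each contain precisely the loss multiset the
probabilities imply, with positions shuffled deterministically within each
cycle from a seed. This mirrors labs' practice of administering a
predetermined card order identical across participants, keeps every draw's
expected value exact over whole cycles, and makes all downstream simulation
reproducible bit-for-bit. Positions past the stored order wrap by whole
cycles, so the guarantees hold for arbitrarily long simulations. The
bankroll may go negative; no bankruptcy rule stops play.

A participant-level quality-control filter (`qc_filter()`) excludes anyone
who selected some deck five times or fewer out of 100 (threshold
`floor(0.05 * n_trials)`), the standard screen for insufficient exploration.

## The trial-level models

All models share one skeleton: a utility of each trial's net outcome, a
per-deck expectancy update, and a softmax choice rule. Net outcomes are
divided by `outcome_scale` (default 100) before the utility — payoffs in
the hundreds raised to a power and multiplied by a softmax sensitivity
overflow otherwise, and rescaling by 1/100 is the convention in this
modelling literature. Whether to rescale is exposed as an argument because
different labs differ.

**Prospect-valence utility** (`utility_pv()`), with outcome sensitivity
$\alpha \in (0,2)$ and loss aversion $\lambda \in [0,5]$:

$$u(x) = \begin{cases} x^{\alpha} & x \ge 0 \\ -\lambda |x|^{\alpha} & x < 0 \end{cases}$$

**PVL-Delta** updates only the chosen deck's expectancy with learning rate
$A$: $E \leftarrow E + A\,(u - E)$. **PVL-DecayRI** instead decays every
deck, $E_j \leftarrow A\,E_j$, then adds $u$ to the chosen deck. The same
symbol $A$ is a learning rate in the first model and a decay/recency weight
in the second; the two parameter constructors keep them apart.

**VPP** (Value-Plus-Perseverance, 8 parameters) adds a perseverance
strength $P_j$ that decays by $K$ every trial and receives an impulse on
the chosen deck — $\varepsilon_p$ after non-negative outcomes,
$\varepsilon_n$ after losses (break-even counts as a gain, following the
update rule's $x \ge 0$ condition). Deck values mix the two systems with
the reinforcement-learning weight $\omega$:
$V_j = \omega E_j + (1-\omega) P_j$. Expectancies follow the delta rule;
although one could pair perseverance with decay-rule learning, the VPP
parameter reported as a "learning rate" in this literature is the
delta-rule $A$, and that is what the package implements.

**Choice rule.** Selection probabilities are a softmax over deck values
with sensitivity $\theta = 3^{\mathrm{cons}} - 1$,
$\mathrm{cons} \in [0,5]$: `cons = 0` is fully random responding and
`cons = 5` near-deterministic exploitation. The softmax is computed with
max-subtraction, so extreme values cannot overflow. Latent states start at
$E = P = 0$, making the first trial uniform — the standard initialisation
when nothing has been observed.

`sequence_loglik()` walks a subject's trials in order, scoring the observed
choice *before* updating the state with the observed outcome, and returns
the per-trial log-likelihood vector needed by the information criteria. The
hot loop is compiled (Rcpp); the test suite checks it against an
independent plain-R scalar implementation to 1e-10 across random models,
parameters and sequences, and checks the nesting identity that VPP with
$\omega = 1$, $\varepsilon_p = \varepsilon_n = 0$ reproduces PVL-Delta
exactly. The registry (`model_registry()`, `register_igt_model()`) lets
further models — e.g. outcome-representation learning variants — plug into
the same fitting and comparison machinery.

## Synthetic cohorts

Because raw participant data for this task are typically not deposited, the
generator is a first-class module. `cohort_spec()` describes a group by
per-parameter means and SDs on the natural scale; subjects' true parameters
are drawn from normals truncated at the parameter bounds (the minimal
assumption honouring both the published group summaries and the bounds;
the unbounded perseverance impacts are drawn untruncated), and each subject
then plays the task generatively via `simulate_agent()`. Ready-made specs
(`hc_cohort_spec()`, `mud_cohort_spec()`, `mud_t_pre_spec()`) carry
published VPP group summaries for healthy controls (n = 39),
methamphetamine users (n = 50) and the treated subgroup (n = 24);
`rtms_post_shift()` holds the published pre-to-post mean changes, applied
additively to each subject's true parameters and truncated at the bounds.
Paired craving scores (1–100 scale) come from a normal with pre mean 66.0
(SD 17.6) and post mean 34.6 (SD 13.8), rounded to integers (optionally to
tens, since patients tend to report round numbers) and clipped to the
scale. One master seed fixes parameters, choices and cravings end-to-end.

What the generator does *not* emulate: between-parameter correlations
within subjects (unreported in the source literature; independence is
assumed), non-stationarity within a session, and any dependence of craving
on task behaviour. Passing tests on these cohorts therefore demonstrate
correctness of the machinery under the stated distributional assumptions,
not fidelity to every property of real patients.

A caveat worth stating plainly: group summaries published for this task
come from hierarchical fits whose per-subject estimates are strongly
shrunken, so their SDs are far smaller than the spread that independent
per-subject estimation can resolve from 100 trials. Simulated at face
value, such cohorts produce groups whose *choice statistics* overlap almost
completely even though their true parameters differ sharply — see
"Identifiability" below.

## Estimation

`fit_map()` maximises log-likelihood plus log-prior per subject on an
unconstrained scale: bounded parameters are represented as
`upper * pnorm(z)` and `z` receives a standard-normal prior (equivalent to
a uniform prior over the bounded range), the perseverance impacts an
identity link with a normal prior. Eight restarts are drawn from the prior;
ties break by the highest objective then the lowest restart index, so fits
are deterministic given the seed. With `laplace_draws > 0` the fit also
samples from a normal approximation at the optimum — with the covariance
eigenvalue-capped at the prior variance, since the inverse Hessian explodes
along likelihood-flat directions — giving per-draw pointwise
log-likelihoods for WAIC/LOO on MAP fits. These Laplace draws are a cheap
surrogate; for model comparison proper the MCMC draws below behave much
better.

`fit_hierarchical()` places a group-level normal on each unconstrained
parameter, `z_i ~ N(mu, sigma)`, with `mu ~ N(0,1)` and
`sigma ~ half-N(0, 0.2)` (scale configurable). The sampler is adaptive
Metropolis-within-Gibbs: coordinate-wise random-walk updates for subject
vectors, conjugate Gibbs for `mu`, random-walk on `log sigma`, plus a joint
translation move that shifts `mu` and all subjects' `z` together — without
it, weakly identified directions mix extremely slowly when the group scale
is small. Split R-hat and effective sample size are reported for every
sampled quantity, and any R-hat above 1.1 attaches a non-convergence
warning to the result. Both group-level summaries are emitted (the
natural-scale transform of `mu` and the mean of subject-level means), since
published tables rarely say which convention they use. Default test-scale
settings are 2 chains × 500 iterations (250 warmup); real analyses should
raise these.

`posterior_predict()` simulates replicate cohorts from fitted parameters
(a posterior draw per subject per replicate, or point estimates for plain
MAP fits) and summarises block-wise advantageous-choice curves and deck
frequencies against the observed data.

## Model comparison

`waic()` implements the standard pointwise formulation
(`lppd - p_waic`, multiplied by −2, with observation-wise standard
errors); `looic()` implements Pareto-smoothed importance-sampling
leave-one-out: per-observation importance ratios, a generalized-Pareto fit
to the largest `min(0.2 S, 3 sqrt(S))` weights by the Zhang–Stephens
profile-posterior method, tail replacement by expected order statistics,
truncation at the raw maximum, and flagging of observations with shape
k > 0.7. Observations are *trials* (the convention of hierarchical IGT
modelling software); `compare_models()` assembles the criteria per
candidate, verifies the fits share an identical cohort, and ranks by LOOIC
with WAIC as tie-break. When the top two models sit within one standard
error, the pipeline reports both and breaks the tie by a configured
preference order.

## Group statistics

The statistical battery mirrors how clinical IGT studies are analysed:

* `independent_t()` — Levene's test (mean-centred; median-centring
  available) gates between the pooled test (df `n1 + n2 − 2`) and Welch's
  test with Satterthwaite df at p < 0.05. Cohen's d always uses the pooled
  SD.
* `t_from_summaries()` — the same tests computed from published means/SDs/ns
  alone, used for worked-example checks against printed tables.
* `paired_t()` — df `n − 1`, d = mean difference over SD of differences.
* `mixed_anova()` (Time within × Group between) and `rm_anova()`
  (Time × Block within) — hand sums-of-squares decompositions reporting
  partial $\eta^2$ = SS_effect / (SS_effect + SS_error) per stratum; the
  test suite verifies both against `stats::aov` Error-stratum output, and
  the algebraic identity that the 2×2 mixed interaction F equals the
  squared independent t on difference scores.
* `pearson_r()` — df `n − 2`, two-sided p via the t transform.

Tests are two-sided at α = 0.05 and no multiplicity correction is applied,
matching the analysis conventions of the studies this package emulates.
Constant data yield F = 0 rather than 0/0; degenerate t inputs (zero
variance with equal means, all-zero paired differences) raise errors
instead of returning NaN.

## The pipeline

`run_pipeline()` chains the stages — ingest or simulate, QC, fit every
configured model, compare, select the winner, then the statistics battery
on the winner's estimates (between-group contrasts per parameter, paired
pre/post contrasts, craving mixed ANOVA and advantageous-rate
repeated-measures ANOVA where the data support them, and correlations of
parameter change against craving change). Artifacts are CSV/JSON plus a
provenance log carrying the seed and a config hash; identical config and
seed reproduce identical tables. A thin command-line wrapper ships in
`inst/scripts/igt-pipeline.R`.

```{r, eval = FALSE}
cfg <- list(
  input = list(synthetic = list(model = "vpp", groups = list(
    HC  = list(n = 39, means = as.list(hc_cohort_spec()$means),
               sds = as.list(hc_cohort_spec()$sds)),
    MUD = list(n = 50, means = as.list(mud_cohort_spec()$means),
               sds = as.list(mud_cohort_spec()$sds))))),
  models = c("pvl_delta", "pvl_decay", "vpp"),
  seed = 1, outdir = "igt-run")
bundle <- run_pipeline(cfg)
bundle$comparison
```

## Identifiability and known limitations

Parameter recovery — simulate from known parameters, refit, correlate — is
the package's central validity experiment, and its results are intentionally
reported without varnish:

* **Response consistency recovers well** (true-vs-estimated r ≈ 0.6 at 30
  subjects × 100 trials) because it directly scales choice determinism.
* **Outcome sensitivity α barely recovers at published group spreads.** A
  single 100-trial session carries a per-subject standard error of ~0.76
  for α (one-parameter Fisher information, all else known), while published
  group SDs are ~0.05–0.09. The attainable truth–estimate correlation,
  `sd_true / sqrt(sd_true² + SE²)`, is then below 0.1 — no estimator can do
  better, and shrinkage cannot raise a correlation that is invariant to
  linear rescaling. Learning rate and loss aversion sit in between.
* The α–cons ridge (compressing utilities while raising sensitivity leaves
  likelihood nearly unchanged) and the ω–perseverance trade-off make the
  full VPP weakly identified at 100 trials; hierarchical pooling stabilises
  group-level location but cannot conjure per-subject information that the
  data do not contain.
* Consequently, group contrasts computed on *fitted* parameters of cohorts
  simulated at published summary values are far weaker than contrasts on
  the true parameters; with published SDs taken at face value the groups'
  behaviour overlaps almost entirely. Studies achieving sharp group
  separations on fitted parameters are, implicitly, reporting strongly
  shrunken hierarchical summaries.
* Model *recovery* is healthier than parameter recovery: with MCMC draws,
  LOOIC prefers PVL-Delta on delta-generated data and VPP on
  perseverance-heavy data in a large majority of replicates (the nested
  model wins by small margins, as complexity penalties predict).

Numerical choices worth knowing: payoff rescaling divisor 100 (argument);
probit transforms with inputs clipped to ±qnorm(1e−12) to avoid infinite
z; softmax max-subtraction; PSIS smoothing skipped (weights left raw) when
fewer than five tail points or zero tail variance, which makes degenerate
all-identical-draw matrices collapse exactly to `−2 Σ log-lik`; R-hat
returns 1 for zero-variance chains. Problem sizes in the test suite (30
recovery subjects, 10 direction replicates, 20 model-recovery replicates at
12 subjects, 2 × 400 MCMC iterations) are the package's chosen
scaled-down experiment sizes; all are arguments, and larger runs only
sharpen the reported rates.
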