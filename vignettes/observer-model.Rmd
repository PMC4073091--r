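---
title: "The Bayesian observer model behind selfpriors: assumptions, parameters, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Bayesian observer model behind selfpriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfpriors)
```

## The scientific question

When people act toward a goal — here, stopping a fast-moving ball exactly
under a target — their later report of where the ball actually stopped is
biased toward the target. The same bias exists, but is weaker, when they
merely watch the action being performed. `selfpriors` implements the
Bayesian-observer account of this asymmetry: perception combines a Gaussian
prior over outcomes, centred on the goal, with Gaussian-noisy sensory
evidence about the true outcome. If the prior for one's *own* actions is
narrower than the true distribution of one's performance, it is
"optimistic": it pulls perception toward success more strongly than the
actual statistics of performance justify. The package provides a synthetic
cohort generator with this population structure, the maximum-likelihood
fitting machinery that recovers the priors from trial data, and the group
statistics that test the optimism hypothesis.

## The observer model

On each trial the true final position $x$ is observed through noisy
evidence ($\sigma_\mathrm{evidence}$) and combined with a prior centred on
the target ($\bar{x}_\mathrm{prior}$, $\sigma_\mathrm{prior}$). The
posterior-maximizing estimate is the reliability-weighted average

$$ x_\mathrm{estimate} = w\,\bar{x}_\mathrm{prior} + (1-w)\,\bar{x}_\mathrm{evidence},
\qquad
w = \frac{\sigma^2_\mathrm{evidence}}{\sigma^2_\mathrm{prior} + \sigma^2_\mathrm{evidence}}. $$

Writing the estimate relative to the truth gives the identity the analysis
leans on throughout: **estimation error $= -w \times$ performance error**,
so an ordinary regression of estimation error on performance error measures
the prior weighting directly, and its residual SD estimates
$(1-w)\,\sigma_\mathrm{evidence}$.

### The likelihood

The observer account is usually stated without an explicit report likelihood;
the package
takes the unique two-parameter Gaussian form consistent with the
optimal-estimate equation: conditional on the truth, the report is Normal
with mean $w(\bar{x}_\mathrm{prior} + \mathit{shift}_\mathrm{prior}) +
(1-w)(x + d\cdot \mathit{shift}_\mathrm{evidence})$ (direction $d = \pm 1$)
and SD $(1-w)\,\sigma_\mathrm{evidence}$. No separate motor/pointing noise
term is included: with only the slope and residual SD observable, an extra
noise term is not identifiable from $(1-w)\sigma_\mathrm{evidence}$, and the
model families fitted here carry exactly two SD parameters per condition.

### Model families and parameter tying

`model_preset()` ships the five tying schemes the analyses use. With self
and agent conditions and one motion direction: a full model (prior SD and
evidence SD per condition, 4 parameters) and two reduced models tying the
evidence SD or the prior SD across conditions (3 parameters each). With two
motion directions and shifts freed: per condition a prior SD, a prior shift
and a direction-coupled evidence shift, with the evidence SD per condition
and direction (10 parameters) or tied across direction (8).
`count_free_params()` is a pure function of the spec and the factor levels
present, so the same presets adapt to single-condition (self-only) data.

## Fitting: numerical choices

* Coordinates: log SDs and raw shifts. Box bounds
  $\log \sigma \in [\log 0.1, \log 10^9]$ px, shifts $\pm 1000$ px.
* Optimizer: L-BFGS-B with **analytic gradients**. The default
  finite-difference gradient stalls on shift models because px-scale shift
  coordinates and log-scale SD coordinates share one step size; the analytic
  gradient removes the failure and most of the cost.
* Multi-start: a moment-based start from the error regression (slope
  $\to w$, residual SD $\to \sigma_\mathrm{evidence}$) plus 7 random
  restarts with log-uniform SDs in $[1, 10^4]$ px; best restart wins.
  Convergence at `factr = 1e7` (about $10^{-9}$ relative on the NLL).
* Flat priors: when the data carry no prior pull, the profile likelihood in
  $\sigma_\mathrm{prior}$ is flat at the top; if raising a prior SD to the
  upper bound changes the NLL by $\le 10^{-6}$ nats the fit reports the
  bound, so `classify_flat()` (strictly $> 10^7$ px) flags it
  deterministically rather than depending on where the optimizer stopped.
  A known consequence: with truly flat generative priors the MLE lands at
  the bound only when the sampled regression slope is non-negative
  (roughly half of datasets at a few hundred trials); otherwise it is a
  large finite SD (order $10^2$–$10^3$ px) set by sampling noise. This is
  why about a quarter to a third of generatively flat agent priors in a
  cohort are reported as wide-but-finite.
* Degenerate inputs (zero variance in both errors) raise a fit error rather
  than returning a boundary fit.
* BIC uses $k\ln n + 2\,\mathrm{NLL}$ with $n$ = non-excluded trials in that
  participant's joint fit; model pairs are called "strong" evidence at a
  mean BIC difference of 6, inclusive.
* Bootstrap CIs are percentile intervals over refits of within-cell
  (participant × condition) resamples, warm-started at the original
  estimate. The conventional default is $B = 5000$; the pipeline's test
  profile uses 500.

## The synthetic cohort

There is no deposited human data, so `make_cohort()` generates participants
with the population structure the analyses assume:

* performance SD drawn from a Normal (default mean 40 px, SD 10 px —
  plausible for stopping a 1200 px/s ball under a target on a 1024-px
  display);
* self prior SD = exaggeration ratio × performance SD, ratio drawn Normal
  (default mean 0.6, SD 0.15), i.e. optimistic priors about half as wide as
  true performance;
* agent prior either tracking the performance SD (log-normal scatter,
  `sdlog` 0.2) or flat with probability 0.25 (the observed 5-of-20 rate);
* agent evidence SD inflated ×1.15 over the self evidence SD (evidence for
  one's own action also has proprioceptive support, and the reported trend
  is smaller self evidence SD). This also makes the full model the
  generative truth, matching the model-selection outcome;
* evidence SD defaults to 0.75 × performance SD, putting the self weighting
  near 0.6;
* trait-optimism scores built from the residual of the log exaggeration
  ratio after regressing out performance SD, mixed with independent noise to
  hit a target partial correlation (default −0.5), affine-mapped and clipped
  to the 0–24 questionnaire range;
* feedback phases (`during`, `after`) multiply performance and evidence SDs
  (defaults 0.85 and 0.8) and never the prior SD — learning improves the
  action and its sensing, not the expectation;
* timing fields are log-normal with occasional ×4 outliers so the 2-SD
  exclusion rules have something to do. No distributional claim is intended;
  they are a stand-in.

What the generator does **not** emulate: sequential dependencies between
trials, motor drift or fatigue, non-Gaussian error tails, any true
psychometric model of optimism, or eye-movement behavior. Passing tests
therefore show that the pipeline recovers the structure it assumes — not
that real data obey that structure.

Randomness is structured as one root seed per session with per-participant
and per-block substreams derived by stable string hashing
(`derive_seed()`), so adding or reordering participants never changes
another participant's data, and identical configurations are byte-identical.

## Design choices where the procedure was genuinely open

* **Replay truncation is clamping.** Agent replays bound the self positions
  to ±2 SD of the self set rather than redrawing them; "truncated" reads
  most naturally as bounding, and clamping preserves the permutation
  property tested in the suite.
* **Exclusions are two-sided** (|t − mean| > 2 SD) within participant ×
  condition cells, with cell statistics over all trials — which makes
  re-application a no-op — and zero-SD cells excluding nothing.
* **Spearman partial correlation** is computed as ranks first, then
  residualization, then correlation of residuals (df = n − 3).
* **Median split** assigns participants at the median (and, for odd n, the
  median participant) to the lower group.
* **Flat-prior handling in group stats**: flat priors are excluded from
  parametric SD contrasts and retained for rank-based correlations. In the
  qualitative checklist the self-vs-agent deviation pattern uses *median*
  absolute deviations, because a weakly identified near-flat agent prior
  (large finite SD under the strict $>10^7$ rule) would dominate a mean;
  the paired t contrast on means is still computed and reported.
* **Per-phase fits** are used for the feedback analyses (the ANOVA needs a
  parameter per phase); all other fits pool the phases' baseline blocks.

## Problem sizes

The analysis drivers and calibration studies run at the study's native
sizes: 20 participants, 52-trial blocks, two blocks per phase and condition
for the main experiment; 10 participants for the control tasks (48-trial
release blocks, 32-trial bidirectional blocks); 6 participants, 40-trial
blocks for the configuration controls. Calibration uses 200 replicates for
model selection and bootstrap coverage (B = 500), and 1000 null cohorts for
the type-I study. A full pipeline pass on these sizes takes a few minutes on
one core.

## A worked example

```{r example, eval = FALSE}
library(selfpriors)

cohort <- make_cohort(cohort_spec(n_participants = 20, seed = 1))
session <- simulate_session(cohort, task_config("stop"), root_seed = 1)
trials <- apply_exclusions(session$trials)

# empirical weighting for one participant's self trials
reg <- fit_error_regression(subset(trials, participant_id == "p001" &
                                     condition == "self" & phase == "before"))
reg$weighting          # about 0.6 under the default cohort

# observer fit and model comparison
fit <- fit_model(subset(trials, participant_id == "p001" & phase == "before"),
                 model_preset("exp1_full"), seed = 1)
fit$params             # prior and evidence SDs per condition
classify_flat(fit)
```

## Known limitations

* The likelihood is Gaussian throughout; heavy-tailed report noise would
  bias the fitted SDs.
* The weighting identity makes $w$ and the evidence SD jointly identifiable
  only through the slope and residual SD, so near $w = 0$ the prior SD is
  weakly identified (see the flat-prior discussion above).
* The bootstrap resamples trials within condition cells; it does not model
  block structure.
* The feedback analysis fits phases independently; a joint model with
  shared priors across phases would be more efficient but prejudges the
  question it tests.
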