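---
title: "Modeling the formation and revision of ability beliefs from adaptive feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the formation and revision of ability beliefs from adaptive feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(looplearn)
library(dplyr)
```

## The task and what it manipulates

`looplearn` simulates and analyses a two-session performance-feedback
paradigm in which people repeatedly rate how well they expect to do in
novel estimation categories (heights, weights, quantities, distances),
receive manipulated percentile feedback, and thereby form — and later have
to revise — beliefs about their own ability (*Self*) and another person's
(*Other*). Each of the four categories is assigned to one cell of the
*Agent* (Self/Other) × *Ability* (High/Low) design, with 20 trials per cell
and session.

Feedback is adaptive rather than fixed: on every trial the feedback equals
the participant's current trailing belief — the mean of their last five
expectation ratings in that category, 50 before any rating exists — plus a
signed modifier. High-ability cells draw 70% positive modifiers, Low cells
30%. This yields prediction errors (PE = FB − EXP) of controlled sign and
magnitude irrespective of where a participant's expectations sit on the
scale. In the second session (T2) the contingencies reverse: each category
keeps its modifier magnitudes but flips their signs, so the prediction
errors match the first session (T1) in absolute size and differ only in
valence. Ratings that track the feedback accurately earn up to 6 cents per
trial, decaying linearly with the absolute rating–feedback gap.

The modifier magnitudes themselves are not dictated by the paradigm, only
their signs are; the engine cycles the multiset {5, 8, 11, 14, 17, 20, 23,
26} (percentile units) through each cell, shuffled per cell from the design
seed. These values span small to large PEs without saturating the scale;
they are configurable. A seeded order constraint prevents the first two
trials of a cell from both opposing the cell's majority valence, which
avoids degenerate early reversals; it can be switched off. Feedback is
clipped to [0, 100] (values off the percentile scale cannot be displayed),
and all internal quantities stay continuous — rounding is a presentation
concern only.

## The model space

All learning models share the delta rule

$$\mathrm{EXP}_{t+1} = \mathrm{EXP}_t + \alpha\,\mathrm{PE}_t,
\qquad \mathrm{PE}_t = \mathrm{FB}_t - \mathrm{EXP}_t,$$

and differ in how the learning rate $\alpha \in [0,1]$ is partitioned:

| id | name | $\alpha$ partition | free parameters |
|----|------|--------------------|-----------------|
| M1 | Unity | agent | 2 α + 8 SV + σ |
| M2 | Ability | agent × ability | 4 α + 8 SV + σ |
| M3 | Valence | agent × PE valence | 4 α + 8 SV + σ |
| M4 | Unity (session) | agent × session | 4 α + 8 SV + σ |
| M5 | Ability (session) | agent × ability × session | 8 α + 8 SV + σ |
| M6 | Valence (session) | agent × valence × session | 8 α + 8 SV + σ |
| M7 | Extended Valence | M6 + session weight $w_s$ | 8 α + 2 w + 8 SV + σ |
| M8 | Expectation | agent × congruency × session | 8 α + 8 SV + σ |
| M9 | Mean | one constant per cell | 8 μ + σ |

The extended valence model (M7) discounts updates from implausibly extreme
feedback:

$$\mathrm{EXP}_{s,a,b,t+1} = \mathrm{EXP}_{s,a,b,t} +
\alpha_{s,a,v}\,\mathrm{PE}_{s,a,b,t}\,\bigl(1 - w_s\,
\mathrm{ND}(\mathrm{FB}_t)\bigr),$$

where $\mathrm{ND}(\mathrm{FB})$ is the density of a normal distribution
centred at percentile 50, scaled so its peak equals 1, and $w_s \in [0,1]$
is a session-specific weight. The scale of that density is not itself
estimated (only $w_s$ is free); we fix it at `sigma_nd = 17` percentile
units, which places the scale ends near three standard deviations so the
discount is near-maximal at 0/100 and negligible around 50. It is a
configurable argument everywhere it appears.

Three structural choices deserve note:

* **Starting values.** Initial expectations are free parameters (SV). The
  winning model frees four per session (one per agent × ability cell); we
  give *every* non-mean model the same 8-SV layout so that model comparison
  differences reflect learning-rate structure, not starting-value
  flexibility.
* **M8 congruency.** A PE is *congruent* when its valence matches the
  cell's majority valence (positive in High cells, negative in Low cells,
  with ability labels session-current). Within a cell, valence and
  congruency are confounded, so M8 indexes rates by agent × congruency ×
  session rather than crossing congruency with valence.
* **Nesting.** M7 with $w = 0$ equals M6; M6 with equal session rates
  equals M3; M3 with equal valence rates equals M1. The test suite asserts
  these identities to machine precision, which pins down the index maps.

## Observation model and estimation

Ratings live on a bounded scale, so observed expectations are modelled as a
normal distribution truncated to [0, 100], centred on the model's latent
prediction, with one free noise σ per participant shared across sessions
and cells — the simplest observation model consistent with bounded ratings.
The first trial of each cell is scored against its SV (the SVs are free
parameters precisely because they are the trial-1 predictions; dropping
trial 1 would leave them unidentified).

Each participant × model pair is fitted separately — there is no group
prior and no shrinkage, matching the per-individual fitting strategy of the
studies this design comes from. Priors are weakly informative and bounded:
uniform on [0, 1] for rates and weights, uniform on [0, 100] for starting
values, half-normal with scale 20 for σ. Sampling runs on an unconstrained
scale (logit / log transforms with the appropriate Jacobians).

The canonical backend is an adaptive random-walk Metropolis sampler with
the draw-count contract: 3 chains, 1,000 burn-in iterations per chain,
3,400 iterations per chain in total, thinned by 3, leaving 2,400 kept draws
overall. The proposal covariance adapts to the empirical chain covariance
(scaled $2.38^2/d$) during burn-in and is frozen afterwards. Convergence is
diagnosed by split-half $\hat R$ (any parameter above 1.05 flags the fit —
"inspected" is not a threshold, so we chose a conventional one) and
effective sample sizes; flags are attached to the fit object rather than
silently dropped. Posterior summaries use the mean, giving one value per
parameter and participant for downstream analyses.

A deterministic MAP + Laplace backend (`sampler = "map"`) optimises the
posterior from several seeded starts and draws from the multivariate normal
approximation at the mode. It is clearly non-canonical — no $\hat R$, no
$n_{\mathrm{eff}}$ — but is an order of magnitude faster and is what the
large recovery studies below use. Both backends honour the same seed
derivation, so every fit is reproducible from one master seed.

## Model comparison

Out-of-sample predictive accuracy per participant and model is estimated by
leave-one-trial-out cross-validation using Pareto-smoothed importance
sampling over the posterior draws. Per trial, the largest importance ratios
are replaced by expected order statistics of a generalized Pareto
distribution fitted to them (Zhang–Stephens profile posterior), truncated
at the raw maximum; the tail shape $\hat k$ is reported per trial, with
$\hat k > 0.7$ counted as unreliable. We cap the smoothed tail at
$3\sqrt{S}$ ratios (at most 20%): on a conjugate fixture with an exact
refit-LOO answer, smoothing a full fifth of a large sample visibly biased
elpd upward, while the capped tail stays within 0.05 nats/trial of the
exact answer. Draws with zero posterior variance make the Pareto fit
undefined; such trials are flagged, not smoothed.

Population-level selection is random-effects Bayesian model selection on
the summed PSIS-LOO scores (used directly as log-evidence proxies, no
rescaling): each participant's generating model is a draw from a population
distribution over models with a Dirichlet(1, …, 1) prior, estimated by
variational updates iterated until the free energy moves less than 1e-6.
Exceedance probabilities are integrated with $10^5$ seeded Dirichlet
Monte-Carlo draws. The Bayesian omnibus risk (BOR) compares the fitted
random-effects model's free energy with the null model in which all
frequencies are equal; protected exceedance probabilities are
$pxp = (1-\mathrm{BOR})\,xp + \mathrm{BOR}/K$. Session-specific selection
reuses the jointly fitted models and sums each trial's LOO contribution
within the session — smoothing is independent across trials, so this equals
running LOO on the session subset.

## Derived statistics

The valence bias score per agent and session,

$$\mathrm{bias} = \frac{\alpha_{PE+} - \alpha_{PE-}}
{\alpha_{PE+} + \alpha_{PE-}} \in [-1, 1],$$

is positive when positive PEs drive larger updates. It is scale-invariant
in the rate pair and undefined (flagged `NA`) only when both rates are 0.
"Initial expectation" is the first rating per cell: averaged over the two
ability cells of an agent at T1 (the manipulation has not yet separated
them), kept apart by former ability at T2. Associations are Spearman rank
correlations with Fisher-z intervals (using the rank-correlation variance
correction $\sqrt{(1+\rho^2/2)/(n-3)}$, since no interval method is
canonical for ρ) and Benjamini–Hochberg adjustment within each declared
family of tests.

## What the synthetic cohorts emulate

`sample_cohort()` replaces the study's participants. Per participant it
draws generating parameters from truncated normals on their native scales,
simulates ratings through the *same* adaptive feedback loop the task engine
uses (latent expectations update from latent prediction errors; reported
ratings add truncated observation noise and drive the trailing-mean
feedback anchor), and emits confidence records at the four assessment
timepoints. Configurable population effects:

* a self-negativity bias: the mean difference `alpha(self, PE-) -
  alpha(self, PE+)` at T1 (default 0.07, chosen with a base rate of 0.25 so
  the generating self bias sits near −0.14 with the other-related bias near
  +0.11, the magnitudes reported for this paradigm);
* suppressed revision: T2 rates are an exact multiple (default 0.45) of the
  T1 rates;
* a starting-value/bias correlation (default 0.3) induced by one latent
  standard-normal factor loading on both the self starting values and the
  (negated) bias asymmetry — one knob, one mechanism;
* confidence trajectories (pre-T1 55, +12 after T1, −4 into T2, on a 0–100
  scale) with a negative coupling between post-T1 confidence and T2
  learning, mirroring the idea that confident beliefs resist revision.
  Confidence is descriptive only: the generating models never weight their
  updates by it, matching its role as a measured covariate.

The generating truth is stored beside the data and is never consumed by
inference. What passing recovery tests on these cohorts shows is that the
estimation and selection machinery identifies the structures it was built
for *under the generator's assumptions* — truncated-normal noise, a
correctly specified learning model, stationary parameters within a session.
Real participants violate all three in ways synthetic data cannot reveal:
lapses, scale-use habits (round numbers, edge avoidance), drifting
strategies, and model misspecification of unknown form. Directional
reproduction of population effects here is therefore a check of internal
consistency, not evidence about people.

## Numerical choices and degenerate inputs

* Updates with PE = 0 are no-ops; such trials can only arise from feedback
  clipping and are classified by their modifier sign for contingency
  bookkeeping.
* The bounded update guarantees `EXP` never overshoots the interval between
  the current expectation and the feedback for $\alpha, w\,\mathrm{ND} \in
  [0,1]$.
* Constant-rating participants and single-session inputs are fitted but
  flagged; zero-trial input returns the prior.
* All randomness flows from one master seed through named substreams
  (design, population, trajectories, chains, BMS Monte Carlo), so any
  artifact regenerates in isolation; the pipeline writes a manifest with
  the configuration fingerprint next to its outputs.
* Ties in the Monte-Carlo exceedance argmax are broken at random inside the
  seeded draw, so they cannot bias a model systematically.

## Problem sizes used in the shipped studies

The packaged recovery studies run at sizes chosen to make their statistical
targets meaningful while staying desk-scale: parameter recovery fits the
extended valence model to 30 simulated participants (σ = 8, rates drawn
uniformly from [0.05, 0.6]) with the MAP backend; model recovery generates
30-participant cohorts from M1, M3 and M7 and compares {M1, M3, M7, M9}
with 600 Laplace draws per fit; the study-like preset runs all 99
participants for the directional checks, with Bayesian model selection over
{M1, M3, M6, M7, M9}. The full nine-model space and the canonical MCMC
backend remain available behind the same interfaces.

## Known limitations

* The adaptive-feedback anchor guarantees the designed PE valence split
  only when ratings track the trailing reference; strong learners whose
  expectations outrun their own trailing mean can experience occasional
  off-design PE signs, as in the real task.
* The random-walk sampler mixes slowly in the 19-parameter extended valence
  model; at the canonical draw counts, $\hat R$ flags are common and should
  be heeded (or the MAP backend used when only point summaries are needed).
* PSIS-LOO reliability degrades when a single trial dominates the
  posterior; the $\hat k$ fraction is the intended guard.
* Correlations between fitted bias scores and other person-level variables
  are attenuated relative to the generating coupling: fitted bias tracks
  the generating bias imperfectly, and the error of the positive-PE self
  learning rate is itself mildly anti-correlated with the starting values —
  an identifiability property of the adaptive design (how much positive-PE
  information a participant yields depends on where their feedback sits on
  the percentile scale), present under both backends. Sign-level
  conclusions survive; magnitudes of such correlations should not be read
  as estimates of the generating coupling.
* The linear mixed-effects analyses of the original workflow are out of
  scope; exported tidy tables feed any standard mixed-model package.
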