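---
title: "Methods: hierarchical Bayesian conjoint analysis of CHB treatment preferences"
author: "hbchoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Bayesian conjoint analysis of CHB treatment preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Chronic hepatitis B (CHB) patients choosing among oral antiviral therapies
trade off efficacy, long-term safety risks, track record and out-of-pocket
cost. A discrete choice experiment (choice-based conjoint) elicits these
trade-offs: respondents repeatedly choose between two hypothetical products
described by six attributes — 5-year efficacy (71/85/92 %), 5-year risk of
bone thinning (<1/7/14 %), 5-year risk of kidney damage (<1/10/20 %),
patients treated worldwide (100k/200k/400k), years approved in the US
(2/4/6) and monthly out-of-pocket cost ($0/$50/$100/$150). `hbchoice`
implements the full analysis pipeline for such a survey — design, choice
model, post-estimation, and the companion cost-sensitivity and attitude
analyses — driven by a synthetic-respondent generator, since the original
respondent-level data were never released.

## Choice model

Products are effect coded (sum-to-zero): an attribute with $L$ levels
contributes $L-1$ free coefficients; the omitted level's part-worth is minus
the sum of the others. The default schema has $p = 5\times 2 + 3 = 13$
coefficients. For a scenario pairing products $A$ and $B$ with coded vectors
$x_A, x_B$ and difference $d = x_A - x_B$, respondent $i$ chooses $A$ with
probability

$$\Pr(A) = \operatorname{logit}^{-1}(d^\top \beta_i),$$

a binary logit with no outside option (the survey forced a choice).
Individual part-worths follow a multivariate-normal population distribution,

$$\beta_i \sim \mathcal{N}(\mu, \Sigma),$$

with weakly informative conjugate priors $\mu \sim \mathcal{N}(0, 100 I)$
and $\Sigma \sim \mathrm{Inverse\text{-}Wishart}(p + 2, I)$. The original
study named only "hierarchical Bayesian methodology" and MCMC; priors and
chain settings are our own documented choices, standard for hierarchical
choice models.

## Sampler

`run_mcmc()` is a Metropolis-within-Gibbs sampler with a compiled core:

* **$\beta_i$** — blocked Metropolis per respondent, mixing two proposal
  kernels: with probability `indep_prob` (default 0.5) an *independence*
  proposal from the current prior $\mathcal{N}(\mu, \Sigma)$, whose
  acceptance ratio reduces to the likelihood ratio; otherwise a random walk
  shaped by $\mathrm{chol}(\Sigma)$ with a per-respondent scalar scale
  adapted in batches of 50 toward 0.23 acceptance during burn-in and frozen
  afterwards (so the post-burn-in kernel is a valid fixed Markov kernel).
  The independence kernel matters: with only 8 binary observations per
  respondent the likelihood is weak, prior draws are accepted often, and the
  hierarchy decorrelates far faster than under a pure random walk (split
  R-hat drops from roughly 2 to 1.1–1.2 at the default run length).
* **$\mu$** — conjugate Gibbs draw from
  $\mathcal{N}((N\Sigma^{-1} + \tau^{-2}I)^{-1}\Sigma^{-1}\sum_i\beta_i,\,(N\Sigma^{-1} + \tau^{-2}I)^{-1})$.
* **$\Sigma$** — conjugate inverse-Wishart draw with degrees of freedom
  $p + 2 + N$ and scale $I + \sum_i (\beta_i - \mu)(\beta_i - \mu)^\top$,
  via the Bartlett decomposition.

Defaults: 2 chains of 20,000 iterations, 10,000 burn-in, thinning 10
(1,000 retained draws per chain). All randomness uses R's RNG, so a seed
makes a chain byte-reproducible; chain $c$ uses `seed + c - 1`. Convergence
is summarized by split R-hat and an autocorrelation-based effective sample
size for every component of $\mu$ and every diagonal element of $\Sigma$;
constant chains are reported as degenerate rather than erroring. Point
estimates are posterior means across all retained draws (not MAP), which is
the conventional input to conjoint post-estimation.

A known behaviour worth stating: when each respondent contributes only a
handful of binary choices, the Gibbs chain for $\Sigma$ cannot approach
zero even if the generating heterogeneity is zero — the conditional update
reflects the posterior spread of the $\beta_i$, which is bounded below by
their likelihood uncertainty. Oracle comparisons against the pooled logit
MLE are therefore run on data with many records per respondent, where
$\Sigma$ is well identified and collapses properly.

## Design construction

The published design is described only as "orthogonal", 64 paired scenarios
in 8 blocks of 8, level-balanced within block, with no duplicated products
within a scenario and no repeated scenarios. `generate_design()` reproduces
those properties by a seeded greedy build: per block, each attribute's
levels are spread over the 16 product slots with occurrence counts
differing by at most 1, slots are paired, invalid blocks (self-paired
products, repeated scenarios as unordered pairs) are rejected, and a swap
polish — exchanging two slots' levels within one attribute, which preserves
marginal balance — accepts only moves that reduce the summed absolute
deviation of pairwise level cross-tabulations from uniform (first
improvement wins under the seeded order, for determinism). This is not a
D-optimal search and does not reconstruct the original 64 scenarios (never
published); it reproduces their stated structure. We balance only level
occurrence, not the left/right position of levels, which the original
description does not constrain either.

## The synthetic population and its calibration

`importance_calibration()` builds the generating population so that the
range-method importances of the population mean equal the published overall
profile (kidney 37.9, cost 23.4, bone 18.0, efficacy 9.0, market 6.8,
patients 4.9 %). Within each attribute the level part-worths are equally
spaced and symmetric about zero, ordered by the attribute's natural
direction (higher efficacy better, lower risk and cost better), with ranges
proportional to the target importances and scaled to sum to 8 — an
arbitrary overall utility scale chosen to give realistic choice
determinism (roughly 75–90 % predictable choices). Defaults: 252
respondents split 111 Treated / 141 Treatment-naive, heterogeneity
$\Sigma_0 = 0.25 I$ (sd 0.5 per coded coefficient). The study reports no
individual-level variance, so the heterogeneity magnitude is a stand-in:
large enough to exercise shrinkage, small enough that aggregate importance
recovery stays near the calibration. It is fully configurable.

What the generator does *not* emulate: recruitment quotas, demographic
marginals, ethnicity effects on preferences (the study found results
"highly consistent" across ethnicities, so none are generated by default),
learning or fatigue over the 8 tasks, and any non-logit choice behaviour.
Passing recovery tests therefore shows the estimator inverts its own
generative model at the study's size — not that it would reproduce the
survey's numbers from the unreleased real data.

The price-response generator is a latent linear model
(`round(a_i + b_i \cdot \text{price} + e)` clamped to 1–5) with negative
group-mean slopes, chosen so mean willingness declines over the $0–$500
grid with Treated respondents slightly more price-sensitive, qualitatively
matching the reported pattern; the instrument description gives no
response model, so this is invented and fully configurable. Attitude
scores are drawn from a discretized-normal categorical distribution with
optional per-group mean shifts.

## Post-estimation

* **Relative importance** (range method): per respondent, each attribute's
  range of level part-worths divided by the sum of ranges, times 100.
  Respondents are normalized first and then averaged (the individual-level
  emphasis of the original analysis); averaging ranges first is available
  via `aggregate = "range_mean"`. A renormalization guards floating-point
  drift, so outputs sum to 100 exactly.
* **Share of preference**: logit shares
  $\exp(x_k^\top\beta_i)/\sum_j \exp(x_j^\top\beta_i)$ per respondent,
  averaged — the default, because individual shares are "added across" in
  the original description; a first-choice rule (ties split) is available.
  Whether the original used logit or first-choice shares is not stated.
* **Sensitivity**: from base-case products A and B, one attribute of one
  product is set to each of its levels with everything else fixed; the
  base-level row equals the unflexed base-case share exactly. The original
  base case is illegible in the source figure, so the default is every
  attribute at its middle level with cost $50 (A) vs $100 (B) — distinct
  products, so the base-case share is informative — and both are
  overridable.

Estimation noise inflates the ranges of low-importance attributes relative
to a noiseless respondent (a max-minus-min of noisy part-worths is biased
upward), so recovered aggregate importances compress slightly toward
uniformity: at the default conditions the top attribute is recovered
2–4 points below its generating value, within the pipeline's stated
recovery tolerance. HB shrinkage is what keeps this small; an unshrunk
per-respondent MLE would be far worse.

## Survey statistics

Willingness is top-2-box (scores 4–5), per the instrument's anchors;
proportions between the measured $250 and $500 points are linearly
interpolated at $300–$450 and flagged extrapolated. The cost "beta" is an
OLS slope of score on price in a configurable window (default $100–$250
in the drivers, matching where the published decline was quantified).
Attitude comparisons are Welch two-sample two-tailed t-tests at
$\alpha = 0.05$, treating Likert scores as interval data as the original
analysis implicitly did; no multiplicity correction by default (none was
applied originally), Bonferroni available. Zero-variance-equal-mean
degenerate comparisons report $t = 0$, $p = 1$.

## Reproducibility and problem sizes

Every generator and the sampler are pure functions of (inputs, seed); the
pipeline derives stage seeds from one master seed by a stable string hash,
so stages can be re-run independently. `replicate_study()` writes identical
bytes for identical configurations.

Sizes used by the shipped analyses and tests, chosen as comfortable desk
scale for this model (p = 13): the full study replication fits
252 respondents × 8 choices with 2 × 20,000 iterations (about 20 s with
the compiled sampler); recovery is assessed over 10 master seeds; the
oracle comparison uses ~50,000 records as 78 respondents × 640 records;
null calibration of the attitude t-test uses 1,000 replicates.

## Known limitations

* The published survey proportions (e.g. 88 %/72 %/39 % agreement, 75 %
  willingness at $100, mean $138 maximum cost) depend on the unreleased raw
  data; the generators emulate them qualitatively and nothing asserts them.
* $\Sigma$ is weakly identified at 8 choices per respondent; off-diagonal
  heterogeneity structure is essentially prior-driven at this size.
* Importance recovery inherits the mild compression bias described above;
  tolerances account for it.
* The design builder targets balance and approximate orthogonality, not
  optimal efficiency; for p = 13 and 64 scenarios this is ample.
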