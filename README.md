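# hbchoice

Hierarchical Bayesian choice-based conjoint analysis of chronic hepatitis B
(CHB) treatment preferences.

Patients choosing an oral antiviral for CHB trade off long-term efficacy,
5-year risks of bone thinning and kidney damage, the drug's track record
(patients treated worldwide, years on the US market) and monthly
out-of-pocket cost. A discrete choice experiment measures those trade-offs
by asking each respondent to choose within pairs of hypothetical products.
`hbchoice` implements the complete analysis pipeline for such a survey,
for analysts who want a tested, reproducible re-implementation rather than
a black-box conjoint tool:

* **Design** — blocked, level-balanced paired-choice designs
  (default: 64 distinct scenarios in 8 blocks of 8; within every block each
  attribute's levels occur equally often up to rounding), with balance and
  orthogonality diagnostics and near-uniform block assignment by
  respondent group.
* **Synthetic respondents** — individual part-worth vectors
  `beta_i ~ MVN(mu, Sigma)`, logit choices on the design, Likert price
  responses at the seven-cost grid ($0–$500/month) and attitude scores.
  `importance_calibration()` sets `mu` so the range-method importances
  equal the published overall profile (kidney 37.9, cost 23.4, bone 18.0,
  efficacy 9.0, market 6.8, patients 4.9 %), with 252 respondents
  (111 Treated / 141 Treatment-naive).
* **Estimation** — binary logit on effect-coded utility differences
  `P(A) = plogis((x_A - x_B)' beta_i)` inside a normal hierarchy
  `beta_i ~ MVN(mu, Sigma)`, priors `mu ~ N(0, 100 I)`,
  `Sigma ~ Inv-Wishart(p + 2, I)`, fitted by Metropolis-within-Gibbs MCMC
  with a compiled (RcppArmadillo) sampler; split R-hat / ESS diagnostics
  and a pooled-logit maximum-likelihood oracle.
* **Post-estimation** — range-method relative importance (per respondent
  and aggregate, each summing to 100 %), logit share-of-preference over a
  product set, and one-attribute-at-a-time sensitivity from a base-case
  pair.
* **Survey statistics** — top-2-box willingness curves with the $300–$450
  extrapolated segment, OLS cost-sensitivity slopes, and Welch t-tests of
  attitude statements between treatment groups.

## Worked example

The numbered scripts under `analysis/` run the whole study replication
(design → simulate → fit → post-estimation → surveys), writing tables to
`results/`. The same computation, condensed:

```r
library(hbchoice)

schema <- build_default_schema()
plan   <- generate_design(schema, n_blocks = 8, scenarios_per_block = 8, seed = 1)
spec   <- importance_calibration(schema)          # 252 calibrated respondents
prof   <- simulate_respondents(spec, seed = 2)
asg    <- assign_blocks(plan, prof$info, seed = 3)
choices <- simulate_choices(prof, plan, asg, seed = 4)

draws <- run_mcmc(choice_dataset(choices, plan), hb_config(seed = 5))
est   <- posterior_point_estimates(draws)
relative_importance(est$beta, schema)
```

Running `analysis/01_design.R` … `analysis/05_surveys.R` prints, among
other things:

```
Generated 64 scenarios; duplicates: 0; max per-block level imbalance: 1
Simulated 2016 choice records from 252 respondents (A chosen 50.0%)
Relative importance (% of total, n = 252 respondents):
  kidney_risk        35.2
  cost               22.2
  bone_risk          17.4
  efficacy            9.8
  years_market        8.1
  patients_treated    7.3
Base-case shares: A 66.7% vs B 33.3%
Cost slope (All, $100-$250): -0.0089 score points/$ (se 0.0005)
```

The importance table is the headline result: the hierarchical fit on one
seed's synthetic sample recovers the calibrated profile to within a few
percentage points, with kidney risk first and cost second — the ordering
the calibration encodes. The base-case share quantifies the $50/month cost
gap between two otherwise-identical mid-level products, and the cost slope
says each extra dollar of monthly cost lowers the mean 1–5 willingness
score by about 0.009 points in the $100–$250 window.

`replicate_study(run_config(master_seed = 1), out_dir = "results")` chains
all stages in one call and writes `report.json` / `report.md`; identical
configurations reproduce identical bytes.

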