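# Shared fixtures, built in code.

default_schema <- build_default_schema()

# Published overall importance profile the calibration targets, in schema
# attribute order (efficacy, bone, kidney, patients, years, cost).
target_importance <- c(efficacy = 9.0, bone_risk = 18.0,
                       kidney_risk = 37.9, patients_treated = 4.9,
                       years_market = 6.8, cost = 23.4)

# A small but balance-feasible plan (4 slots per block = max level count).
small_plan <- function(seed = 11L) {
  generate_design(default_schema, n_blocks = 2L, scenarios_per_block = 2L,
                  seed = seed)
}

# Respondent profiles with every beta fixed to a given vector.
fixed_profiles <- function(beta, n) {
  spec <- population_spec(beta, 0, n_respondents = n)
  simulate_respondents(spec, seed = 1L)
}

# Run the full calibrated pipeline (design -> simulate -> fit) for one
# master seed and return the aggregate importance vector.
recovered_importance <- function(master_seed,
                                 sampler = hb_config()) {
  spec <- importance_calibration(default_schema)
  plan <- generate_design(default_schema, 8, 8,
                          seed = derive_seed(master_seed, "design"))
  prof <- simulate_respondents(spec,
                               seed = derive_seed(master_seed,
                                                  "respondents"))
  asg <- assign_blocks(plan, prof$info,
                       seed = derive_seed(master_seed, "assign"))
  ch <- simulate_choices(prof, plan, asg,
                         seed = derive_seed(master_seed, "choices"))
  ds <- choice_dataset(ch, plan)
  sampler$seed <- derive_seed(master_seed, "mcmc")
  dr <- run_mcmc(ds, sampler)
  relative_importance(posterior_point_estimates(dr)$beta,
                      default_schema)$aggregate
}

# Minimal hand-built posterior_draws object for diagnostics tests.
fake_draws <- function(chain_mu_list, p = ncol(chain_mu_list[[1]])) {
  chains <- lapply(chain_mu_list, function(m) {
    list(mu = m,
         Sigma = matrix(1, nrow(m), p * p),
         n_keep = nrow(m), accept_rate = numeric(0))
  })
  structure(list(chains = chains, p = p, N = 0L,
                 respondent_ids = character(0), schema = default_schema,
                 config = hb_config(n_iter = 2L, n_burnin = 1L, thin = 1L),
                 prior_df = p + 2),
            class = "posterior_draws")
}
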