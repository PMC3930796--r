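test_that("choice log-likelihood matches closed forms and symmetries", {
  D <- matrix(0, 8, 13)
  expect_equal(choice_log_likelihood(rep(0, 13), D, rep(1, 8)),
               8 * log(0.5), tolerance = 1e-12)

  # one record with utility difference ln 3, A chosen -> log(0.75)
  d <- c(log(3), rep(0, 12))
  expect_equal(choice_log_likelihood(c(1, rep(0, 12)),
                                     matrix(d, 1), 1),
               log(0.75), tolerance = 1e-12)

  # swapping A/B labels together with the choice leaves it unchanged
  set.seed(9)
  D <- matrix(rnorm(5 * 13), 5)
  y <- c(1, -1, 1, 1, -1)
  beta <- rnorm(13)
  expect_equal(choice_log_likelihood(beta, D, y),
               choice_log_likelihood(beta, -D, -y))
  expect_error(choice_log_likelihood(rep(0, 5), D, y), "columns")
})

test_that("choice_dataset codes records against the plan", {
  plan <- small_plan()
  prof <- fixed_profiles(rep(0, 13), 8L)
  asg <- assign_blocks(plan, prof$info, seed = 1)
  ch <- simulate_choices(prof, plan, asg, seed = 2)
  ds <- choice_dataset(ch, plan)
  expect_equal(ds$N, 8L)
  expect_equal(ds$p, 13L)
  expect_equal(nrow(ds$D), nrow(ch))
  # rows are the coded A-B differences of the referenced scenarios
  i <- 1L
  sid <- ch$scenario_id[order(match(ch$respondent_id,
                                    ds$respondent_ids))][i]
  srow <- match(sid, plan$scenarios$scenario_id)
  expect_equal(ds$D[i, ],
               encode_product(default_schema, plan$a_levels[srow, ]) -
                 encode_product(default_schema, plan$b_levels[srow, ]))
  bad <- ch
  bad$scenario_id[1] <- 999L
  expect_error(choice_dataset(bad, plan), "unknown scenario")
})

test_that("pooled logit MLE behaves like a proper estimator", {
  plan <- generate_design(default_schema, 8, 8, seed = 2)
  # coin-flip choices on a symmetric design: coefficients near zero
  prof <- fixed_profiles(rep(0, 13), 500L)
  asg <- assign_blocks(plan, prof$info, seed = 3)
  ch <- simulate_choices(prof, plan, asg, seed = 4)
  ds <- choice_dataset(ch, plan)
  fit <- pooled_logit_mle(ds)
  expect_false(fit$separation)
  expect_true(all(abs(fit$coef) < 4 * fit$se))

  # consistency: data at beta*, sigma = 0 -> MLE within Wald bounds
  beta_star <- importance_calibration(default_schema)$mu
  profs <- fixed_profiles(beta_star, 2000L)
  asgs <- assign_blocks(plan, profs$info, seed = 5)
  chs <- simulate_choices(profs, plan, asgs, seed = 6)
  dss <- choice_dataset(chs, plan)
  fits <- pooled_logit_mle(dss)
  expect_true(all(abs(fits$coef - beta_star) < 4 * fits$se))
  # MLE log-likelihood is at least the truth's
  expect_gte(fits$loglik,
             choice_log_likelihood(beta_star, dss$D, dss$y))
})

test_that("MCMC draws are reproducible given a seed", {
  plan <- small_plan()
  prof <- fixed_profiles(rep(0, 13), 12L)
  asg <- assign_blocks(plan, prof$info, seed = 1)
  ch <- simulate_choices(prof, plan, asg, seed = 2)
  ds <- choice_dataset(ch, plan)
  cfg <- hb_config(n_iter = 400L, n_burnin = 200L, thin = 2L, seed = 99L)
  d1 <- run_mcmc(ds, cfg)
  d2 <- run_mcmc(ds, cfg)
  expect_identical(d1$chains[[1]]$mu, d2$chains[[1]]$mu)
  expect_identical(d1$chains[[2]]$Sigma, d2$chains[[2]]$Sigma)
  expect_identical(d1$chains[[1]]$beta, d2$chains[[1]]$beta)
  # different seed moves the draws
  d3 <- run_mcmc(ds, hb_config(n_iter = 400L, n_burnin = 200L,
                               thin = 2L, seed = 100L))
  expect_false(identical(d1$chains[[1]]$mu, d3$chains[[1]]$mu))
})

test_that("with no data the sampler reproduces the priors", {
  plan <- small_plan()
  empty <- data.frame(respondent_id = character(0),
                      scenario_id = integer(0), choice = character(0))
  ds <- choice_dataset(empty, plan)
  expect_equal(ds$N, 0L)
  cfg <- hb_config(n_iter = 6000L, n_burnin = 1000L, thin = 1L, seed = 5L)
  dr <- run_mcmc(ds, cfg)
  mu_draws <- do.call(rbind, lapply(dr$chains, `[[`, "mu"))
  # mu ~ N(0, 100 I): mean near 0, sd near 10
  se <- 10 / sqrt(nrow(mu_draws))
  expect_true(all(abs(colMeans(mu_draws)) < 4 * se))
  expect_true(all(abs(apply(mu_draws, 2, sd) - 10) < 1))
  # Sigma_jj ~ Inverse-Gamma(3/2, 1/2) under IW(p + 2, I): check medians
  Sig <- do.call(rbind, lapply(dr$chains, `[[`, "Sigma"))
  diag_idx <- (seq_len(13) - 1L) * 13 + seq_len(13)
  med <- apply(Sig[, diag_idx], 2, median)
  analytic_med <- 0.5 / qgamma(0.5, shape = 1.5)
  expect_true(all(abs(med - analytic_med) / analytic_med < 0.15))
})

test_that("posterior point estimates are draw means with PSD Sigma", {
  plan <- small_plan()
  prof <- fixed_profiles(rep(0, 13), 6L)
  asg <- assign_blocks(plan, prof$info, seed = 1)
  ch <- simulate_choices(prof, plan, asg, seed = 2)
  ds <- choice_dataset(ch, plan)
  dr <- run_mcmc(ds, hb_config(n_iter = 300L, n_burnin = 100L,
                               thin = 1L, seed = 3L))
  est <- posterior_point_estimates(dr)
  mu_manual <- colMeans(do.call(rbind, lapply(dr$chains, `[[`, "mu")))
  expect_equal(est$mu, mu_manual)
  expect_equal(est$Sigma, t(est$Sigma))
  expect_gte(min(eigen(est$Sigma, symmetric = TRUE,
                       only.values = TRUE)$values), 0)
  expect_equal(dim(est$beta), c(6L, 13L))
})

test_that("split R-hat and ESS behave on reference chains", {
  set.seed(31)
  # i.i.d. standard normal chains: R-hat in [0.99, 1.02]
  ch <- list(matrix(rnorm(4000), 2000, 2), matrix(rnorm(4000), 2000, 2))
  dg <- diagnostics(fake_draws(ch, p = 2))
  mu_rows <- grepl("^mu", dg$parameter)
  expect_true(all(dg$rhat[mu_rows] > 0.99 & dg$rhat[mu_rows] < 1.02))
  expect_true(all(dg$ess[mu_rows] > 1000))
  expect_false(any(dg$flagged[mu_rows]))

  # a chain copied twice has R-hat ~ 1
  one <- matrix(rnorm(2000), 1000, 2)
  dg2 <- diagnostics(fake_draws(list(one, one), p = 2))
  expect_true(all(abs(dg2$rhat[grepl("^mu", dg2$parameter)] - 1) < 0.01))

  # constant equal chains: reported degenerate, not a division error
  cst <- matrix(1, 1000, 2)
  dg3 <- diagnostics(fake_draws(list(cst, cst), p = 2))
  expect_true(all(dg3$degenerate[grepl("^mu", dg3$parameter)]))
  expect_true(all(is.na(dg3$rhat[grepl("^mu", dg3$parameter)])))
})

test_that("posterior summaries are invariant to relabeling A and B", {
  plan <- small_plan()
  prof <- fixed_profiles(c(rep(0.4, 6), rep(-0.2, 7)), 20L)
  asg <- assign_blocks(plan, prof$info, seed = 1)
  ch <- simulate_choices(prof, plan, asg, seed = 2)
  ds <- choice_dataset(ch, plan)

  flipped <- plan
  flipped$a_levels <- plan$b_levels
  flipped$b_levels <- plan$a_levels
  ch2 <- ch
  ch2$choice <- ifelse(ch$choice == "A", "B", "A")
  ds2 <- choice_dataset(ch2, flipped)
  expect_equal(ds$D * ds$y, ds2$D * ds2$y)

  cfg <- hb_config(n_iter = 500L, n_burnin = 200L, thin = 2L, seed = 7L)
  e1 <- posterior_point_estimates(run_mcmc(ds, cfg))
  e2 <- posterior_point_estimates(run_mcmc(ds2, cfg))
  expect_equal(e1$mu, e2$mu)
  expect_equal(e1$beta, e2$beta)
})
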