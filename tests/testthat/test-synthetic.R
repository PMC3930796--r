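test_that("calibration population reproduces the published importances", {
  spec <- importance_calibration(default_schema)
  expect_equal(spec$n_respondents, 252L)
  ranges <- attribute_ranges(spec$mu, default_schema)
  expect_equal(unname(ranges),
               c(0.720, 1.440, 3.032, 0.392, 0.544, 1.872),
               tolerance = 1e-12)
  expect_equal(sum(ranges), 8.0)
  imp <- relative_importance(spec$mu, default_schema)$aggregate
  expect_equal(unname(imp), unname(target_importance), tolerance = 1e-10)
  # higher efficacy / lower risk / lower cost are preferred
  pw <- decode_partworths(default_schema, spec$mu)
  expect_true(all(diff(pw$efficacy) > 0))
  expect_true(all(diff(pw$kidney_risk) < 0))
  expect_true(all(diff(pw$cost) < 0))
  expect_error(importance_calibration(attribute_schema(list(
    attribute_spec("a", "d", c("1", "2", "3"))))), "default")
})

test_that("respondent simulation honours sigma, mix and seed", {
  spec0 <- population_spec(rep(1, 13), 0, n_respondents = 10L)
  prof0 <- simulate_respondents(spec0, seed = 1)
  expect_true(all(prof0$beta == 1))

  spec <- population_spec(rep(0.3, 13), 0.25, n_respondents = 10000L)
  prof <- simulate_respondents(spec, seed = 2)
  # CLT: per-coordinate mean within 3 * 0.5 / sqrt(n) of mu
  expect_true(all(abs(colMeans(prof$beta) - 0.3) < 3 * 0.5 / 100))
  expect_identical(simulate_respondents(spec, seed = 2), prof)

  mix <- table(prof$info$group) / nrow(prof$info)
  expect_equal(as.numeric(mix["Treated"]), 111 / 252, tolerance = 0.01)

  expect_error(population_spec(rep(0, 2), matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("choice simulation follows the logit rule", {
  plan <- generate_design(default_schema, 8, 8, seed = 1)
  # indifferent respondents choose A about half the time
  prof <- fixed_profiles(rep(0, 13), 252L)
  asg <- assign_blocks(plan, prof$info, seed = 2)
  ch <- simulate_choices(prof, plan, asg, seed = 3)
  expect_equal(nrow(ch), 2016L)  # 252 x 8
  expect_true(abs(mean(ch$choice == "A") - 0.5) < 3 * 0.5 / sqrt(2016))
  expect_identical(simulate_choices(prof, plan, asg, seed = 3), ch)

  # a +10 utility difference makes A near-certain
  d <- encode_product(default_schema, plan$a_levels[1, ]) -
    encode_product(default_schema, plan$b_levels[1, ])
  beta10 <- 10 * d / sum(d * d)
  prof10 <- fixed_profiles(beta10, 5000L)
  asg10 <- assign_blocks(plan, prof10$info, seed = 4)
  asg10$block <- 1L  # everyone sees the block containing scenario 1
  ch10 <- simulate_choices(prof10, plan, asg10, seed = 5)
  s1 <- ch10[ch10$scenario_id == 1L, ]
  expect_equal(stats::plogis(10), 0.9999546, tolerance = 1e-6)
  expect_gt(mean(s1$choice == "A"), 0.9995)

  expect_error(simulate_choices(prof, plan, asg[-1, ], seed = 1),
               "lacking a block assignment")
})

test_that("price responses cover the grid and decrease with price", {
  prof <- fixed_profiles(rep(0, 13), 252L)
  rec <- simulate_price_responses(prof, price_config(), seed = 1)
  expect_equal(nrow(rec), 252L * 7L)
  expect_equal(sort(unique(rec$price_usd)),
               c(0, 50, 100, 150, 200, 250, 500))
  expect_true(all(rec$score %in% 1:5))
  m <- tapply(rec$score, rec$price_usd, mean)
  expect_gte(m[["0"]], m[["500"]])
  expect_identical(simulate_price_responses(prof, price_config(),
                                            seed = 1), rec)

  # degenerate config: zero slope, zero noise, intercept 5 -> all scores 5
  cfg <- price_config(intercept_mean = 5, intercept_sd = 0,
                      slope_mean = c("Treated" = 0,
                                     "Treatment-naive" = 0),
                      slope_sd = 0, noise_sd = 0)
  rec5 <- simulate_price_responses(prof, cfg, seed = 2)
  expect_true(all(rec5$score == 5L))
})

test_that("attitude scores respect counts, shifts and degeneracy", {
  prof <- fixed_profiles(rep(0, 13), 252L)
  rec <- simulate_attitudes(prof, seed = 1)
  expect_equal(nrow(rec), 1260L)  # 252 x 5 statements
  expect_true(all(rec$score %in% 1:5))

  # zero group effect, large n: group means nearly equal
  prof_big <- fixed_profiles(rep(0, 13), 5000L)
  st <- data.frame(statement_id = "S1", mean_score = 3.2)
  rec0 <- simulate_attitudes(prof_big, st, group_effects = NULL, seed = 2)
  mg <- tapply(rec0$score, rec0$group, mean)
  expect_lt(abs(diff(mg)), 0.1)

  # degenerate distribution centred at 3 with sd 0
  rec3 <- simulate_attitudes(prof, data.frame(statement_id = "S1",
                                              mean_score = 3),
                             sd = 0, seed = 3)
  expect_true(all(rec3$score == 3L))

  # a positive group shift raises that group's mean
  recs <- simulate_attitudes(prof_big, st,
                             group_effects = c("Treated" = 0.5,
                                               "Treatment-naive" = 0),
                             seed = 4)
  ms <- tapply(recs$score, recs$group, mean)
  expect_gt(ms[["Treated"]], ms[["Treatment-naive"]])
})
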