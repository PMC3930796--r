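test_that("attribute ranges decode correctly and respect invariances", {
  mu <- importance_calibration(default_schema)$mu
  r <- attribute_ranges(mu, default_schema)
  expect_equal(unname(r), c(0.720, 1.440, 3.032, 0.392, 0.544, 1.872),
               tolerance = 1e-12)
  expect_equal(unname(attribute_ranges(rep(0, 13), default_schema)),
               rep(0, 6))
  # range of decoded part-worths is location-invariant
  pw <- decode_partworths(default_schema, mu)$kidney_risk
  expect_equal(max(pw + 5) - min(pw + 5), max(pw) - min(pw))
  expect_error(attribute_ranges(rep(0, 5), default_schema), "length")
})

test_that("relative importance normalizes per respondent and aggregates", {
  mu <- importance_calibration(default_schema)$mu
  one <- relative_importance(mu, default_schema)
  expect_equal(unname(one$aggregate), unname(target_importance),
               tolerance = 1e-10)
  expect_equal(sum(one$aggregate), 100)
  expect_equal(unname(rowSums(one$per_respondent)), 100)

  # aggregate of two respondents is the mean of their vectors
  set.seed(5)
  b2 <- rbind(rnorm(13), rnorm(13))
  res <- relative_importance(b2, default_schema)
  expect_equal(res$aggregate,
               colMeans(res$per_respondent), tolerance = 1e-10)

  # scale invariance: c * beta gives identical importances
  res_scaled <- relative_importance(3.7 * b2, default_schema)
  expect_equal(res$per_respondent, res_scaled$per_respondent)

  # all-zero respondents are excluded with a warning
  expect_warning(res0 <- relative_importance(rbind(b2, 0), default_schema),
                 "excluded")
  expect_equal(res0$aggregate, res$aggregate)

  # property: sums are 100 within 1e-6 over many random draws
  set.seed(77)
  B <- matrix(rnorm(1000 * 13), 1000, 13)
  res_many <- relative_importance(B, default_schema)
  expect_true(all(abs(rowSums(res_many$per_respondent) - 100) < 1e-6))
  expect_lt(abs(sum(res_many$aggregate) - 100), 1e-6)
})

test_that("preference shares follow the logit rule", {
  pA <- c(1, 1, 1, 1, 1, 1)
  pB <- c(2, 2, 2, 2, 2, 2)
  z <- matrix(0, 3, 13)
  sh0 <- preference_shares(z, list(A = pA, B = pB), default_schema)
  expect_equal(unname(sh0$aggregate), c(50, 50))

  # engineered ln 3 utility difference: shares 75/25
  d <- encode_product(default_schema, pA) -
    encode_product(default_schema, pB)
  beta <- log(3) * d / sum(d * d)
  sh <- preference_shares(rbind(beta, beta),
                          list(A = pA, B = pB), default_schema)
  expect_equal(unname(sh$aggregate), c(75, 25), tolerance = 1e-10)
  # two-product logit share equals logistic of the utility difference
  expect_equal(sh$per_respondent[1, "A"] / 100,
               stats::plogis(sum(d * beta)), tolerance = 1e-12)

  # shares always sum to 100
  set.seed(21)
  B <- matrix(rnorm(40 * 13), 40)
  prods <- list(a = c(1, 2, 1, 3, 2, 4), b = c(3, 1, 2, 1, 1, 1),
                c = c(2, 3, 3, 2, 3, 2))
  shm <- preference_shares(B, prods, default_schema)
  expect_true(all(abs(rowSums(shm$per_respondent) - 100) < 1e-9))
  expect_equal(sum(shm$aggregate), 100, tolerance = 1e-9)

  # first-choice rule gives each row's full share to its best product
  fc <- preference_shares(B, prods, default_schema,
                          rule = "first_choice")
  expect_true(all(shm$per_respondent > 0))
  expect_true(all(fc$per_respondent %in% c(0, 50, 100)))

  expect_error(preference_shares(B, list(pA, pA), default_schema),
               "duplicate")
  expect_error(preference_shares(B, list(pA), default_schema),
               "at least 2")
})

test_that("sensitivity analysis flexes one attribute at a time", {
  spec <- importance_calibration(default_schema)
  prof <- simulate_respondents(spec, seed = 8)
  base_a <- c(2, 2, 1, 2, 2, 2)  # kidney at best level
  base_b <- c(2, 2, 2, 2, 2, 3)
  sens <- sensitivity_analysis(prof$beta, base_a, base_b, default_schema)

  # base rows reproduce the unflexed base-case share exactly
  base_share <- preference_shares(
    prof$beta, list(A = base_a, B = base_b),
    default_schema)$aggregate[["A"]]
  base_rows <- sens[sens$is_base, ]
  expect_true(all(abs(base_rows$share_a - base_share) < 1e-9))

  # worsening kidney risk of A strictly decreases its share
  ka <- sens[sens$product == "A" & sens$attribute == "kidney_risk", ]
  expect_true(all(diff(ka$share_a) < 0))

  # flexing an attribute with zero part-worths leaves shares constant
  z <- prof$beta
  z[, 7:8] <- 0  # patients_treated coefficients
  sz <- sensitivity_analysis(z, base_a, base_b, default_schema)
  pa <- sz[sz$product == "A" & sz$attribute == "patients_treated", ]
  expect_equal(diff(range(pa$share_a)), 0)

  # shares of A and B sum to 100 in every row
  expect_true(all(abs(sens$share_a + sens$share_b - 100) < 1e-9))
})

test_that("a universally dominant product takes a majority share", {
  spec <- importance_calibration(default_schema)
  prof <- simulate_respondents(population_spec(spec$mu, 0.01), seed = 3)
  best <- c(3, 1, 1, 3, 3, 1)   # best level on every attribute
  worst <- c(1, 3, 3, 1, 1, 4)
  sh <- preference_shares(prof$beta, list(best = best, worst = worst),
                          default_schema)
  expect_gt(sh$aggregate[["best"]], 50)
})
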