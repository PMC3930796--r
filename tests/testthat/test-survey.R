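make_price_records <- function(scores_by_price, ids = NULL) {
  grid <- as.numeric(names(scores_by_price))
  n <- length(scores_by_price[[1]])
  if (is.null(ids)) ids <- sprintf("R%02d", seq_len(n))
  do.call(rbind, lapply(seq_along(grid), function(k) {
    data.frame(respondent_id = ids, group = "G1",
               price_usd = grid[k], score = scores_by_price[[k]])
  }))
}

test_that("willingness curve computes top-2-box and extrapolates", {
  prof <- fixed_profiles(rep(0, 13), 252L)
  rec <- simulate_price_responses(prof, price_config(), seed = 1)
  curve <- willingness_curve(rec)
  all_measured <- curve[curve$group == "All" & !curve$extrapolated, ]
  expect_equal(nrow(all_measured), 7L)  # seven measured price points
  ex <- curve[curve$group == "All" & curve$extrapolated, ]
  expect_equal(ex$price_usd, c(300, 350, 400, 450))
  # midpoint extrapolation at $375 would be the mean of $250 and $500;
  # check the interpolation line at $350/$400 instead
  v250 <- all_measured$pct_willing[all_measured$price_usd == 250]
  v500 <- all_measured$pct_willing[all_measured$price_usd == 500]
  expect_equal(ex$pct_willing[ex$price_usd == 350],
               v250 + (v500 - v250) * 100 / 250, tolerance = 1e-10)
  expect_equal(mean(c(v250, v500)),
               approx(c(250, 500), c(v250, v500), xout = 375)$y)

  # all scores 5 at $0 -> 100 % at $0
  rec5 <- make_price_records(list(`0` = rep(5L, 4), `100` = rep(1L, 4)))
  c5 <- willingness_curve(rec5)
  expect_equal(c5$pct_willing[c5$group == "All" & c5$price_usd == 0], 100)

  # incomplete coverage excluded with a warning
  expect_warning(willingness_curve(rec[-1, ]), "coverage")
})

test_that("cost beta is an exact OLS slope on the score-price line", {
  grid <- c(0, 50, 100, 150, 200, 250)
  recs <- do.call(rbind, lapply(grid, function(pr) {
    data.frame(respondent_id = "R1", group = "All", price_usd = pr,
               score = 5 - 0.02 * pr)
  }))
  cb <- cost_beta(recs)
  expect_equal(cb$slope, -0.02, tolerance = 1e-12)
  expect_equal(cb$intercept, 5, tolerance = 1e-12)

  # constant scores: slope 0
  recc <- transform(recs, score = 3)
  expect_equal(cost_beta(recc)$slope, 0, tolerance = 1e-12)

  # doubling prices halves the slope
  rec2 <- transform(recs, price_usd = 2 * price_usd)
  expect_equal(cost_beta(rec2)$slope, -0.01, tolerance = 1e-12)

  # a single price point is rejected
  expect_error(cost_beta(recs, price_window = c(100, 100)),
               "at least 2 distinct prices")

  # window subsetting really subsets
  cw <- cost_beta(recs, price_window = c(100, 250))
  expect_equal(cw$n_obs, 4L)
})

test_that("maximum acceptable price summaries", {
  s <- max_price_summary(c(100, 100, 150))
  expect_equal(s$median, 100)
  expect_equal(s$mean, 350 / 3)
  s1 <- max_price_summary(276)
  expect_equal(s1$mean, s1$median)
  expect_equal(max_price_summary(c(0, 276))$mean, 138)
  expect_error(max_price_summary(numeric(0)), "no maximum prices")
  expect_error(max_price_summary(c(10, -5)), "negative")
})

test_that("attitude comparisons run Welch t-tests per statement", {
  rec <- data.frame(
    respondent_id = sprintf("R%02d", 1:40),
    group = rep(c("Treated", "Treatment-naive"), each = 20),
    statement_id = "S1",
    score = c(rep(c(2L, 4L), 10), rep(c(2L, 4L), 10)))
  cmp <- compare_attitudes(rec, "Treated", "Treatment-naive")
  expect_equal(cmp$t, 0, tolerance = 1e-12)
  expect_equal(cmp$p_value, 1, tolerance = 1e-12)
  expect_false(cmp$significant)

  # swapping group labels flips t, keeps p
  rec2 <- rec
  rec2$score[rec2$group == "Treated"] <- rec2$score[
    rec2$group == "Treated"] + 1L
  a <- compare_attitudes(rec2, "Treated", "Treatment-naive")
  b <- compare_attitudes(rec2, "Treatment-naive", "Treated")
  expect_equal(a$t, -b$t)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$mean_a, b$mean_b)

  # agrees with stats::t.test directly
  ht <- t.test(score ~ group, data = rec2)
  expect_equal(a$t, unname(ht$statistic))
  expect_equal(a$p_value, ht$p.value)

  # degenerate zero-variance case reports t = 0, p = 1
  recd <- transform(rec, score = 3L)
  cd <- compare_attitudes(recd, "Treated", "Treatment-naive")
  expect_equal(cd$t, 0)
  expect_equal(cd$p_value, 1)

  # bonferroni option inflates p-values across statements
  rec3 <- rbind(rec2, transform(rec2, statement_id = "S2"))
  raw <- compare_attitudes(rec3, "Treated", "Treatment-naive")
  adj <- compare_attitudes(rec3, "Treated", "Treatment-naive",
                           adjust = "bonferroni")
  expect_equal(adj$p_value, pmin(1, 2 * raw$p_value))
})

test_that("willingness is monotone non-increasing on default data", {
  prof <- fixed_profiles(rep(0, 13), 2000L)
  rec <- simulate_price_responses(prof, price_config(), seed = 4)
  curve <- willingness_curve(rec)
  overall <- curve[curve$group == "All" & !curve$extrapolated, ]
  expect_true(all(diff(overall$pct_willing) <= 0))
  # and the fitted cost slope is negative
  expect_lt(cost_beta(rec, price_window = c(100, 250))$slope, 0)
})
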