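# Synthetic respondent generator: individual part-worth vectors drawn around
# a population mean with multivariate-normal heterogeneity, logit choices on
# the paired design, Likert price-response and attitude records.

#' Construct a population specification
#'
#' Holds the data-generating counterparts of the hierarchical choice model's
#' population parameters: mean part-worth vector `mu` (effect-coded space),
#' heterogeneity covariance `sigma`, group mix and sample size.
#'
#' @param mu Numeric vector, length `coding_dim(schema)` of the schema it is
#'   used with.
#' @param sigma Covariance matrix (symmetric positive semi-definite), or a
#'   single number `s` meaning `s * I`.
#' @param group_mix Named numeric vector of group proportions summing to 1.
#' @param n_respondents Number of respondents to simulate.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(mu, sigma,
                            group_mix = c("Treated" = 111 / 252,
                                          "Treatment-naive" = 141 / 252),
                            n_respondents = 252L) {
  mu <- as.numeric(mu)
  p <- length(mu)
  if (is.matrix(sigma)) {
    stopifnot(nrow(sigma) == p, ncol(sigma) == p)
  } else {
    stopifnot(length(sigma) == 1L, sigma >= 0)
    sigma <- diag(as.numeric(sigma), p)
  }
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("sigma must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("sigma must be positive semi-definite")
  }
  if (abs(sum(group_mix) - 1) > 1e-8 || any(group_mix < 0)) {
    stop("group_mix must be non-negative proportions summing to 1")
  }
  structure(list(mu = mu, sigma = sigma, group_mix = group_mix,
                 n_respondents = as.integer(n_respondents)),
            class = "population_spec")
}

#' Population calibrated to the published importance profile
#'
#' Returns a `population_spec` whose mean part-worth vector `mu` yields
#' range-method relative importances of (37.9, 23.4, 18.0, 9.0, 6.8, 4.9) %
#' for (kidney risk, cost, bone risk, efficacy, years on market, patients
#' treated) — the overall importance profile reported for the CHB
#' treatment-preference study this pipeline emulates. Per-attribute level
#' part-worths are symmetric about zero (equally spaced best to worst, in
#' the direction of each attribute's `higher_better` flag) with ranges
#' proportional to the target importances, scaled so the six ranges sum
#' to 8. Heterogeneity defaults to `0.25 * I` (sd 0.5 per coded
#' coefficient) and the sample to 252 respondents split 111 Treated /
#' 141 Treatment-naive.
#'
#' @param schema The default schema from [build_default_schema()].
#' @param sigma Heterogeneity covariance (matrix or scalar for `s * I`).
#' @param n_respondents Sample size.
#' @return A `population_spec`.
#' @export
importance_calibration <- function(schema = build_default_schema(),
                                   sigma = 0.25, n_respondents = 252L) {
  target <- c(efficacy = 9.0, bone_risk = 18.0, kidney_risk = 37.9,
              patients_treated = 4.9, years_market = 6.8, cost = 23.4)
  if (!identical(names(schema$attributes), names(target))) {
    stop("importance_calibration requires the default six-attribute schema")
  }
  ranges <- 8 * target / sum(target)
  L <- level_counts(schema)
  mu <- numeric(0)
  for (j in seq_along(L)) {
    # equally spaced, symmetric about zero, from worst to best in level order
    grid <- seq(-ranges[j] / 2, ranges[j] / 2, length.out = L[j])
    if (!schema$attributes[[j]]$higher_better) grid <- rev(grid)
    mu <- c(mu, grid[seq_len(L[j] - 1L)])  # effect-coded free coefficients
  }
  population_spec(mu, sigma, n_respondents = n_respondents)
}

#' Simulate respondent profiles
#'
#' Draws each respondent's part-worth vector from a multivariate normal
#' `MVN(mu, sigma)` (eigen-decomposition sampler, so singular covariances —
#' including `sigma = 0` — are valid) and assigns group labels to match the
#' group mix as closely as rounding allows.
#'
#' @param spec A `population_spec`.
#' @param seed Integer seed.
#' @return A `respondent_profiles` object: `$info` data frame
#'   (respondent_id, group) and `$beta` numeric matrix (one row per
#'   respondent).
#' @export
simulate_respondents <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n <- spec$n_respondents
  p <- length(spec$mu)
  beta <- rmvnorm_psd(n, spec$mu, spec$sigma)

  n_per <- round(spec$group_mix * n)
  # fix rounding drift on the last group
  n_per[length(n_per)] <- n - sum(n_per[-length(n_per)])
  group <- sample(rep(names(spec$group_mix), times = n_per))

  ids <- sprintf("R%03d", seq_len(n))
  rownames(beta) <- ids
  structure(list(info = data.frame(respondent_id = ids, group = group),
                 beta = beta),
            class = "respondent_profiles")
}

# MVN sampler valid for any symmetric PSD covariance (rank-deficient
# included): mu + E sqrt(max(lambda, 0)) z.
rmvnorm_psd <- function(n, mu, sigma) {
  p <- length(mu)
  if (all(sigma == 0)) {
    return(matrix(mu, n, p, byrow = TRUE))
  }
  ed <- eigen(sigma, symmetric = TRUE)
  rt <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), p)
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% t(rt), 2L, mu, `+`)
}

#' Simulate paired choices on a design
#'
#' For every scenario in a respondent's assigned block, product A is chosen
#' with probability `plogis((x_A - x_B)' beta_i)` — the binary-logit rule the
#' hierarchical model assumes. Exactly tied utilities resolve through the
#' same rule (probability 0.5).
#'
#' @param profiles A `respondent_profiles` object.
#' @param plan A `design_plan`.
#' @param assignment Data frame from [assign_blocks()] (respondent_id,
#'   group, block).
#' @param seed Integer seed.
#' @return Data frame of choice records: respondent_id, group, block,
#'   scenario_id, choice ("A"/"B").
#' @export
simulate_choices <- function(profiles, plan, assignment, seed = 1L) {
  stopifnot(inherits(profiles, "respondent_profiles"),
            inherits(plan, "design_plan"))
  miss <- setdiff(profiles$info$respondent_id, assignment$respondent_id)
  if (length(miss)) {
    stop("respondents lacking a block assignment: ",
         paste(utils::head(miss, 3L), collapse = ", "))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  D_all <- design_difference_matrix(plan)
  block_of <- stats::setNames(assignment$block, assignment$respondent_id)

  out <- vector("list", nrow(profiles$info))
  for (i in seq_len(nrow(profiles$info))) {
    id <- profiles$info$respondent_id[i]
    blk <- block_of[[id]]
    rows <- which(plan$scenarios$block == blk)
    pA <- stats::plogis(D_all[rows, , drop = FALSE] %*% profiles$beta[i, ])
    out[[i]] <- data.frame(
      respondent_id = id,
      group = profiles$info$group[i],
      block = blk,
      scenario_id = plan$scenarios$scenario_id[rows],
      choice = ifelse(stats::runif(length(rows)) < pA, "A", "B"))
  }
  do.call(rbind, out)
}

# Effect-coded utility-difference matrix x_A - x_B, one row per scenario.
design_difference_matrix <- function(plan) {
  encode_products(plan$schema, plan$a_levels) -
    encode_products(plan$schema, plan$b_levels)
}

#' Default configuration for the price-response generator
#'
#' Latent-score model: respondent i scores price c as
#' `round(a_i + b_i * c + e)`, clamped to 1..5, with
#' `a_i ~ N(intercept_mean, intercept_sd^2)`,
#' `b_i ~ N(slope_mean[group], slope_sd^2)` and `e ~ N(0, noise_sd^2)`.
#' Defaults give a monotone-decreasing mean score over the measured grid
#' ($0–$500/month), with Treated respondents slightly more price-sensitive
#' than Treatment-naive ones.
#'
#' @param price_grid Monthly out-of-pocket costs (USD) every respondent
#'   scores; default the seven-point grid $0, $50, $100, $150, $200, $250,
#'   $500.
#' @param intercept_mean,intercept_sd Latent intercept distribution.
#' @param slope_mean Named per-group mean latent slope (score points per
#'   dollar; negative).
#' @param slope_sd Slope heterogeneity sd.
#' @param noise_sd Observation noise sd.
#' @return A list of class `price_config`.
#' @export
price_config <- function(price_grid = c(0, 50, 100, 150, 200, 250, 500),
                         intercept_mean = 5.2, intercept_sd = 0.5,
                         slope_mean = c("Treated" = -0.010,
                                       "Treatment-naive" = -0.008),
                         slope_sd = 0.002, noise_sd = 0.6) {
  stopifnot(length(price_grid) >= 1L)
  structure(list(price_grid = sort(unique(price_grid)),
                 intercept_mean = intercept_mean,
                 intercept_sd = intercept_sd,
                 slope_mean = slope_mean, slope_sd = slope_sd,
                 noise_sd = noise_sd),
            class = "price_config")
}

#' Simulate Likert price responses
#'
#' Each respondent scores every price on the grid on a 1–5 scale
#' (1 = definitely not ... 5 = definitely) under the latent linear model of
#' [price_config()].
#'
#' @param profiles A `respondent_profiles` object.
#' @param config A `price_config`.
#' @param seed Integer seed.
#' @return Data frame: respondent_id, group, price_usd, score (integer 1–5).
#' @export
simulate_price_responses <- function(profiles, config = price_config(),
                                     seed = 1L) {
  stopifnot(inherits(profiles, "respondent_profiles"),
            inherits(config, "price_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  info <- profiles$info
  n <- nrow(info)
  sl_mean <- config$slope_mean[info$group]
  if (anyNA(sl_mean)) {
    # groups without a configured slope fall back to the mean of the config
    sl_mean[is.na(sl_mean)] <- mean(config$slope_mean)
  }
  a <- stats::rnorm(n, config$intercept_mean, config$intercept_sd)
  b <- stats::rnorm(n, sl_mean, config$slope_sd)

  grid <- config$price_grid
  out <- expand.grid(price_usd = grid, row = seq_len(n))
  latent <- a[out$row] + b[out$row] * out$price_usd +
    stats::rnorm(nrow(out), 0, config$noise_sd)
  data.frame(respondent_id = info$respondent_id[out$row],
             group = info$group[out$row],
             price_usd = out$price_usd,
             score = pmin(5L, pmax(1L, as.integer(round(latent)))))
}

#' Default attitude-statement battery
#'
#' Five statements mirroring the themes of the survey's attitudinal battery
#' (disease severity if untreated, availability of effective medication,
#' reluctance toward long-term therapy, side-effect concern, trust in
#' physician advice), with population mean agreement levels on the 1–5
#' scale (1 = completely disagree ... 5 = completely agree).
#'
#' @return Data frame: statement_id, statement, mean_score.
#' @export
attitude_statements <- function() {
  data.frame(
    statement_id = paste0("S", 1:5),
    statement = c(
      "Untreated CHB can lead to serious liver damage",
      "Effective prescription medications exist to treat CHB",
      "I am reluctant to be on long-term therapy for CHB",
      "I am concerned about side effects of CHB medication",
      "I follow my doctor's treatment recommendations"),
    mean_score = c(4.4, 3.9, 3.1, 3.4, 4.0))
}

#' Simulate Likert attitude responses
#'
#' Per respondent and statement, draws an integer 1–5 score from a
#' discretized-normal categorical distribution centred at the statement's
#' mean plus the respondent group's configured shift.
#'
#' @param profiles A `respondent_profiles` object.
#' @param statements Data frame with statement_id and mean_score
#'   (default [attitude_statements()]).
#' @param group_effects Named list or matrix of mean shifts: either a single
#'   named numeric vector (one shift per group, applied to all statements)
#'   or a matrix `statements x groups`. Default: no shift.
#' @param sd Latent sd of the categorical distribution (0 collapses to the
#'   nearest integer score).
#' @param seed Integer seed.
#' @return Data frame: respondent_id, group, statement_id, score.
#' @export
simulate_attitudes <- function(profiles, statements = attitude_statements(),
                               group_effects = NULL, sd = 1, seed = 1L) {
  stopifnot(inherits(profiles, "respondent_profiles"),
            nrow(statements) >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  info <- profiles$info
  groups <- unique(info$group)
  shift <- matrix(0, nrow(statements), length(groups),
                  dimnames = list(statements$statement_id, groups))
  if (!is.null(group_effects)) {
    if (is.matrix(group_effects)) {
      shift[rownames(group_effects), colnames(group_effects)] <-
        group_effects
    } else {
      for (g in names(group_effects)) shift[, g] <- group_effects[[g]]
    }
  }

  out <- expand.grid(s = seq_len(nrow(statements)),
                     i = seq_len(nrow(info)))
  m <- statements$mean_score[out$s] + shift[cbind(out$s,
                                                  match(info$group[out$i],
                                                        groups))]
  score <- if (sd == 0) {
    pmin(5L, pmax(1L, as.integer(round(m))))
  } else {
    # categorical over 1..5 with probabilities from a normal kernel at m
    vapply(m, function(mi) {
      pr <- stats::dnorm(1:5, mi, sd)
      sample.int(5L, 1L, prob = pr / sum(pr))
    }, integer(1))
  }
  data.frame(respondent_id = info$respondent_id[out$i],
             group = info$group[out$i],
             statement_id = statements$statement_id[out$s],
             score = score)
}
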