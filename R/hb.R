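# Hierarchical Bayesian binary-logit choice model.
#
# Likelihood: for each recorded scenario, P(choose A) = plogis(d' beta_i)
# with d = x_A - x_B the effect-coded utility difference; no outside option
# (the survey forced a choice between the two products). Hierarchy:
# beta_i ~ MVN(mu, Sigma) with weakly informative conjugate priors
# mu ~ N(0, tau2 I), Sigma ~ Inverse-Wishart(p + 2, I).

#' Build a coded choice dataset from records and a design plan
#'
#' @param choices Data frame of choice records with columns respondent_id,
#'   scenario_id, choice ("A"/"B"); as produced by [simulate_choices()] or
#'   read from `choices.csv`.
#' @param plan The `design_plan` the scenarios refer to.
#' @return A `choice_dataset`: difference matrix `D` (records x p, rows
#'   sorted by respondent), sign vector `y` (+1 if A chosen), respondent
#'   index, id table and dimensions.
#' @export
choice_dataset <- function(choices, plan) {
  stopifnot(inherits(plan, "design_plan"),
            all(c("respondent_id", "scenario_id", "choice") %in%
                  names(choices)))
  srow <- match(choices$scenario_id, plan$scenarios$scenario_id)
  if (anyNA(srow)) {
    stop("choice records reference unknown scenario ids: ",
         paste(utils::head(unique(choices$scenario_id[is.na(srow)]), 3L),
               collapse = ", "))
  }
  if (!all(choices$choice %in% c("A", "B"))) {
    stop("choice must be 'A' or 'B'")
  }
  ids <- unique(choices$respondent_id)
  resp <- match(choices$respondent_id, ids)
  ord <- order(resp)

  D_all <- design_difference_matrix(plan)
  structure(
    list(D = D_all[srow[ord], , drop = FALSE],
         y = ifelse(choices$choice[ord] == "A", 1, -1),
         resp = resp[ord],
         respondent_ids = ids,
         N = length(ids),
         p = coding_dim(plan$schema),
         schema = plan$schema),
    class = "choice_dataset"
  )
}

#' Binary-logit choice log-likelihood for one part-worth vector
#'
#' `sum(log plogis(y * D beta))` with `y = +1` where A was chosen and `-1`
#' otherwise; invariant to jointly swapping the A/B labels and the choice.
#'
#' @param beta Numeric vector of length p.
#' @param D Utility-difference matrix (records x p).
#' @param y Sign vector (+1 A chosen, -1 B chosen).
#' @return Log-likelihood (scalar).
#' @export
choice_log_likelihood <- function(beta, D, y) {
  D <- as.matrix(D)
  if (length(beta) != ncol(D)) {
    stop("beta has length ", length(beta), " but D has ", ncol(D),
         " columns")
  }
  u <- as.numeric(D %*% beta) * y
  sum(ifelse(u > 0, -log1p(exp(-u)), u - log1p(exp(u))))
}

#' Sampler configuration
#'
#' @param n_chains Number of independent chains (>= 2 enables R-hat).
#' @param n_iter Iterations per chain.
#' @param n_burnin Burn-in iterations (adaptation window; must be
#'   < `n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param tau2 Prior variance of each component of mu.
#' @param prior_df Inverse-Wishart degrees of freedom; default p + 2 (set at
#'   fit time when `NULL`).
#' @param target_accept Adaptation target for the per-respondent
#'   random-walk proposal scale.
#' @param init_scale Initial proposal scale.
#' @param indep_prob Probability of replacing the random-walk proposal by
#'   an independence proposal from the current MVN(mu, Sigma) prior, which
#'   speeds mixing when each respondent contributes few records (0
#'   disables).
#' @param save_beta Keep individual-level draws (set `FALSE` for very large
#'   N to store only their running mean).
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @return A list of class `hb_config`.
#' @export
hb_config <- function(n_chains = 2L, n_iter = 20000L, n_burnin = 10000L,
                      thin = 10L, tau2 = 100, prior_df = NULL,
                      target_accept = 0.23, init_scale = 0.5,
                      indep_prob = 0.5, save_beta = TRUE, seed = 1L) {
  stopifnot(n_burnin < n_iter, thin >= 1L, n_chains >= 1L, tau2 > 0,
            indep_prob >= 0, indep_prob < 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), tau2 = tau2,
                 prior_df = prior_df, target_accept = target_accept,
                 init_scale = init_scale, indep_prob = indep_prob,
                 save_beta = isTRUE(save_beta),
                 seed = as.integer(seed)),
            class = "hb_config")
}

#' Fit the hierarchical Bayesian choice model by MCMC
#'
#' Metropolis-within-Gibbs: blocked random-walk Metropolis updates of each
#' respondent's part-worth vector against the logit likelihood plus its
#' MVN(mu, Sigma) prior, then conjugate Gibbs updates of mu and (inverse-
#' Wishart) Sigma. Proposal scales adapt toward the target acceptance rate
#' during burn-in and are frozen afterwards. With zero records the draws
#' come straight from the priors.
#'
#' @param data A `choice_dataset`.
#' @param config An `hb_config`.
#' @return A `posterior_draws` object: one element per chain with matrices
#'   `mu` (draws x p), `Sigma` (draws x p^2, row-major vectorised) and
#'   `beta` (N x p x draws array, if saved), plus acceptance rates and
#'   frozen proposal scales.
#' @export
run_mcmc <- function(data, config = hb_config()) {
  stopifnot(inherits(data, "choice_dataset"), inherits(config, "hb_config"))
  p <- data$p
  prior_df <- if (is.null(config$prior_df)) p + 2 else config$prior_df
  if (prior_df <= p - 1) stop("prior_df must exceed p - 1")

  # per-respondent record ranges (data rows are sorted by respondent)
  if (data$N > 0 && nrow(data$D) > 0) {
    counts <- tabulate(data$resp, nbins = data$N)
    hi <- cumsum(counts)
    lo <- c(0L, hi[-length(hi)])
  } else {
    lo <- hi <- integer(data$N)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    chains[[ch]] <- .hb_mcmc_chain(
      t(data$D), data$y, lo, hi,
      config$n_iter, config$n_burnin, config$thin,
      config$tau2, prior_df, diag(p),
      config$target_accept, config$init_scale, config$save_beta,
      config$indep_prob)
  }
  if (config$n_chains < 2L) {
    warning("fewer than 2 chains: R-hat diagnostics unavailable")
  }
  structure(list(chains = chains, p = p, N = data$N,
                 respondent_ids = data$respondent_ids,
                 schema = data$schema, config = config,
                 prior_df = prior_df),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  nk <- x$chains[[1]]$n_keep
  cat("HB posterior draws:", length(x$chains), "chains x", nk,
      "retained draws | N =", x$N, "respondents, p =", x$p, "\n")
  acc <- unlist(lapply(x$chains, `[[`, "accept_rate"))
  if (length(acc)) {
    cat(sprintf("  mean beta acceptance rate: %.3f\n", mean(acc)))
  }
  invisible(x)
}

#' Posterior point estimates
#'
#' Arithmetic means over all retained draws across chains.
#'
#' @param draws A `posterior_draws` object.
#' @return List with `beta` (N x p matrix of per-respondent posterior
#'   means), `mu` (length-p vector) and `Sigma` (p x p matrix; a mean of
#'   symmetric positive-definite draws, hence symmetric PSD).
#' @export
posterior_point_estimates <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  p <- draws$p
  mu <- colMeans(do.call(rbind, lapply(draws$chains, `[[`, "mu")))
  Sigma <- matrix(colMeans(do.call(rbind,
                                   lapply(draws$chains, `[[`, "Sigma"))),
                  p, p)
  beta <- NULL
  if (draws$N > 0) {
    per_chain <- lapply(draws$chains, function(ch) {
      if (!is.null(ch$beta)) {
        apply(ch$beta, c(1, 2), mean)
      } else {
        ch$beta_mean
      }
    })
    beta <- Reduce(`+`, per_chain) / length(per_chain)
    rownames(beta) <- draws$respondent_ids
  }
  list(beta = beta, mu = mu, Sigma = Sigma)
}

#' MCMC convergence diagnostics
#'
#' Split R-hat and effective sample size for each component of mu and each
#' diagonal element of Sigma, computed across chains. Constant (degenerate)
#' parameters are reported as such rather than producing division errors.
#'
#' @param draws A `posterior_draws` object (>= 2 chains for meaningful
#'   R-hat).
#' @param rhat_threshold Flagging threshold (default 1.1).
#' @return Data frame: parameter, mean, sd, rhat, ess, flagged, degenerate.
#' @export
diagnostics <- function(draws, rhat_threshold = 1.1) {
  stopifnot(inherits(draws, "posterior_draws"))
  p <- draws$p
  mats <- lapply(draws$chains, function(ch) {
    cbind(ch$mu, ch$Sigma[, (seq_len(p) - 1L) * p + seq_len(p),
                          drop = FALSE])
  })
  par_names <- c(paste0("mu[", seq_len(p), "]"),
                 paste0("Sigma[", seq_len(p), ",", seq_len(p), "]"))
  out <- lapply(seq_along(par_names), function(j) {
    ch <- lapply(mats, function(m) m[, j])
    all_draws <- unlist(ch)
    degenerate <- stats::sd(all_draws) < 1e-12
    r <- if (degenerate) NA_real_ else split_rhat(ch)
    e <- if (degenerate) NA_real_ else ess_scalar(ch)
    data.frame(parameter = par_names[j],
               mean = mean(all_draws), sd = stats::sd(all_draws),
               rhat = r, ess = e,
               flagged = !degenerate && is.finite(r) && r > rhat_threshold,
               degenerate = degenerate)
  })
  do.call(rbind, out)
}

# Split-R-hat (each chain halved, between/within variance ratio).
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W < 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size: multi-chain autocorrelation estimate with Geyer
# initial-positive-pair truncation.
ess_scalar <- function(chain_list) {
  n <- min(lengths(chain_list))
  m <- length(chain_list)
  chain_list <- lapply(chain_list, function(x) x[seq_len(n)])
  W <- mean(vapply(chain_list, stats::var, numeric(1)))
  means <- vapply(chain_list, mean, numeric(1))
  B_over_n <- if (m > 1) stats::var(means) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  if (var_plus < 1e-300) return(NA_real_)

  acov <- vapply(chain_list, function(x) {
    a <- stats::acf(x, lag.max = min(n - 1L, 1000L), plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(min(n - 1L, 1000L) + 1L))
  acov <- rowMeans(acov)
  rho <- 1 - (W - acov) / var_plus
  rho[1] <- 1

  # sum initial positive pairs
  s <- 0
  t <- 1L
  while (t + 1L < length(rho)) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

#' Pooled (no-heterogeneity) logit maximum likelihood
#'
#' Fits a single shared part-worth vector to all records by logistic
#' regression on the utility differences — the classical aggregate-logit
#' oracle the hierarchical posterior mean of mu must agree with when
#' heterogeneity is absent and data are plentiful.
#'
#' @param data A `choice_dataset`.
#' @return List: `coef`, `se`, `vcov`, `loglik`, `separation` (TRUE when
#'   fitted probabilities hit 0/1, i.e. the MLE is unbounded).
#' @export
pooled_logit_mle <- function(data) {
  stopifnot(inherits(data, "choice_dataset"))
  if (nrow(data$D) == 0L) stop("no records")
  y01 <- as.integer(data$y > 0)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(data$D, y01, family = stats::binomial(),
                   intercept = FALSE),
    warning = function(w) {
      if (grepl("0 or 1", conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  eta <- as.numeric(data$D %*% fit$coefficients)
  pr <- stats::plogis(eta)
  if (any(pr < 1e-10) || any(pr > 1 - 1e-10)) sep <- TRUE
  Wd <- pr * (1 - pr)
  info <- crossprod(data$D * sqrt(Wd))
  vc <- tryCatch(solve(info), error = function(e) {
    sep <<- TRUE
    matrix(NA_real_, data$p, data$p)
  })
  list(coef = stats::setNames(fit$coefficients,
                              paste0("b", seq_len(data$p))),
       se = sqrt(diag(vc)), vcov = vc,
       loglik = choice_log_likelihood(fit$coefficients, data$D, data$y),
       separation = sep)
}
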