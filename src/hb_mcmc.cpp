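// Metropolis-within-Gibbs sampler for the hierarchical Bayesian binary-logit
// choice model:
//   choice_r ~ Bernoulli(plogis(d_r' beta_i)),  d = x_A - x_B
//   beta_i ~ MVN(mu, Sigma)
//   mu ~ N(0, tau2 I),  Sigma ~ Inverse-Wishart(prior_df, prior_scale)
// Individual betas get blocked Metropolis updates mixing (i) a random walk
// shaped by the current chol(Sigma), with a per-respondent scalar scale
// adapted toward a target acceptance rate during burn-in (frozen
// afterwards), and (ii) an independence proposal from the current
// MVN(mu, Sigma) prior, whose acceptance ratio reduces to the likelihood
// ratio and which decorrelates the hierarchy quickly when each respondent
// contributes few records. mu and Sigma get conjugate Gibbs updates. All
// randomness goes through R's RNG so set.seed() on the R side makes a chain
// fully reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// log plogis(u), numerically stable on both tails
static inline double log_logistic(double u) {
  if (u > 0.0) return -std::log1p(std::exp(-u));
  return u - std::log1p(std::exp(u));
}

// log-likelihood of one respondent's records [lo, hi): sum log plogis(s d'b)
static double loglik_resp(const arma::mat& Dt, const arma::vec& sgn,
                          int lo, int hi, const arma::vec& beta) {
  double ll = 0.0;
  for (int r = lo; r < hi; ++r) {
    ll += log_logistic(sgn[r] * arma::dot(Dt.col(r), beta));
  }
  return ll;
}

// Inverse-Wishart(df, S) draw via the Bartlett decomposition of
// Wishart(df, S^{-1})
static arma::mat riwishart(double df, const arma::mat& S) {
  const int p = S.n_rows;
  arma::mat L = arma::chol(arma::inv_sympd(S), "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    A(j, j) = std::sqrt(R::rchisq(df - j));
    for (int k = 0; k < j; ++k) A(j, k) = norm_rand();
  }
  arma::mat LA = L * A;
  return arma::inv_sympd(LA * LA.t());
}

// [[Rcpp::export(name = ".hb_mcmc_chain")]]
List hb_mcmc_chain(const arma::mat& Dt,      // p x n_records (transposed)
                   const arma::vec& sgn,     // +1 if A chosen, -1 if B
                   const arma::ivec& rec_lo, // per-respondent record start
                   const arma::ivec& rec_hi, // per-respondent record end
                   int n_iter, int burnin, int thin,
                   double tau2, double prior_df, const arma::mat& prior_scale,
                   double target_accept, double init_scale, bool save_beta,
                   double indep_prob = 0.25) {
  const int p = Dt.n_rows;
  const int N = rec_lo.n_elem;
  const int n_keep = (burnin < n_iter) ? (n_iter - burnin) / thin : 0;

  arma::mat beta(N, p, arma::fill::zeros);
  arma::vec mu(p, arma::fill::zeros);
  arma::mat Sigma = arma::eye(p, p);
  arma::mat Sigmainv = arma::eye(p, p);
  arma::mat Sigchol = arma::eye(p, p);  // lower chol(Sigma)

  arma::vec scale(N);
  scale.fill(init_scale);
  arma::vec ll_cur(N, arma::fill::zeros);
  for (int i = 0; i < N; ++i) {
    ll_cur[i] = loglik_resp(Dt, sgn, rec_lo[i], rec_hi[i], beta.row(i).t());
  }

  arma::vec mu_draw_store;
  arma::mat mu_draws(n_keep, p);
  arma::mat Sigma_draws(n_keep, p * p);
  arma::cube beta_draws;
  if (save_beta && N > 0) beta_draws.set_size(N, p, n_keep);
  arma::mat beta_sum(std::max(N, 1), p, arma::fill::zeros);

  arma::ivec acc_batch(N, arma::fill::zeros);
  arma::ivec rw_att(N, arma::fill::zeros);
  arma::ivec acc_post(N, arma::fill::zeros);
  const int batch_len = 50;
  int batch_no = 0;
  int kept = 0;

  for (int t = 1; t <= n_iter; ++t) {
    // (a) blocked Metropolis update of each beta_i
    for (int i = 0; i < N; ++i) {
      arma::vec cur = beta.row(i).t();
      arma::vec z(p);
      for (int j = 0; j < p; ++j) z[j] = norm_rand();
      bool indep = unif_rand() < indep_prob;
      arma::vec prop = indep ? arma::vec(mu + Sigchol * z)
                             : arma::vec(cur + scale[i] * (Sigchol * z));
      double llp = loglik_resp(Dt, sgn, rec_lo[i], rec_hi[i], prop);
      if (!std::isfinite(llp)) stop("non-finite likelihood in beta update");
      double lr;
      if (indep) {
        // proposal density equals the prior: prior terms cancel
        lr = llp - ll_cur[i];
      } else {
        arma::vec dc = cur - mu, dp = prop - mu;
        lr = llp - ll_cur[i]
          - 0.5 * (arma::dot(dp, Sigmainv * dp)
                   - arma::dot(dc, Sigmainv * dc));
      }
      if (!indep) rw_att[i]++;  // adaptation tracks only the RW kernel
      if (std::log(unif_rand()) < lr) {
        beta.row(i) = prop.t();
        ll_cur[i] = llp;
        if (!indep) acc_batch[i]++;
        if (t > burnin) acc_post[i]++;
      }
    }

    // proposal-scale adaptation in burn-in batches, frozen afterwards
    if (t <= burnin && t % batch_len == 0) {
      ++batch_no;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batch_no));
      for (int i = 0; i < N; ++i) {
        double rate = rw_att[i] > 0
          ? (double)acc_batch[i] / rw_att[i] : target_accept;
        scale[i] *= std::exp(rate > target_accept ? delta : -delta);
        scale[i] = std::min(10.0, std::max(1e-3, scale[i]));
        acc_batch[i] = 0;
        rw_att[i] = 0;
      }
    }

    // (b) conjugate Gibbs update of mu | beta, Sigma
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z[j] = norm_rand();
    if (N > 0) {
      arma::mat Vinv = (double)N * Sigmainv;
      Vinv.diag() += 1.0 / tau2;
      arma::vec rhs = Sigmainv * arma::sum(beta, 0).t();
      arma::vec m = arma::solve(Vinv, rhs, arma::solve_opts::likely_sympd);
      arma::mat R = arma::chol(Vinv);  // upper: R'R = Vinv
      mu = m + arma::solve(arma::trimatu(R), z);
    } else {
      mu = std::sqrt(tau2) * z;
    }

    // (c) conjugate inverse-Wishart Gibbs update of Sigma | beta, mu
    arma::mat S = prior_scale;
    for (int i = 0; i < N; ++i) {
      arma::vec d = beta.row(i).t() - mu;
      S += d * d.t();
    }
    Sigma = riwishart(prior_df + N, S);
    Sigmainv = arma::inv_sympd(Sigma);
    Sigchol = arma::chol(Sigma, "lower");

    if (t > burnin && (t - burnin) % thin == 0) {
      mu_draws.row(kept) = mu.t();
      Sigma_draws.row(kept) = arma::vectorise(Sigma).t();
      if (save_beta && N > 0) beta_draws.slice(kept) = beta;
      if (N > 0) beta_sum.rows(0, N - 1) += beta;
      ++kept;
    }
  }

  List out = List::create(
    Named("mu") = mu_draws,
    Named("Sigma") = Sigma_draws,
    Named("accept_rate") = (n_iter > burnin)
      ? arma::conv_to<arma::vec>::from(acc_post) / (double)(n_iter - burnin)
      : arma::vec(N, arma::fill::zeros),
    Named("proposal_scale") = scale,
    Named("n_keep") = n_keep);
  if (save_beta && N > 0) {
    out["beta"] = beta_draws;
  } else if (N > 0 && n_keep > 0) {
    out["beta_mean"] = beta_sum.rows(0, N - 1) / (double)n_keep;
  }
  return out;
}
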