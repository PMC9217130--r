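#include <Rcpp.h>
using namespace Rcpp;

// Delta-rule Q-learning with softmax choice for a two-option
// pain-avoidance task. Outcomes are coded -1 (pain) / 0 (no pain),
// Q values start at -0.5 and stay in [-1, 0]; only the chosen
// option's Q is updated.

static inline double softmax_ll(double q0, double q1, int choice, double beta) {
  // log P(choice) under softmax with inverse temperature beta
  double x0 = beta * q0, x1 = beta * q1;
  double m = (x0 > x1) ? x0 : x1;
  double lse = m + std::log(std::exp(x0 - m) + std::exp(x1 - m));
  return (choice == 0 ? x0 : x1) - lse;
}

// [[Rcpp::export(name = ".seq_loglik_cpp")]]
double seq_loglik_cpp(IntegerVector choice, IntegerVector outcome,
                      double a_pain, double a_nopain, double beta) {
  int n = choice.size();
  double q0 = -0.5, q1 = -0.5, ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int c = choice[t], o = outcome[t];
    ll += softmax_ll(q0, q1, c, beta);
    double a = (o == -1) ? a_pain : a_nopain;
    if (c == 0) q0 += a * (o - q0); else q1 += a * (o - q1);
  }
  return ll;
}

// [[Rcpp::export(name = ".expected_pain_cpp")]]
NumericVector expected_pain_cpp(IntegerVector choice, IntegerVector outcome,
                                double a_pain, double a_nopain) {
  int n = choice.size();
  NumericVector out(n);
  double q0 = -0.5, q1 = -0.5;
  for (int t = 0; t < n; ++t) {
    int c = choice[t], o = outcome[t];
    out[t] = -(c == 0 ? q0 : q1);  // pre-outcome expectation of chosen option
    double a = (o == -1) ? a_pain : a_nopain;
    if (c == 0) q0 += a * (o - q0); else q1 += a * (o - q1);
  }
  return out;
}

// [[Rcpp::export(name = ".simulate_agent_cpp")]]
List simulate_agent_cpp(NumericMatrix pain_prob, double a_pain, double a_nopain,
                        double beta, double lapse_rate) {
  int n = pain_prob.nrow();
  IntegerVector choice(n), outcome(n);
  LogicalVector missed(n);
  double q0 = -0.5, q1 = -0.5;
  for (int t = 0; t < n; ++t) {
    int c;
    if (unif_rand() < lapse_rate) {
      c = (unif_rand() < 0.5) ? 0 : 1;  // random fallback when no response
      missed[t] = true;
    } else {
      double p0 = 1.0 / (1.0 + std::exp(-beta * (q0 - q1)));
      c = (unif_rand() < p0) ? 0 : 1;
      missed[t] = false;
    }
    int o = (unif_rand() < pain_prob(t, c)) ? -1 : 0;
    choice[t] = c;
    outcome[t] = o;
    double a = (o == -1) ? a_pain : a_nopain;
    if (c == 0) q0 += a * (o - q0); else q1 += a * (o - q1);
  }
  return List::create(_["choice"] = choice, _["outcome"] = outcome,
                      _["missed"] = missed);
}

// Per-draw, per-subject log-likelihoods for stored posterior draws.
// a_pain, a_nopain, beta: draws x subjects matrices of constrained values.
// [[Rcpp::export(name = ".pointwise_loglik_cpp")]]
NumericMatrix pointwise_loglik_cpp(IntegerMatrix choices, IntegerMatrix outcomes,
                                   IntegerVector n_trials,
                                   NumericMatrix a_pain, NumericMatrix a_nopain,
                                   NumericMatrix beta) {
  int D = a_pain.nrow(), S = a_pain.ncol();
  NumericMatrix ll(D, S);
  for (int s = 0; s < S; ++s) {
    int n = n_trials[s];
    IntegerVector ch(n), oc(n);
    for (int t = 0; t < n; ++t) { ch[t] = choices(s, t); oc[t] = outcomes(s, t); }
    for (int d = 0; d < D; ++d)
      ll(d, s) = seq_loglik_cpp(ch, oc, a_pain(d, s), a_nopain(d, s), beta(d, s));
  }
  return ll;
}

// ---------------------------------------------------------------------------
// Hierarchical sampler: adaptive Metropolis-within-Gibbs, one chain.
//
// Non-centered parameterization: subject-level unconstrained parameter
// j of subject s is mu[j] + sigma[j] * z[s][j], mapped through the
// inverse-probit transform (rates -> [0,1]; beta -> [0,20]).
// Hyperpriors: mu ~ Normal(0,1), sigma ~ half-Cauchy(0,5).
// Proposal scales adapt toward ~0.44 acceptance during warmup only.
// ---------------------------------------------------------------------------

struct HierModel {
  const IntegerMatrix &choices, &outcomes;
  const IntegerVector &n_trials;
  int S, P, model;  // model: 1 = single learning rate, 2 = dual

  HierModel(const IntegerMatrix &ch, const IntegerMatrix &oc,
            const IntegerVector &nt, int model_)
    : choices(ch), outcomes(oc), n_trials(nt),
      S(ch.nrow()), P(model_ == 2 ? 3 : 2), model(model_) {}

  // constrained (a_pain, a_nopain, beta) for subject s given hypers and z
  void constrain_subject(const std::vector<double> &mu,
                         const std::vector<double> &sigma,
                         const std::vector<double> &z_s,
                         double &ap, double &anp, double &bt) const {
    if (model == 2) {
      ap  = R::pnorm(mu[0] + sigma[0] * z_s[0], 0.0, 1.0, 1, 0);
      anp = R::pnorm(mu[1] + sigma[1] * z_s[1], 0.0, 1.0, 1, 0);
      bt  = 20.0 * R::pnorm(mu[2] + sigma[2] * z_s[2], 0.0, 1.0, 1, 0);
    } else {
      ap  = R::pnorm(mu[0] + sigma[0] * z_s[0], 0.0, 1.0, 1, 0);
      anp = ap;
      bt  = 20.0 * R::pnorm(mu[1] + sigma[1] * z_s[1], 0.0, 1.0, 1, 0);
    }
  }

  double subject_ll(int s, const std::vector<double> &mu,
                    const std::vector<double> &sigma,
                    const std::vector<std::vector<double> > &z) const {
    double ap, anp, bt;
    constrain_subject(mu, sigma, z[s], ap, anp, bt);
    int n = n_trials[s];
    double q0 = -0.5, q1 = -0.5, ll = 0.0;
    for (int t = 0; t < n; ++t) {
      int c = choices(s, t), o = outcomes(s, t);
      ll += softmax_ll(q0, q1, c, bt);
      double a = (o == -1) ? ap : anp;
      if (c == 0) q0 += a * (o - q0); else q1 += a * (o - q1);
    }
    return ll;
  }
};

static inline double lp_mu(double m) { return -0.5 * m * m; }
// half-Cauchy(0, 5) on sigma = exp(ls), with log-Jacobian ls
static inline double lp_logsigma(double ls) {
  double sig = std::exp(ls);
  return -std::log1p((sig / 5.0) * (sig / 5.0)) + ls;
}
static inline double lp_z(double zv) { return -0.5 * zv * zv; }

// [[Rcpp::export(name = ".sample_chain_cpp")]]
List sample_chain_cpp(IntegerMatrix choices, IntegerMatrix outcomes,
                      IntegerVector n_trials, int model,
                      int iter, int warmup, int thin, int sweeps,
                      NumericVector init_mu, NumericVector init_logsigma,
                      NumericMatrix init_z) {
  HierModel hm(choices, outcomes, n_trials, model);
  const int S = hm.S, P = hm.P;

  std::vector<double> mu(P), ls(P), sigma(P);
  std::vector<std::vector<double> > z(S, std::vector<double>(P));
  for (int j = 0; j < P; ++j) {
    mu[j] = init_mu[j];
    ls[j] = init_logsigma[j];
    sigma[j] = std::exp(ls[j]);
  }
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < P; ++j) z[s][j] = init_z(s, j);

  std::vector<double> subj_ll(S);
  for (int s = 0; s < S; ++s) subj_ll[s] = hm.subject_ll(s, mu, sigma, z);

  // proposal log-scales and acceptance bookkeeping
  std::vector<double> scale_mu(P, 0.1), scale_ls(P, 0.1);
  std::vector<std::vector<double> > scale_z(S, std::vector<double>(P, 0.4));
  std::vector<int> acc_mu(P, 0), try_mu(P, 0), acc_ls(P, 0), try_ls(P, 0);
  std::vector<std::vector<int> > acc_z(S, std::vector<int>(P, 0)),
      try_z(S, std::vector<int>(P, 0));
  std::vector<double> scale_joint(S, 0.25);
  std::vector<int> acc_joint(S, 0), try_joint(S, 0);

  const int n_keep = (iter - warmup) / thin;
  NumericMatrix mu_draws(n_keep, P), sigma_draws(n_keep, P),
      mu_c_draws(n_keep, P), ll_draws(n_keep, S);
  NumericVector subj_draws(Dimension(n_keep, S, P));

  int batch = 0, kept = 0;
  const int batch_len = 50;

  for (int it = 1; it <= iter; ++it) {
   for (int sweep = 0; sweep < sweeps; ++sweep) {
    // --- group-level means ---
    for (int j = 0; j < P; ++j) {
      double prop = mu[j] + norm_rand() * scale_mu[j];
      double old_sum = 0.0, new_sum = 0.0;
      std::vector<double> new_ll(S);
      double keep_mu = mu[j];
      mu[j] = prop;
      for (int s = 0; s < S; ++s) { new_ll[s] = hm.subject_ll(s, mu, sigma, z); new_sum += new_ll[s]; }
      for (int s = 0; s < S; ++s) old_sum += subj_ll[s];
      double lacc = new_sum - old_sum + lp_mu(prop) - lp_mu(keep_mu);
      ++try_mu[j];
      if (std::log(unif_rand()) < lacc) { subj_ll = new_ll; ++acc_mu[j]; }
      else mu[j] = keep_mu;
    }
    // --- group-level SDs (log scale) ---
    for (int j = 0; j < P; ++j) {
      double prop = ls[j] + norm_rand() * scale_ls[j];
      double keep_ls = ls[j], keep_sig = sigma[j];
      ls[j] = prop; sigma[j] = std::exp(prop);
      double old_sum = 0.0, new_sum = 0.0;
      std::vector<double> new_ll(S);
      for (int s = 0; s < S; ++s) { new_ll[s] = hm.subject_ll(s, mu, sigma, z); new_sum += new_ll[s]; }
      for (int s = 0; s < S; ++s) old_sum += subj_ll[s];
      double lacc = new_sum - old_sum + lp_logsigma(prop) - lp_logsigma(keep_ls);
      ++try_ls[j];
      if (std::log(unif_rand()) < lacc) { subj_ll = new_ll; ++acc_ls[j]; }
      else { ls[j] = keep_ls; sigma[j] = keep_sig; }
    }
    // --- subject-level standardized deviations ---
    for (int s = 0; s < S; ++s) {
      for (int j = 0; j < P; ++j) {
        double keep_z = z[s][j];
        double prop = keep_z + norm_rand() * scale_z[s][j];
        z[s][j] = prop;
        double new_ll_s = hm.subject_ll(s, mu, sigma, z);
        double lacc = new_ll_s - subj_ll[s] + lp_z(prop) - lp_z(keep_z);
        ++try_z[s][j];
        if (std::log(unif_rand()) < lacc) { subj_ll[s] = new_ll_s; ++acc_z[s][j]; }
        else z[s][j] = keep_z;
      }
      // joint isotropic move across this subject's deviations: mixes along
      // the within-subject learning-rate/inverse-temperature ridge that
      // component-wise updates traverse slowly
      {
        std::vector<double> keep(P);
        double dlp = 0.0;
        for (int j = 0; j < P; ++j) {
          keep[j] = z[s][j];
          double prop = keep[j] + norm_rand() * scale_joint[s];
          dlp += lp_z(prop) - lp_z(keep[j]);
          z[s][j] = prop;
        }
        double new_ll_s = hm.subject_ll(s, mu, sigma, z);
        ++try_joint[s];
        if (std::log(unif_rand()) < new_ll_s - subj_ll[s] + dlp) {
          subj_ll[s] = new_ll_s; ++acc_joint[s];
        } else {
          for (int j = 0; j < P; ++j) z[s][j] = keep[j];
        }
      }
    }

    // --- interweaved centered-coordinate update of the hyperparameters ---
    // Holding the subject-level unconstrained values theta_s = mu + sigma*z_s
    // fixed (so the likelihood is unchanged), mu has a conjugate normal
    // conditional and log sigma a cheap prior-only conditional; updating in
    // these coordinates and mapping back to z decorrelates the hypers from
    // the subject-level deviations and greatly improves mixing.
    for (int j = 0; j < P; ++j) {
      std::vector<double> theta(S);
      double sum_theta = 0.0;
      for (int s = 0; s < S; ++s) { theta[s] = mu[j] + sigma[j] * z[s][j]; sum_theta += theta[s]; }
      // Gibbs: mu | theta, sigma  with prior Normal(0, 1)
      double prec = 1.0 + (double)S / (sigma[j] * sigma[j]);
      double mean = (sum_theta / (sigma[j] * sigma[j])) / prec;
      mu[j] = mean + norm_rand() / std::sqrt(prec);
      // MH on log sigma | theta, mu (prior + normal density of theta)
      double ss = 0.0;
      for (int s = 0; s < S; ++s) { double d = theta[s] - mu[j]; ss += d * d; }
      for (int rep = 0; rep < 2; ++rep) {
        double cur = ls[j];
        double prop = cur + 0.4 * norm_rand();
        double lp_cur = lp_logsigma(cur) - S * cur - 0.5 * ss * std::exp(-2.0 * cur);
        double lp_prop = lp_logsigma(prop) - S * prop - 0.5 * ss * std::exp(-2.0 * prop);
        if (std::log(unif_rand()) < lp_prop - lp_cur) {
          ls[j] = prop; sigma[j] = std::exp(prop);
        }
      }
      for (int s = 0; s < S; ++s) z[s][j] = (theta[s] - mu[j]) / sigma[j];
    }
   } // sweeps

    // --- adaptation (warmup only), diminishing batch adjustments ---
    if (it <= warmup && it % batch_len == 0) {
      ++batch;
      double delta = std::min(0.25, 1.0 / std::sqrt((double)batch));
      for (int j = 0; j < P; ++j) {
        if (try_mu[j] > 0)
          scale_mu[j] *= std::exp(((double)acc_mu[j] / try_mu[j] > 0.44 ? 1 : -1) * delta);
        if (try_ls[j] > 0)
          scale_ls[j] *= std::exp(((double)acc_ls[j] / try_ls[j] > 0.44 ? 1 : -1) * delta);
        acc_mu[j] = try_mu[j] = acc_ls[j] = try_ls[j] = 0;
      }
      for (int s = 0; s < S; ++s) {
        for (int j = 0; j < P; ++j) {
          if (try_z[s][j] > 0)
            scale_z[s][j] *= std::exp(((double)acc_z[s][j] / try_z[s][j] > 0.44 ? 1 : -1) * delta);
          acc_z[s][j] = try_z[s][j] = 0;
        }
        if (try_joint[s] > 0)
          scale_joint[s] *= std::exp(((double)acc_joint[s] / try_joint[s] > 0.234 ? 1 : -1) * delta);
        acc_joint[s] = try_joint[s] = 0;
      }
    }

    // --- retain ---
    if (it > warmup && (it - warmup) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < P; ++j) {
        mu_draws(kept, j) = mu[j];
        sigma_draws(kept, j) = sigma[j];
        double cm = R::pnorm(mu[j], 0.0, 1.0, 1, 0);
        bool is_beta = (model == 2) ? (j == 2) : (j == 1);
        mu_c_draws(kept, j) = is_beta ? 20.0 * cm : cm;
      }
      for (int s = 0; s < S; ++s) {
        double ap, anp, bt;
        hm.constrain_subject(mu, sigma, z[s], ap, anp, bt);
        if (model == 2) {
          subj_draws[kept + n_keep * (s + S * 0)] = ap;
          subj_draws[kept + n_keep * (s + S * 1)] = anp;
          subj_draws[kept + n_keep * (s + S * 2)] = bt;
        } else {
          subj_draws[kept + n_keep * (s + S * 0)] = ap;
          subj_draws[kept + n_keep * (s + S * 1)] = bt;
        }
        ll_draws(kept, s) = subj_ll[s];
      }
      ++kept;
    }
  }

  double acc_total = 0.0; int try_total = 0;
  for (int j = 0; j < P; ++j) { acc_total += acc_mu[j] + acc_ls[j]; try_total += try_mu[j] + try_ls[j]; }
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < P; ++j) { acc_total += acc_z[s][j]; try_total += try_z[s][j]; }

  return List::create(
    _["mu"] = mu_draws, _["sigma"] = sigma_draws,
    _["mu_constrained"] = mu_c_draws, _["subject"] = subj_draws,
    _["log_lik"] = ll_draws,
    _["acc_rate"] = try_total > 0 ? acc_total / try_total : NA_REAL);
}
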