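# Independent brute-force oracles, written directly from the model
# equations and kept free of the package's incremental code paths.

# Trial-by-trial recomputation of the sequence log-likelihood: re-derives
# the Q history from scratch at every trial.
oracle_loglik <- function(choice, outcome, a_pain, a_nopain, beta) {
  n <- length(choice)
  total <- 0
  for (t in seq_len(n)) {
    # rebuild Q at the start of trial t from the full history
    q <- c(-0.5, -0.5)
    if (t > 1) {
      for (u in seq_len(t - 1)) {
        a <- if (outcome[u] == -1) a_pain else a_nopain
        q[choice[u] + 1] <- q[choice[u] + 1] + a * (outcome[u] - q[choice[u] + 1])
      }
    }
    num <- exp(beta * q[choice[t] + 1])
    den <- exp(beta * q[1]) + exp(beta * q[2])
    total <- total + log(num / den)
  }
  total
}

# Direct-formula WAIC on a draws x observations matrix, no log-sum-exp.
oracle_waic <- function(ll) {
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, var))
  list(lppd = lppd, p_waic = p, waic = -2 * (lppd - p))
}

# Exhaustive switch-rate enumeration.
oracle_switch <- function(choice, outcome) {
  n <- length(choice)
  sw_pain <- c(); sw_nopain <- c()
  for (t in seq_len(n - 1)) {
    sw <- choice[t + 1] != choice[t]
    if (outcome[t] == -1) sw_pain <- c(sw_pain, sw) else sw_nopain <- c(sw_nopain, sw)
  }
  list(pain_count = sum(outcome == -1),
       rate_after_pain = if (length(sw_pain)) mean(sw_pain) else NA_real_,
       rate_after_nopain = if (length(sw_nopain)) mean(sw_nopain) else NA_real_)
}

# One-way ANOVA from explicit sums of squares.
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ss_total <- sum((values - gm)^2)
  ss_b <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_b <- ss_b + length(v) * (mean(v) - gm)^2
  }
  ss_w <- ss_total - ss_b
  df_b <- length(unique(groups)) - 1
  df_w <- length(values) - length(unique(groups))
  list(F = (ss_b / df_b) / (ss_w / df_w), eta_squared = ss_b / ss_total,
       df = c(df_b, df_w))
}

# Random short trial sequence as a data.frame.
random_trials <- function(n) {
  data.frame(trial = seq_len(n),
             choice = sample(0:1, n, replace = TRUE),
             outcome = sample(c(-1L, 0L), n, replace = TRUE))
}

# Light sampler settings shared by the slower estimation tests.
fit_reduced <- function(data, model = "dual", seed = 1L) {
  pal_fit(data, model = model, chains = 2L, iter = 1500L, warmup = 500L,
          thin = 5L, seed = seed)
}
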