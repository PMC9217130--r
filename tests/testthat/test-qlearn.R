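# Core learning and choice equations.

test_that("delta-rule update matches its closed form and boundary cases", {
  expect_identical(update_q(-0.5, 0, -1), -0.5)   # no learning
  expect_identical(update_q(-0.5, 1, -1), -1.0)   # full update to the outcome
  expect_equal(update_q(-0.5, 0.72, -1), -0.86)   # -0.5 + 0.72 * (-0.5)
  expect_equal(update_q(-0.9, 0.3, 0), -0.63)
  expect_error(update_q(-0.5, 1.2, -1), "alpha")
  expect_error(update_q(-0.5, 0.5, 1), "outcome")
})

test_that("updated Q stays in [-1, 0] for any valid alpha/outcome (convexity)", {
  set.seed(7)
  for (i in 1:500) {
    q <- runif(1, -1, 0)
    a <- runif(1)
    o <- sample(c(-1, 0), 1)
    q2 <- update_q(q, a, o)
    expect_gte(q2, -1)
    expect_lte(q2, 0)
  }
})

test_that("softmax choice probabilities behave as specified", {
  expect_equal(choice_prob(c(-0.5, -0.5), 8.8), c(0.5, 0.5))
  expect_equal(choice_prob(c(-0.2, -0.8), 0), c(0.5, 0.5))
  p <- choice_prob(c(-0.2, -0.8), 8.8)
  expect_equal(p[1], 1 / (1 + exp(-8.8 * 0.6)), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-14)
  expect_error(choice_prob(c(-0.2, -0.8), -1), "beta")
  expect_error(choice_prob(c(-0.2), 1), "length 2")
})

test_that("softmax favors the better option, monotonically in beta", {
  set.seed(11)
  for (i in 1:200) {
    q <- sort(runif(2, -1, 0))  # q[2] is the better (less negative) option
    betas <- sort(runif(3, 0, 20))
    ps <- vapply(betas, function(b) choice_prob(q, b)[2], numeric(1))
    expect_true(all(ps >= 0.5 - 1e-12))
    expect_true(all(diff(ps) >= -1e-12))
    expect_equal(sum(choice_prob(q, betas[2])), 1, tolerance = 1e-12)
  }
})

test_that("sequence log-likelihood matches the brute-force oracle", {
  set.seed(23)
  for (i in 1:1000) {
    n <- sample(1:12, 1)
    tr <- random_trials(n)
    ap <- runif(1); anp <- runif(1); b <- runif(1, 0, 20)
    expect_equal(pal_loglik(tr, ap, anp, b),
                 oracle_loglik(tr$choice, tr$outcome, ap, anp, b),
                 tolerance = 1e-10)
  }
})

test_that("sequence log-likelihood special cases", {
  tr1 <- data.frame(choice = 0L, outcome = -1L)
  expect_equal(pal_loglik(tr1, 0.5, 0.5, 7), log(0.5))  # symmetric start
  # beta = 0: every choice has probability 0.5
  tr <- random_trials(20)
  expect_equal(pal_loglik(tr, 0.9, 0.1, 0), 20 * log(0.5))
  # two-trial toy, hand-computed: choose 0 (pain, alpha_pain = 1), then choose 1
  toy <- data.frame(choice = c(0L, 1L), outcome = c(-1L, 0L))
  expected <- log(0.5) + log(exp(2 * -0.5) / (exp(2 * -1) + exp(2 * -0.5)))
  expect_equal(pal_loglik(toy, 1, 0.3, 2), expected, tolerance = 1e-12)
  expect_error(pal_loglik(data.frame(choice = integer(), outcome = integer()),
                          0.5, 0.5, 1), "at least 1")
})

test_that("expected pain trajectory is -Q of the chosen option", {
  # repeated pain on one option at alpha_pain = 0.5: 0.5, 0.75, 0.875, ...
  tr <- data.frame(choice = rep(0L, 5), outcome = rep(-1L, 5))
  expect_equal(expected_pain_trajectory(tr, 0.5, 0.2),
               c(0.5, 0.75, 0.875, 0.9375, 0.96875))
  # no learning: constant initialization value
  tr2 <- random_trials(30)
  expect_equal(expected_pain_trajectory(tr2, 0, 0), rep(0.5, 30))
  # first trial is always 0.5
  set.seed(3)
  for (i in 1:20) {
    tr3 <- random_trials(sample(2:20, 1))
    ep <- expected_pain_trajectory(tr3, runif(1), runif(1))
    expect_equal(ep[1], 0.5)
    expect_true(all(ep >= 0 & ep <= 1))
  }
})

test_that("agent simulation is reproducible and respects the greedy limit", {
  # deterministic environment p = (0, 1): near-greedy fast learner locks
  # onto option 0 and receives no pain after the first few trials
  env <- list(pain_prob = cbind(rep(0, 60), rep(1, 60)), n_runs = 1L)
  tr <- simulate_agent(env, 1, 1, 20, lapse_rate = 0, seed = 5)
  expect_true(all(tr$choice[11:60] == 0))
  expect_true(all(tr$outcome[11:60] == 0))
  # reproducibility
  tk <- pal_task(seed = 9)
  a <- simulate_agent(tk, 0.7, 0.3, 9, seed = 42)
  b <- simulate_agent(tk, 0.7, 0.3, 9, seed = 42)
  expect_identical(a, b)
  expect_error(simulate_agent(list(pain_prob = 1:3), 0.5, 0.5, 5), "pain_prob")
})

test_that("generating parameters outscore perturbed ones on average (self-consistency)", {
  set.seed(31)
  gen <- c(ap = 0.72, anp = 0.32, b = 8.8)
  diffs <- replicate(50, {
    tk <- pal_task()
    tr <- simulate_agent(tk, gen["ap"], gen["anp"], gen["b"])
    ll_true <- pal_loglik(tr, gen["ap"], gen["anp"], gen["b"])
    pert <- pmin(1, pmax(0, gen[c("ap", "anp")] + sample(c(-0.3, 0.3), 2, TRUE)))
    ll_pert <- pal_loglik(tr, pert[1], pert[2], gen["b"])
    ll_true - ll_pert
  })
  expect_gt(mean(diffs), 0)
})
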