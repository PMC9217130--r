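# Hierarchical inference: transforms, diagnostics, and estimation.

test_that("inverse-probit constraining transform and its inverse", {
  expect_equal(constrain_param(0, "rate"), 0.5)
  expect_equal(constrain_param(0, "beta"), 10)
  expect_equal(constrain_param(1.6449, "rate"), 0.95, tolerance = 1e-4)
  expect_equal(unconstrain_param(constrain_param(0.7, "rate"), "rate"), 0.7)
  expect_equal(unconstrain_param(constrain_param(-0.3, "beta"), "beta"), -0.3)
  expect_error(constrain_param(Inf, "rate"), "finite")
  expect_error(unconstrain_param(1.5, "rate"), "inside")
  # strict monotonicity
  x <- sort(rnorm(50))
  expect_true(all(diff(constrain_param(x, "rate")) > 0))
  expect_true(all(diff(constrain_param(x, "beta")) > 0))
})

test_that("hyperpriors cover the constrained parameter ranges", {
  set.seed(5)
  mu <- rnorm(4000, 0, 1)
  sigma <- abs(5 * tan(pi * (runif(4000) - 0.5)))  # half-Cauchy(0, 5)
  z <- rnorm(4000)
  rates <- constrain_param(mu + sigma * z, "rate")
  betas <- constrain_param(mu + sigma * z, "beta")
  # positive density across the interior of both ranges
  expect_true(all(table(cut(rates, seq(0, 1, by = 0.1))) > 0))
  expect_true(all(table(cut(betas, seq(0, 20, by = 2))) > 0))
})

test_that("split-Rhat flags constructed non-convergence and passes degenerate draws", {
  set.seed(8)
  chain <- rep(1:2, each = 400)
  x_bad <- c(rnorm(400, 0, 1), rnorm(400, 5, 1))
  expect_gt(split_rhat(x_bad, chain), 1.5)
  x_good <- rnorm(800)
  expect_lt(split_rhat(x_good, chain), 1.1)
  x_const <- rep(1.3, 800)
  expect_equal(split_rhat(x_const, chain), 1)
  expect_error(split_rhat(rnorm(100), rep(1, 100)), "2 chains")
})

test_that("fit validates its inputs", {
  coh <- simulate_cohort(3, pal_group_params("placebo"), seed = 2)
  expect_error(pal_fit(coh, iter = 0), "positive")
  expect_error(pal_fit(coh, iter = 100, warmup = 100), "warmup")
  one <- coh$trials[coh$trials$subject == 1, ]
  expect_error(pal_fit(one, chains = 2, iter = 200, warmup = 50),
               "at least 2 subjects")
})

test_that("reduced fit recovers simulated group-level parameters and asymmetry", {
  coh <- simulate_cohort(12, pal_group_params("placebo"), seed = 33)
  fit <- fit_reduced(coh, seed = 34)
  est <- coef(fit)
  # loose tolerances for the light configuration at n = 12
  expect_lt(abs(est["alpha_pain"] - 0.72), 0.2)
  expect_lt(abs(est["alpha_nopain"] - 0.32), 0.2)
  expect_lt(abs(est["beta"] - 8.8), 3.5)
  # the simulated asymmetry (0.72 vs 0.32) is detected in the posterior
  expect_gt(proportion_greater(fit$group_mean[, "alpha_pain"],
                               fit$group_mean[, "alpha_nopain"]), 0.9)
  conv <- check_convergence(fit)
  expect_true(conv$pass)
  expect_lt(conv$max_rhat, 1.1)
  # constrained draws respect their ranges; draw count matches the spec
  expect_true(all(fit$group_mean[, 1:2] >= 0 & fit$group_mean[, 1:2] <= 1))
  expect_true(all(fit$group_mean[, 3] >= 0 & fit$group_mean[, 3] <= 20))
  expect_equal(nrow(fit$group_mean), 2 * (1500 - 500) / 5)
  expect_equal(dim(fit$log_lik), c(400L, 12L))
})

test_that("default sampler settings retain 3200 draws (800 per chain)", {
  # verified on the spec arithmetic without running the full sampler
  expect_equal(4 * (5000 - 1000) %/% 5, 3200)
  coh <- simulate_cohort(4, pal_group_params("placebo"), n_trials = 36,
                         seed = 41)
  fit <- pal_fit(coh, chains = 4, iter = 250, warmup = 50, thin = 5, seed = 4)
  expect_equal(fit$diagnostics$n_draws, 4 * (250 - 50) / 5)
  expect_equal(length(unique(fit$chain)), 4L)
})

test_that("fits are reproducible from the master seed", {
  coh <- simulate_cohort(5, pal_group_params("drug"), n_trials = 72, seed = 55)
  f1 <- pal_fit(coh, chains = 2, iter = 400, warmup = 100, thin = 5, seed = 77)
  f2 <- pal_fit(coh, chains = 2, iter = 400, warmup = 100, thin = 5, seed = 77)
  expect_identical(f1$group_mean, f2$group_mean)
  expect_identical(f1$log_lik, f2$log_lik)
})

test_that("posterior-predictive simulation returns cohorts shaped like the data", {
  coh <- simulate_cohort(4, pal_group_params("placebo"), n_trials = 36,
                         seed = 58)
  fit <- pal_fit(coh, chains = 2, iter = 300, warmup = 100, thin = 5, seed = 59)
  sims <- simulate(fit, nsim = 2, seed = 60,
                   tasks = list(pal_task(n_trials = 36)))
  expect_length(sims, 2L)
  for (s in sims) {
    expect_equal(sort(unique(s$subject)), 1:4)
    expect_equal(nrow(s), 4L * 36L)
    expect_true(all(s$outcome %in% c(-1L, 0L)))
  }
})

test_that("missed trials can be excluded from the likelihood", {
  coh <- simulate_cohort(4, pal_group_params("placebo"), lapse_rate = 0.2,
                         n_trials = 72, seed = 66)
  f_in <- pal_fit(coh, chains = 2, iter = 300, warmup = 100, thin = 2, seed = 5)
  f_ex <- pal_fit(coh, chains = 2, iter = 300, warmup = 100, thin = 2, seed = 5,
                  include_missed = FALSE)
  expect_true(all(f_ex$n_trials < f_in$n_trials))
})
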