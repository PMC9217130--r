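# Model-independent behavioral metrics.

test_that("switch rates match hand enumeration", {
  # choices A A B B B, outcomes pain no pain no no
  tr <- data.frame(choice = c(0L, 0L, 1L, 1L, 1L),
                   outcome = c(-1L, 0L, -1L, 0L, 0L))
  r <- switch_rates(tr)
  expect_equal(r$pain_count, 2L)
  expect_equal(r$switch_rate_after_pain, 0)       # 0 of 2
  expect_equal(r$switch_rate_after_nopain, 0.5)   # 1 of 2
  # constant choices: both rates zero
  tr2 <- data.frame(choice = rep(1L, 6),
                    outcome = c(-1L, -1L, 0L, 0L, -1L, 0L))
  r2 <- switch_rates(tr2)
  expect_equal(r2$switch_rate_after_pain, 0)
  expect_equal(r2$switch_rate_after_nopain, 0)
  expect_error(switch_rates(tr[1, ]), "at least 2")
})

test_that("switch rates agree with brute-force enumeration on random sequences", {
  set.seed(19)
  for (i in 1:1000) {
    tr <- random_trials(sample(2:15, 1))
    r <- switch_rates(tr)
    o <- oracle_switch(tr$choice, tr$outcome)
    expect_equal(r$pain_count, o$pain_count)
    expect_equal(r$switch_rate_after_pain, o$rate_after_pain)
    expect_equal(r$switch_rate_after_nopain, o$rate_after_nopain)
  }
})

test_that("missed trials are excluded from transitions but not pain counts", {
  tr <- data.frame(choice = c(0L, 1L, 1L, 0L),
                   outcome = c(-1L, -1L, 0L, 0L),
                   missed = c(FALSE, TRUE, FALSE, FALSE))
  r <- switch_rates(tr)
  # transitions 1->2 and 2->3 dropped (trial 2 missed); only 3->4 remains
  expect_equal(r$n_after_pain, 0L)
  expect_true(is.na(r$switch_rate_after_pain))
  expect_equal(r$switch_rate_after_nopain, 1)
  expect_equal(r$pain_count, 2L)
  r_keep <- switch_rates(tr, exclude_missed = FALSE)
  expect_equal(r_keep$n_after_pain, 2L)
})

test_that("paired switch contrast reproduces the direct t formula", {
  s <- data.frame(switch_rate_after_pain = c(0.5, 0.6, 0.7),
                  switch_rate_after_nopain = c(0.1, 0.1, 0.1))
  out <- paired_switch_contrast(s)
  expect_equal(out$t, 0.5 / (sd(c(0.4, 0.5, 0.6)) / sqrt(3)), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$cohens_d, 0.5 / 0.1, tolerance = 1e-12)
  # zero differences: t = 0 by convention
  s0 <- data.frame(switch_rate_after_pain = c(0.3, 0.4),
                   switch_rate_after_nopain = c(0.3, 0.4))
  expect_equal(paired_switch_contrast(s0)$t, 0)
  # undefined rates excluded with a warning
  s_na <- rbind(s, data.frame(switch_rate_after_pain = NA,
                              switch_rate_after_nopain = 0.2))
  expect_warning(paired_switch_contrast(s_na), "excluded")
})

test_that("lagged regression: outcome-independent choices give null coefficients", {
  set.seed(20)
  trials <- do.call(rbind, lapply(1:20, function(s) {
    data.frame(subject = s, trial = 1:144,
               choice = sample(0:1, 144, replace = TRUE),
               outcome = sample(c(-1L, 0L), 144, replace = TRUE))
  }))
  lr <- lagged_switch_regression(trials)
  expect_equal(dim(lr$coefficients), c(20L, 6L))
  expect_true(all(abs(lr$summary$mean) < 0.3))
  expect_true(all(lr$summary$p > 0.001))
})

test_that("lagged regression: a strict lose-shift agent loads on lag 1 only", {
  set.seed(22)
  trials <- do.call(rbind, lapply(1:12, function(s) {
    ch <- integer(144); out <- integer(144)
    ch[1] <- sample(0:1, 1)
    out[1] <- sample(c(-1L, 0L), 1)
    for (t in 2:144) {
      ch[t] <- if (out[t - 1] == -1L) 1L - ch[t - 1] else ch[t - 1]
      out[t] <- sample(c(-1L, 0L), 1)
    }
    data.frame(subject = s, trial = 1:144, choice = ch, outcome = out)
  }))
  lr <- lagged_switch_regression(trials)
  expect_true(all(lr$penalized))  # deterministic policy separates perfectly
  expect_gt(lr$summary$mean[1], 2)
  expect_true(all(abs(lr$summary$mean[2:6]) < 1))
  expect_gt(lr$summary$mean[1], 3 * max(abs(lr$summary$mean[2:6])))
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  set.seed(24)
  v <- c(rnorm(10, 5), rnorm(12, 5.5), rnorm(9, 4.8))
  g <- rep(c("a", "b", "c"), c(10, 12, 9))
  res <- group_anova(v, g)
  o <- oracle_anova(v, g)
  expect_equal(res$F, o$F, tolerance = 1e-10)
  expect_equal(res$eta_squared, o$eta_squared, tolerance = 1e-10)
  expect_equal(unname(res$df), o$df)
  # identical groups: F = 0
  v0 <- rep(c(1, 2, 3), 2)
  g0 <- rep(c("x", "y"), each = 3)
  expect_equal(group_anova(v0, g0)$F, 0)
  expect_error(group_anova(1:5, rep("a", 5)), "2 groups")
  expect_error(group_anova(1:3, c("a", "a", "b")), "at least 2 subjects")
})

test_that("simulated placebo- and drug-like cohorts perform alike (effects cancel)", {
  set.seed(26)
  reps <- 12
  p_pain <- numeric(reps); p_switch <- numeric(reps)
  for (i in 1:reps) {
    tasks <- lapply(1:3, function(k) pal_task())
    a <- simulate_cohort(14, pal_group_params("placebo"), tasks = tasks)
    b <- simulate_cohort(14, pal_group_params("drug"), tasks = tasks)
    sa <- switch_summary(a); sb <- switch_summary(b)
    p_pain[i] <- t.test(sa$pain_count, sb$pain_count)$p.value
    p_switch[i] <- t.test(sa$switch_rate_after_pain,
                          sb$switch_rate_after_pain)$p.value
  }
  # learning-asymmetry and choice-stochasticity effects cancel: mostly
  # no detectable difference in model-independent measures
  expect_gte(mean(p_pain > 0.05), 0.8)
  expect_gte(mean(p_switch > 0.05), 0.7)
})
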