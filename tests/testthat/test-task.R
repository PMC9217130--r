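# Task environment generation and cohort simulation.

test_that("bounded walk honours variance, bounds and reproducibility", {
  expect_equal(pal_walk(50, 0.4, 0, seed = 1), rep(0.4, 50))
  expect_identical(pal_walk(100, 0.5, 0.03, seed = 7),
                   pal_walk(100, 0.5, 0.03, seed = 7))
  expect_error(pal_walk(10, 0.05, 0.02, bounds = c(0.1, 0.9)), "within")
  # empirical increment SD with wide bounds (few reflections)
  w <- pal_walk(10000, 0.5, 0.025, bounds = c(0.001, 0.999), seed = 2)
  expect_equal(sd(diff(w)), 0.025, tolerance = 0.05)
  w2 <- pal_walk(5000, 0.5, 0.05, bounds = c(0.2, 0.8), seed = 3)
  expect_true(all(w2 >= 0.2 & w2 <= 0.8))
})

test_that("task environments cross at least once and stay in bounds", {
  for (s in 1:10) {
    tk <- pal_task(seed = s)
    expect_true(all(tk$pain_prob >= 0.1 & tk$pain_prob <= 0.9))
    d <- tk$pain_prob[, 1] - tk$pain_prob[, 2]
    expect_true(any(d == 0) || any(sign(d[-1]) != sign(d[-length(d)])))
    expect_equal(nrow(tk$pain_prob), 144L)
  }
  # distinct seeds give distinct walk pairs
  t1 <- pal_task(seed = 1); t2 <- pal_task(seed = 2); t3 <- pal_task(seed = 3)
  expect_false(identical(t1$pain_prob, t2$pain_prob))
  expect_false(identical(t2$pain_prob, t3$pain_prob))
  expect_error(pal_task(n_trials = 145), "divisible")
})

test_that("cohort simulation draws parameters hierarchically and reproducibly", {
  coh <- simulate_cohort(9, pal_group_params("placebo"), seed = 21)
  expect_equal(nrow(coh$params), 9L)
  expect_equal(nrow(coh$trials), 9L * 144L)
  expect_true(all(coh$params$alpha_pain >= 0 & coh$params$alpha_pain <= 1))
  expect_true(all(coh$params$alpha_nopain >= 0 & coh$params$alpha_nopain <= 1))
  expect_true(all(coh$params$beta >= 0 & coh$params$beta <= 20))
  expect_true(all(coh$trials$outcome %in% c(-1L, 0L)))
  # walk pairs split across thirds
  expect_equal(unname(table(coh$task_of_subject)), rep(3L, 3L),
               ignore_attr = TRUE)
  # bit-reproducible
  coh2 <- simulate_cohort(9, pal_group_params("placebo"), seed = 21)
  expect_identical(coh$trials, coh2$trials)
  expect_identical(coh$params, coh2$params)
})

test_that("near-zero group SD collapses subjects onto the group parameters", {
  coh <- simulate_cohort(6, c(0.6, 0.4, 8), sd_unconstrained = 1e-8, seed = 4)
  expect_equal(coh$params$alpha_pain, rep(0.6, 6), tolerance = 1e-6)
  expect_equal(coh$params$alpha_nopain, rep(0.4, 6), tolerance = 1e-6)
  expect_equal(coh$params$beta, rep(8, 6), tolerance = 1e-5)
  expect_error(simulate_cohort(0, c(0.5, 0.5, 5)), "n_subjects")
  expect_error(simulate_cohort(4, c(0.5, 0.5, 5), sd_unconstrained = 0),
               "positive")
})

test_that("single-variant cohorts share one learning-rate deviation per subject", {
  coh <- simulate_cohort(8, c(0.55, 0.55, 8), variant = "single", seed = 13)
  expect_equal(coh$params$alpha_pain, coh$params$alpha_nopain)
  expect_error(simulate_cohort(8, c(0.7, 0.3, 8), variant = "single"), "equal")
})

test_that("placebo-like cohorts produce plausible pain counts and missed rates", {
  set.seed(17)
  counts <- replicate(6, {
    coh <- simulate_cohort(28, pal_group_params("placebo"))
    mean(switch_summary(coh)$pain_count)
  })
  # wide stochastic band around the ~57 pain trials expected of the task:
  # walk realizations move cohort means substantially
  expect_gt(mean(counts), 40)
  expect_lt(mean(counts), 85)
  coh <- simulate_cohort(40, pal_group_params("placebo"), seed = 19)
  miss_rate <- mean(coh$trials$missed)
  expect_gt(miss_rate, 0)    # lapses occur at the ~1.2% default rate
  expect_lt(miss_rate, 0.05)
})
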