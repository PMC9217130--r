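# Task environment: bounded random-walk pain probabilities and cohort
# simulation with subject parameters drawn from group-level distributions.

#' Bounded Gaussian random walk
#'
#' Generates a probability series by accumulating Gaussian increments and
#' reflecting at the bounds, the standard way slowly drifting outcome
#' probabilities are built for probabilistic learning tasks.
#'
#' @param n Number of trials.
#' @param start Starting probability, inside `bounds`.
#' @param step_sd Standard deviation of the per-trial Gaussian increment.
#' @param bounds Length-2 numeric, lower and upper reflection bounds.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` within `bounds`.
#' @export
pal_walk <- function(n, start = 0.5, step_sd = 0.025, bounds = c(0.1, 0.9),
                     seed = NULL) {
  stopifnot(n >= 1, step_sd >= 0, length(bounds) == 2L, bounds[1] < bounds[2])
  if (start < bounds[1] || start > bounds[2]) {
    stop("'start' must lie within 'bounds'", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n)
  x[1] <- start
  steps <- rnorm(n, 0, step_sd)
  for (t in seq_len(n - 1L)) {
    v <- x[t] + steps[t + 1L]
    # reflect at the bounds (repeatedly, for pathological step sizes)
    while (v < bounds[1] || v > bounds[2]) {
      if (v < bounds[1]) v <- 2 * bounds[1] - v
      if (v > bounds[2]) v <- 2 * bounds[2] - v
    }
    x[t + 1L] <- v
  }
  x
}

#' Construct a pain-avoidance task environment
#'
#' Builds the per-trial pain probabilities of the two choice options as two
#' independent bounded random walks, rejection-resampled until the two
#' series cross at least once (so that the initially better option does not
#' stay better throughout and participants must keep learning).
#'
#' Defaults (144 trials in 4 runs; walks starting at 0.35/0.65 with step SD
#' 0.025, reflected into \[0.1, 0.9\]) emulate the volatility and range of
#' the task this package models; the walk parameters are package defaults
#' and all exposed here.
#'
#' @param n_trials Total number of trials (default 144).
#' @param n_runs Number of runs the trials are split into (default 4);
#'   must divide `n_trials`.
#' @param start Length-2 numeric, starting pain probability per option.
#' @param step_sd Per-trial increment SD of the walks.
#' @param bounds Reflection bounds for the pain probabilities.
#' @param max_attempts Maximum rejection-sampling attempts for the crossing
#'   constraint before failing.
#' @param seed Optional integer seed.
#' @return An object of class `pal_task`: list with `pain_prob`
#'   (`n_trials` x 2 matrix), `n_trials`, `n_runs`, `walk_id` (attempt
#'   index that satisfied the crossing constraint).
#' @export
pal_task <- function(n_trials = 144L, n_runs = 4L, start = c(0.35, 0.65),
                     step_sd = 0.025, bounds = c(0.1, 0.9),
                     max_attempts = 1000L, seed = NULL) {
  stopifnot(length(start) == 2L)
  if (n_trials %% n_runs != 0L) {
    stop("'n_trials' must be divisible by 'n_runs'", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    p1 <- pal_walk(n_trials, start[1], step_sd, bounds)
    p2 <- pal_walk(n_trials, start[2], step_sd, bounds)
    d <- p1 - p2
    crosses <- any(d == 0) || any(sign(d[-1]) != sign(d[-length(d)]))
    if (crosses) {
      out <- list(pain_prob = cbind(option0 = p1, option1 = p2),
                  n_trials = as.integer(n_trials),
                  n_runs = as.integer(n_runs),
                  walk_id = attempt)
      class(out) <- "pal_task"
      return(out)
    }
  }
  stop("could not generate a crossing walk pair in ", max_attempts,
       " attempts; widen 'step_sd' or the trial count", call. = FALSE)
}

#' @export
print.pal_task <- function(x, ...) {
  cat("Pain-avoidance task environment:", x$n_trials, "trials in",
      x$n_runs, "runs\n")
  rng <- round(range(x$pain_prob), 3)
  cat("  pain probabilities in [", rng[1], ", ", rng[2],
      "]; walks crossed (attempt ", x$walk_id, ")\n", sep = "")
  invisible(x)
}

#' @export
plot.pal_task <- function(x, ...) {
  plot(x$pain_prob[, 1], type = "l", col = "forestgreen", ylim = c(0, 1),
       xlab = "Trial", ylab = "P(pain)", ...)
  lines(x$pain_prob[, 2], col = "steelblue")
  legend("topright", legend = c("option 0", "option 1"),
         col = c("forestgreen", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Reported group-level parameter medians, by treatment group
#'
#' Constrained-scale group-level medians of the dual-learning-rate model
#' used as simulation presets: `placebo` (0.72, 0.32, 8.8), `levodopa`
#' (0.66, 0.66, 5.3), `naltrexone` (0.72, 0.76, 5.7), and the generic
#' `drug` scenario (0.70, 0.70, 5.5) used for recovery analyses.
#'
#' @param group One of `"placebo"`, `"levodopa"`, `"naltrexone"`, `"drug"`.
#' @return Named numeric vector `c(alpha_pain, alpha_nopain, beta)`.
#' @export
pal_group_params <- function(group = c("placebo", "levodopa", "naltrexone", "drug")) {
  group <- match.arg(group)
  presets <- list(
    placebo    = c(alpha_pain = 0.72, alpha_nopain = 0.32, beta = 8.8),
    levodopa   = c(alpha_pain = 0.66, alpha_nopain = 0.66, beta = 5.3),
    naltrexone = c(alpha_pain = 0.72, alpha_nopain = 0.76, beta = 5.7),
    drug       = c(alpha_pain = 0.70, alpha_nopain = 0.70, beta = 5.5)
  )
  presets[[group]]
}

#' Simulate a cohort of learning agents
#'
#' Draws each subject's unconstrained parameters from
#' `Normal(group_mean, group_sd)`, maps them through the inverse-probit
#' constraining transform (rates to \[0,1\], beta to \[0,20\]; see
#' [constrain_param()]), and simulates each subject with
#' [simulate_agent()]. Walk pairs are allocated round-robin so each of
#' `n_tasks` task environments is administered to approximately a third of
#' the cohort (with the default `n_tasks = 3`).
#'
#' `mean_constrained` gives the group-level means on the constrained scale
#' (the scale results are reported on); they are converted to unconstrained
#' means internally. `sd_unconstrained` is the between-subject SD on the
#' unconstrained (probit) scale; the default 0.5 gives a realistic
#' between-subject spread for this class of task.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param mean_constrained Named or positional numeric of length 3:
#'   group-level means `(alpha_pain, alpha_nopain, beta)` on the
#'   constrained scale. Presets available via [pal_group_params()].
#' @param sd_unconstrained Group-level SD(s) on the unconstrained scale;
#'   recycled to length 3. Must be > 0 (use a tiny value for a
#'   near-degenerate cohort).
#' @param group_label Label stored in the output's `group` column.
#' @param lapse_rate Per-trial missed-response probability (default 0.012).
#' @param n_tasks Number of distinct walk pairs shared across the cohort.
#' @param tasks Optional list of [pal_task] objects to reuse; generated
#'   otherwise.
#' @param n_trials,n_runs,step_sd,bounds,start Task parameters, passed to
#'   [pal_task()] when `tasks` is NULL.
#' @param variant `"dual"` (default): each subject's pain and no-pain
#'   learning rates are drawn independently around their group means;
#'   `"single"`: one learning-rate deviation per subject is shared by both
#'   outcomes (data truly generated by the single-learning-rate model; the
#'   two rate entries of `mean_constrained` must then be equal).
#' @param seed Optional integer seed governing parameter draws, task
#'   generation, and agent simulation (bit-reproducible).
#' @return List of class `pal_cohort`: `trials` (stacked data.frame with
#'   `subject`, `group`, `trial`, `run`, `choice`, `outcome`, `missed`),
#'   `params` (per-subject true constrained parameters), `tasks`,
#'   `task_of_subject`.
#' @export
simulate_cohort <- function(n_subjects,
                            mean_constrained = pal_group_params("placebo"),
                            sd_unconstrained = 0.5,
                            group_label = "group1",
                            lapse_rate = 0.012,
                            n_tasks = 3L,
                            tasks = NULL,
                            n_trials = 144L, n_runs = 4L,
                            step_sd = 0.025, bounds = c(0.1, 0.9),
                            start = c(0.35, 0.65),
                            variant = c("dual", "single"),
                            seed = NULL) {
  variant <- match.arg(variant)
  if (n_subjects < 1L) stop("'n_subjects' must be >= 1", call. = FALSE)
  stopifnot(length(mean_constrained) == 3L)
  if (variant == "single" &&
      abs(mean_constrained[[1]] - mean_constrained[[2]]) > 1e-12) {
    stop("'single' variant requires equal rate entries in 'mean_constrained'",
         call. = FALSE)
  }
  sd_unconstrained <- rep_len(sd_unconstrained, 3L)
  if (any(sd_unconstrained <= 0)) {
    stop("'sd_unconstrained' must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  mu <- c(unconstrain_param(mean_constrained[[1]], "rate"),
          unconstrain_param(mean_constrained[[2]], "rate"),
          unconstrain_param(mean_constrained[[3]], "beta"))

  if (is.null(tasks)) {
    tasks <- lapply(seq_len(min(n_tasks, n_subjects)), function(i) {
      pal_task(n_trials, n_runs, start = start, step_sd = step_sd,
               bounds = bounds)
    })
  }
  task_of_subject <- rep_len(seq_along(tasks), n_subjects)

  raw <- matrix(rnorm(n_subjects * 3L, mean = rep(mu, each = n_subjects),
                      sd = rep(sd_unconstrained, each = n_subjects)),
                ncol = 3L)
  if (variant == "single") raw[, 2L] <- raw[, 1L]  # shared rate deviation
  params <- data.frame(
    subject = seq_len(n_subjects),
    alpha_pain = constrain_param(raw[, 1], "rate"),
    alpha_nopain = constrain_param(raw[, 2], "rate"),
    beta = constrain_param(raw[, 3], "beta")
  )

  trial_list <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    tr <- simulate_agent(tasks[[task_of_subject[s]]],
                         alpha_pain = params$alpha_pain[s],
                         alpha_nopain = params$alpha_nopain[s],
                         beta = params$beta[s],
                         lapse_rate = lapse_rate)
    tr <- cbind(subject = s, group = group_label, tr)
    trial_list[[s]] <- tr
  }
  out <- list(trials = do.call(rbind, trial_list),
              params = params,
              tasks = tasks,
              task_of_subject = task_of_subject,
              group_label = group_label)
  class(out) <- "pal_cohort"
  out
}

#' @export
print.pal_cohort <- function(x, ...) {
  cat("Simulated cohort '", x$group_label, "': ",
      nrow(x$params), " subjects x ",
      nrow(x$trials) / nrow(x$params), " trials (",
      length(x$tasks), " walk pair(s))\n", sep = "")
  cat("  true constrained parameter means:",
      paste(sprintf("%s=%.3f", names(x$params)[-1],
                    colMeans(x$params[-1])), collapse = ", "), "\n")
  invisible(x)
}
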