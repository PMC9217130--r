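# Core learning and choice equations.
#
# Outcome coding: -1 = pain, 0 = no pain. Q values are expected outcomes on
# [-1, 0], initialized at -0.5 for both options, so -Q is the expected
# probability of pain. Only the chosen option's Q is updated.

Q_INIT <- -0.5

#' Delta-rule update of a single Q value
#'
#' Applies the Rescorla-Wagner update `q + alpha * (outcome - q)`. With
#' outcomes coded in \{-1, 0\} and `alpha` in \[0, 1\], the result is a convex
#' combination of `q` and the outcome and therefore stays in \[-1, 0\]. The
#' unchosen option's value is never updated; callers only pass the chosen
#' option's Q.
#'
#' @param q Current expected-outcome value, in \[-1, 0\].
#' @param alpha Learning rate, in \[0, 1\]: the fraction of the prediction
#'   error `(outcome - q)` incorporated into the new expectation.
#' @param outcome Coded outcome, -1 (pain) or 0 (no pain).
#' @return The updated Q value.
#' @examples
#' update_q(-0.5, 0.72, -1)  # one pain outcome at the initial expectation
#' @export
update_q <- function(q, alpha, outcome) {
  stopifnot(is.numeric(q), is.numeric(alpha), is.numeric(outcome))
  if (any(alpha < 0 | alpha > 1)) {
    stop("'alpha' must be in [0, 1]", call. = FALSE)
  }
  if (!all(outcome %in% c(-1, 0))) {
    stop("'outcome' must be coded -1 (pain) or 0 (no pain)", call. = FALSE)
  }
  q + alpha * (outcome - q)
}

#' Softmax choice probabilities over two options
#'
#' Converts a pair of Q values into choice probabilities,
#' `P(s) = exp(beta * Q_s) / sum_s' exp(beta * Q_s')`. Because Q values are
#' negative expected-pain codes, the option with the less negative Q (lower
#' expected pain probability) receives the higher choice probability; with
#' `beta = 0` both options are chosen with probability 0.5.
#'
#' @param q Numeric vector of length 2: Q values of the two options.
#' @param beta Inverse temperature, nonnegative; higher values make choice
#'   more deterministic toward the better option.
#' @return Numeric vector of length 2 summing to 1.
#' @examples
#' choice_prob(c(-0.2, -0.8), 8.8)
#' @export
choice_prob <- function(q, beta) {
  if (length(q) != 2L || !is.numeric(q)) {
    stop("'q' must be a numeric vector of length 2", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("'beta' must be a single nonnegative number", call. = FALSE)
  }
  x <- beta * q
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

# Normalize a single-participant trial table: required columns, ordering,
# and coding checks. Returns the data.frame ordered by trial.
check_trials <- function(trials, require_n = 1L) {
  if (!is.data.frame(trials)) {
    stop("'trials' must be a data.frame of trial records", call. = FALSE)
  }
  need <- c("choice", "outcome")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("'trials' is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) < require_n) {
    stop("'trials' must contain at least ", require_n, " trial(s)",
         call. = FALSE)
  }
  if ("trial" %in% names(trials)) {
    if (anyDuplicated(trials$trial)) {
      stop("duplicate trial indices within participant", call. = FALSE)
    }
    trials <- trials[order(trials$trial), , drop = FALSE]
  }
  if (!all(trials$choice %in% c(0L, 1L))) {
    stop("'choice' must be coded 0/1", call. = FALSE)
  }
  if (!all(trials$outcome %in% c(-1L, 0L))) {
    stop("'outcome' must be coded -1 (pain) / 0 (no pain)", call. = FALSE)
  }
  trials
}

check_rates <- function(alpha_pain, alpha_nopain) {
  if (any(c(alpha_pain, alpha_nopain) < 0) || any(c(alpha_pain, alpha_nopain) > 1)) {
    stop("learning rates must be in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Log-likelihood of one participant's choice sequence
#'
#' Sums, across trials, the log softmax probability of the observed choice,
#' updating the chosen option's Q value after each trial with `alpha_pain`
#' when the outcome was pain and `alpha_nopain` when pain was avoided. Both
#' Q values start at -0.5 at the beginning of the sequence (runs are
#' concatenated; Q is not reset between runs). The single-learning-rate
#' model variant is obtained by passing `alpha_nopain = alpha_pain`
#' (the default).
#'
#' @param trials data.frame with integer columns `choice` (0/1) and
#'   `outcome` (-1/0); if a `trial` column is present rows are ordered by it.
#' @param alpha_pain Learning rate applied after pain outcomes, in \[0, 1\].
#' @param alpha_nopain Learning rate applied after no-pain outcomes, in
#'   \[0, 1\]. Defaults to `alpha_pain` (single-learning-rate model).
#' @param beta Inverse temperature, nonnegative.
#' @return The summed log-likelihood (a single number).
#' @seealso [expected_pain_trajectory()] for the corresponding latent
#'   expectation series.
#' @export
pal_loglik <- function(trials, alpha_pain, alpha_nopain = alpha_pain, beta) {
  trials <- check_trials(trials, require_n = 1L)
  check_rates(alpha_pain, alpha_nopain)
  if (beta < 0) stop("'beta' must be nonnegative", call. = FALSE)
  .seq_loglik_cpp(as.integer(trials$choice), as.integer(trials$outcome),
                  alpha_pain, alpha_nopain, beta)
}

#' Trial-wise expected pain probability of the chosen option
#'
#' Replays a participant's choice/outcome sequence through the Q-learning
#' model at fixed learning rates and returns, for every trial, the
#' pre-outcome expected pain probability of the chosen option (the negation
#' of its Q value; the first trial is always 0.5). The series is suitable
#' as a parametric-modulator regressor in downstream GLM analyses; the
#' conventional choice of learning rates is the individual-level posterior
#' medians averaged across all participants (see [mean_posterior_alphas()]).
#'
#' @inheritParams pal_loglik
#' @return Numeric vector, one value in \[0, 1\] per trial.
#' @export
expected_pain_trajectory <- function(trials, alpha_pain, alpha_nopain = alpha_pain) {
  trials <- check_trials(trials, require_n = 1L)
  check_rates(alpha_pain, alpha_nopain)
  .expected_pain_cpp(as.integer(trials$choice), as.integer(trials$outcome),
                     alpha_pain, alpha_nopain)
}

#' Simulate one agent on a task environment
#'
#' Plays a softmax Q-learning agent through a task: on each trial the agent
#' either lapses with probability `lapse_rate` (the choice is then uniform
#' random and flagged `missed`, emulating trials on which no response was
#' made and the computer selected an option) or samples its choice from the
#' softmax over current Q values; the outcome is then drawn Bernoulli from
#' the chosen option's pain probability, coded -1/0, and the chosen Q is
#' updated by the delta rule.
#'
#' @param task A [pal_task] object (or any list with a two-column
#'   `pain_prob` matrix and `n_runs`).
#' @param alpha_pain,alpha_nopain Learning rates in \[0, 1\].
#' @param beta Inverse temperature, nonnegative.
#' @param lapse_rate Probability of a missed response per trial, in \[0, 1\].
#'   Default 0.012 (about 1.2% of trials).
#' @param seed Optional integer seed; identical seeds and inputs give
#'   identical trial lists.
#' @return data.frame with columns `trial`, `run`, `choice`, `outcome`,
#'   `missed`.
#' @export
simulate_agent <- function(task, alpha_pain, alpha_nopain = alpha_pain, beta,
                           lapse_rate = 0.012, seed = NULL) {
  pp <- task$pain_prob
  if (is.null(pp) || !is.matrix(pp) || ncol(pp) != 2L) {
    stop("'task' must provide a two-column 'pain_prob' matrix", call. = FALSE)
  }
  check_rates(alpha_pain, alpha_nopain)
  if (beta < 0) stop("'beta' must be nonnegative", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate > 1) {
    stop("'lapse_rate' must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sim <- .simulate_agent_cpp(pp, alpha_pain, alpha_nopain, beta, lapse_rate)
  n <- nrow(pp)
  n_runs <- if (!is.null(task$n_runs)) task$n_runs else 1L
  data.frame(
    trial = seq_len(n),
    run = rep(seq_len(n_runs), each = n %/% n_runs)[seq_len(n)],
    choice = sim$choice,
    outcome = sim$outcome,
    missed = sim$missed
  )
}
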