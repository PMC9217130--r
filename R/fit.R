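# Hierarchical Bayesian estimation of the Q-learning models for one
# treatment group.
#
# Model (non-centered): each subject's unconstrained parameter j is
# mu_j + sigma_j * z_sj with z ~ Normal(0,1); hyperpriors mu ~ Normal(0,1),
# sigma ~ half-Cauchy(0,5). Unconstrained values map to the working scale
# through the inverse-probit transform: rates = Phi(x), beta = 20 * Phi(x).
# Sampling is by adaptive component-wise Metropolis-within-Gibbs (proposal
# scales tuned toward ~44% acceptance during burn-in only), with the
# sequence likelihood evaluated in compiled code.

#' Constraining transform for model parameters
#'
#' Maps an unconstrained real value to the parameter's working range using
#' the inverse-probit (standard normal CDF) transform: learning rates to
#' \[0, 1\] as `pnorm(x)`, the inverse temperature to \[0, 20\] as
#' `20 * pnorm(x)`. `unconstrain_param()` is the inverse map.
#'
#' @param x Numeric vector of finite unconstrained values (for
#'   `unconstrain_param`, constrained values strictly inside the range).
#' @param kind `"rate"` or `"beta"`.
#' @return Numeric vector of constrained (resp. unconstrained) values.
#' @export
constrain_param <- function(x, kind = c("rate", "beta")) {
  kind <- match.arg(kind)
  if (!all(is.finite(x))) stop("'x' must be finite", call. = FALSE)
  p <- pnorm(x)
  if (kind == "beta") 20 * p else p
}

#' @rdname constrain_param
#' @export
unconstrain_param <- function(x, kind = c("rate", "beta")) {
  kind <- match.arg(kind)
  if (kind == "beta") x <- x / 20
  if (any(x <= 0) || any(x >= 1)) {
    stop("constrained values must lie strictly inside the parameter range",
         call. = FALSE)
  }
  qnorm(x)
}

pal_param_names <- function(model) {
  if (model == "dual") c("alpha_pain", "alpha_nopain", "beta")
  else c("alpha", "beta")
}

# Split a stacked cohort trial table into per-subject integer matrices.
cohort_matrices <- function(data, subject_col = "subject") {
  if (inherits(data, "pal_cohort")) data <- data$trials
  if (!is.data.frame(data)) {
    stop("'data' must be a trial data.frame or a pal_cohort", call. = FALSE)
  }
  if (!subject_col %in% names(data)) {
    stop("column '", subject_col, "' not found in data", call. = FALSE)
  }
  ids <- unique(data[[subject_col]])
  S <- length(ids)
  per <- lapply(ids, function(id) {
    check_trials(data[data[[subject_col]] == id, , drop = FALSE],
                 require_n = 1L)
  })
  nt <- vapply(per, nrow, integer(1))
  Tmax <- max(nt)
  choices <- matrix(0L, S, Tmax)
  outcomes <- matrix(0L, S, Tmax)
  for (s in seq_len(S)) {
    choices[s, seq_len(nt[s])] <- as.integer(per[[s]]$choice)
    outcomes[s, seq_len(nt[s])] <- as.integer(per[[s]]$outcome)
  }
  list(choices = choices, outcomes = outcomes, n_trials = nt, subjects = ids)
}

#' Fit a hierarchical Q-learning model to one group's choice data
#'
#' Estimates the single- or dual-learning-rate Q-learning model for one
#' treatment group with a hierarchical Bayesian model: subject-level
#' parameters are drawn from group-level normal distributions on an
#' unconstrained scale (non-centered parameterization), with Normal(0, 1)
#' hyperpriors on the group-level means and half-Cauchy(0, 5) hyperpriors
#' on the group-level SDs, and mapped to their working ranges by the
#' inverse-probit transform (rates to \[0,1\], beta to \[0,20\]). Groups are
#' fit in fully independent runs; cross-group contrasts operate on the
#' saved draws (see [pal_contrast()]).
#'
#' Sampling uses an adaptive component-wise Metropolis-within-Gibbs sampler
#' written in compiled code: proposal scales are tuned during the burn-in
#' phase only, then frozen so the retained draws target the exact
#' posterior. At the defaults (4 chains x 5000 iterations, 1000 burn-in,
#' thinning 5) the fit retains 3200 draws (800 per chain). Per-chain seeds
#' are derived deterministically from `seed`. Split-Rhat is computed for
#' every monitored quantity; see [check_convergence()].
#'
#' Missed-response trials (random fallback choices) are retained in the
#' likelihood by default — the participant still observed the outcome — and
#' can be dropped with `include_missed = FALSE`.
#'
#' @param data A stacked trial data.frame (columns `subject`, `trial`,
#'   `choice`, `outcome`, optionally `missed`) or a `pal_cohort`.
#' @param model `"dual"` (separate learning rates for pain and no-pain
#'   outcomes) or `"single"` (one shared learning rate).
#' @param chains Number of independent MCMC chains (>= 2 for diagnostics).
#' @param iter Total iterations per chain.
#' @param warmup Burn-in iterations discarded from each chain.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param sweeps Full Metropolis-within-Gibbs update sweeps performed per
#'   iteration (default 3). More sweeps lower the autocorrelation per
#'   recorded iteration at proportional cost; the retained draw count is
#'   unaffected.
#' @param seed Integer master seed; chain `k` uses `seed + k - 1`.
#' @param group_label Optional label stored with the fit.
#' @param include_missed Keep missed-response trials in the likelihood
#'   (default TRUE).
#' @param subject_col Name of the subject identifier column.
#' @return An object of class `pal_fit` with components `group_mean`
#'   (retained draws x parameter matrix of constrained group-level means),
#'   `group_mean_unc`, `group_sd`, `subject` (draws x subject x parameter
#'   array of constrained subject-level values), `log_lik` (draws x subject
#'   matrix, the pointwise likelihood used for WAIC), `chain` (chain index
#'   per draw), `rhat`, `diagnostics`, `spec`.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(12, pal_group_params("placebo"), seed = 1)
#' fit <- pal_fit(coh, model = "dual", chains = 2, iter = 1200,
#'                warmup = 400, thin = 2, seed = 1)
#' coef(fit)
#' }
#' @export
pal_fit <- function(data, model = c("dual", "single"),
                    chains = 4L, iter = 5000L, warmup = 1000L, thin = 5L,
                    sweeps = 3L, seed = 1L, group_label = NULL,
                    include_missed = TRUE, subject_col = "subject") {
  model <- match.arg(model)
  if (iter < 1L) stop("'iter' must be a positive number of iterations",
                      call. = FALSE)
  if (warmup >= iter) stop("'warmup' must be smaller than 'iter'",
                           call. = FALSE)
  if (thin < 1L) stop("'thin' must be >= 1", call. = FALSE)
  if (chains < 1L) stop("'chains' must be >= 1", call. = FALSE)
  if (sweeps < 1L) stop("'sweeps' must be >= 1", call. = FALSE)

  if (!include_missed) {
    d <- if (inherits(data, "pal_cohort")) data$trials else data
    if ("missed" %in% names(d)) d <- d[!d$missed, , drop = FALSE]
    data <- d
  }
  dat <- cohort_matrices(data, subject_col = subject_col)
  S <- length(dat$subjects)
  if (S < 2L) stop("hierarchical estimation needs at least 2 subjects",
                   call. = FALSE)
  if (is.null(group_label)) {
    d <- if (inherits(data, "pal_cohort")) data$trials else data
    group_label <- if ("group" %in% names(d)) as.character(d$group[1]) else "group"
  }

  model_code <- if (model == "dual") 2L else 1L
  P <- if (model == "dual") 3L else 2L
  n_keep <- (iter - warmup) %/% thin

  chain_out <- vector("list", chains)
  for (k in seq_len(chains)) {
    set.seed(seed + k - 1L)
    # overdispersed but sane starting values
    init_mu <- rnorm(P, 0, 0.5)
    init_ls <- rnorm(P, log(0.5), 0.3)
    init_z <- matrix(rnorm(S * P, 0, 0.5), S, P)
    chain_out[[k]] <- .sample_chain_cpp(dat$choices, dat$outcomes,
                                        dat$n_trials, model_code,
                                        as.integer(iter), as.integer(warmup),
                                        as.integer(thin), as.integer(sweeps),
                                        init_mu, init_ls, init_z)
  }

  pn <- pal_param_names(model)
  bind2 <- function(name) {
    m <- do.call(rbind, lapply(chain_out, `[[`, name))
    colnames(m) <- pn
    m
  }
  group_mean <- bind2("mu_constrained")
  group_mean_unc <- bind2("mu")
  group_sd <- bind2("sigma")
  log_lik <- do.call(rbind, lapply(chain_out, `[[`, "log_lik"))
  colnames(log_lik) <- as.character(dat$subjects)
  subject <- array(NA_real_, dim = c(chains * n_keep, S, P),
                   dimnames = list(NULL, as.character(dat$subjects), pn))
  for (k in seq_len(chains)) {
    rows <- (k - 1L) * n_keep + seq_len(n_keep)
    subject[rows, , ] <- chain_out[[k]]$subject
  }
  chain_id <- rep(seq_len(chains), each = n_keep)

  # split-Rhat over all monitored quantities
  monitored <- cbind(group_mean_unc, group_sd, group_mean)
  colnames(monitored) <- c(paste0("mu_", pn), paste0("sigma_", pn),
                           paste0("mean_", pn))
  subj_flat <- matrix(subject, nrow = dim(subject)[1])
  colnames(subj_flat) <- paste0(rep(pn, each = S), "[",
                                rep(dat$subjects, times = P), "]")
  rhat <- c(apply(monitored, 2, split_rhat, chain = chain_id),
            apply(subj_flat, 2, split_rhat, chain = chain_id))

  out <- list(
    group_mean = group_mean,
    group_mean_unc = group_mean_unc,
    group_sd = group_sd,
    subject = subject,
    log_lik = log_lik,
    chain = chain_id,
    rhat = rhat,
    diagnostics = list(
      acc_rate = vapply(chain_out, `[[`, numeric(1), "acc_rate"),
      n_draws = chains * n_keep
    ),
    spec = list(model = model, chains = chains, iter = iter,
                warmup = warmup, thin = thin, sweeps = sweeps, seed = seed,
                include_missed = include_missed),
    subjects = dat$subjects,
    n_trials = dat$n_trials,
    group_label = group_label
  )
  class(out) <- "pal_fit"
  out
}

#' Split-Rhat convergence diagnostic for one quantity
#'
#' Computes the split-chain potential scale reduction factor: each chain is
#' split in half and the classical between/within variance ratio is taken
#' over the resulting sequences. Values near 1 indicate convergence;
#' degenerate (zero-variance) draws return 1 by convention.
#'
#' @param x Numeric vector of draws, stacked by chain.
#' @param chain Integer vector assigning each draw to a chain (>= 2 chains).
#' @return The split-Rhat value.
#' @export
split_rhat <- function(x, chain) {
  ids <- unique(chain)
  if (length(ids) < 2L) {
    stop("Rhat requires at least 2 chains", call. = FALSE)
  }
  halves <- list()
  for (id in ids) {
    xs <- x[chain == id]
    n <- length(xs)
    if (n < 4L) stop("chains too short to split for Rhat", call. = FALSE)
    h <- n %/% 2L
    halves <- c(halves, list(xs[seq_len(h)], xs[(h + 1L):(2L * h)]))
  }
  n <- length(halves[[1]])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W == 0) {
    # all chains constant: degenerate but trivially "converged"
    return(if (!is.finite(B) || B == 0) 1 else Inf)
  }
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Convergence report for a fitted model
#'
#' Checks split-Rhat for every monitored quantity of a [pal_fit] against a
#' threshold (1.1 by convention).
#'
#' @param fit A `pal_fit`.
#' @param threshold Rhat pass threshold.
#' @return List of class `pal_convergence`: `pass` (all Rhat < threshold),
#'   `rhat` (named vector), `max_rhat`, `worst` (name of worst quantity),
#'   `threshold`.
#' @export
check_convergence <- function(fit, threshold = 1.1) {
  stopifnot(inherits(fit, "pal_fit"))
  if (fit$spec$chains < 2L) {
    stop("Rhat is undefined for a single chain", call. = FALSE)
  }
  r <- fit$rhat
  out <- list(pass = all(r < threshold, na.rm = TRUE),
              rhat = r,
              max_rhat = max(r, na.rm = TRUE),
              worst = names(r)[which.max(r)],
              threshold = threshold)
  class(out) <- "pal_convergence"
  out
}

#' @export
print.pal_convergence <- function(x, ...) {
  cat("Convergence:", if (x$pass) "PASS" else "FAIL",
      sprintf("(max split-Rhat = %.3f at '%s', threshold %.2f)\n",
              x$max_rhat, x$worst, x$threshold))
  invisible(x)
}

# ---- pal_fit methods -------------------------------------------------------

#' @export
print.pal_fit <- function(x, ...) {
  cat("Hierarchical Q-learning fit (", x$spec$model, "-learning-rate model), group '",
      x$group_label, "'\n", sep = "")
  cat("  ", length(x$subjects), " subjects, ",
      x$diagnostics$n_draws, " retained draws (",
      x$spec$chains, " chains x ", x$spec$iter, " iter, burn-in ",
      x$spec$warmup, ", thin ", x$spec$thin, ")\n", sep = "")
  cat("  posterior medians of constrained group-level means:\n")
  print(round(coef(x), 3))
  cat("  max split-Rhat:", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' @export
coef.pal_fit <- function(object, ...) {
  apply(object$group_mean, 2, median)
}

#' @export
summary.pal_fit <- function(object, mass = 0.95, ...) {
  sm <- t(apply(object$group_mean, 2, function(v) {
    h <- hdi(v, mass)
    c(median = median(v), mean = mean(v), hdi_low = h[1], hdi_high = h[2])
  }))
  sds <- t(apply(object$group_sd, 2, function(v) {
    c(median = median(v))
  }))
  out <- list(group_mean = sm, group_sd_median = sds[, 1],
              rhat_max = max(object$rhat, na.rm = TRUE),
              model = object$spec$model, group_label = object$group_label,
              n_subjects = length(object$subjects),
              n_draws = object$diagnostics$n_draws, mass = mass)
  class(out) <- "summary.pal_fit"
  out
}

#' @export
print.summary.pal_fit <- function(x, ...) {
  cat("Group '", x$group_label, "', ", x$model, "-learning-rate model: ",
      x$n_subjects, " subjects, ", x$n_draws, " draws\n", sep = "")
  cat("Constrained group-level means (median and ",
      round(100 * x$mass), "% HDI):\n", sep = "")
  print(round(x$group_mean, 3))
  cat("Group-level SD medians (unconstrained scale):\n")
  print(round(x$group_sd_median, 3))
  cat("Max split-Rhat:", round(x$rhat_max, 3), "\n")
  invisible(x)
}

#' @export
plot.pal_fit <- function(x, ...) {
  pn <- colnames(x$group_mean)
  op <- par(mfrow = c(1, length(pn)))
  on.exit(par(op))
  for (p in pn) {
    d <- density(x$group_mean[, p])
    plot(d, main = p, xlab = "constrained group-level mean", ...)
    h <- hdi(x$group_mean[, p])
    abline(v = h, col = "red", lty = 2)
  }
  invisible(x)
}

#' Posterior-predictive simulation from a fitted model
#'
#' For each replicate, picks one retained posterior draw of the
#' subject-level constrained parameters and simulates every subject on a
#' task environment, giving posterior-predictive cohorts comparable to the
#' observed data.
#'
#' @param object A `pal_fit`.
#' @param nsim Number of replicate cohorts.
#' @param seed Optional integer seed.
#' @param tasks List of [pal_task] objects recycled over subjects; a fresh
#'   set of 3 is generated when NULL.
#' @param lapse_rate Missed-response probability passed to [simulate_agent()].
#' @param ... Unused.
#' @return List of `nsim` stacked trial data.frames.
#' @export
simulate.pal_fit <- function(object, nsim = 1, seed = NULL, tasks = NULL,
                             lapse_rate = 0.012, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(object$subjects)
  if (is.null(tasks)) tasks <- lapply(1:3, function(i) pal_task())
  task_of_subject <- rep_len(seq_along(tasks), S)
  dual <- object$spec$model == "dual"
  D <- dim(object$subject)[1]
  lapply(seq_len(nsim), function(i) {
    d <- sample.int(D, 1L)
    per <- lapply(seq_len(S), function(s) {
      ap <- object$subject[d, s, 1L]
      anp <- if (dual) object$subject[d, s, 2L] else ap
      bt <- object$subject[d, s, if (dual) 3L else 2L]
      tr <- simulate_agent(tasks[[task_of_subject[s]]], ap, anp, bt,
                           lapse_rate = lapse_rate)
      cbind(subject = object$subjects[s], group = object$group_label, tr)
    })
    do.call(rbind, per)
  })
}
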