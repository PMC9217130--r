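# Model-independent behavioral metrics: pain counts, outcome-conditioned
# switch rates, the lagged outcome -> switch logistic regression, and the
# one-way group ANOVA.

#' Outcome-conditioned switch rates for one participant
#'
#' For every non-final trial t, a switch is `choice[t+1] != choice[t]`.
#' Switch rates are the proportion of switches among transitions whose
#' trial-t outcome was pain (-1) respectively no pain (0). Transitions
#' involving a missed-response trial are excluded by default, since the
#' recorded choice there was not the participant's own; `pain_count` always
#' counts all pain outcomes (stimuli delivered).
#'
#' @param trials Single-participant trial data.frame (`choice`, `outcome`,
#'   optionally `trial` and `missed`), at least 2 trials.
#' @param exclude_missed Drop transitions in which either trial was a
#'   missed response (default TRUE).
#' @return data.frame (one row) with `pain_count`, `n_after_pain`,
#'   `n_after_nopain`, `switch_rate_after_pain`, `switch_rate_after_nopain`
#'   (NA when the denominator is 0).
#' @export
switch_rates <- function(trials, exclude_missed = TRUE) {
  trials <- check_trials(trials, require_n = 2L)
  n <- nrow(trials)
  sw <- trials$choice[-1L] != trials$choice[-n]
  out_prev <- trials$outcome[-n]
  keep <- rep(TRUE, n - 1L)
  if (exclude_missed && "missed" %in% names(trials)) {
    m <- as.logical(trials$missed)
    keep <- !(m[-n] | m[-1L])
  }
  after_pain <- keep & out_prev == -1L
  after_nopain <- keep & out_prev == 0L
  data.frame(
    pain_count = sum(trials$outcome == -1L),
    n_after_pain = sum(after_pain),
    n_after_nopain = sum(after_nopain),
    switch_rate_after_pain =
      if (sum(after_pain) > 0L) mean(sw[after_pain]) else NA_real_,
    switch_rate_after_nopain =
      if (sum(after_nopain) > 0L) mean(sw[after_nopain]) else NA_real_
  )
}

#' Per-subject switch summary for a cohort
#'
#' Applies [switch_rates()] to every participant of a stacked trial table.
#'
#' @param data Stacked trial data.frame or `pal_cohort`.
#' @param exclude_missed Passed to [switch_rates()].
#' @return data.frame with one row per subject (`subject`, `group` if
#'   present, plus the [switch_rates()] columns).
#' @export
switch_summary <- function(data, exclude_missed = TRUE) {
  d <- if (inherits(data, "pal_cohort")) data$trials else data
  ids <- unique(d$subject)
  rows <- lapply(ids, function(id) {
    tr <- d[d$subject == id, , drop = FALSE]
    r <- switch_rates(tr, exclude_missed = exclude_missed)
    r <- cbind(subject = id, r)
    if ("group" %in% names(tr)) r <- cbind(r, group = tr$group[1])
    r
  })
  do.call(rbind, rows)
}

#' Paired contrast of after-pain vs after-no-pain switch rates
#'
#' Paired t test across subjects of the difference
#' (after-pain switch rate - after-no-pain switch rate), with Cohen's d for
#' paired data (mean difference / SD of differences). Subjects with an
#' undefined rate are excluded with a warning.
#'
#' @param summaries Output of [switch_summary()] (or any data.frame with
#'   `switch_rate_after_pain` and `switch_rate_after_nopain`).
#' @return List of class `pal_switch_test`: `t`, `df`, `p_value`,
#'   `cohens_d`, `mean_after_pain`, `mean_after_nopain`, `n`.
#' @export
paired_switch_contrast <- function(summaries) {
  need <- c("switch_rate_after_pain", "switch_rate_after_nopain")
  stopifnot(all(need %in% names(summaries)))
  ok <- complete.cases(summaries[, need])
  if (any(!ok)) {
    warning(sum(!ok), " subject(s) with undefined switch rate excluded",
            call. = FALSE)
  }
  a <- summaries$switch_rate_after_pain[ok]
  b <- summaries$switch_rate_after_nopain[ok]
  if (length(a) < 2L) stop("need at least 2 subjects with defined rates",
                           call. = FALSE)
  d <- a - b
  sd_d <- sd(d)
  if (sd_d == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1L),
               p.value = 1)
    cd <- 0
  } else {
    tt <- t.test(a, b, paired = TRUE)
    cd <- mean(d) / sd_d
  }
  out <- list(t = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value, cohens_d = cd,
              mean_after_pain = mean(a), mean_after_nopain = mean(b),
              n = length(a))
  class(out) <- "pal_switch_test"
  out
}

#' @export
print.pal_switch_test <- function(x, ...) {
  cat(sprintf("Switch after pain %.1f%% vs after no pain %.1f%% (n = %d)\n",
              100 * x$mean_after_pain, 100 * x$mean_after_nopain, x$n))
  cat(sprintf("  paired t(%d) = %.2f, p = %.3g, Cohen's d = %.2f\n",
              x$df, x$t, x$p_value, x$cohens_d))
  invisible(x)
}

# Ridge-penalized logistic regression by Newton iterations; used as the
# fallback when a subject's data separate perfectly (e.g. a deterministic
# lose-shift policy).
ridge_logistic <- function(X, y, lambda = 0.5, max_iter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(lambda, p)
  pen[1L, 1L] <- 0  # intercept unpenalized
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + 2 * pen
    g <- crossprod(X, y - mu) - 2 * pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Lagged outcome-to-switch logistic regression
#'
#' Per participant, regresses the switch indicator (next choice differs
#' from the current one) on indicators of pain at the 1..`n_lags`
#' preceding trials, by logistic regression; trials without a full lag
#' history are excluded. Coefficients are then aggregated across subjects
#' into per-lag means, SEs, one-sample t statistics and Cohen's d. Subjects
#' whose data separate perfectly (deterministic policies) are retained via
#' a small ridge penalty and flagged.
#'
#' @param data Stacked trial table or `pal_cohort`.
#' @param n_lags Number of preceding trials (default 6).
#' @param ridge Ridge penalty used for separated subjects (default 0.5).
#' @return List of class `pal_lag_regression`: `coefficients` (subject x
#'   lag matrix), `penalized` (logical per subject), `summary` (per lag:
#'   mean, se, t, p, Cohen's d), `n_lags`.
#' @export
lagged_switch_regression <- function(data, n_lags = 6L, ridge = 0.5) {
  d <- if (inherits(data, "pal_cohort")) data$trials else data
  ids <- unique(d$subject)
  coefs <- matrix(NA_real_, length(ids), n_lags,
                  dimnames = list(as.character(ids),
                                  paste0("lag", seq_len(n_lags))))
  penalized <- logical(length(ids))
  groups <- character(length(ids))
  for (i in seq_along(ids)) {
    tr <- check_trials(d[d$subject == ids[i], , drop = FALSE],
                       require_n = n_lags + 2L)
    n <- nrow(tr)
    # switch decided at trial t+1, for t = n_lags .. n-1
    idx <- n_lags:(n - 1L)
    y <- as.integer(tr$choice[idx + 1L] != tr$choice[idx])
    X <- cbind(1, vapply(seq_len(n_lags), function(l) {
      as.numeric(tr$outcome[idx - l + 1L] == -1L)
    }, numeric(length(idx))))
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    b <- fit$coefficients
    separated <- !fit$converged || any(!is.finite(b)) || any(abs(b) > 8)
    if (separated) {
      b <- ridge_logistic(X, y, lambda = ridge)
      penalized[i] <- TRUE
    }
    coefs[i, ] <- b[-1L]
    groups[i] <- if ("group" %in% names(tr)) as.character(tr$group[1]) else ""
  }
  smry <- data.frame(
    lag = seq_len(n_lags),
    mean = colMeans(coefs),
    se = apply(coefs, 2, sd) / sqrt(nrow(coefs)),
    cohens_d = colMeans(coefs) / apply(coefs, 2, sd)
  )
  smry$t <- smry$mean / smry$se
  smry$p <- 2 * pt(-abs(smry$t), df = nrow(coefs) - 1L)
  out <- list(coefficients = coefs, penalized = penalized,
              summary = smry, n_lags = n_lags, group = groups)
  class(out) <- "pal_lag_regression"
  out
}

#' @export
print.pal_lag_regression <- function(x, ...) {
  cat("Lagged outcome -> switch logistic regression (",
      nrow(x$coefficients), " subjects, ", x$n_lags, " lags; ",
      sum(x$penalized), " ridge-penalized)\n", sep = "")
  print(round(x$summary, 3), row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA across treatment groups
#'
#' Standard one-way analysis of variance of a per-subject scalar across
#' group labels, with eta squared (SS_between / SS_total).
#'
#' @param values Numeric vector, one value per subject.
#' @param groups Group labels, same length.
#' @return List of class `pal_anova`: `F`, `df` (between, within),
#'   `p_value`, `eta_squared`.
#' @export
group_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  ss_b <- tab[["Sum Sq"]][1L]
  ss_w <- tab[["Sum Sq"]][2L]
  out <- list(F = tab[["F value"]][1L],
              df = c(between = tab[["Df"]][1L], within = tab[["Df"]][2L]),
              p_value = tab[["Pr(>F)"]][1L],
              eta_squared = ss_b / (ss_b + ss_w))
  class(out) <- "pal_anova"
  out
}

#' @export
print.pal_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.3g, eta^2 = %.3f\n",
              x$df[1], x$df[2], x$F, x$p_value, x$eta_squared))
  invisible(x)
}
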