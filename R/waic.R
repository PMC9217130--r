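# WAIC model comparison on the deviance scale.

#' Widely applicable information criterion (WAIC)
#'
#' Computes WAIC from a pointwise log-likelihood matrix:
#' `lppd = sum_i log mean_d exp(loglik[d, i])` (evaluated with log-sum-exp
#' for numerical stability), the effective-parameter penalty
#' `p_waic = sum_i var_d(loglik[d, i])`, and
#' `waic = -2 * (lppd - p_waic)` on the deviance scale, so lower values
#' indicate better expected out-of-sample predictive accuracy.
#'
#' The default pointwise unit for a fitted model is one participant (one
#' log-likelihood per subject per draw); per-trial pointwise WAIC is
#' available via `pointwise = "trial"`.
#'
#' @param x A draws-by-observations log-likelihood matrix, or a [pal_fit].
#' @param ... Passed to methods.
#' @return Object of class `pal_waic`: list with `lppd`, `p_waic`, `waic`,
#'   `n_points`, `n_draws`, `pointwise` (per-observation lppd and p_waic
#'   contributions), and for fits `model` and `group_label`.
#' @examples
#' ll <- matrix(c(-3, -3, -3, -2, -2.5, -1.5), nrow = 3)  # 3 draws, 2 subjects
#' waic(ll)
#' @export
waic <- function(x, ...) UseMethod("waic")

#' @rdname waic
#' @export
waic.matrix <- function(x, ...) {
  if (nrow(x) < 2L) stop("WAIC needs at least 2 draws", call. = FALSE)
  if (ncol(x) < 1L) stop("WAIC needs at least 1 observation", call. = FALSE)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite log-likelihood at draw %d, observation %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  D <- nrow(x)
  # log mean exp per column, stabilized
  mx <- apply(x, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(x, 2, mx)))) # log(mean(exp(x - mx)))
  p_i <- apply(x, 2, var)
  out <- list(lppd = sum(lppd_i), p_waic = sum(p_i),
              waic = -2 * (sum(lppd_i) - sum(p_i)),
              n_points = ncol(x), n_draws = D,
              pointwise = data.frame(lppd = lppd_i, p_waic = p_i))
  class(out) <- "pal_waic"
  out
}

#' @rdname waic
#' @param pointwise For fits: `"subject"` (default) or `"trial"`. Per-trial
#'   pointwise WAIC needs the original trial table via `data`.
#' @param data Trial data, required only for `pointwise = "trial"`.
#' @export
waic.pal_fit <- function(x, pointwise = c("subject", "trial"), data = NULL, ...) {
  pointwise <- match.arg(pointwise)
  ll <- if (pointwise == "subject") {
    x$log_lik
  } else {
    if (is.null(data)) {
      stop("per-trial pointwise WAIC requires the original trial data",
           call. = FALSE)
    }
    fit_trialwise(x, data)
  }
  out <- waic.matrix(ll)
  out$model <- x$spec$model
  out$group_label <- x$group_label
  out$pointwise_unit <- pointwise
  out
}

#' Per-trial pointwise log-likelihood for a fitted model
#'
#' Recomputes, for every retained posterior draw and every trial, the log
#' softmax probability of the observed choice — the per-trial pointwise
#' matrix used by `waic(fit, pointwise = "trial", data = data)`.
#'
#' @param fit A `pal_fit`.
#' @param data The trial data the model was fitted to.
#' @return A draws x (total trials) matrix, trials stacked by subject.
#' @export
fit_trialwise <- function(fit, data) {
  dat <- cohort_matrices(data)
  dual <- fit$spec$model == "dual"
  D <- dim(fit$subject)[1]
  S <- length(dat$subjects)
  cols <- vector("list", S)
  for (s in seq_len(S)) {
    nt <- dat$n_trials[s]
    ch <- dat$choices[s, seq_len(nt)]
    oc <- dat$outcomes[s, seq_len(nt)]
    m <- matrix(NA_real_, D, nt)
    for (d in seq_len(D)) {
      ap <- fit$subject[d, s, 1L]
      anp <- if (dual) fit$subject[d, s, 2L] else ap
      bt <- fit$subject[d, s, if (dual) 3L else 2L]
      q0 <- -0.5; q1 <- -0.5
      for (t in seq_len(nt)) {
        pr <- choice_prob(c(q0, q1), bt)
        m[d, t] <- log(pr[ch[t] + 1L])
        a <- if (oc[t] == -1L) ap else anp
        if (ch[t] == 0L) q0 <- q0 + a * (oc[t] - q0)
        else q1 <- q1 + a * (oc[t] - q1)
      }
    }
    cols[[s]] <- m
  }
  do.call(cbind, cols)
}

#' @export
print.pal_waic <- function(x, ...) {
  if (!is.null(x$group_label)) {
    cat("WAIC for group '", x$group_label, "' (", x$model,
        "-learning-rate model)\n", sep = "")
  }
  cat(sprintf("  lppd = %.2f, p_waic = %.2f, WAIC = %.2f (deviance scale, %d %s)\n",
              x$lppd, x$p_waic, x$waic, x$n_points,
              if (is.null(x$pointwise_unit)) "points" else
                paste0(x$pointwise_unit, "s")))
  invisible(x)
}

#' Grade the evidence implied by a WAIC difference
#'
#' Interprets `|waic_a - waic_b|` on the conventional deviance-scale bands:
#' a difference below 2 is negligible, 2-6 positive evidence, 6-10 strong
#' evidence, and above 10 very strong evidence for the lower-WAIC model.
#'
#' @param waic_a,waic_b WAIC values (deviance scale) or `pal_waic` objects.
#' @return List of class `pal_evidence`: `difference` (waic_a - waic_b),
#'   `grade`, and `preferred` (`"a"`, `"b"`, or `"none"`).
#' @examples
#' grade_evidence(3109, 2959)
#' @export
grade_evidence <- function(waic_a, waic_b) {
  val <- function(w) if (inherits(w, "pal_waic")) w$waic else w
  a <- val(waic_a); b <- val(waic_b)
  if (!is.finite(a) || !is.finite(b)) {
    stop("WAIC values must be finite", call. = FALSE)
  }
  d <- a - b
  ad <- abs(d)
  grade <- if (ad < 2) "negligible"
  else if (ad < 6) "positive"
  else if (ad <= 10) "strong"
  else "very strong"
  preferred <- if (ad < 2) "none" else if (d > 0) "b" else "a"
  out <- list(difference = d, grade = grade, preferred = preferred)
  class(out) <- "pal_evidence"
  out
}

#' @export
print.pal_evidence <- function(x, ...) {
  if (x$preferred == "none") {
    cat(sprintf("WAIC difference %.2f: negligible; no preferred model\n",
                x$difference))
  } else {
    cat(sprintf("WAIC difference %.2f: %s evidence for model %s\n",
                x$difference, x$grade, x$preferred))
  }
  invisible(x)
}

#' Compare two fitted models by WAIC
#'
#' @param fit_a,fit_b `pal_fit` or `pal_waic` objects.
#' @return List of class `pal_waic_compare` with both WAIC reports, the
#'   difference `waic_a - waic_b`, and the evidence grade.
#' @export
waic_compare <- function(fit_a, fit_b) {
  wa <- if (inherits(fit_a, "pal_waic")) fit_a else waic(fit_a)
  wb <- if (inherits(fit_b, "pal_waic")) fit_b else waic(fit_b)
  out <- list(waic_a = wa, waic_b = wb,
              difference = wa$waic - wb$waic,
              evidence = grade_evidence(wa, wb))
  class(out) <- "pal_waic_compare"
  out
}

#' @export
print.pal_waic_compare <- function(x, ...) {
  cat(sprintf("Model A: WAIC = %.1f | Model B: WAIC = %.1f\n",
              x$waic_a$waic, x$waic_b$waic))
  print(x$evidence)
  invisible(x)
}
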