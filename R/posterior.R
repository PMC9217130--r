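# Posterior summaries and between-group contrasts.

#' Highest density interval of a sample
#'
#' Shortest contiguous interval containing at least `ceiling(mass * n)` of
#' the sorted samples. Assumes a unimodal posterior (for which the HDI is a
#' single interval); a warning is issued when the sample looks clearly
#' multimodal.
#'
#' @param x Numeric vector of draws (>= 2 finite values).
#' @param mass Probability mass to cover, in (0, 1). Default 0.95.
#' @param check_multimodal Emit a warning when a kernel density estimate of
#'   `x` has more than one pronounced mode (only checked for n >= 200).
#' @return Numeric vector `c(low, high)`.
#' @export
hdi <- function(x, mass = 0.95, check_multimodal = TRUE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("'x' must contain at least 2 finite samples", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("'mass' must be in (0, 1)", call. = FALSE)
  s <- sort(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(s[1L], s[n]))
  # windows of exactly k consecutive sorted samples
  lows <- s[seq_len(n - k + 1L)]
  highs <- s[k:n]
  w <- highs - lows
  i <- which.min(w)
  if (check_multimodal && n >= 200L && s[1L] < s[n]) {
    d <- density(x, n = 128)
    y <- d$y / max(d$y)
    peak <- which(diff(sign(diff(y))) == -2) + 1L
    peak <- peak[y[peak] > 0.5]
    # two pronounced peaks separated by a deep valley
    if (length(peak) >= 2L &&
        min(y[min(peak):max(peak)]) < 0.3) {
      warning("sample looks multimodal; a single HDI interval may be misleading",
              call. = FALSE)
    }
  }
  c(s[i], s[i + k - 1L])
}

#' Proportion of paired draws where a exceeds b
#'
#' Fraction of draw indices with `a > b` (strict), the posterior
#' probability statement used for within-group parameter orderings (e.g.
#' the proportion of draws on which the pain learning rate exceeds the
#' no-pain learning rate).
#'
#' @param draws_a,draws_b Equal-length numeric vectors, paired by draw.
#' @return A probability in \[0, 1\].
#' @export
proportion_greater <- function(draws_a, draws_b) {
  if (length(draws_a) != length(draws_b)) {
    stop("'draws_a' and 'draws_b' must have equal length", call. = FALSE)
  }
  if (length(draws_a) == 0L) stop("empty draw vectors", call. = FALSE)
  mean(draws_a > draws_b)
}

#' Difference distribution between two sets of posterior draws
#'
#' Elementwise difference `draws_a - draws_b` paired by draw index, with
#' the proportion of differences strictly above zero and its 95% HDI — the
#' between-group contrast used to compare group-level means across
#' independently fitted treatment groups. Because the fits are independent,
#' pairing by draw index is a harmless convention; set
#' `shuffle = TRUE` to verify insensitivity to the pairing.
#'
#' @param draws_a,draws_b Equal-length draw vectors.
#' @param mass HDI mass (default 0.95).
#' @param parameter Optional label carried in the result.
#' @param shuffle Randomly permute `draws_b` before differencing.
#' @return Object of class `pal_contrast`: `draws` (the differences),
#'   `proportion_above_zero`, `hdi`, `median`, `parameter`.
#' @export
difference_distribution <- function(draws_a, draws_b, mass = 0.95,
                                    parameter = NULL, shuffle = FALSE) {
  if (length(draws_a) == 0L || length(draws_b) == 0L) {
    stop("empty draw vectors", call. = FALSE)
  }
  if (length(draws_a) != length(draws_b)) {
    stop("'draws_a' and 'draws_b' must have equal length ",
         "(draws are paired by index)", call. = FALSE)
  }
  if (shuffle) draws_b <- sample(draws_b)
  d <- draws_a - draws_b
  out <- list(draws = d,
              proportion_above_zero = mean(d > 0),
              hdi = if (length(d) >= 2L) hdi(d, mass) else c(d, d),
              median = median(d),
              mass = mass,
              parameter = parameter)
  class(out) <- "pal_contrast"
  out
}

#' Contrast a group-level mean parameter between two fitted groups
#'
#' Convenience wrapper around [difference_distribution()] operating on the
#' constrained group-level mean draws of two [pal_fit] objects (group A
#' minus group B).
#'
#' @param fit_a,fit_b `pal_fit` objects sharing the model variant.
#' @param parameter Parameter name, e.g. `"alpha_nopain"` or `"beta"`.
#' @param ... Passed to [difference_distribution()].
#' @return A `pal_contrast`.
#' @export
pal_contrast <- function(fit_a, fit_b, parameter, ...) {
  stopifnot(inherits(fit_a, "pal_fit"), inherits(fit_b, "pal_fit"))
  if (!parameter %in% colnames(fit_a$group_mean) ||
      !parameter %in% colnames(fit_b$group_mean)) {
    stop("parameter '", parameter, "' not found in both fits", call. = FALSE)
  }
  out <- difference_distribution(fit_a$group_mean[, parameter],
                                 fit_b$group_mean[, parameter],
                                 parameter = parameter, ...)
  out$groups <- c(fit_a$group_label, fit_b$group_label)
  out
}

#' @export
print.pal_contrast <- function(x, ...) {
  lab <- if (!is.null(x$groups)) {
    paste0(x$groups[1], " - ", x$groups[2],
           if (!is.null(x$parameter)) paste0(" (", x$parameter, ")") else "")
  } else if (!is.null(x$parameter)) x$parameter else "contrast"
  cat("Posterior contrast ", lab, ":\n", sep = "")
  cat(sprintf("  median difference %.3f, %d%% HDI [%.3f, %.3f]\n",
              x$median, round(100 * x$mass), x$hdi[1], x$hdi[2]))
  cat(sprintf("  %.1f%% of the difference distribution lies above 0\n",
              100 * x$proportion_above_zero))
  invisible(x)
}

#' Per-subject posterior medians and HDIs
#'
#' Summarizes each subject's constrained parameter draws of a fitted model
#' as posterior medians with HDIs.
#'
#' @param fit A `pal_fit`.
#' @param mass HDI mass (default 0.95).
#' @return data.frame with columns `subject`, `parameter`, `median`,
#'   `hdi_low`, `hdi_high`.
#' @export
individual_medians <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "pal_fit"))
  pn <- dimnames(fit$subject)[[3]]
  subs <- fit$subjects
  rows <- list()
  for (p in seq_along(pn)) {
    for (s in seq_along(subs)) {
      v <- fit$subject[, s, p]
      h <- if (length(unique(v)) == 1L) c(v[1], v[1])
      else hdi(v, mass, check_multimodal = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subs[s], parameter = pn[p],
        median = median(v), hdi_low = h[1], hdi_high = h[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
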