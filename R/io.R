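# Trial-table ingestion/export and regressor files.

#' Column mapping for trial tables
#'
#' Declares how the columns of a delimited trial table map to the canonical
#' fields, and which outcome coding the file uses. `outcome_dialect`
#' `"auto"` recognizes `pain`/`no_pain` tokens, 1/0 (1 = pain), and -1/0.
#'
#' @param participant_id,group,trial,run,choice,outcome,missed,rt_ms Source
#'   column names (set `run`, `missed`, `rt_ms`, `group` to NA if absent).
#' @param outcome_dialect One of `"auto"`, `"pain_nopain"`, `"binary01"`,
#'   `"neg1_0"`.
#' @return A named list of class `pal_column_map`.
#' @export
pal_column_map <- function(participant_id = "participant_id", group = "group",
                           trial = "trial", run = "run", choice = "choice",
                           outcome = "outcome", missed = "missed",
                           rt_ms = "rt_ms",
                           outcome_dialect = c("auto", "pain_nopain",
                                               "binary01", "neg1_0")) {
  out <- list(participant_id = participant_id, group = group, trial = trial,
              run = run, choice = choice, outcome = outcome, missed = missed,
              rt_ms = rt_ms, outcome_dialect = match.arg(outcome_dialect))
  class(out) <- "pal_column_map"
  out
}

normalize_outcome <- function(x, dialect) {
  if (dialect == "auto") {
    tokens <- unique(as.character(x))
    dialect <- if (all(tokens %in% c("pain", "no_pain"))) "pain_nopain"
    else if (all(tokens %in% c("1", "0"))) "binary01"
    else if (all(tokens %in% c("-1", "0"))) "neg1_0"
    else stop("unrecognized outcome coding; tokens found: ",
              paste(utils::head(tokens, 5), collapse = ", "), call. = FALSE)
  }
  out <- switch(dialect,
                pain_nopain = ifelse(as.character(x) == "pain", -1L, 0L),
                binary01 = -as.integer(as.character(x)),
                neg1_0 = as.integer(as.character(x)))
  if (any(is.na(out)) || !all(out %in% c(-1L, 0L))) {
    stop("outcome values do not match declared dialect '", dialect, "'",
         call. = FALSE)
  }
  out
}

#' Read a cohort trial table from delimited text
#'
#' Parses a CSV/TSV of single-trial data into the canonical stacked format:
#' columns `subject`, `group`, `trial`, `run`, `choice` (0/1), `outcome`
#' (-1 = pain, 0 = no pain), `missed`, `rt_ms`. Outcomes are normalized
#' from the declared dialect; arbitrary two-level choice labels are mapped
#' to 0/1 (sorted label order). Rows are ordered by subject and trial, and
#' duplicate trial indices within a participant are an error.
#'
#' @param path Path to a delimited text file.
#' @param column_map A [pal_column_map()].
#' @param sep Field separator (default `,`).
#' @return data.frame in canonical form.
#' @export
read_pal_trials <- function(path, column_map = pal_column_map(), sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  cm <- column_map
  need <- c("participant_id", "trial", "choice", "outcome")
  for (f in need) {
    if (is.na(cm[[f]]) || !cm[[f]] %in% names(raw)) {
      stop("required column '", cm[[f]], "' (", f, ") not found in ", path,
           call. = FALSE)
    }
  }
  ch_raw <- raw[[cm$choice]]
  ch_levels <- sort(unique(as.character(ch_raw)))
  if (length(ch_levels) > 2L) {
    stop("'choice' has more than two levels: ",
         paste(ch_levels, collapse = ", "), call. = FALSE)
  }
  choice <- if (all(ch_levels %in% c("0", "1"))) {
    as.integer(as.character(ch_raw))
  } else if (all(ch_levels %in% c("1", "2"))) {
    as.integer(as.character(ch_raw)) - 1L
  } else {
    as.integer(factor(as.character(ch_raw), levels = ch_levels)) - 1L
  }
  out <- data.frame(
    subject = raw[[cm$participant_id]],
    group = if (!is.na(cm$group) && cm$group %in% names(raw))
      as.character(raw[[cm$group]]) else "all",
    trial = as.integer(raw[[cm$trial]]),
    run = if (!is.na(cm$run) && cm$run %in% names(raw))
      as.integer(raw[[cm$run]]) else 1L,
    choice = choice,
    outcome = normalize_outcome(raw[[cm$outcome]], cm$outcome_dialect),
    missed = if (!is.na(cm$missed) && cm$missed %in% names(raw))
      as.logical(raw[[cm$missed]]) else FALSE
  )
  if (!is.na(cm$rt_ms) && cm$rt_ms %in% names(raw)) {
    out$rt_ms <- as.numeric(raw[[cm$rt_ms]])
    if (any(out$rt_ms < 0, na.rm = TRUE)) {
      stop("negative reaction times in column '", cm$rt_ms, "'", call. = FALSE)
    }
  }
  dup <- duplicated(out[, c("subject", "trial")])
  if (any(dup)) {
    stop("duplicate trial index for participant(s) ",
         paste(unique(out$subject[dup]), collapse = ", "),
         " (first at row ", which(dup)[1L], ")", call. = FALSE)
  }
  out <- out[order(out$subject, out$trial), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a cohort trial table as CSV
#'
#' @param data Stacked trial data.frame or `pal_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pal_trials <- function(data, path) {
  d <- if (inherits(data, "pal_cohort")) data$trials else data
  names(d)[names(d) == "subject"] <- "participant_id"
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Mean of individual-level posterior median learning rates
#'
#' The conventional learning rates for regressor generation: per fit, each
#' participant's posterior median, averaged across all participants of all
#' supplied fits (all treatment groups pooled).
#'
#' @param ... One or more `pal_fit` objects (dual-learning-rate model).
#' @return Named vector `c(alpha_pain, alpha_nopain)`.
#' @export
mean_posterior_alphas <- function(...) {
  fits <- list(...)
  stopifnot(length(fits) >= 1L)
  meds <- lapply(fits, function(f) {
    stopifnot(inherits(f, "pal_fit"))
    m <- individual_medians(f)
    m[m$parameter %in% c("alpha_pain", "alpha_nopain"), ]
  })
  m <- do.call(rbind, meds)
  c(alpha_pain = mean(m$median[m$parameter == "alpha_pain"]),
    alpha_nopain = mean(m$median[m$parameter == "alpha_nopain"]))
}

#' Compute expected-pain-probability regressors for a cohort
#'
#' Replays every participant through [expected_pain_trajectory()] at common
#' learning rates (typically [mean_posterior_alphas()] of the fitted
#' groups).
#'
#' @param data Stacked trial table or `pal_cohort`.
#' @param alpha_pain,alpha_nopain Learning rates in \[0, 1\].
#' @return Named list (one element per participant) of data.frames with
#'   `trial` and `expected_pain_probability`.
#' @export
pain_regressors <- function(data, alpha_pain, alpha_nopain = alpha_pain) {
  d <- if (inherits(data, "pal_cohort")) data$trials else data
  ids <- unique(d$subject)
  out <- lapply(ids, function(id) {
    tr <- d[d$subject == id, , drop = FALSE]
    tr <- check_trials(tr)
    data.frame(trial = if ("trial" %in% names(tr)) tr$trial else seq_len(nrow(tr)),
               expected_pain_probability =
                 expected_pain_trajectory(tr, alpha_pain, alpha_nopain))
  })
  names(out) <- as.character(ids)
  out
}

#' Write per-participant regressor files
#'
#' One CSV per participant (`regressor_<id>.csv`: columns `trial`,
#' `expected_pain_probability`), for use as parametric modulators in
#' downstream GLM analyses.
#'
#' @param trajectories Named list as returned by [pain_regressors()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_pain_regressors <- function(trajectories, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (length(trajectories) == 0L) {
    warning("no trajectories supplied; nothing written", call. = FALSE)
    return(invisible(character(0)))
  }
  paths <- vapply(names(trajectories), function(id) {
    p <- file.path(out_dir, paste0("regressor_", id, ".csv"))
    df <- trajectories[[id]]
    # full double precision so the file round-trips bit-exactly
    df$expected_pain_probability <-
      sprintf("%.17g", df$expected_pain_probability)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }, character(1))
  invisible(unname(paths))
}
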