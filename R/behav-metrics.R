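# Behavioural summary measures computed identically on observed and
# simulated data: mean response time, probability of choosing the
# highest-rated seen item, probability of choosing the last-gazed item,
# fraction of items seen, and the regression-based gaze-influence
# statistic.

#' Probability of choosing the highest-rated seen item
#'
#' Fraction of valid trials in which the chosen item's liking rating
#' equals the maximum rating among the items the subject looked at
#' (ties count as success).
#'
#' @param trials List of valid [trial_record()] objects.
#' @return Proportion in `[0, 1]`, or `NA` with no valid trials.
#' @export
p_choose_best_seen <- function(trials) {
  trials <- Filter(function(tr) tr$valid, trials)
  if (!length(trials)) return(NA_real_)
  hits <- vapply(trials, function(tr) {
    st <- gaze_stats(tr)
    tr$items$rating[tr$choice_index] == max(tr$items$rating[st$seen])
  }, NA)
  mean(hits)
}

#' Probability of choosing the last-gazed item
#'
#' @inheritParams p_choose_best_seen
#' @return Proportion in `[0, 1]`, or `NA` with no valid trials.
#' @export
p_choose_last_seen <- function(trials) {
  trials <- Filter(function(tr) tr$valid, trials)
  if (!length(trials)) return(NA_real_)
  mean(vapply(trials, function(tr) {
    gaze_stats(tr)$last_gazed_item == tr$choice_index
  }, NA))
}

#' Fraction of the choice set that was looked at
#'
#' @param trial A valid trial.
#' @return `|seen| / set_size`.
#' @export
frac_items_seen <- function(trial) {
  sum(gaze_stats(trial)$seen) / trial$set_size
}

# per item x trial design rows for the gaze-influence regression
gaze_influence_rows <- function(trials, seen_only = FALSE) {
  rows <- lapply(trials, function(tr) {
    st <- gaze_stats(tr)
    adv <- gaze_advantage(st)
    r <- tr$items$rating
    n <- tr$set_size
    rel <- vapply(seq_len(n), function(i) r[i] - mean(r[-i]), 0)
    mean_o <- vapply(seq_len(n), function(i) mean(r[-i]), 0)
    range_o <- vapply(seq_len(n), function(i) diff(range(r[-i])), 0)
    df <- data.frame(
      y = as.integer(seq_len(n) == tr$choice_index),
      rel_rating = rel, mean_others = mean_o, range_others = range_o,
      adv = adv
    )
    if (seen_only) df <- df[st$seen, , drop = FALSE]
    df
  })
  do.call(rbind, rows)
}

# logistic fit with a small ridge penalty; fallback under separation
penalized_logistic <- function(X, y, lambda = 1e-3) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda * sum(beta[-1]^2)
  }
  grad <- function(beta) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    drop(crossprod(X, p - y)) + 2 * lambda * c(0, beta[-1])
  }
  fit <- optim(numeric(ncol(X)), nll, grad, method = "BFGS",
               control = list(maxit = 500))
  1 / (1 + exp(-drop(X %*% fit$par)))
}

#' Gaze influence on choice probability (percentage points)
#'
#' Quantifies the mean increase in choice probability for the item
#' looked at longest, after accounting for the liking ratings. Per item
#' per trial, a binary choice outcome is regressed (logistic, with
#' intercept) on the item's relative rating (its rating minus the mean
#' rating of the other items), and the mean and range of the other
#' items' ratings. The residual (outcome minus fitted probability) is
#' then contrasted between items with a positive cumulative gaze
#' advantage and all other items:
#' `100 * (mean residual | adv > 0  -  mean residual | adv <= 0)`.
#'
#' Under complete separation the logistic fit falls back to a weakly
#' ridge-regularized fit. Degenerate predictors (zero variance) give
#' `NA`.
#'
#' @param trials Valid trials of one subject in one set-size condition.
#' @param seen_only Restrict the regression to seen items (default
#'   includes all items; unseen items have cumulative gaze 0).
#' @param engine `"logistic"` (default) or `"linear"` (linear
#'   probability model, for sensitivity checks).
#' @return Gaze influence in percentage points, or `NA`.
#' @export
gaze_influence <- function(trials, seen_only = FALSE,
                           engine = c("logistic", "linear")) {
  engine <- match.arg(engine)
  trials <- Filter(function(tr) tr$valid, trials)
  if (length(trials) < 2L) return(NA_real_)
  df <- gaze_influence_rows(trials, seen_only)
  preds <- c("rel_rating", "mean_others", "range_others")
  if (any(vapply(df[preds], function(x) var(x) == 0, NA))) {
    return(NA_real_)
  }
  if (engine == "linear") {
    fitted <- stats::lm(y ~ rel_rating + mean_others + range_others,
                        data = df)$fitted.values
  } else {
    fit <- withCallingHandlers(
      glm(y ~ rel_rating + mean_others + range_others,
          family = binomial(), data = df),
      warning = function(w) invokeRestart("muffleWarning")
    )
    fitted <- if (fit$converged && max(abs(stats::coef(fit)[-1])) < 50) {
      fit$fitted.values
    } else {
      X <- cbind(1, as.matrix(df[preds]))
      penalized_logistic(X, df$y)
    }
  }
  res <- df$y - fitted
  pos <- df$adv > 0
  if (!any(pos) || all(pos)) return(NA_real_)
  100 * (mean(res[pos]) - mean(res[!pos]))
}

#' Behavioural summary per subject and set size
#'
#' Assembles the five summary measures over each subject's valid trials
#' in each set-size condition. The same code path serves observed and
#' simulated datasets.
#'
#' @param datasets List of [subject_dataset()] objects (a single dataset
#'   is also accepted).
#' @return `data.frame` with columns `subject`, `set_size`, `n_trials`,
#'   `mean_rt_ms`, `p_choose_best_seen`, `p_choose_last_seen`,
#'   `frac_items_seen`, `gaze_influence`.
#' @export
behaviour_summary <- function(datasets) {
  if (inherits(datasets, "mc_dataset")) datasets <- list(datasets)
  rows <- list()
  for (ds in datasets) {
    valid <- Filter(function(tr) tr$valid, ds$trials)
    sizes <- sort(unique(vapply(valid, function(tr) tr$set_size, 1L)))
    for (n in sizes) {
      trs <- Filter(function(tr) tr$set_size == n, valid)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = ds$subject_id,
        set_size = n,
        n_trials = length(trs),
        mean_rt_ms = mean(vapply(trs, function(tr) tr$rt_ms, 1L)),
        p_choose_best_seen = p_choose_best_seen(trs),
        p_choose_last_seen = p_choose_last_seen(trs),
        frac_items_seen = mean(vapply(trs, frac_items_seen, 0)),
        gaze_influence = gaze_influence(trs),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(subject = character(), set_size = integer(),
                      n_trials = integer(), mean_rt_ms = double(),
                      p_choose_best_seen = double(),
                      p_choose_last_seen = double(),
                      frac_items_seen = double(),
                      gaze_influence = double()))
  }
  do.call(rbind, rows)
}
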