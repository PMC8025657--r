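# Gaze-stream cleaning, trial exclusion rules, and per-trial gaze
# statistics shared by all models and behavioural measures.

#' Clean a raw gaze stream into item-only gazes
#'
#' Applies the preprocessing rules used for all gaze analyses, in this
#' order: (1) missing segments flanked by two segments of the same item
#' are relabelled to that item; (2) time-contiguous same-item segments
#' are merged into single gazes; (3) leading and trailing non-item and
#' missing segments are discarded; (4) remaining non-item and missing
#' segments (those between gazes to different items) are discarded.
#' A non-item fixation interrupts a gaze, so `item, non-item, item`
#' yields two separate gazes to the item, whereas `item, missing, item`
#' becomes one merged gaze spanning all three durations.
#'
#' The function is idempotent: cleaning a clean stream is a no-op.
#'
#' @param gaze `data.frame` with columns `item` (1-based index, 0 =
#'   non-item, -1 = missing), `onset_ms`, `dur_ms`; ordered,
#'   non-overlapping.
#' @return `data.frame` of item-only gaze segments.
#' @export
clean_gaze <- function(gaze) {
  if (!nrow(gaze)) return(gaze)
  if (any(diff(gaze$onset_ms) < 0) ||
      any(gaze$onset_ms[-1] < head(gaze$onset_ms + gaze$dur_ms, -1))) {
    stop("gaze segments must be ordered and non-overlapping", call. = FALSE)
  }
  item <- gaze$item
  onset <- gaze$onset_ms
  dur <- gaze$dur_ms
  n <- length(item)

  # (1) relabel missing flanked by the same item
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (item[i] == GAZE_MISSING && item[i - 1] >= 1L &&
          item[i - 1] == item[i + 1]) {
        item[i] <- item[i - 1]
      }
    }
  }

  # (2) merge time-contiguous same-item runs
  out_item <- integer(0); out_onset <- integer(0); out_dur <- integer(0)
  for (i in seq_len(n)) {
    m <- length(out_item)
    if (m > 0 && item[i] >= 1L && out_item[m] == item[i] &&
        onset[i] == out_onset[m] + out_dur[m]) {
      out_dur[m] <- out_dur[m] + dur[i]
    } else {
      out_item <- c(out_item, item[i])
      out_onset <- c(out_onset, onset[i])
      out_dur <- c(out_dur, dur[i])
    }
  }

  # (3) + (4) keep item segments only (this drops leading/trailing
  # non-item/missing segments and those between different items alike)
  keep <- out_item >= 1L
  data.frame(item = out_item[keep], onset_ms = out_onset[keep],
             dur_ms = out_dur[keep])
}

#' Apply the experiment's trial exclusion rules
#'
#' A trial is marked invalid when the subject did not choose in time
#' (`timeout`), clicked the empty space between item images
#' (`clicked_empty`, carried over from the recorded marker), or chose an
#' item never gazed before the spacebar press (`chose_unseen`). The
#' returned record carries cleaned gaze.
#'
#' @param trial An [trial_record()] object.
#' @return The trial with cleaned gaze and `valid`/`exclusion_reason` set.
#' @export
apply_exclusions <- function(trial) {
  trial$gaze <- clean_gaze(trial$gaze)
  if (identical(trial$exclusion_reason, "clicked_empty")) {
    trial$valid <- FALSE
    return(trial)
  }
  if (is.na(trial$choice_index) || is.na(trial$rt_ms)) {
    trial$valid <- FALSE
    trial$exclusion_reason <- "timeout"
    return(trial)
  }
  g <- trial$gaze
  seen_before_rt <- g$item[g$onset_ms < trial$rt_ms]
  if (!trial$choice_index %in% seen_before_rt) {
    trial$valid <- FALSE
    trial$exclusion_reason <- "chose_unseen"
    return(trial)
  }
  trial$valid <- TRUE
  trial$exclusion_reason <- "none"
  trial
}

#' Per-trial gaze statistics
#'
#' Computes, for each item of a valid trial: whether it was seen, total
#' gaze time, cumulative gaze as a fraction of total trial time (the
#' denominator is the response time, so non-item time dilutes every
#' fraction), the onset of the first gaze (`t0_ms`), and the number of
#' gazes; plus the index of the last-gazed item.
#'
#' @param trial A valid trial with cleaned gaze.
#' @return List with per-item vectors `seen`, `total_gaze_ms`,
#'   `cum_gaze_frac`, `t0_ms`, `n_gazes` and scalars `last_gazed_item`,
#'   `rt_ms`, `set_size`.
#' @export
gaze_stats <- function(trial) {
  g <- trial$gaze
  if (any(g$item < 1L)) {
    stop("gaze_stats requires a cleaned, item-only gaze stream",
         call. = FALSE)
  }
  if (!nrow(g)) {
    stop("valid trial with empty gaze stream", call. = FALSE)
  }
  rt <- trial$rt_ms
  n <- trial$set_size
  # clip segments at the response time
  dur <- pmin(g$dur_ms, pmax(rt - g$onset_ms, 0L))
  keep <- g$onset_ms < rt & dur > 0L
  g <- g[keep, , drop = FALSE]
  dur <- dur[keep]
  total <- integer(n)
  t0 <- rep(NA_integer_, n)
  ngz <- integer(n)
  for (i in seq_len(nrow(g))) {
    it <- g$item[i]
    total[it] <- total[it] + dur[i]
    ngz[it] <- ngz[it] + 1L
    if (is.na(t0[it])) t0[it] <- g$onset_ms[i]
  }
  list(
    seen = total > 0L,
    total_gaze_ms = total,
    cum_gaze_frac = total / rt,
    t0_ms = t0,
    n_gazes = ngz,
    last_gazed_item = g$item[nrow(g)],
    rt_ms = rt,
    set_size = n
  )
}

#' Gaze fraction time course g_i(t)
#'
#' For each item, the fraction of elapsed trial time spent gazing it,
#' evaluated on the grid t = dt, 2 dt, ..., rt. When `dt_ms` does not
#' divide the response time the final step is evaluated at t = rt.
#'
#' @param trial A valid trial with cleaned gaze.
#' @param dt_ms Grid step in milliseconds (>= 1).
#' @return Matrix of dimension `set_size` x `length(grid)` with attribute
#'   `"t_ms"` holding the grid.
#' @export
gaze_timecourse <- function(trial, dt_ms = 1L) {
  stopifnot(dt_ms >= 1L)
  rt <- trial$rt_ms
  tgrid <- seq(dt_ms, rt, by = dt_ms)
  if (tail(tgrid, 1L) < rt) tgrid <- c(tgrid, rt)
  g <- trial$gaze
  n <- trial$set_size
  out <- matrix(0, nrow = n, ncol = length(tgrid))
  for (i in seq_len(nrow(g))) {
    it <- g$item[i]
    if (it < 1L) next
    a <- g$onset_ms[i]
    b <- min(a + g$dur_ms[i], rt)
    if (b <= a) next
    # gaze time to item within [0, t]: overlap of [a, b) with [0, t)
    out[it, ] <- out[it, ] + pmax(0, pmin(tgrid, b) - a)
  }
  out <- sweep(out, 2L, tgrid, "/")
  attr(out, "t_ms") <- tgrid
  out
}

#' Cumulative gaze advantage per item
#'
#' The difference between an item's cumulative gaze and the maximum
#' cumulative gaze of any other item in the trial. At most one item can
#' have a positive advantage; under a tie for the longest gaze no item
#' does.
#'
#' @param stats Output of [gaze_stats()] (or any list with a
#'   `cum_gaze_frac` vector of length >= 2).
#' @return Numeric vector of advantages.
#' @export
gaze_advantage <- function(stats) {
  g <- stats$cum_gaze_frac
  if (length(g) < 2L) stop("need at least two items", call. = FALSE)
  vapply(seq_along(g), function(i) g[i] - max(g[-i]), 0)
}

#' Export per-trial gaze statistics as a long table
#'
#' @param datasets List of [subject_dataset()] objects with cleaned,
#'   validated trials.
#' @return `data.frame` with one row per valid trial x item.
#' @export
gaze_stats_table <- function(datasets) {
  rows <- list()
  for (ds in datasets) {
    for (tr in ds$trials) {
      if (!tr$valid) next
      st <- gaze_stats(tr)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = tr$subject_id, trial = tr$trial_id,
        item = seq_len(tr$set_size), seen = st$seen,
        total_gaze_ms = st$total_gaze_ms,
        cum_gaze_frac = st$cum_gaze_frac, t0_ms = st$t0_ms,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(subject = character(), trial = integer(),
                      item = integer(), seen = logical(),
                      total_gaze_ms = integer(), cum_gaze_frac = double(),
                      t0_ms = integer()))
  }
  do.call(rbind, rows)
}
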