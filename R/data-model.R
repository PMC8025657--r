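#' manychoice: gaze-dependent choice models for many-alternative forced choice
#'
#' Tools for modelling choices and response times from large (9--36 item)
#' value-based choice sets with eye tracking: gaze-stream cleaning,
#' behavioural summary measures, three gaze-dependent likelihood models
#' (probabilistic satisficing, independent accumulation, relative
#' accumulation) with passive/active gaze variants, per-subject Metropolis
#' estimation with WAIC comparison, forward simulation, and a synthetic
#' experiment generator.
#'
#' @useDynLib manychoice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgamma glm binomial optim pnorm var sd
#'   cor setNames qnorm quantile median rbinom chisq.test complete.cases
#' @importFrom utils read.csv write.csv head tail
#' @keywords internal
"_PACKAGE"

# Sentinel codes used in the internal gaze table (1-based item indices):
# 0 = non-item gaze, -1 = missing gaze. On disk these are 0-based with
# -1 = non-item and -2 = missing.
GAZE_NONITEM <- 0L
GAZE_MISSING <- -1L

VALID_SET_SIZES <- c(9L, 16L, 25L, 36L)
EXCLUSION_REASONS <- c("none", "timeout", "chose_unseen", "clicked_empty")

#' Construct a single choice trial record
#'
#' A trial bundles the item set (with liking ratings, grid positions, and
#' image-coverage sizes), the ordered gaze stream, the recorded choice and
#' response time, and a validity flag.
#'
#' @param subject_id Character scalar.
#' @param trial_id Integer scalar.
#' @param items `data.frame` with columns `item_id`, `rating` (integer in
#'   -3..3), `row`, `col` (1-based grid indices), `size_frac` (fraction of
#'   the item image covered by the food depiction, in (0, 1]). One row per
#'   item, ordered row-major so that list position equals grid position.
#' @param gaze `data.frame` with columns `item` (1-based item index, or
#'   0 = non-item gaze, -1 = missing/blink), `onset_ms`, `dur_ms`.
#'   Segments are half-open `[onset, onset + dur)` and must be ordered and
#'   non-overlapping.
#' @param choice_index 1-based index of the chosen item, or `NA` if no
#'   choice was recorded.
#' @param rt_ms Response time (spacebar press) in integer milliseconds,
#'   or `NA`.
#' @param valid Logical; whether the trial enters analysis.
#' @param exclusion_reason One of `"none"`, `"timeout"`, `"chose_unseen"`,
#'   `"clicked_empty"`.
#' @return An object of class `mc_trial`.
#' @export
trial_record <- function(subject_id, trial_id, items, gaze,
                         choice_index = NA_integer_, rt_ms = NA_integer_,
                         valid = TRUE, exclusion_reason = "none") {
  trial <- structure(
    list(
      subject_id = as.character(subject_id),
      trial_id = as.integer(trial_id),
      set_size = nrow(items),
      items = items,
      gaze = gaze,
      choice_index = as.integer(choice_index),
      rt_ms = as.integer(rt_ms),
      valid = isTRUE(valid),
      exclusion_reason = exclusion_reason
    ),
    class = "mc_trial"
  )
  validate_trial(trial)
  trial
}

validate_trial <- function(trial) {
  n <- trial$set_size
  if (!n %in% VALID_SET_SIZES) {
    stop("set size must be one of 9, 16, 25, 36; got ", n, call. = FALSE)
  }
  k <- as.integer(sqrt(n))
  items <- trial$items
  req <- c("item_id", "rating", "row", "col", "size_frac")
  missing_cols <- setdiff(req, names(items))
  if (length(missing_cols)) {
    stop("items table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(items$rating < -3 | items$rating > 3)) {
    stop("liking ratings must lie on the 7-point scale -3..3", call. = FALSE)
  }
  if (any(items$row < 1 | items$row > k | items$col < 1 | items$col > k)) {
    stop("grid positions must lie in 1..sqrt(set_size)", call. = FALSE)
  }
  if (any(items$size_frac <= 0 | items$size_frac > 1)) {
    stop("size_frac must lie in (0, 1]", call. = FALSE)
  }
  gaze <- trial$gaze
  if (nrow(gaze)) {
    if (any(gaze$dur_ms <= 0)) {
      stop("gaze durations must be positive", call. = FALSE)
    }
    ends <- gaze$onset_ms + gaze$dur_ms
    if (any(diff(gaze$onset_ms) < 0) ||
        any(gaze$onset_ms[-1] < head(ends, -1))) {
      stop("gaze segments must be ordered and non-overlapping", call. = FALSE)
    }
    if (any(gaze$item > n)) {
      stop("gaze item index exceeds set size", call. = FALSE)
    }
  }
  if (!is.na(trial$choice_index) &&
      (trial$choice_index < 1L || trial$choice_index > n)) {
    stop("choice index out of range for set size ", n, call. = FALSE)
  }
  if (!trial$exclusion_reason %in% EXCLUSION_REASONS) {
    stop("unknown exclusion reason: ", trial$exclusion_reason, call. = FALSE)
  }
  invisible(trial)
}

#' @export
print.mc_trial <- function(x, ...) {
  cat(sprintf("<mc_trial> subject %s, trial %d, %d items, %d gaze segments,",
              x$subject_id, x$trial_id, x$set_size, nrow(x$gaze)))
  cat(sprintf(" choice %s, rt %s ms, %s\n",
              ifelse(is.na(x$choice_index), "NA", x$choice_index),
              ifelse(is.na(x$rt_ms), "NA", x$rt_ms),
              if (x$valid) "valid" else paste0("invalid (", x$exclusion_reason, ")")))
  invisible(x)
}

#' Construct a subject dataset
#'
#' @param subject_id Character scalar.
#' @param trials List of [trial_record()] objects for this subject.
#' @param ratings `data.frame` with columns `item_id`, `rating`, and
#'   `size_frac` covering every item referenced by the trials.
#' @return An object of class `mc_dataset`.
#' @export
subject_dataset <- function(subject_id, trials, ratings) {
  ds <- structure(
    list(subject_id = as.character(subject_id), trials = trials,
         ratings = ratings),
    class = "mc_dataset"
  )
  referenced <- unique(unlist(lapply(trials, function(tr) tr$items$item_id)))
  unknown <- setdiff(referenced, ratings$item_id)
  if (length(unknown)) {
    stop("items without a liking rating: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  ds
}

#' @export
print.mc_dataset <- function(x, ...) {
  cat(sprintf("<mc_dataset> subject %s: %d trials, %d rated items\n",
              x$subject_id, length(x$trials), nrow(x$ratings)))
  invisible(x)
}

#' Rescale a liking rating from the -3..3 scale to 1..7
#'
#' Model code requires strictly positive item values; the experiment's
#' 7-point liking scale is shifted affinely so -3 maps to 1 and 3 maps
#' to 7.
#'
#' @param rating Integer vector with entries in -3..3.
#' @return Integer vector with entries in 1..7.
#' @export
rescale_rating <- function(rating) {
  if (any(is.na(rating)) || any(rating < -3 | rating > 3) ||
      any(rating != round(rating))) {
    stop("ratings must be integers in -3..3", call. = FALSE)
  }
  as.integer(rating) + 4L
}

# ---- CSV interface ---------------------------------------------------------
# trials.csv:  subject, trial, setsize, choice (0-based or ""), rt_ms,
#              valid, exclusion_reason, items (";"-joined ids, grid order)
# gaze.csv:    subject, trial, item (0-based; -1 non-item, -2 missing),
#              onset_ms, dur_ms
# ratings.csv: subject, item_id, rating, size_frac

require_columns <- function(df, cols, file) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("file '%s' is missing required column(s): %s", file,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
}

item_grid <- function(n) {
  k <- as.integer(sqrt(n))
  data.frame(row = rep(seq_len(k), each = k), col = rep(seq_len(k), times = k))
}

#' Read a choice experiment from its three CSV files
#'
#' Assembles subject datasets from the trials, gaze, and ratings tables
#' (UTF-8, comma-separated, header row). Gaze rows whose (subject, trial)
#' key does not appear in the trials table are a validation error; item
#' indices are converted from the 0-based on-disk convention to 1-based.
#'
#' @param trials_path,gaze_path,ratings_path File paths.
#' @return List of [subject_dataset()] objects, ordered by subject id.
#' @export
read_choice_data <- function(trials_path, gaze_path, ratings_path) {
  for (p in c(trials_path, gaze_path, ratings_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  trials_df <- read.csv(trials_path, stringsAsFactors = FALSE,
                        colClasses = c(subject = "character"))
  gaze_df <- read.csv(gaze_path, stringsAsFactors = FALSE,
                      colClasses = c(subject = "character"))
  ratings_df <- read.csv(ratings_path, stringsAsFactors = FALSE,
                         colClasses = c(subject = "character"))
  require_columns(trials_df, c("subject", "trial", "setsize", "choice",
                               "rt_ms", "valid", "exclusion_reason", "items"),
                  trials_path)
  require_columns(gaze_df, c("subject", "trial", "item", "onset_ms", "dur_ms"),
                  gaze_path)
  require_columns(ratings_df, c("subject", "item_id", "rating", "size_frac"),
                  ratings_path)
  if (any(ratings_df$rating < -3 | ratings_df$rating > 3)) {
    bad <- ratings_df[ratings_df$rating < -3 | ratings_df$rating > 3, ]
    stop("ratings outside -3..3 for item(s): ",
         paste(head(bad$item_id, 5), collapse = ", "), call. = FALSE)
  }

  trial_keys <- paste(trials_df$subject, trials_df$trial)
  gaze_keys <- paste(gaze_df$subject, gaze_df$trial)
  orphans <- setdiff(gaze_keys, trial_keys)
  if (length(orphans)) {
    stop("gaze rows reference unknown (subject, trial) key(s): ",
         paste(head(orphans, 5), collapse = "; "), call. = FALSE)
  }

  gaze_split <- split(gaze_df, gaze_keys)
  datasets <- lapply(split(trials_df, trials_df$subject), function(sub_df) {
    sid <- sub_df$subject[[1]]
    ratings <- ratings_df[ratings_df$subject == sid,
                          c("item_id", "rating", "size_frac")]
    if (!nrow(ratings)) {
      stop("no ratings found for subject ", sid, call. = FALSE)
    }
    rownames(ratings) <- NULL
    sub_df <- sub_df[order(sub_df$trial), , drop = FALSE]
    trials <- lapply(seq_len(nrow(sub_df)), function(i) {
      r <- sub_df[i, ]
      ids <- strsplit(r$items, ";", fixed = TRUE)[[1]]
      if (length(ids) != r$setsize) {
        stop(sprintf("trial %s/%d: %d item ids for set size %d",
                     sid, r$trial, length(ids), r$setsize), call. = FALSE)
      }
      idx <- match(ids, ratings$item_id)
      if (anyNA(idx)) {
        stop(sprintf("trial %s/%d references unrated item(s): %s", sid,
                     r$trial, paste(ids[is.na(idx)], collapse = ", ")),
             call. = FALSE)
      }
      items <- cbind(
        data.frame(item_id = ids,
                   rating = as.integer(ratings$rating[idx]),
                   stringsAsFactors = FALSE),
        item_grid(r$setsize)
      )
      items$size_frac <- ratings$size_frac[idx]
      g <- gaze_split[[paste(sid, r$trial)]]
      if (is.null(g)) {
        gaze <- data.frame(item = integer(), onset_ms = integer(),
                           dur_ms = integer())
      } else {
        g <- g[order(g$onset_ms), , drop = FALSE]
        gaze <- data.frame(
          item = ifelse(g$item >= 0L, as.integer(g$item) + 1L,
                        ifelse(g$item == -1L, GAZE_NONITEM, GAZE_MISSING)),
          onset_ms = as.integer(g$onset_ms),
          dur_ms = as.integer(g$dur_ms)
        )
      }
      choice <- if (is.na(r$choice) || r$choice == "") NA_integer_
                else as.integer(r$choice) + 1L
      trial_record(sid, r$trial, items, gaze,
                   choice_index = choice,
                   rt_ms = if (is.na(r$rt_ms)) NA_integer_ else r$rt_ms,
                   valid = as.logical(r$valid),
                   exclusion_reason = r$exclusion_reason)
    })
    subject_dataset(sid, trials, ratings)
  })
  datasets[order(names(datasets))]
}

#' Write subject datasets to the three-file CSV layout
#'
#' Inverse of [read_choice_data()]: rows are emitted in deterministic
#' (subject, trial, onset) order and item indices are converted to the
#' 0-based on-disk convention.
#'
#' @param datasets List of [subject_dataset()] objects.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_choice_data <- function(datasets, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trial_rows <- list()
  gaze_rows <- list()
  rating_rows <- list()
  ord <- order(vapply(datasets, function(d) d$subject_id, ""))
  for (ds in datasets[ord]) {
    rating_rows[[length(rating_rows) + 1L]] <- data.frame(
      subject = ds$subject_id, item_id = ds$ratings$item_id,
      rating = ds$ratings$rating, size_frac = ds$ratings$size_frac,
      stringsAsFactors = FALSE
    )
    trs <- ds$trials[order(vapply(ds$trials, function(tr) tr$trial_id, 1L))]
    for (tr in trs) {
      trial_rows[[length(trial_rows) + 1L]] <- data.frame(
        subject = tr$subject_id, trial = tr$trial_id, setsize = tr$set_size,
        choice = if (is.na(tr$choice_index)) "" else
          as.character(tr$choice_index - 1L),
        rt_ms = tr$rt_ms, valid = tr$valid,
        exclusion_reason = tr$exclusion_reason,
        items = paste(tr$items$item_id, collapse = ";"),
        stringsAsFactors = FALSE
      )
      if (nrow(tr$gaze)) {
        g <- tr$gaze[order(tr$gaze$onset_ms), , drop = FALSE]
        gaze_rows[[length(gaze_rows) + 1L]] <- data.frame(
          subject = tr$subject_id, trial = tr$trial_id,
          item = ifelse(g$item >= 1L, g$item - 1L,
                        ifelse(g$item == GAZE_NONITEM, -1L, -2L)),
          onset_ms = g$onset_ms, dur_ms = g$dur_ms,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  bind_or_empty <- function(rows, template) {
    if (length(rows)) do.call(rbind, rows) else template
  }
  trials_df <- bind_or_empty(trial_rows, data.frame(
    subject = character(), trial = integer(), setsize = integer(),
    choice = character(), rt_ms = integer(), valid = logical(),
    exclusion_reason = character(), items = character()))
  gaze_df <- bind_or_empty(gaze_rows, data.frame(
    subject = character(), trial = integer(), item = integer(),
    onset_ms = integer(), dur_ms = integer()))
  ratings_df <- bind_or_empty(rating_rows, data.frame(
    subject = character(), item_id = character(), rating = integer(),
    size_frac = double()))
  paths <- c(trials = file.path(out_dir, "trials.csv"),
             gaze = file.path(out_dir, "gaze.csv"),
             ratings = file.path(out_dir, "ratings.csv"))
  write.csv(trials_df, paths[["trials"]], row.names = FALSE, quote = FALSE)
  write.csv(gaze_df, paths[["gaze"]], row.names = FALSE, quote = FALSE)
  write.csv(ratings_df, paths[["ratings"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
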