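# Synthetic experiment generator: liking ratings, stylized gaze
# trajectories over square item grids, and choices/response times
# produced by the package's own model simulators (plus uniform
# contaminant trials). The generator's only contract with real data is
# qualitative: seen-set growth that slows with set size, rating- and
# size-weighted looking with spatial-neighbour preference, shorter
# initial gazes, and growing revisit probability.

#' Configuration for a synthetic experiment
#'
#' @param n_subjects Number of subjects.
#' @param set_sizes Subset of `c(9, 16, 25, 36)`.
#' @param trials_per_cond Trials per set-size condition (default 50, the
#'   experiment's count).
#' @param n_items Size of the item universe (default 80).
#' @param rating_probs Probabilities of ratings -3..3 (length 7).
#' @param gaze List of gaze-process settings; see Details.
#' @param generator List with `model` (`"psm"`, `"iam"`, `"glam"`, or
#'   `"null"` for gaze-independent rating-softmax choices), `variant`
#'   (`"active"`/`"passive"`), and `params` (named vector, or a function
#'   of the subject index returning one; for `"null"`, a vector with
#'   `tau`).
#' @param contaminant_rate Probability that a trial is a uniform
#'   contaminant (default 0.05).
#' @param seed RNG seed for the whole experiment.
#'
#' @details Gaze settings (defaults in parentheses): `frac_seen_base`
#' (1.08) and `frac_seen_slope_per_item` (-0.013) set the target
#' fraction of distinct items seen as `base + slope * set_size`;
#' `gaze_dur_mean_ms` (400) and `gaze_dur_shape` (2) parameterise the
#' gamma gaze-duration distribution; `initial_gaze_shortening_ms` (44)
#' shortens first visits (floored at `min_gaze_ms` = 50);
#' `return_prob_base` (0.1) and `return_prob_growth` (0.02) grow the
#' revisit probability with the number of elapsed gazes; `rating_weight`
#' (0.15), `size_weight` (0.5) and `dist_weight` (0.5, per grid step)
#' weight the next-item choice; `start_bias` (`"center_topleft"` or
#' `"uniform"`) sets where search begins. Absolute duration parameters
#' are package choices -- the experiment reports effects (e.g. initial
#' gazes ~44 ms shorter), not full distributions.
#'
#' @return List of class `mc_synth_config`.
#' @export
synth_config <- function(n_subjects = 1L,
                         set_sizes = c(9L, 16L, 25L, 36L),
                         trials_per_cond = 50L,
                         n_items = 80L,
                         rating_probs = c(0.08, 0.11, 0.14, 0.18, 0.18,
                                          0.17, 0.14),
                         gaze = list(),
                         generator = list(model = "glam",
                                          variant = "active",
                                          params = c(v = 2e-4, sigma = 0.006,
                                                     tau = 2, gamma = 0.6,
                                                     zeta = 1.5)),
                         contaminant_rate = 0.05,
                         seed = 1L) {
  stopifnot(all(set_sizes %in% VALID_SET_SIZES),
            length(rating_probs) == 7L, all(rating_probs >= 0),
            sum(rating_probs) > 0,
            contaminant_rate >= 0, contaminant_rate <= 1)
  gaze_defaults <- list(
    frac_seen_base = 1.08, frac_seen_slope_per_item = -0.013,
    gaze_dur_mean_ms = 400, gaze_dur_shape = 2,
    initial_gaze_shortening_ms = 44, min_gaze_ms = 50,
    return_prob_base = 0.1, return_prob_growth = 0.02,
    return_dur_growth = 0.04, revisit_rating_boost = 0.35,
    rating_weight = 0.15, size_weight = 0.5, dist_weight = 0.5,
    start_bias = "center_topleft"
  )
  gaze <- utils::modifyList(gaze_defaults, gaze)
  if (gaze$gaze_dur_mean_ms <= 0 || gaze$min_gaze_ms <= 0) {
    stop("gaze durations must be positive", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         set_sizes = as.integer(set_sizes),
         trials_per_cond = as.integer(trials_per_cond),
         n_items = as.integer(n_items),
         rating_probs = rating_probs / sum(rating_probs),
         gaze = gaze, generator = generator,
         contaminant_rate = contaminant_rate, seed = as.integer(seed)),
    class = "mc_synth_config"
  )
}

#' Item universe with image-coverage sizes
#'
#' @param n_items Number of items.
#' @return `data.frame` with `item_id` and `size_frac`.
#' @export
gen_item_catalogue <- function(n_items = 80L) {
  data.frame(
    item_id = sprintf("item_%02d", seq_len(n_items)),
    size_frac = round(runif(n_items, 0.35, 0.9), 3),
    stringsAsFactors = FALSE
  )
}

#' Draw per-subject liking ratings
#'
#' @param catalogue Output of [gen_item_catalogue()].
#' @param rating_probs Probabilities over the 7-point scale -3..3.
#' @return `data.frame` with `item_id`, `rating`, `size_frac`.
#' @export
gen_ratings <- function(catalogue, rating_probs) {
  if (sum(rating_probs) <= 0) stop("empty rating distribution", call. = FALSE)
  ratings <- sample(-3:3, nrow(catalogue), replace = TRUE,
                    prob = rating_probs)
  data.frame(item_id = catalogue$item_id, rating = as.integer(ratings),
             size_frac = catalogue$size_frac, stringsAsFactors = FALSE)
}

chebyshev <- function(items, i, j) {
  max(abs(items$row[i] - items$row[j]), abs(items$col[i] - items$col[j]))
}

#' Generate a stylized gaze trajectory over a choice set
#'
#' Sequential item gazes with gamma-distributed durations (first visits
#' shortened), saccade gaps of 20--40 ms between gazes, next-item
#' selection weighted by rating, size, and spatial proximity, and a
#' revisit probability that grows with the number of elapsed gazes. New
#' items stop being introduced once the target seen fraction
#' (`frac_seen_base + slope * set_size`) is reached.
#'
#' @param items Per-trial item table (`rating`, `size_frac`, `row`,
#'   `col`).
#' @param gaze_cfg Gaze settings from [synth_config()].
#' @param horizon_ms Scaffold length in ms.
#' @param target_seen Optional override of the distinct-items target
#'   (e.g. `nrow(items)` to force full coverage).
#' @return `data.frame` with `item`, `onset_ms`, `dur_ms` (item-only,
#'   non-overlapping, already clean).
#' @export
gen_gaze_sequence <- function(items, gaze_cfg, horizon_ms,
                              target_seen = NULL) {
  n <- nrow(items)
  if (is.null(target_seen)) {
    frac <- gaze_cfg$frac_seen_base +
      gaze_cfg$frac_seen_slope_per_item * n
    target_seen <- max(2L, min(n, round(frac * n)))
  }
  attract <- exp(gaze_cfg$rating_weight * items$rating +
                 gaze_cfg$size_weight * items$size_frac)
  k <- sqrt(n)
  centre <- (1 + k) / 2
  current <- if (identical(gaze_cfg$start_bias, "uniform")) {
    sample.int(n, 1L)
  } else {
    d <- pmax(abs(items$row - centre), abs(items$col - centre))
    sample.int(n, 1L, prob = exp(-1.5 * d))
  }
  seen <- logical(n)
  t <- round(runif(1, 150, 250))
  rows <- list()
  n_gazes <- 0L
  while (t < horizon_ms) {
    base <- rgamma(1, shape = gaze_cfg$gaze_dur_shape,
                   scale = gaze_cfg$gaze_dur_mean_ms / gaze_cfg$gaze_dur_shape)
    if (!seen[current]) {
      base <- base - gaze_cfg$initial_gaze_shortening_ms
    } else {
      # returning gazes lengthen as the trial progresses
      base <- base * (1 + min(1, gaze_cfg$return_dur_growth * n_gazes))
    }
    dur <- max(gaze_cfg$min_gaze_ms, round(base))
    rows[[length(rows) + 1L]] <- c(current, t, dur)
    seen[current] <- TRUE
    n_gazes <- n_gazes + 1L
    t <- t + dur + round(runif(1, 20, 40))
    # choose the next item
    unseen <- which(!seen)
    revisits <- setdiff(which(seen), current)
    p_ret <- min(0.85, gaze_cfg$return_prob_base +
                   gaze_cfg$return_prob_growth * n_gazes)
    pool <- if (sum(seen) >= target_seen || !length(unseen)) {
      if (length(revisits)) revisits else setdiff(seq_len(n), current)
    } else if (length(revisits) && runif(1) < p_ret) {
      revisits
    } else {
      unseen
    }
    w <- attract[pool] *
      exp(-gaze_cfg$dist_weight *
            vapply(pool, function(j) chebyshev(items, current, j), 0))
    if (all(seen[pool])) {
      # late search focuses on the highly rated contenders
      w <- w * exp(gaze_cfg$revisit_rating_boost * items$rating[pool])
    }
    current <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = w)
  }
  df <- do.call(rbind, rows)
  data.frame(item = as.integer(df[, 1]), onset_ms = as.integer(df[, 2]),
             dur_ms = as.integer(df[, 3]))
}

# truncate a gaze stream at the response time
truncate_gaze <- function(gaze, rt) {
  keep <- gaze$onset_ms < rt
  g <- gaze[keep, , drop = FALSE]
  if (nrow(g)) {
    g$dur_ms <- pmin(g$dur_ms, rt - g$onset_ms)
    g <- g[g$dur_ms > 0L, , drop = FALSE]
  }
  rownames(g) <- NULL
  g
}

# rescale a gaze stream so its total extent matches the simulated rt
# (used for the relative accumulator, whose gaze fractions are defined
# over the whole trial)
rescale_gaze <- function(gaze, rt) {
  stream_end <- max(gaze$onset_ms + gaze$dur_ms)
  f <- rt / stream_end
  onset <- as.integer(round(gaze$onset_ms * f))
  end <- as.integer(round((gaze$onset_ms + gaze$dur_ms) * f))
  g <- data.frame(item = gaze$item, onset_ms = onset, dur_ms = end - onset)
  g <- g[g$dur_ms > 0L, , drop = FALSE]
  rownames(g) <- NULL
  g
}

# scaffold length heuristics so the gaze process covers the bulk of the
# simulated stopping times
scaffold_horizon <- function(model, params) {
  h <- switch(model,
    psm = {
      a <- params[["alpha"]] * 6      # typical cached-value hazard
      v <- params[["v"]]
      t3 <- if (v > 0) (-a + sqrt(a^2 + 6 * v)) / v else 3 / max(a, 1e-9)
      t3
    },
    iam = 2000 + 1 / (params[["v"]] * 2),
    glam = 1 / (params[["v"]] * 0.5),
    null = 12000
  )
  min(60000, max(4000, round(h)))
}

# typical duration of a relative-accumulator race: median of pilot race
# minima with flat relative signals (drift 1/2 for every racer)
glam_pilot_horizon <- function(params, n_seen, n_pilot = 30L) {
  mu <- 1 / (params[["v"]] * 0.5)
  lambda <- 1 / params[["sigma"]]^2
  draws <- matrix(rinvgauss(n_pilot * n_seen, mu, lambda), nrow = n_pilot)
  h <- median(apply(draws, 1, min))
  min(60000, max(1500, round(h)))
}

# typical duration of an independent-accumulator race, using a
# representative drift (mid-scale value, moderate remaining-time gaze)
iam_pilot_horizon <- function(params, n_seen, n_pilot = 30L) {
  D <- 0.4 * (4 + params[["zeta"]]) + 0.6 * params[["gamma"]] * 4
  mu <- 1 / (params[["v"]] * D)
  lambda <- 1 / params[["sigma"]]^2
  draws <- matrix(rinvgauss(n_pilot * n_seen, mu, lambda), nrow = n_pilot)
  h <- median(apply(draws, 1, min)) + 1200
  min(60000, max(2000, round(h)))
}

# gaze statistics over a raw scaffold (whole extent, not rt-relative)
scaffold_stats <- function(gaze, n) {
  stream_end <- max(gaze$onset_ms + gaze$dur_ms)
  total <- integer(n); t0 <- rep(-1, n)
  for (i in seq_len(nrow(gaze))) {
    it <- gaze$item[i]
    total[it] <- total[it] + gaze$dur_ms[i]
    if (t0[it] < 0) t0[it] <- gaze$onset_ms[i]
  }
  seen <- total > 0L
  g_rem <- rep(0, n)
  for (i in which(seen)) {
    denom <- stream_end - t0[i]
    g_rem[i] <- if (denom <= 0) 1 else min(1, total[i] / denom)
  }
  list(seen = seen, g = total / stream_end, g_rem = g_rem, t0 = t0,
       stream_end = stream_end)
}

#' Generate one synthetic subject
#'
#' For every trial a gaze scaffold is generated, then the configured
#' model produces choice and response time on it (or, with probability
#' `contaminant_rate`, a uniform contaminant does); the emitted gaze
#' stream is truncated at the response time (for the relative
#' accumulator, rescaled to it, since that model's gaze fractions are
#' defined over the whole trial). The experiment's exclusion rules are
#' applied to every emitted trial.
#'
#' @param config [synth_config()] object.
#' @param subject_id Subject label.
#' @param catalogue Item universe from [gen_item_catalogue()].
#' @param params Resolved generating parameter vector for this subject.
#' @return List with `dataset` (an [subject_dataset()]) and
#'   `ground_truth` (`data.frame` of per-trial generating model and
#'   contaminant flags).
#' @export
gen_subject <- function(config, subject_id, catalogue = NULL,
                        params = NULL) {
  if (is.null(catalogue)) catalogue <- gen_item_catalogue(config$n_items)
  model <- config$generator$model
  variant <- config$generator$variant %||% "active"
  if (is.null(params)) {
    params <- config$generator$params
    if (is.function(params)) params <- params(subject_id)
  }
  if (!identical(model, "null")) params <- resolve_variant(params, variant)
  ratings <- gen_ratings(catalogue, config$rating_probs)
  trials <- list()
  truth <- list()
  trial_id <- 0L
  for (n in config$set_sizes) {
    horizon <- scaffold_horizon(model, params)
    for (j in seq_len(config$trials_per_cond)) {
      trial_id <- trial_id + 1L
      idx <- sample.int(nrow(ratings), n)
      items <- cbind(ratings[idx, c("item_id", "rating")], item_grid(n))
      items$size_frac <- ratings$size_frac[idx]
      rownames(items) <- NULL
      contam <- runif(1) < config$contaminant_rate
      res <- if (contam) {
        scaffold <- gen_gaze_sequence(items, config$gaze, horizon)
        rt <- as.integer(round(runif(1, 600, horizon)))
        list(choice = sample.int(n, 1L), rt = rt,
             gaze = truncate_gaze(scaffold, rt))
      } else {
        sim_trial_from_scaffold(model, items, params, config$gaze, horizon)
      }
      tr <- trial_record(subject_id, trial_id, items, res$gaze,
                         choice_index = res$choice, rt_ms = res$rt)
      trials[[trial_id]] <- apply_exclusions(tr)
      truth[[trial_id]] <- data.frame(
        subject = subject_id, trial = trial_id, set_size = n,
        model = model, contaminant = contam, stringsAsFactors = FALSE)
    }
  }
  list(dataset = subject_dataset(subject_id, trials, ratings),
       ground_truth = do.call(rbind, truth))
}

sim_trial_from_scaffold <- function(model, items, params, gaze_cfg,
                                    horizon) {
  n <- nrow(items)
  if (model %in% c("glam", "iam")) {
    # scale the scaffold to the race's typical duration so that the gaze
    # statistics seen at fitting time stay close to the generating ones
    frac <- gaze_cfg$frac_seen_base + gaze_cfg$frac_seen_slope_per_item * n
    n_seen <- max(2L, min(n, round(frac * n)))
    horizon <- if (model == "glam") glam_pilot_horizon(params, n_seen)
               else iam_pilot_horizon(params, n_seen)
  }
  scaffold <- gen_gaze_sequence(items, gaze_cfg, horizon)
  l <- as.numeric(rescale_rating(items$rating))
  st <- scaffold_stats(scaffold, n)
  if (model == "psm") {
    ms_item <- integer(st$stream_end)
    for (i in seq_len(nrow(scaffold))) {
      a <- scaffold$onset_ms[i] + 1L
      b <- min(scaffold$onset_ms[i] + scaffold$dur_ms[i], st$stream_end)
      if (b >= a) ms_item[a:b] <- scaffold$item[i]
    }
    input <- list(l = l, ms_item = ms_item, g = st$g, g_rem = st$g_rem,
                  t0 = st$t0, seen = st$seen, rt = st$stream_end,
                  choice = 1L, N = n)
    sim <- psm_simulate(input, params, 1L)
    rt <- sim$rt_ms[1L]
    list(choice = sim$choice[1L], rt = rt,
         gaze = truncate_gaze(scaffold, rt))
  } else if (model == "iam") {
    input <- list(l = l, g = st$g, g_rem = st$g_rem, t0 = st$t0,
                  seen = st$seen, rt = st$stream_end, choice = 1L, N = n)
    sim <- iam_simulate(input, params, 1L)
    rt <- max(sim$rt_ms[1L], 1L)
    list(choice = sim$choice[1L], rt = rt,
         gaze = truncate_gaze(scaffold, rt))
  } else if (model == "glam") {
    input <- list(l = l, g = st$g, g_rem = st$g_rem, t0 = st$t0,
                  seen = st$seen, rt = st$stream_end, choice = 1L, N = n)
    sim <- glam_simulate(input, params, 1L)
    rt <- max(sim$rt_ms[1L], 300L)
    list(choice = sim$choice[1L], rt = rt,
         gaze = rescale_gaze(scaffold, rt))
  } else {
    stop("unknown generating model: ", model, call. = FALSE)
  }
}

#' Generate a gaze-independent control subject
#'
#' Negative control for the gaze-influence measure: every item of every
#' trial is gazed at least once (full coverage removes the seen-set
#' confound), the response time is the scaffold's natural end, and the
#' choice is drawn from a softmax over ALL items' rescaled ratings --
#' independent of the gaze pattern.
#'
#' @param config [synth_config()] with `generator$model = "null"`;
#'   `generator$params` may supply the softmax scale `tau`
#'   (default 0.8).
#' @param subject_id Subject label.
#' @param catalogue Item universe.
#' @return List with `dataset` and `ground_truth` as [gen_subject()].
#' @export
gen_null_gaze_subject <- function(config, subject_id, catalogue = NULL) {
  if (is.null(catalogue)) catalogue <- gen_item_catalogue(config$n_items)
  # the control's gaze process is value-independent: any residual
  # association between gaze and choice would be an artifact of the
  # measure, not of the generator
  config$gaze$rating_weight <- 0
  config$gaze$size_weight <- 0
  config$gaze$revisit_rating_boost <- 0
  tau <- (config$generator$params %||% c(tau = 0.8))[["tau"]]
  ratings <- gen_ratings(catalogue, config$rating_probs)
  trials <- list()
  truth <- list()
  trial_id <- 0L
  for (n in config$set_sizes) {
    horizon <- round(n * 550 + 2500)
    for (j in seq_len(config$trials_per_cond)) {
      trial_id <- trial_id + 1L
      idx <- sample.int(nrow(ratings), n)
      items <- cbind(ratings[idx, c("item_id", "rating")], item_grid(n))
      items$size_frac <- ratings$size_frac[idx]
      rownames(items) <- NULL
      scaffold <- gen_gaze_sequence(items, config$gaze, horizon,
                                    target_seen = n)
      # extend until every item has been gazed
      while (length(unique(scaffold$item)) < n) {
        scaffold <- gen_gaze_sequence(items, config$gaze,
                                      horizon + 4000, target_seen = n)
        horizon <- horizon + 4000
      }
      rt <- max(scaffold$onset_ms + scaffold$dur_ms) + round(runif(1, 50, 250))
      l <- as.numeric(rescale_rating(items$rating))
      p <- exp(tau * (l - max(l)))
      choice <- sample.int(n, 1L, prob = p / sum(p))
      tr <- trial_record(subject_id, trial_id, items, scaffold,
                         choice_index = choice, rt_ms = rt)
      trials[[trial_id]] <- apply_exclusions(tr)
      truth[[trial_id]] <- data.frame(
        subject = subject_id, trial = trial_id, set_size = n,
        model = "null", contaminant = FALSE, stringsAsFactors = FALSE)
    }
  }
  list(dataset = subject_dataset(subject_id, trials, ratings),
       ground_truth = do.call(rbind, truth))
}

#' Generate a complete synthetic experiment
#'
#' @param config [synth_config()] object; `config$seed` drives all
#'   randomness.
#' @return List with `datasets` (list of [subject_dataset()]),
#'   `ground_truth` (per-trial generating model and contaminant flags),
#'   and `params` (per-subject generating parameters).
#' @export
gen_experiment <- function(config) {
  set.seed(config$seed)
  catalogue <- gen_item_catalogue(config$n_items)
  datasets <- list()
  truth <- list()
  par_rows <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("synth_%02d", s)
    model <- config$generator$model
    if (identical(model, "null")) {
      res <- gen_null_gaze_subject(config, sid, catalogue)
      pars <- NULL
    } else {
      pars <- config$generator$params
      if (is.function(pars)) pars <- pars(s)
      pars <- resolve_variant(pars, config$generator$variant %||% "active")
      res <- gen_subject(config, sid, catalogue, pars)
    }
    datasets[[sid]] <- res$dataset
    truth[[sid]] <- res$ground_truth
    if (!is.null(pars)) {
      par_rows[[sid]] <- data.frame(subject = sid,
                                    t(as.data.frame(pars)),
                                    row.names = NULL)
    }
  }
  list(datasets = datasets,
       ground_truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       params = if (length(par_rows)) do.call(rbind, par_rows) else NULL)
}
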