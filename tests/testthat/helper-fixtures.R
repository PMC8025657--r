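# Shared fixtures and independent reference implementations used as
# oracles. Everything here is deliberately slow and literal.

# a small item table on a 3x3 grid
toy_items <- function(ratings = c(2, -1, 0, 3, 1, -2, 0, 2, -3),
                      sizes = seq(0.4, 0.8, length.out = 9)) {
  n <- length(ratings)
  k <- sqrt(n)
  data.frame(
    item_id = sprintf("it%02d", seq_len(n)),
    rating = as.integer(ratings),
    row = rep(seq_len(k), each = k),
    col = rep(seq_len(k), times = k),
    size_frac = sizes
  )
}

# gaze data frame from compact (item, onset, dur) triplets
gaze_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(item = as.integer(m[, 1]), onset_ms = as.integer(m[, 2]),
             dur_ms = as.integer(m[, 3]))
}

toy_trial <- function(gaze = gaze_df(1, 100, 400,
                                     4, 550, 300,
                                     2, 900, 500),
                      choice = 4L, rt = 1500L, ratings = NULL,
                      trial_id = 1L, subject = "s1") {
  items <- if (is.null(ratings)) toy_items() else toy_items(ratings)
  trial_record(subject, trial_id, items, gaze, choice_index = choice,
               rt_ms = rt)
}

# random valid trial built through the package generator
random_trial <- function(seed, set_size = 9L) {
  set.seed(seed)
  items <- toy_items(sample(-3:3, set_size, replace = TRUE))
  g <- list()
  t <- sample(100:300, 1)
  for (i in seq_len(sample(3:10, 1))) {
    it <- sample(set_size, 1)
    dur <- sample(80:600, 1)
    g[[i]] <- c(it, t, dur)
    t <- t + dur + sample(10:50, 1)
  }
  gz <- do.call(gaze_df, as.list(unlist(g)))
  rt <- t + sample(0:200, 1)
  choice <- sample(unique(gz$item), 1)
  trial_record("s1", 1L, items, gz, choice_index = choice, rt_ms = rt)
}

# --- oracles ---------------------------------------------------------------

# per-millisecond counting implementation of the gaze fraction time course
ms_counting_timecourse <- function(trial, dt = 1L) {
  rt <- trial$rt_ms
  tgrid <- seq(dt, rt, by = dt)
  if (tail(tgrid, 1) < rt) tgrid <- c(tgrid, rt)
  active <- integer(rt) # item gazed during each ms, 0 = none
  for (i in seq_len(nrow(trial$gaze))) {
    it <- trial$gaze$item[i]
    if (it < 1) next
    a <- trial$gaze$onset_ms[i] + 1L
    b <- min(trial$gaze$onset_ms[i] + trial$gaze$dur_ms[i], rt)
    if (b >= a) active[a:b] <- it
  }
  out <- matrix(0, trial$set_size, length(tgrid))
  for (k in seq_along(tgrid)) {
    tt <- tgrid[k]
    cnt <- tabulate(active[seq_len(tt)], nbins = trial$set_size)
    out[, k] <- cnt / tt
  }
  out
}

# independent, literal implementation of the satisficing trial likelihood
# (plain R, per-millisecond loops, written from the model equations)
slow_psm_loglik <- function(input, pars, u) {
  rt <- input$rt
  N <- input$N
  Tn <- length(input$ms_item)
  G <- numeric(N)
  logQ <- 0
  p <- NA_real_
  for (t in seq_len(rt)) {
    if (t <= Tn) {
      it <- input$ms_item[t]
      if (it >= 1) G[it] <- G[it] + 1
      seen <- G > 0
      g <- G / t
    } else {
      seen <- G > 0
      g <- G / Tn
    }
    cvals <- g * (input$l + pars[["zeta"]]) +
      (1 - g) * pars[["gamma"]] * input$l
    cvals[!seen] <- 0
    q <- if (!any(seen)) 0 else
      min(pars[["alpha"]] * max(cvals[seen]) + pars[["v"]] * t, 1)
    if (t == rt) {
      f <- q * exp(logQ)
      sm <- numeric(N)
      z <- pars[["tau"]] * cvals[seen]
      sm[seen] <- exp(z - max(z)) / sum(exp(z - max(z)))
      p <- f * sm[input$choice]
    } else {
      if (q >= 1) { p <- 0; break }
      logQ <- logQ + log1p(-q)
    }
  }
  log(0.95 * p + 0.05 * u)
}

# two-pass WAIC oracle (textbook formulas, no shortcuts)
waic_oracle <- function(ll) {
  S <- nrow(ll)
  lppd <- 0; p_waic <- 0
  for (tr in seq_len(ncol(ll))) {
    x <- ll[, tr]
    lppd <- lppd + log(sum(exp(x)) / S)
    p_waic <- p_waic + sum((x - mean(x))^2) / (S - 1)
  }
  c(waic = lppd - p_waic, lppd = lppd, p_waic = p_waic)
}

# Euler-Maruyama race: literal discrete accumulator simulation
euler_race <- function(D, v, sigma, t0 = rep(0, length(D)), n_reps = 500,
                       dt = 5, horizon = 30000) {
  n <- length(D)
  steps <- ceiling(horizon / dt)
  choice <- integer(n_reps); rt <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    E <- numeric(n)
    done <- FALSE
    for (s in seq_len(steps)) {
      t <- s * dt
      on <- t > t0 & D > 0
      E[on] <- E[on] + v * D[on] * dt +
        rnorm(sum(on), 0, sigma * sqrt(dt))
      if (any(E >= 1)) {
        choice[r] <- which.max(E)
        rt[r] <- t
        done <- TRUE
        break
      }
    }
    if (!done) { choice[r] <- NA; rt[r] <- NA }
  }
  data.frame(choice = choice, rt_ms = rt)
}

# standard model input used across likelihood tests
fixture_input <- function(seed = 5, set_size = 9L, trials_per_cond = 2L) {
  cfg <- synth_config(n_subjects = 1, set_sizes = set_size,
                      trials_per_cond = trials_per_cond, seed = seed)
  ds <- gen_experiment(cfg)$datasets[[1]]
  tr <- Filter(function(t) t$valid, ds$trials)[[1]]
  trial_model_input(tr)
}
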