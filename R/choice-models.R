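# The three gaze-dependent likelihood models (probabilistic satisficing,
# independent accumulation, relative accumulation), their contaminant
# mixture, and trial-level forward simulators. The decision boundary b is
# fixed at 1 throughout; the model time grid is dt = 1 ms.

MODEL_NAMES <- c("psm", "iam", "glam")
CONTAM_RATE <- 0.05

#' Prepare a trial for likelihood evaluation and simulation
#'
#' Precomputes everything the model code needs from a valid, cleaned
#' trial: rescaled item values (1..7), the per-millisecond gazed-item
#' vector, cumulative gaze fractions, first-gaze onsets, and the
#' remaining-time gaze fractions used by the independent accumulator
#' (clamped to `[0, 1]`; an item first seen exactly at the response gets
#' 1, i.e. all remaining time looked at).
#'
#' @param trial A valid [trial_record()] with cleaned gaze.
#' @param horizon_ms Optional stream extent for simulation scaffolds;
#'   defaults to the later of the response time and the gaze stream end.
#' @return List with fields `l`, `ms_item`, `g`, `g_rem`, `t0`, `seen`,
#'   `rt`, `choice`, `N`.
#' @export
trial_model_input <- function(trial, horizon_ms = NULL) {
  st <- gaze_stats(trial)
  g <- trial$gaze
  stream_end <- max(g$onset_ms + g$dur_ms)
  extent <- max(trial$rt_ms, stream_end, horizon_ms %||% 0L)
  ms_item <- integer(min(extent, stream_end))
  for (i in seq_len(nrow(g))) {
    if (g$item[i] < 1L) next
    a <- g$onset_ms[i] + 1L
    b <- min(g$onset_ms[i] + g$dur_ms[i], length(ms_item))
    if (b >= a) ms_item[a:b] <- g$item[i]
  }
  t0 <- ifelse(is.na(st$t0_ms), -1, as.numeric(st$t0_ms))
  g_rem <- rep(0, trial$set_size)
  for (i in which(st$seen)) {
    denom <- trial$rt_ms - st$t0_ms[i]
    g_rem[i] <- if (denom <= 0) 1 else
      min(1, max(0, st$total_gaze_ms[i] / denom))
  }
  list(
    l = as.numeric(rescale_rating(trial$items$rating)),
    ms_item = ms_item,
    g = st$cum_gaze_frac,
    g_rem = g_rem,
    t0 = t0,
    seen = st$seen,
    rt = as.numeric(trial$rt_ms),
    choice = trial$choice_index,
    N = trial$set_size
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaze-weighted cached item values
#'
#' `c_i(t) = g_i(t) (l_i + zeta) + (1 - g_i(t)) gamma l_i` for seen items
#' and 0 for items not yet looked at. With `gamma = 1, zeta = 0` this is
#' the passive-gaze identity `c_i = l_i`.
#'
#' @param g_t Per-item gaze fractions of elapsed time, in `[0, 1]`.
#' @param values Rescaled item values (1..7).
#' @param gamma Multiplicative gaze bias in `[0, 1]`.
#' @param zeta Additive gaze bias in `[0, 10]`.
#' @param seen Logical vector; unseen items get cached value 0.
#' @return Numeric vector of cached values.
#' @export
psm_cached_value <- function(g_t, values, gamma, zeta, seen = rep(TRUE, length(values))) {
  stopifnot(all(g_t >= 0 & g_t <= 1))
  c_t <- g_t * (values + zeta) + (1 - g_t) * gamma * values
  c_t[!seen] <- 0
  c_t
}

#' Softmax choice probabilities over the seen set
#'
#' @param c_t Cached values.
#' @param tau Softmax scale (>= 0); 0 gives a uniform choice over seen
#'   items. Overflow is guarded by max-subtraction, which is exact in
#'   real arithmetic.
#' @param seen Logical vector; unseen items get probability 0.
#' @return Probability vector summing to 1 over seen items.
#' @export
psm_choice_prob <- function(c_t, tau, seen = rep(TRUE, length(c_t))) {
  if (!any(seen)) stop("softmax over an empty seen set", call. = FALSE)
  p <- numeric(length(c_t))
  z <- tau * c_t[seen]
  z <- z - max(z)
  p[seen] <- exp(z) / sum(exp(z))
  p
}

#' PSM stopping hazard, survival, and stopping density
#'
#' Evaluates the satisficing stopping rule on the grid t = dt, 2 dt, ...
#' The hazard is `q(t) = min(alpha C(t) + v t, 1)` with cached value
#' `C(t) = max` over seen items of [psm_cached_value()], and 0 before the
#' first item gaze (no choice is possible from an empty seen set). The
#' survival is `Q(t) = prod(1 - q(s))` over grid points up to `t` and the
#' stopping density `f(t) = q(t) Q(t - dt)`. Only `dt_ms = 1` reproduces
#' the model exactly; coarser grids are a documented approximation.
#'
#' @param input A [trial_model_input()] list.
#' @param params Named vector with `v`, `alpha`, `tau`, `gamma`, `zeta`.
#' @param dt_ms Grid step (default 1 ms).
#' @param horizon_ms Grid end; defaults to the trial response time.
#' @return List with vectors `t_ms`, `q`, `Q`, `f`.
#' @export
psm_stop_density <- function(input, params, dt_ms = 1L, horizon_ms = NULL) {
  horizon_ms <- horizon_ms %||% input$rt
  if (dt_ms == 1L) {
    d <- cpp_psm_density(input, params[["v"]], params[["alpha"]],
                         params[["tau"]], params[["gamma"]],
                         params[["zeta"]], as.integer(horizon_ms))
    return(list(t_ms = seq_len(horizon_ms), q = d$q, Q = d$Q, f = d$f,
                p_choice = d$p_choice))
  }
  # coarse-grid reference path: the 1 ms hazard is evaluated at the grid
  # points and compounded over each dt-step, so the per-step stopping
  # probability is 1 - (1 - q)^dt
  tgrid <- seq(dt_ms, horizon_ms, by = dt_ms)
  Tn <- length(input$ms_item)
  N <- input$N
  q <- numeric(length(tgrid))
  for (k in seq_along(tgrid)) {
    t <- min(tgrid[k], Tn)
    active <- input$ms_item[seq_len(t)]
    G <- tabulate(active[active >= 1L], nbins = N)
    seen <- G > 0L
    if (!any(seen)) next
    ct <- psm_cached_value(G / t, input$l, params[["gamma"]],
                           params[["zeta"]], seen)
    q[k] <- min(params[["alpha"]] * max(ct[seen]) + params[["v"]] * tgrid[k], 1)
  }
  q_step <- 1 - (1 - q)^dt_ms
  Q <- cumprod(1 - q_step)
  f <- q_step * c(1, head(Q, -1))
  hit <- which(q_step >= 1)
  if (length(hit) && hit[1] < length(f)) f[(hit[1] + 1L):length(f)] <- 0
  list(t_ms = tgrid, q = q_step, Q = Q, f = f)
}

#' Per-trial PSM log likelihood
#'
#' Log of the 95/5 contaminant mixture applied to
#' `p(choice, rt) = f(rt) * sigma_choice(rt)`.
#'
#' @param input A [trial_model_input()] list (or list of them).
#' @param params Named vector `v`, `alpha`, `tau`, `gamma`, `zeta`.
#' @param u Contaminant density (per item-millisecond) for the trial's
#'   subject and set-size condition; see [contaminant_density()].
#' @return Numeric log-likelihood (vector if a list of inputs is given).
#' @export
psm_trial_loglik <- function(input, params, u) {
  inputs <- if (!is.null(input$l)) list(input) else input
  cpp_psm_loglik(inputs, params[["v"]], params[["alpha"]], params[["tau"]],
                 params[["gamma"]], params[["zeta"]],
                 rep_len(u, length(inputs)))
}

#' Simulate choices and response times from the PSM
#'
#' At each millisecond the search stops with probability `q(t)`; on
#' stopping the choice is drawn from the softmax over the seen items'
#' cached values. Beyond the end of the observed gaze stream the gaze
#' fractions are frozen at their final values.
#'
#' @inheritParams psm_trial_loglik
#' @param n_reps Number of simulated trials.
#' @param horizon_ms Simulation horizon; by default grown until the
#'   stopping distribution's survival falls below 1e-12.
#' @return `data.frame` with columns `choice`, `rt_ms`.
#' @export
psm_simulate <- function(input, params, n_reps = 1L, horizon_ms = NULL) {
  if (is.null(horizon_ms)) horizon_ms <- psm_horizon(input, params)
  m <- cpp_psm_simulate(input, params[["v"]], params[["alpha"]],
                        params[["tau"]], params[["gamma"]], params[["zeta"]],
                        as.integer(n_reps), as.integer(horizon_ms))
  data.frame(choice = m[, 1], rt_ms = m[, 2])
}

# horizon at which the PSM stopping distribution is numerically exhausted
psm_horizon <- function(input, params, tol = 1e-12) {
  horizon <- max(length(input$ms_item), 2000L)
  repeat {
    d <- cpp_psm_density(input, params[["v"]], params[["alpha"]],
                         params[["tau"]], params[["gamma"]],
                         params[["zeta"]], as.integer(horizon))
    if (tail(d$Q, 1L) < tol) return(horizon)
    if (horizon > 5e6) {
      stop("PSM stopping distribution does not terminate (v = alpha = 0?)",
           call. = FALSE)
    }
    horizon <- horizon * 2L
  }
}

# ---------------------------------------------------------------------------
# Inverse Gaussian first-passage-time distribution
# ---------------------------------------------------------------------------

#' Inverse Gaussian first-passage-time distribution
#'
#' Density, distribution function, and random generation for the first
#' passage time of a drifting diffusion to a single absorbing boundary,
#' parameterised by mean `mu = b / (v D)` and shape `lambda = b^2 /
#' sigma^2`. Nonpositive times have density 0 and distribution 0. The
#' sampler uses the Michael--Schucany--Haas transform and draws from R's
#' RNG stream.
#'
#' @param t Vector of times (ms).
#' @param mu Mean parameter (> 0).
#' @param lambda Shape parameter (> 0).
#' @param log,log.p Return log density / log probability.
#' @param lower.tail If `FALSE`, return the survival function.
#' @param n Number of draws.
#' @return Numeric vector.
#' @name invgauss
NULL

#' @rdname invgauss
#' @export
dinvgauss <- function(t, mu, lambda, log = FALSE) {
  stopifnot(mu > 0, lambda > 0)
  lp <- cpp_ig_logpdf(as.numeric(t), mu, lambda)
  if (log) lp else exp(lp)
}

#' @rdname invgauss
#' @export
pinvgauss <- function(t, mu, lambda, lower.tail = TRUE, log.p = FALSE) {
  stopifnot(mu > 0, lambda > 0)
  lp <- if (lower.tail) cpp_ig_logcdf(as.numeric(t), mu, lambda)
        else vapply(as.numeric(t), function(ti) {
          if (ti <= 0) 0 else {
            s <- cpp_ig_logcdf(ti, mu, lambda)
            log1p(-exp(s))
          }
        }, 0)
  if (log.p) lp else exp(lp)
}

#' @rdname invgauss
#' @export
rinvgauss <- function(n, mu, lambda) {
  stopifnot(mu > 0, lambda > 0)
  cpp_ig_sample(as.integer(n), mu, lambda)
}

# ---------------------------------------------------------------------------
# Race models: IAM and GLAM
# ---------------------------------------------------------------------------

#' Independent-accumulator drift signals
#'
#' `D_i = g_i (l_i + zeta) + (1 - g_i) gamma l_i` where `g_i` is the
#' fraction of the remaining trial time (after the item's first gaze)
#' spent looking at item i. Unseen items receive no accumulator (drift
#' 0, which the likelihood treats as survival 1: the accumulator never
#' finishes).
#'
#' @param g_rem Remaining-time gaze fractions in `[0, 1]`.
#' @param values Rescaled item values.
#' @param gamma,zeta Gaze bias parameters.
#' @param seen Logical vector.
#' @return Numeric drift vector.
#' @export
iam_drift <- function(g_rem, values, gamma, zeta, seen = rep(TRUE, length(values))) {
  D <- g_rem * (values + zeta) + (1 - g_rem) * gamma * values
  D[!seen] <- 0
  D
}

#' Relative-accumulator (GLAM) decision signals
#'
#' Computes the average absolute signal `A_i = g_i (l_i + zeta) +
#' (1 - g_i) gamma l_i` (whole-trial gaze fractions), the relative
#' signal `R_i = A_i - max_{j != i} A_j` over seen items, and the drift
#' `D_i = 1 / (1 + exp(-tau R_i))`. With a single seen item the relative
#' signal is defined as 0 (drift 1/2).
#'
#' @param g Whole-trial cumulative gaze fractions.
#' @param values Rescaled item values.
#' @param gamma,zeta,tau Model parameters.
#' @param seen Logical vector.
#' @return List with vectors `A`, `R`, `D` (zero entries for unseen items).
#' @export
glam_signals <- function(g, values, gamma, zeta, tau, seen = rep(TRUE, length(values))) {
  n <- length(values)
  A <- numeric(n); R <- numeric(n); D <- numeric(n)
  idx <- which(seen)
  A[idx] <- g[idx] * (values[idx] + zeta) + (1 - g[idx]) * gamma * values[idx]
  for (i in idx) {
    others <- setdiff(idx, i)
    R[i] <- if (length(others)) A[i] - max(A[others]) else 0
    D[i] <- 1 / (1 + exp(-tau * R[i]))
  }
  list(A = A, R = R, D = D)
}

#' Per-trial race-model log likelihoods
#'
#' Log of the 95/5 contaminant mixture applied to the race density
#' `p_i(rt) = f_i(rt - t0_i) prod_{j != i} (1 - F_j(rt - t0_j))` over
#' seen items, with inverse-Gaussian first-passage times
#' (`mu_i = 1 / (v D_i)`, `lambda = 1 / sigma^2`). The IAM starts each
#' accumulator at the item's first-gaze onset `t0_i`; the GLAM starts
#' all accumulators at stimulus onset.
#'
#' @param input A [trial_model_input()] list (or list of them).
#' @param params Named vector: `v`, `sigma`, `gamma`, `zeta` (IAM), plus
#'   `tau` for the GLAM.
#' @param u Contaminant density for the trial's condition.
#' @return Numeric log-likelihood (vector for a list of inputs).
#' @export
iam_trial_loglik <- function(input, params, u) {
  inputs <- if (!is.null(input$l)) list(input) else input
  cpp_race_loglik(inputs, params[["v"]], params[["sigma"]],
                  params[["gamma"]], params[["zeta"]], 0, 0L,
                  rep_len(u, length(inputs)))
}

#' @rdname iam_trial_loglik
#' @export
glam_trial_loglik <- function(input, params, u) {
  inputs <- if (!is.null(input$l)) list(input) else input
  cpp_race_loglik(inputs, params[["v"]], params[["sigma"]],
                  params[["gamma"]], params[["zeta"]], params[["tau"]], 1L,
                  rep_len(u, length(inputs)))
}

#' Simulate a race-model trial
#'
#' Draws an inverse-Gaussian first passage time for every seen item with
#' positive drift; for the IAM the empirically observed first-gaze onset
#' `t0_i` is added. The earliest finisher determines choice and response
#' time (ties, which have probability zero in continuous time, go to the
#' lowest item index).
#'
#' @inheritParams iam_trial_loglik
#' @param n_reps Number of simulated trials.
#' @return `data.frame` with columns `choice`, `rt_ms`.
#' @export
iam_simulate <- function(input, params, n_reps = 1L) {
  race_simulate(input, params, n_reps, model = "iam")
}

#' @rdname iam_simulate
#' @export
glam_simulate <- function(input, params, n_reps = 1L) {
  race_simulate(input, params, n_reps, model = "glam")
}

race_simulate <- function(input, params, n_reps, model) {
  if (model == "iam") {
    D <- iam_drift(input$g_rem, input$l, params[["gamma"]], params[["zeta"]],
                   input$seen)
    offsets <- ifelse(input$t0 < 0, 0, input$t0)
  } else {
    D <- glam_signals(input$g, input$l, params[["gamma"]], params[["zeta"]],
                      params[["tau"]], input$seen)$D
    offsets <- rep(0, input$N)
  }
  racers <- which(input$seen & D > 0)
  if (!length(racers)) {
    stop("no accumulator can finish (all drifts zero)", call. = FALSE)
  }
  lambda <- 1 / params[["sigma"]]^2
  choice <- integer(n_reps); rt <- numeric(n_reps)
  fpt <- matrix(NA_real_, nrow = n_reps, ncol = length(racers))
  for (k in seq_along(racers)) {
    i <- racers[k]
    fpt[, k] <- rinvgauss(n_reps, 1 / (params[["v"]] * D[i]), lambda) +
      offsets[i]
  }
  win <- max.col(-fpt, ties.method = "first")
  data.frame(choice = racers[win],
             rt_ms = as.integer(round(fpt[cbind(seq_len(n_reps), win)])))
}

# ---------------------------------------------------------------------------
# Contaminant mixture
# ---------------------------------------------------------------------------

#' Uniform contaminant density
#'
#' Density of a random choice among the N available items at a uniform
#' time in the subject's observed response-time range:
#' `u = 1 / (N (maxRT - minRT))`, in probability per item-millisecond.
#'
#' @param n_items Set size N.
#' @param rt_range_ms Length-2 numeric, the condition's observed
#'   min/max response time.
#' @return Scalar density.
#' @export
contaminant_density <- function(n_items, rt_range_ms) {
  span <- diff(range(rt_range_ms))
  if (!is.finite(span) || span <= 0) {
    stop("degenerate response-time range; supply an explicit range with ",
         "max > min", call. = FALSE)
  }
  1 / (n_items * span)
}

#' Contaminant mixture likelihood
#'
#' `l = 0.95 p + 0.05 u`: spurious trials are included at a fixed 5%
#' rate, which also floors every trial likelihood away from zero.
#'
#' @param p_model Model likelihood of the observed (choice, rt).
#' @param u Contaminant density.
#' @param rate Contaminant rate (default 0.05).
#' @return Mixture likelihood.
#' @export
mix_likelihood <- function(p_model, u, rate = CONTAM_RATE) {
  (1 - rate) * p_model + rate * u
}

# ---------------------------------------------------------------------------
# Experiment-level simulation
# ---------------------------------------------------------------------------

#' Simulate a full dataset from a fitted model
#'
#' Repeats every valid trial of a subject dataset `reps` times. Each
#' repetition is a contaminant with probability `contaminant_rate`
#' (uniform choice among all N items, uniform response time in the
#' subject's observed range for that set size); otherwise the configured
#' model generates choice and response time on the trial's observed gaze.
#' The output is a subject dataset whose trials carry the simulated
#' choice and response time together with the source trial's items and
#' gaze stream (revalidated with the experiment's exclusion rules), so
#' that all behavioural measures run unchanged on simulated data.
#'
#' @param dataset A [subject_dataset()] with cleaned, validated trials.
#' @param model One of `"psm"`, `"iam"`, `"glam"`.
#' @param variant `"active"` or `"passive"` (passive fixes
#'   `gamma = 1, zeta = 0`).
#' @param params Named parameter vector, or a list of such vectors keyed
#'   by set size (as character) for per-condition fits.
#' @param reps Repetitions per observed trial (default 50).
#' @param contaminant_rate Contaminant probability per repetition.
#' @return A [subject_dataset()] of simulated trials; simulated trial ids
#'   are `source_trial_id * 1000 + rep`.
#' @export
simulate_experiment <- function(dataset, model, variant = "active", params,
                                reps = 50L, contaminant_rate = CONTAM_RATE) {
  model <- match.arg(model, MODEL_NAMES)
  valid_trials <- Filter(function(tr) tr$valid, dataset$trials)
  if (!length(valid_trials)) stop("no valid trials to simulate", call. = FALSE)
  set_sizes <- vapply(valid_trials, function(tr) tr$set_size, 1L)
  rts <- vapply(valid_trials, function(tr) tr$rt_ms, 1L)
  out <- list()
  for (k in seq_along(valid_trials)) {
    tr <- valid_trials[[k]]
    pars <- if (is.list(params) && !is.null(names(params)) &&
                as.character(tr$set_size) %in% names(params)) {
      params[[as.character(tr$set_size)]]
    } else params
    pars <- resolve_variant(pars, variant)
    cond_rts <- rts[set_sizes == tr$set_size]
    input <- trial_model_input(tr)
    contam <- runif(reps) < contaminant_rate
    n_model <- sum(!contam)
    sim <- if (n_model > 0) {
      switch(model,
             psm = psm_simulate(input, pars, n_model),
             iam = iam_simulate(input, pars, n_model),
             glam = glam_simulate(input, pars, n_model))
    } else data.frame(choice = integer(), rt_ms = integer())
    ch <- integer(reps); rt <- integer(reps)
    ch[!contam] <- sim$choice
    rt[!contam] <- sim$rt_ms
    nc <- sum(contam)
    if (nc > 0) {
      ch[contam] <- sample.int(tr$set_size, nc, replace = TRUE)
      rt[contam] <- as.integer(round(runif(nc, min(cond_rts), max(cond_rts))))
    }
    for (r in seq_len(reps)) {
      sim_tr <- tr
      sim_tr$trial_id <- tr$trial_id * 1000L + r
      sim_tr$choice_index <- ch[r]
      sim_tr$rt_ms <- max(1L, rt[r])
      sim_tr$valid <- TRUE
      sim_tr$exclusion_reason <- "none"
      out[[length(out) + 1L]] <- apply_exclusions(sim_tr)
    }
  }
  subject_dataset(dataset$subject_id, out, dataset$ratings)
}

# expand a free-parameter vector to the full parameter set of a model
resolve_variant <- function(params, variant) {
  params <- unlist(params)
  if (identical(variant, "passive")) {
    params[["gamma"]] <- 1
    params[["zeta"]] <- 0
  }
  for (nm in c("gamma", "zeta")) {
    if (!nm %in% names(params)) {
      stop("parameter vector is missing '", nm, "'", call. = FALSE)
    }
  }
  params
}
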