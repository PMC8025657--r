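test_that("rating generation follows the configured distribution", {
  set.seed(1)
  cat80 <- gen_item_catalogue(80)
  uni <- rep(1 / 7, 7)
  draws <- unlist(replicate(150, gen_ratings(cat80, uni)$rating,
                            simplify = FALSE))
  freq <- tabulate(draws + 4L, nbins = 7) / length(draws)
  chi <- suppressWarnings(chisq.test(tabulate(draws + 4L, 7),
                                     p = uni))
  expect_gt(chi$p.value, 0.001)
  point <- gen_ratings(cat80, c(0, 0, 0, 1, 0, 0, 0))
  expect_true(all(point$rating == 0L))
  expect_error(gen_ratings(cat80, rep(0, 7)), "empty")
})

test_that("experiments are reproducible from the seed", {
  cfg <- synth_config(n_subjects = 1, set_sizes = 9L, trials_per_cond = 6,
                      seed = 123)
  a <- gen_experiment(cfg)
  b <- gen_experiment(cfg)
  for (i in seq_along(a$datasets[[1]]$trials)) {
    expect_identical(a$datasets[[1]]$trials[[i]]$choice_index,
                     b$datasets[[1]]$trials[[i]]$choice_index)
    expect_identical(a$datasets[[1]]$trials[[i]]$rt_ms,
                     b$datasets[[1]]$trials[[i]]$rt_ms)
    expect_equal(a$datasets[[1]]$trials[[i]]$gaze,
                 b$datasets[[1]]$trials[[i]]$gaze)
  }
})

test_that("generated gaze streams are already clean and validated", {
  for (m in c("psm", "iam", "glam")) {
    pars <- switch(m,
      psm = c(v = 3e-7, alpha = 8e-5, tau = 1.2, gamma = 0.6, zeta = 1.5),
      iam = c(v = 1e-4, sigma = 0.005, gamma = 0.3, zeta = 1),
      glam = c(v = 2e-4, sigma = 0.006, tau = 2, gamma = 0.6, zeta = 1.5))
    cfg <- synth_config(n_subjects = 1, set_sizes = 9L, trials_per_cond = 8,
                        generator = list(model = m, variant = "active",
                                         params = pars),
                        seed = 50 + match(m, c("psm", "iam", "glam")))
    ds <- gen_experiment(cfg)$datasets[[1]]
    for (tr in ds$trials) {
      expect_equal(clean_gaze(tr$gaze), tr$gaze, ignore_attr = TRUE)
      if (tr$valid) {
        st <- gaze_stats(tr)
        expect_lte(sum(st$total_gaze_ms), tr$rt_ms)
        expect_true(st$seen[tr$choice_index])
      }
    }
    # most trials survive the exclusion rules
    expect_gte(mean(vapply(ds$trials, function(t) t$valid, NA)), 0.7)
  }
})

test_that("rating weight induces a rating-gaze correlation", {
  cfg <- synth_config(n_subjects = 1, set_sizes = 16L, trials_per_cond = 25,
                      gaze = list(rating_weight = 0.6), seed = 31)
  ds <- gen_experiment(cfg)$datasets[[1]]
  pairs <- do.call(rbind, lapply(Filter(function(t) t$valid, ds$trials),
    function(tr) {
      st <- gaze_stats(tr)
      cbind(tr$items$rating, st$cum_gaze_frac)
    }))
  expect_gt(suppressWarnings(cor(pairs[, 1], pairs[, 2],
                                 method = "spearman")), 0.1)
})

test_that("unweighted uniform-start looking is spatially even", {
  cfg <- synth_config(gaze = list(rating_weight = 0, size_weight = 0,
                                  dist_weight = 0, start_bias = "uniform"))
  set.seed(9)
  items <- cbind(gen_ratings(gen_item_catalogue(9), rep(1 / 7, 7)),
                 manychoice:::item_grid(9))
  visits <- integer(9)
  for (i in 1:300) {
    g <- gen_gaze_sequence(items, cfg$gaze, horizon_ms = 3000)
    visits <- visits + tabulate(g$item, nbins = 9)
  }
  chi <- suppressWarnings(chisq.test(visits, p = rep(1 / 9, 9)))
  expect_gt(chi$p.value, 0.001)
})

test_that("seen fraction decreases with set size under a negative slope", {
  cfg <- synth_config(n_subjects = 1, set_sizes = c(9L, 36L),
                      trials_per_cond = 15, seed = 77)
  ds <- gen_experiment(cfg)$datasets[[1]]
  bs <- behaviour_summary(ds)
  expect_gt(bs$frac_items_seen[bs$set_size == 9],
            bs$frac_items_seen[bs$set_size == 36])
})

test_that("initial gazes are shorter than revisit gazes", {
  cfg <- synth_config()
  set.seed(5)
  items <- cbind(gen_ratings(gen_item_catalogue(16), rep(1 / 7, 7))[1:16, ],
                 manychoice:::item_grid(16))
  first <- c(); revisit <- c()
  for (i in 1:120) {
    g <- gen_gaze_sequence(items, cfg$gaze, horizon_ms = 8000)
    isfirst <- !duplicated(g$item)
    first <- c(first, g$dur_ms[isfirst])
    revisit <- c(revisit, g$dur_ms[!isfirst])
  }
  expect_gt(mean(revisit) - mean(first), 15)
})

test_that("the null generator sees everything and ignores gaze", {
  cfg <- synth_config(n_subjects = 1, set_sizes = 9L, trials_per_cond = 30,
                      generator = list(model = "null",
                                       params = c(tau = 0.8)),
                      seed = 60)
  set.seed(cfg$seed)
  res <- gen_null_gaze_subject(cfg, "null_01")
  trials <- Filter(function(t) t$valid, res$dataset$trials)
  expect_gt(length(trials), 25)
  expect_true(all(vapply(trials, frac_items_seen, 0) == 1))
  # sharp softmax approaches the rating argmax
  cfg2 <- synth_config(n_subjects = 1, set_sizes = 9L, trials_per_cond = 30,
                       generator = list(model = "null",
                                        params = c(tau = 40)),
                       seed = 61)
  set.seed(cfg2$seed)
  res2 <- gen_null_gaze_subject(cfg2, "null_02")
  expect_gt(p_choose_best_seen(res2$dataset$trials), 0.95)
})

test_that("contaminant-free configurations emit only model trials", {
  cfg <- synth_config(n_subjects = 1, set_sizes = 9L, trials_per_cond = 20,
                      contaminant_rate = 0, seed = 71)
  res <- gen_experiment(cfg)
  expect_true(all(!res$ground_truth$contaminant))
  cfg1 <- synth_config(n_subjects = 1, set_sizes = 9L, trials_per_cond = 40,
                       contaminant_rate = 0.5, seed = 72)
  res1 <- gen_experiment(cfg1)
  expect_gt(mean(res1$ground_truth$contaminant), 0.2)
})
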