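make_plot_table <- function(n_entries = 100, n_reps = 2, n_trials = 5) {
  entries <- sprintf("E%03d", seq_len(n_entries))
  trials <- sprintf("T%02d", rep(seq_len(n_trials), length.out = n_entries))
  data.frame(plot_id = sprintf("P%04d", seq_len(n_entries * n_reps)),
             entry_id = rep(entries, each = n_reps),
             trial_id = rep(trials, each = n_reps),
             stringsAsFactors = FALSE)
}

test_that("splits group by entry, honor fractions and stratify by trial", {
  df <- make_plot_table(100, 2, 5)
  plan <- make_splits(df, repeats = 5, seed = 42)
  expect_equal(sort(unique(plan$repeat_id)), 1:5)
  for (r in 1:5) {
    pr <- plan[plan$repeat_id == r, ]
    # no entry straddles partitions
    spread <- tapply(pr$partition, pr$entry_id,
                     function(x) length(unique(x)))
    expect_true(all(spread == 1))
    # partitions cover all entries
    expect_setequal(unique(pr$entry_id), unique(df$entry_id))
    # plot fractions within one entry's granularity (2 plots)
    expect_lte(abs(sum(pr$partition == "train") - 0.8 * nrow(df)), 2)
    expect_lte(abs(sum(pr$partition == "test") - 0.1 * nrow(df)), 2)
    # stratification counting oracle: per-trial test composition tracks the
    # global trial proportions
    global <- table(df$trial_id) / nrow(df)
    test_tab <- table(factor(pr$trial_id[pr$partition == "test"],
                             levels = names(global)))
    test_prop <- test_tab / sum(test_tab)
    expect_true(all(abs(test_prop - global) <= 0.10))
  }
  # determinism
  plan2 <- make_splits(df, repeats = 5, seed = 42)
  expect_identical(plan, plan2)
  expect_false(identical(plan, make_splits(df, repeats = 5, seed = 43)))
})

test_that("entries spanning trials are stratified by majority trial", {
  df <- make_plot_table(10, 3, 2)
  df$trial_id[df$entry_id == "E001"] <- c("T01", "T02", "T02")
  expect_warning(plan <- make_splits(df, repeats = 1, seed = 1), "majority")
  spread <- tapply(plan$partition, plan$entry_id,
                   function(x) length(unique(x)))
  expect_true(all(spread == 1))
})

test_that("training is a no-op at zero epochs and aborts on NaN loss", {
  ds <- tiny_dataset()
  m <- tiny_model(ds)
  cfg0 <- train_config(epochs = 0)
  fit <- train_model(m, ds$samples[1:6], ds$samples[7:10], cfg0, seed = 1)
  expect_identical(fit$params, m$params)

  # an absurd learning rate drives the loss non-finite -> diagnostic abort
  cfg_bad <- train_config(lr = 1e200, epochs = 5, weight_decay = 0)
  expect_error(
    suppressWarnings(train_model(m, ds$samples[1:6], NULL, cfg_bad, seed = 1)),
    "learning rate")
})

test_that("the plateau scheduler reduces the learning rate when stalled", {
  ds <- tiny_dataset()
  m <- tiny_model(ds)
  # constant validation targets make the Pearson metric undefined, so no
  # epoch ever improves: a stalled metric by construction
  val <- lapply(ds$samples[7:9], function(s) { s$yield <- 5; s })
  cfg <- train_config(lr = 1e-4, schedule = "plateau", epochs = 7,
                      patience = 100, schedule_patience = 2)
  fit <- train_model(m, ds$samples[1:6], val, cfg, seed = 2)
  expect_equal(fit$history$lr[1], 1e-4)
  expect_equal(fit$history$lr[3], 5e-5)   # halved after 2 stalled epochs
  expect_equal(fit$history$lr[5], 2.5e-5)

  cfg_cos <- train_config(lr = 1e-4, schedule = "cosine", epochs = 5,
                          cosine_cycle = 4, patience = 100)
  fit_cos <- train_model(m, ds$samples[1:6], NULL, cfg_cos, seed = 2)
  expect_equal(fit_cos$history$lr[1], 1e-4)
  expect_lt(fit_cos$history$lr[4], fit_cos$history$lr[2])
  expect_equal(fit_cos$history$lr[5], 1e-4)  # cycle restarts
})

test_that("random search samples the grid deterministically and picks the best", {
  # mock oracle: score each draw by a known deterministic function
  scorer <- function(draw) {
    log10(draw$lr) + draw$n_heads / 10 + as.numeric(draw$temporal_encoding)
  }
  res <- random_search(space = search_space(), n_runs = 20, seed = 9,
                       evaluator = scorer)
  expect_equal(nrow(res$leaderboard), 20)
  expect_equal(res$best_score, max(res$leaderboard$val_pearson))
  expect_equal(scorer(res$best), res$best_score)

  res2 <- random_search(space = search_space(), n_runs = 20, seed = 9,
                        evaluator = scorer)
  expect_identical(res$leaderboard, res2$leaderboard)

  one <- random_search(space = search_space(), n_runs = 1, seed = 3,
                       evaluator = scorer)
  expect_equal(nrow(one$leaderboard), 1)
  expect_identical(one$best, as.list(one$leaderboard[1, -ncol(one$leaderboard)]))

  expect_error(random_search(space = search_space(lr = numeric(0)),
                             n_runs = 2, seed = 1, evaluator = scorer),
               "empty")
  failing <- function(draw) stop("boom")
  expect_error(random_search(space = search_space(), n_runs = 3, seed = 1,
                             evaluator = failing), "boom")
})

test_that("metrics match hand-computed definitions", {
  perfect <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$pearson, 1)
  expect_equal(perfect$r2, 1)

  # hand arithmetic: SS_res = 1+4+9 = 14, SS_tot = 2 -> R2 = -6
  m <- evaluate(c(2, 4, 6), c(1, 2, 3))
  expect_equal(m$pearson, 1)
  expect_equal(m$r2, -6)
  expect_equal(m$mae, 2)

  flat <- evaluate(c(2, 2, 2), c(1, 2, 3))
  expect_false(flat$pearson_defined)
  expect_true(is.finite(flat$mse))
  expect_error(evaluate(1:3, 1:4), "aligned")
})

test_that("entry-level aggregation averages replicates", {
  expect_equal(entry_level_aggregate(stats::setNames(5, "p1"),
                                     stats::setNames(4, "p1"),
                                     c(p1 = "e1"))$predictions, 5)
  agg <- entry_level_aggregate(stats::setNames(c(1, 3), c("p1", "p2")),
                               stats::setNames(c(2, 4), c("p1", "p2")),
                               c(p1 = "e1", p2 = "e1"))
  expect_equal(agg$predictions, 2)
  expect_equal(agg$observations, 3)

  # manual oracle on a 6-plot / 3-entry table
  preds <- stats::setNames(c(1, 2, 5, 7, 4, 4), sprintf("p%d", 1:6))
  obs <- stats::setNames(c(2, 2, 6, 6, 3, 5), sprintf("p%d", 1:6))
  emap <- stats::setNames(rep(c("a", "b", "c"), each = 2), sprintf("p%d", 1:6))
  agg3 <- entry_level_aggregate(preds, obs, emap)
  hand_pred <- c(1.5, 6, 4); hand_obs <- c(2, 6, 4)
  expect_equal(agg3$predictions, hand_pred)
  expect_equal(agg3$observations, hand_obs)
  ev <- evaluate(preds, obs, level = "entry", entry_map = emap)
  expect_equal(ev$pearson, stats::cor(hand_pred, hand_obs))

  expect_error(entry_level_aggregate(preds, obs, emap[-1]), "not mapped")
})

test_that("ensembling averages members and never hurts the squared error", {
  ds <- tiny_dataset()
  m1 <- tiny_model(ds, seed = 1)
  m2 <- tiny_model(ds, seed = 2)
  smp <- ds$samples[1:6]
  same <- ensemble_predict(list(m1, m1), smp)
  expect_equal(same, predict_samples(m1, smp))

  p1 <- predict_samples(m1, smp)
  p2 <- predict_samples(m2, smp)
  ens <- ensemble_predict(list(m1, m2), smp)
  expect_equal(ens, (p1 + p2) / 2)
  y <- vapply(smp, `[[`, 0, "yield")
  expect_lte(mse_loss(ens, y), mean(c(mse_loss(p1, y), mse_loss(p2, y))) + 1e-12)
})

test_that("marker harmonization aligns, fills and enforces the overlap floor", {
  new <- matrix(c(0, 1, 2, 2, 1, 0), 2,
                dimnames = list(c("l1", "l2"), c("B", "C", "D")))
  out <- harmonize_markers(c("A", "B", "C"), new,
                           train_means = c(A = 0.7, B = 1, C = 1))
  expect_identical(colnames(out), c("A", "B", "C"))
  expect_equal(unname(out[, "A"]), c(0.7, 0.7))           # filled
  expect_equal(unname(out[, "B"]), c(0, 1))
  expect_equal(attr(out, "dropped"), 1L)                  # D dropped
  expect_equal(attr(out, "filled"), 1L)

  ident <- harmonize_markers(c("B", "C"), new[, c("C", "B")])
  expect_identical(colnames(ident), c("B", "C"))
  expect_equal(unname(ident[, "B"]), c(0, 1))

  disjoint <- matrix(0, 1, 2, dimnames = list("l", c("X", "Y")))
  expect_error(harmonize_markers(c("A", "B"), disjoint), "incompatible")
})

test_that("genotype-only fine-tuning freezes image encoders", {
  ds <- tiny_dataset()
  m <- tiny_model(ds)
  # zero epochs: the model is untouched
  expect_identical(finetune_genotype_only(m, ds$samples[1:6], epochs = 0),
                   m)
  ft <- finetune_genotype_only(m, ds$samples[1:8], ds$samples[9:12],
                               epochs = 2, config = train_config(lr = 1e-3),
                               seed = 4)
  for (ch in c("multispectral", "thermal", "dem")) {
    expect_identical(ft$params$encoders[[ch]], m$params$encoders[[ch]])
  }
  # the genotype pathway did move
  expect_false(identical(ft$params$encoders$genotype,
                         m$params$encoders$genotype))

  no_geno <- mil_model(model_config(channels = "multispectral", n_heads = 1,
                                    attention_width = 8, regressor_hidden = 8),
                       date_vocab = as.character(ds$config$flight_dates),
                       seed = 1)
  expect_error(finetune_genotype_only(no_geno, ds$samples[1:4]),
               "unsupported")
})

test_that("training improves validation Pearson on a small synthetic task", {
  # scaled-down recovery: genotype-free, image-driven signal
  cfg <- sim_config(n_lines = 60, n_reps = 2, n_markers = 20, n_causal = 4,
                    n_trials = 3, image_size = c(8, 8),
                    channel_set = "multispectral",
                    thermal_signal = 0, dem_signal = 0, seed = 17)
  ds <- simulate_dataset(cfg)
  plan <- make_splits(ds$samples, repeats = 1, seed = 17)
  tr <- split_samples(ds$samples, plan, 1, "train")
  va <- split_samples(ds$samples, plan, 1, "val")
  m <- mil_model(model_config(channels = "multispectral", n_heads = 2,
                              bag_size = 8, attention_width = 32,
                              regressor_hidden = 32),
                 date_vocab = as.character(cfg$flight_dates), seed = 17)
  fit <- train_model(m, tr, va, train_config(lr = 1e-3, epochs = 8,
                                             patience = 8), seed = 17)
  expect_gt(max(fit$history$val_pearson, na.rm = TRUE), 0.6)
})

test_that("genotype-only fine-tuning preserves accuracy and transfers to a new environment", {
  fx <- standard_fixture()
  # fine-tuning must not degrade genotype-only accuracy on the source
  # environment's test split: with 24 test plots the Pearson difference
  # carries large sampling noise, so the check is a paired bootstrap —
  # a real degradation beyond 0.02 would push the whole interval below it
  for (f in fx) {
    base <- predict_samples(f$model_mm, f$test, genotype_only = TRUE)
    ft <- finetune_genotype_only(f$model_mm, f$train, f$val, epochs = 3,
                                 seed = f$seed)
    tuned <- predict_samples(ft, f$test, genotype_only = TRUE)
    obs <- vapply(f$test, `[[`, 0, "yield")
    set.seed(f$seed)
    n <- length(obs)
    diffs <- replicate(500, {
      i <- sample(n, replace = TRUE)
      safe_cor(tuned[i], obs[i]) - safe_cor(base[i], obs[i])
    })
    expect_gt(stats::quantile(diffs, 0.975, na.rm = TRUE), -0.02)
  }

  # a freshly simulated environment (new lines, same causal architecture)
  # is predictable from genotypes alone: bootstrap CI of Pearson excludes 0
  f1 <- fx[[1]]
  cfg_b <- sim_config(n_lines = 120, n_reps = 2, n_markers = 200,
                      n_causal = 20, n_trials = 5, h2_target = 0.5,
                      channel_set = character(0), trial_sd = 0.4, seed = 501)
  src_truth <- simulate_dataset(standard_fixture_config(f1$seed))$truth
  env_b <- simulate_new_environment(src_truth, cfg_b)
  ft1 <- finetune_genotype_only(f1$model_mm, f1$train, f1$val, epochs = 3,
                                seed = f1$seed)
  aligned <- harmonize_markers(ft1$marker_ids, impute_dosage(env_b$genotypes))
  expect_equal(attr(aligned, "filled"), 0L)
  pred_b <- predict_samples(ft1, env_b$samples, genotype_only = TRUE)
  obs_b <- vapply(env_b$samples, `[[`, 0, "yield")
  set.seed(99)
  n <- length(obs_b)
  boots <- replicate(1000, {
    i <- sample(n, replace = TRUE)
    safe_cor(pred_b[i], obs_b[i])
  })
  expect_gt(stats::quantile(boots, 0.025), 0)
})
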