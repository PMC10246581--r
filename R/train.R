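#' Grouped, trial-stratified train/validation/test splits
#'
#' Builds repeated random splits grouped by entry (so replicate plots of
#' one breeding line never straddle partitions, which would upwardly bias
#' accuracy) and stratified by trial (each partition mirrors the trial
#' composition). Partition sizes honor the requested plot fractions within
#' one entry's granularity via largest-remainder allocation of per-trial
#' entry quotas. An entry with replicates in several trials is stratified
#' by its majority trial, with a warning. Baseline consumers that need no
#' validation data may merge `val` into `train`; the `test` partition is
#' identical across methods.
#'
#' @param samples List of [plot_sample()] objects (or a data.frame with
#'   `plot_id`, `entry_id`, `trial_id`).
#' @param fractions Length-3 train/val/test plot fractions summing to 1
#'   (default `c(0.8, 0.1, 0.1)`).
#' @param repeats Number of repeated splits (default 5).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A data.frame of class `split_plan` with columns `plot_id`,
#'   `entry_id`, `trial_id`, `repeat_id`, `partition`.
#' @export
make_splits <- function(samples, fractions = c(0.8, 0.1, 0.1), repeats = 5,
                        seed = 1) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8 ||
      any(fractions < 0)) {
    stopf("fractions must be three non-negative values summing to 1")
  }
  df <- if (is.data.frame(samples)) samples else
    data.frame(plot_id = vapply(samples, `[[`, "", "plot_id"),
               entry_id = vapply(samples, `[[`, "", "entry_id"),
               trial_id = vapply(samples, `[[`, "", "trial_id"),
               stringsAsFactors = FALSE)
  # entry -> majority trial
  entry_trial <- tapply(df$trial_id, df$entry_id, function(tr) {
    tab <- sort(table(tr), decreasing = TRUE)
    if (length(tab) > 1) names(tab)[1] else names(tab)
  })
  multi <- tapply(df$trial_id, df$entry_id, function(tr) length(unique(tr)) > 1)
  if (any(multi)) {
    warnf("%d entr(ies) span multiple trials; stratifying by majority trial",
          sum(multi))
  }
  entries <- names(entry_trial)
  n_entries <- length(entries)
  plan <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, 300 + r))
    target_train <- round(fractions[1] * n_entries)
    target_val <- round(fractions[2] * n_entries)
    by_trial <- split(entries, entry_trial[entries])
    counts <- vapply(by_trial, length, 0L)
    train_q <- largest_remainder(counts * fractions[1], target_train)
    val_q <- largest_remainder(counts * fractions[2], target_val)
    val_q <- pmin(val_q, counts - train_q)
    assign <- character(n_entries)
    names(assign) <- entries
    for (ti in seq_along(by_trial)) {
      es <- sample(by_trial[[ti]])
      nt <- train_q[ti]; nv <- val_q[ti]
      assign[es] <- c(rep("train", nt), rep("val", nv),
                      rep("test", length(es) - nt - nv))
    }
    plan[[r]] <- data.frame(plot_id = df$plot_id,
                            entry_id = df$entry_id,
                            trial_id = df$trial_id,
                            repeat_id = r,
                            partition = unname(assign[df$entry_id]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, plan)
  class(out) <- c("split_plan", "data.frame")
  out
}

# Integer allocation with the requested total: floors plus the largest
# fractional remainders.
largest_remainder <- function(quota, total) {
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  } else if (rem < 0) {
    victims <- order(quota - base)[seq_len(-rem)]
    base[victims] <- pmax(base[victims] - 1, 0)
  }
  as.integer(base)
}

#' Extract the samples of one partition of one repeat
#'
#' @param samples Named list of [plot_sample()] objects.
#' @param plan A [make_splits()] plan.
#' @param repeat_id Which repeat.
#' @param partition `"train"`, `"val"` or `"test"`.
#' @return The subset of `samples`.
#' @export
split_samples <- function(samples, plan, repeat_id, partition) {
  ids <- plan$plot_id[plan$repeat_id == repeat_id & plan$partition == partition]
  pid <- vapply(samples, `[[`, "", "plot_id")
  samples[match(ids, pid)]
}

#' Training configuration
#'
#' @param lr Initial learning rate (search grid: 1e-5, 1e-4, 1e-3).
#' @param schedule `"none"`, `"plateau"` (halve the learning rate after
#'   `schedule_patience` epochs without validation improvement) or
#'   `"cosine"` (cyclic cosine annealing with period `cosine_cycle`).
#' @param batch_size Minibatch size (search grid: 8, 16).
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience on validation Pearson.
#' @param weight_decay Decoupled L2 weight decay.
#' @param schedule_patience,cosine_cycle Scheduler parameters.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, schedule = c("none", "plateau", "cosine"),
                         batch_size = 8, epochs = 30, patience = 8,
                         weight_decay = 1e-4, schedule_patience = 3,
                         cosine_cycle = 10) {
  schedule <- match.arg(schedule)
  structure(list(lr = lr, schedule = schedule, batch_size = batch_size,
                 epochs = epochs, patience = patience,
                 weight_decay = weight_decay,
                 schedule_patience = schedule_patience,
                 cosine_cycle = cosine_cycle),
            class = "train_config")
}

scheduled_lr <- function(cfg, epoch, plateau_drops) {
  if (cfg$schedule == "cosine") {
    phase <- ((epoch - 1) %% cfg$cosine_cycle) / cfg$cosine_cycle
    cfg$lr * (0.01 + 0.99 * 0.5 * (1 + cos(pi * phase)))
  } else if (cfg$schedule == "plateau") {
    cfg$lr * 0.5^plateau_drops
  } else {
    cfg$lr
  }
}

#' Train the MIL model
#'
#' Minimizes the MSE loss with Adam over minibatches, drawing a fresh bag
#' subsample per sample per iteration. Validation Pearson is tracked each
#' epoch; the best-epoch weights are returned and training stops early
#' after `patience` epochs without improvement. All randomness is seeded.
#' `epochs = 0` returns the initialization unchanged.
#'
#' @param model A [mil_model()].
#' @param train,val Lists of [plot_sample()] with yields; `val` may be
#'   `NULL` (no early stopping or plateau signal).
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @param freeze Character vector of encoder names whose weights stay fixed
#'   (e.g. `c("multispectral", "thermal", "dem")` for genotype-only
#'   fine-tuning).
#' @param genotype_only Present genotype-only bags during training.
#' @param verbose Print per-epoch progress.
#' @return The trained model with a `history` data.frame attached
#'   (`epoch`, `train_mse`, `val_pearson`, `lr`). The network regresses
#'   standardized yields internally; `train_mse` is reported on that
#'   standardized scale, while predictions are always mapped back to t/ha.
#' @export
train_model <- function(model, train, val = NULL, config = train_config(),
                        seed = 1, freeze = character(0),
                        genotype_only = FALSE, verbose = FALSE) {
  stopifnot(inherits(model, "mil_model"), inherits(config, "train_config"))
  set.seed(derive_seed(seed, 400))
  params <- model$params
  frozen_ref <- model$params$encoders
  state <- adam_init(params)
  best <- list(pearson = -Inf, params = params)
  history <- data.frame()
  stall <- 0
  plateau_drops <- 0
  n <- length(train)
  y_raw <- vapply(train, `[[`, 0, "yield")
  if (config$epochs > 0 && n == 0) stopf("empty training set")
  # the network regresses standardized targets; predictions are mapped back
  # to t/ha through the stored affine transform
  if (config$epochs > 0) {
    model$y_center <- mean(y_raw)
    ys <- stats::sd(y_raw)
    model$y_scale <- if (is.na(ys) || ys == 0) 1 else ys
  }
  y <- (y_raw - (model$y_center %||% 0)) / (model$y_scale %||% 1)
  for (epoch in seq_len(config$epochs)) {
    lr <- scheduled_lr(config, epoch, plateau_drops)
    ord <- sample(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      gacc <- NULL
      batch_loss <- 0
      for (i in idx) {
        model$params <- params
        fw <- mil_forward(model, train[[i]], training = TRUE,
                          genotype_only = genotype_only)
        err <- fw$yhat - y[i]
        batch_loss <- batch_loss + err^2
        g <- mil_backward(model, fw, 2 * err / length(idx))
        gacc <- if (is.null(gacc)) g else tree_add(gacc, g)
      }
      batch_loss <- batch_loss / length(idx)
      if (!is.finite(batch_loss)) {
        stopf("non-finite training loss at epoch %d, batch starting %d (lr %.2e); lower the learning rate",
              epoch, start, lr)
      }
      losses <- c(losses, batch_loss)
      if (length(freeze)) {
        for (f in intersect(freeze, names(gacc$encoders))) {
          gacc$encoders[[f]] <- tree_zeros(gacc$encoders[[f]])
        }
      }
      upd <- adam_step(params, gacc, state, lr,
                       weight_decay = config$weight_decay)
      params <- upd$params
      state <- upd$state
      if (length(freeze)) {
        for (f in intersect(freeze, names(params$encoders))) {
          params$encoders[[f]] <- frozen_ref[[f]]
        }
      }
    }
    model$params <- params
    val_p <- NA_real_
    if (!is.null(val) && length(val) >= 2) {
      vp <- predict_samples(model, val, genotype_only = genotype_only)
      vy <- vapply(val, `[[`, 0, "yield")
      val_p <- safe_pearson(vp, vy)$value
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, train_mse = mean(losses),
                                val_pearson = val_p, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  mse %.4f  val r %s  lr %.1e", epoch,
                      mean(losses),
                      ifelse(is.na(val_p), "NA", sprintf("%.3f", val_p)), lr))
    }
    if (!is.na(val_p) && val_p > best$pearson + 1e-6) {
      best <- list(pearson = val_p, params = params)
      stall <- 0
    } else {
      stall <- stall + 1
      if (config$schedule == "plateau" && stall > 0 &&
          stall %% config$schedule_patience == 0) {
        plateau_drops <- plateau_drops + 1
      }
      if (!is.null(val) && stall >= config$patience) break
    }
  }
  if (is.finite(best$pearson)) model$params <- best$params
  model$history <- history
  model
}

#' Hyperparameter search space
#'
#' The random-search grid: learning rate, schedule, batch size, bag size,
#' attention heads, and the temporal/channel encoding flags.
#'
#' @param ... Named overrides of any grid dimension.
#' @return A named list of candidate values, class `search_space`.
#' @export
search_space <- function(...) {
  space <- list(lr = c(1e-5, 1e-4, 1e-3),
                schedule = c("none", "plateau", "cosine"),
                batch_size = c(8, 16),
                bag_size = c(8, 16, 32),
                n_heads = c(1, 4, 8),
                temporal_encoding = c(TRUE, FALSE),
                channel_encoding = c(TRUE, FALSE))
  over <- list(...)
  for (nm in names(over)) space[[nm]] <- over[[nm]]
  structure(space, class = "search_space")
}

#' Random hyperparameter search
#'
#' Draws `n_runs` i.i.d. configurations from the grid (duplicates allowed),
#' evaluates each by validation Pearson, and returns the best configuration
#' with the full leaderboard. The default evaluator builds and trains a
#' model on the supplied data; tests may inject a custom `evaluator`.
#'
#' @param train,val Sample lists passed to the evaluator.
#' @param space A [search_space()].
#' @param n_runs Number of draws (default 20).
#' @param seed Seed; the sampled configuration sequence is deterministic.
#' @param evaluator `function(draw)` returning a validation Pearson, where
#'   `draw` is a named list with one value per grid dimension. `NULL` uses
#'   the built-in model-training evaluator.
#' @param model_builder Used by the default evaluator:
#'   `function(draw)` returning an untrained [mil_model()].
#' @param base_train_config A [train_config()] whose `lr`, `schedule` and
#'   `batch_size` are overridden per draw (default evaluator only).
#' @return List with `best` (named list), `leaderboard` (data.frame with
#'   one row per run, ordered as executed) and `best_score`.
#' @export
random_search <- function(train = NULL, val = NULL, space = search_space(),
                          n_runs = 20, seed = 1, evaluator = NULL,
                          model_builder = NULL,
                          base_train_config = train_config()) {
  if (any(vapply(space, length, 0L) == 0)) stopf("empty search space dimension")
  set.seed(derive_seed(seed, 500))
  draws <- lapply(seq_len(n_runs), function(i) {
    lapply(space, function(vals) vals[[sample.int(length(vals), 1)]])
  })
  if (is.null(evaluator)) {
    if (is.null(model_builder)) {
      stopf("the default evaluator needs a model_builder")
    }
    evaluator <- function(draw) {
      cfg <- base_train_config
      cfg$lr <- draw$lr
      cfg$schedule <- draw$schedule
      cfg$batch_size <- draw$batch_size
      fitted <- train_model(model_builder(draw), train, val, cfg, seed = seed)
      max(fitted$history$val_pearson, na.rm = TRUE)
    }
  }
  scores <- rep(NA_real_, n_runs)
  errors <- character(n_runs)
  for (i in seq_len(n_runs)) {
    res <- tryCatch(evaluator(draws[[i]]),
                    error = function(e) {
                      errors[i] <<- conditionMessage(e)
                      NA_real_
                    })
    scores[i] <- res
  }
  if (all(is.na(scores))) {
    stopf("all %d search runs failed; first cause: %s", n_runs,
          errors[errors != ""][1])
  }
  leaderboard <- cbind(do.call(rbind, lapply(draws, function(d) {
    as.data.frame(d, stringsAsFactors = FALSE)
  })), val_pearson = scores)
  best_i <- which.max(scores)
  list(best = draws[[best_i]], leaderboard = leaderboard,
       best_score = scores[best_i])
}

#' Regression metrics report
#'
#' MAE (t/ha), MSE (t/ha^2), Pearson correlation and the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot`, at the plot or entry level
#' (the latter averages replicate plots per entry first). Zero-variance
#' inputs flag the Pearson coefficient as undefined while the other metrics
#' are still reported.
#'
#' @param predictions,observations Aligned numeric vectors (length >= 2 for
#'   a defined correlation).
#' @param level `"plot"` or `"entry"`.
#' @param entry_map Named character vector mapping plot id -> entry id
#'   (required for entry-level evaluation, names matching
#'   `names(predictions)`).
#' @return A list of class `metrics_report`.
#' @export
evaluate <- function(predictions, observations, level = c("plot", "entry"),
                     entry_map = NULL) {
  level <- match.arg(level)
  if (length(predictions) != length(observations)) {
    stopf("predictions (%d) and observations (%d) are not aligned",
          length(predictions), length(observations))
  }
  if (level == "entry") {
    agg <- entry_level_aggregate(predictions, observations, entry_map)
    predictions <- agg$predictions
    observations <- agg$observations
  }
  pr <- safe_pearson(predictions, observations)
  ss_tot <- sum((observations - mean(observations))^2)
  r2 <- if (ss_tot == 0) NA_real_ else
    1 - sum((predictions - observations)^2) / ss_tot
  structure(list(mae = mean(abs(predictions - observations)),
                 mse = mean((predictions - observations)^2),
                 pearson = pr$value, pearson_defined = pr$defined,
                 r2 = r2, level = level, n = length(predictions)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics (%s level, n=%d): MAE %.3f t/ha | MSE %.3f | Pearson %s | R2 %s\n",
              x$level, x$n, x$mae, x$mse,
              ifelse(x$pearson_defined, sprintf("%.3f", x$pearson), "undefined"),
              ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2))))
  invisible(x)
}

#' Aggregate plot-level pairs to entry level
#'
#' Per entry, the mean of predictions and of observations over its
#' replicate plots.
#'
#' @param predictions,observations Aligned plot-level vectors, named by
#'   plot id (or aligned with `entry_map` order).
#' @param entry_map Named character vector plot id -> entry id covering
#'   every plot.
#' @return List with per-entry `predictions`, `observations` and
#'   `entry_ids`.
#' @export
entry_level_aggregate <- function(predictions, observations, entry_map) {
  if (is.null(entry_map)) stopf("entry_map is required for entry-level aggregation")
  ids <- names(predictions) %||% names(entry_map)
  unmapped <- setdiff(ids, names(entry_map))
  if (length(unmapped)) {
    stopf("plot %s is not mapped to an entry", unmapped[1])
  }
  ent <- entry_map[ids]
  pred <- tapply(predictions, ent, mean)
  obs <- tapply(observations, ent, mean)
  entries <- sort(unique(ent))
  list(predictions = as.numeric(pred[entries]),
       observations = as.numeric(obs[entries]),
       entry_ids = entries)
}

#' Ensemble prediction
#'
#' The arithmetic mean of member predictions per sample (the usual
#' cross-validation ensemble: one member per training split).
#'
#' @param models List of trained [mil_model()] objects with compatible
#'   marker sets.
#' @param samples List of [plot_sample()] objects.
#' @param genotype_only Predict from genotypes alone.
#' @return Named numeric vector of ensembled predictions.
#' @export
ensemble_predict <- function(models, samples, genotype_only = FALSE) {
  if (length(models) < 1) stopf("at least one model is required")
  marker_sets <- lapply(models, `[[`, "marker_ids")
  if (length(unique(vapply(marker_sets, paste, "", collapse = "|"))) > 1) {
    stopf("models have incompatible marker sets; harmonize before ensembling")
  }
  preds <- vapply(models, predict_samples, numeric(length(samples)),
                  samples = samples, genotype_only = genotype_only)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  out <- rowMeans(preds)
  names(out) <- vapply(samples, `[[`, "", "plot_id")
  out
}

#' Align new-environment genotypes to a trained marker set
#'
#' Restricts and reorders a new dosage matrix to the marker list a model
#' was trained on. Markers missing from the new set are filled with the
#' training-set mean dosage; extra markers are dropped. Errors if the
#' intersection falls below `min_overlap`.
#'
#' @param train_markers Character vector of trained marker ids.
#' @param new_genotypes A [genotype_matrix()] or complete numeric dosage
#'   matrix with marker column names.
#' @param train_means Named mean-dosage vector for fills (defaults to 1,
#'   i.e. allele frequency 0.5, when a marker has no recorded mean).
#' @param min_overlap Minimum fraction of trained markers that must be
#'   present (default 0.5).
#' @return Numeric matrix (lines x trained markers) with attributes
#'   `dropped` and `filled` counting the adjustments.
#' @export
harmonize_markers <- function(train_markers, new_genotypes,
                              train_means = NULL, min_overlap = 0.5) {
  X <- if (inherits(new_genotypes, "genotype_matrix")) {
    impute_dosage(new_genotypes)
  } else {
    as.matrix(new_genotypes)
  }
  if (is.null(colnames(X))) stopf("new genotypes must carry marker column names")
  common <- intersect(train_markers, colnames(X))
  if (length(common) < min_overlap * length(train_markers)) {
    stopf("only %d of %d trained markers present (floor %.0f%%); marker sets are incompatible",
          length(common), length(train_markers), 100 * min_overlap)
  }
  out <- matrix(NA_real_, nrow(X), length(train_markers),
                dimnames = list(rownames(X), train_markers))
  out[, common] <- X[, common]
  fill_markers <- setdiff(train_markers, common)
  for (mk in fill_markers) {
    out[, mk] <- if (!is.null(train_means) && mk %in% names(train_means)) {
      train_means[[mk]]
    } else {
      1
    }
  }
  attr(out, "dropped") <- ncol(X) - length(common)
  attr(out, "filled") <- length(fill_markers)
  out
}

#' Genotype-only fine-tuning for cross-environment prediction
#'
#' Continues MSE training of a multi-modally trained model while presenting
#' genotype-only bags, with the image encoders frozen and a reduced
#' learning rate, so the genotype pathway adapts to carrying predictions
#' alone. Fine-tuning uses the original training environment's samples;
#' the new environment's yields are never touched.
#'
#' @param model A trained [mil_model()] with a genotype encoder.
#' @param train_samples Training-split samples of the source environment.
#' @param val_samples Optional validation samples (genotype-only scoring).
#' @param lr_factor Learning-rate multiplier (default 0.1).
#' @param epochs Fine-tuning epochs (default 5); 0 is a no-op.
#' @param config Base [train_config()]; its `lr` is scaled by `lr_factor`.
#' @param seed Seed.
#' @return The fine-tuned model.
#' @export
finetune_genotype_only <- function(model, train_samples, val_samples = NULL,
                                   lr_factor = 0.1, epochs = 5,
                                   config = train_config(), seed = 1) {
  if (is.null(model$arch$genotype)) {
    stopf("model has no genotype encoder; genotype-only fine-tuning unsupported")
  }
  if (epochs == 0) return(model)
  config$lr <- config$lr * lr_factor
  config$epochs <- epochs
  config$patience <- epochs
  train_model(model, train_samples, val_samples, config, seed = seed,
              freeze = intersect(names(model$params$encoders), CHANNEL_TAGS),
              genotype_only = TRUE)
}
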