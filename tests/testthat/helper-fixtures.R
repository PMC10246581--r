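# Shared fixtures. Everything is generated in code at test time; the heavy
# recovery experiment is memoized so several test files can share one run.

.fixture_cache <- new.env(parent = emptyenv())

# A small, fast dataset for unit tests of IO, features, model plumbing.
tiny_dataset <- function(seed = 5, ...) {
  key <- paste0("tiny_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_cache[[key]])) {
    cfg <- sim_config(n_lines = 12, n_markers = 40, n_causal = 5,
                      n_trials = 2, n_reps = 2, image_size = c(6, 6),
                      flight_dates = as.Date(c("2018-02-01", "2018-02-15",
                                               "2018-03-01")),
                      images_per_plot_per_date_mean = 2, seed = seed, ...)
    .fixture_cache[[key]] <- simulate_dataset(cfg)
  }
  .fixture_cache[[key]]
}

tiny_model <- function(ds, seed = 3, ...) {
  cfg <- model_config(n_heads = 2, encoder_scale = "tiny",
                      genotype_hidden = c(32, 16), attention_width = 16,
                      regressor_hidden = 16, tiny_hidden = 16, ...)
  mil_model(cfg, marker_ids = ds$genotypes$marker_ids,
            date_vocab = as.character(ds$config$flight_dates), seed = seed)
}

# Uniform multispectral image with exactly known band means (band order
# blue, green, red, rededge, nir).
uniform_ms_image <- function(bands, date = "2018-02-10", h = 4, w = 4) {
  px <- array(rep(bands, each = h * w), c(h, w, 5))
  image_instance("multispectral", date, px)
}

# The standard desk-scale recovery fixture: 240 plots (120 entries x 2
# reps), h2 = 0.5, informative mid-season multispectral images, thermal and
# DEM rendered as signal-free channels, tiny encoders throughout.
standard_fixture_config <- function(seed) {
  sim_config(n_lines = 120, n_reps = 2, n_markers = 200, n_causal = 20,
             n_trials = 6, h2_target = 0.5, image_size = c(16, 16),
             thermal_signal = 0, dem_signal = 0, seed = seed)
}

standard_model_config <- function(channels = c("multispectral", "thermal",
                                               "dem", "genotype")) {
  model_config(channels = channels, n_heads = 4, bag_size = 8,
               encoder_scale = "tiny", genotype_hidden = c(256, 128))
}

# Trains the multimodal model and the genotype-only network on one seed of
# the standard fixture and summarizes test performance and attention.
run_fixture_seed <- function(seed, with_attention = TRUE) {
  cfg <- standard_fixture_config(seed)
  ds <- simulate_dataset(cfg)
  plan <- make_splits(ds$samples, repeats = 1, seed = seed)
  tr <- split_samples(ds$samples, plan, 1, "train")
  va <- split_samples(ds$samples, plan, 1, "val")
  te <- split_samples(ds$samples, plan, 1, "test")
  marker_ids <- ds$genotypes$marker_ids
  dates <- as.character(cfg$flight_dates)
  mm <- train_model(
    mil_model(standard_model_config(), marker_ids = marker_ids,
              date_vocab = dates, seed = seed),
    tr, va, train_config(lr = 1e-3, epochs = 20, patience = 8), seed = seed)
  gm <- train_model(
    mil_model(standard_model_config(channels = "genotype"),
              marker_ids = marker_ids, date_vocab = dates, seed = seed),
    tr, va, train_config(lr = 1e-3, epochs = 30, patience = 10), seed = seed)
  obs <- vapply(te, `[[`, 0, "yield")
  pred_mm <- predict_samples(mm, te)
  pred_gm <- predict_samples(gm, te)
  out <- list(seed = seed, plan = plan,
              pearson_mm = safe_cor(pred_mm, obs),
              pearson_gm = safe_cor(pred_gm, obs),
              test = te, train = tr, val = va, model_mm = mm, model_gm = gm)
  if (with_attention) {
    out$att_channel <- attention_by_channel(mm, te)
    out$att_date <- attention_by_date(mm, te)
  }
  out
}

safe_cor <- function(a, b) suppressWarnings(stats::cor(a, b))

standard_fixture <- function() {
  if (is.null(.fixture_cache$standard)) {
    .fixture_cache$standard <- lapply(c(11, 12, 13), run_fixture_seed)
  }
  .fixture_cache$standard
}
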