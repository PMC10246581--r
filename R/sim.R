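#' Configuration for the synthetic breeding-trial generator
#'
#' Defines every condition of a simulated field season: the genetic
#' architecture (marker panel, causal loci, heritability), the field design
#' (trials, replicates, yield variance components in t/ha), and the UAV
#' acquisition campaign (flight dates, per-date image counts, image geometry,
#' channels). The seed fully determines the generated dataset.
#'
#' Phenotypic variance is partitioned so that the standardized breeding value
#' `g` has unit variance; when `residual_sd` is `NULL` it is derived from
#' `h2_target` and `trial_sd` via
#' `residual_sd = sqrt(1/h2 - 1 - trial_sd^2)`, so that
#' `var(g)/var(yield) = h2_target` in expectation.
#'
#' @param n_lines Number of genetically unique breeding lines (entries).
#' @param n_markers Number of SNP markers.
#' @param n_causal Number of causal markers with nonzero additive effect.
#' @param maf_range Length-2 range of per-marker minor allele frequencies,
#'   within `(0, 0.5]`.
#' @param marker_missing_rate I.i.d. missing-call rate.
#' @param het_rate Expected heterozygous-call fraction (inbred lines are
#'   mostly homozygous; residual heterozygosity is a few percent).
#' @param h2_target Narrow-sense heritability of plot yield, in `[0, 1]`.
#' @param n_trials Number of trials (stratification blocks).
#' @param n_reps Replicate plots per line.
#' @param trial_sd Between-trial yield standard deviation (t/ha).
#' @param residual_sd Residual plot-level yield sd (t/ha), or `NULL` to derive
#'   it from `h2_target`.
#' @param mean_yield Population mean yield (t/ha).
#' @param flight_dates Strictly increasing `Date` vector of UAV flights.
#' @param images_per_plot_per_date_mean Poisson mean of the per-plot,
#'   per-date, per-channel image count (zero counts emulate irregular
#'   coverage).
#' @param image_size Integer `(height, width)` of rendered plot crops.
#' @param channel_set Subset of `c("multispectral", "thermal", "dem")`.
#' @param thermal_signal Slope of the thermal band on latent health (0
#'   renders thermal as pure noise).
#' @param dem_signal Line-stature amplitude of the DEM channel per sd of
#'   yield deviation (0 renders DEM uninformative about yield).
#' @param seed Integer seed; identical configurations give identical datasets.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 150,
                       n_markers = 200,
                       n_causal = 20,
                       maf_range = c(0.1, 0.5),
                       marker_missing_rate = 0.05,
                       het_rate = 0.03,
                       h2_target = 0.5,
                       n_trials = 6,
                       n_reps = 2,
                       trial_sd = 0.3,
                       residual_sd = NULL,
                       mean_yield = 6,
                       flight_dates = default_flight_dates(),
                       images_per_plot_per_date_mean = 3,
                       image_size = c(64, 64),
                       channel_set = c("multispectral", "thermal", "dem"),
                       thermal_signal = 0.4,
                       dem_signal = 0.15,
                       seed = 1L) {
  for (nm in c("n_lines", "n_markers", "n_causal", "n_trials", "n_reps")) {
    if (!is_count(get(nm))) stopf("%s must be a single non-negative integer", nm)
  }
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stopf("maf_range must be an increasing pair within (0, 0.5]")
  }
  for (nm in c("marker_missing_rate", "het_rate", "h2_target")) {
    if (!is_fraction(get(nm))) stopf("%s must lie in [0, 1]", nm)
  }
  if (n_causal > n_markers) stopf("n_causal (%d) exceeds n_markers (%d)",
                                  n_causal, n_markers)
  if (n_trials > n_lines) stopf("n_trials (%d) exceeds n_lines (%d)",
                                n_trials, n_lines)
  if (het_rate / 2 > maf_range[1]) {
    stopf("het_rate/2 must not exceed the lower MAF bound (marker-level genotype probabilities would be negative)")
  }
  flight_dates <- as.Date(flight_dates)
  if (length(flight_dates) == 0) stopf("flight_dates must be non-empty")
  if (any(diff(as.numeric(flight_dates)) <= 0)) {
    stopf("flight_dates must be strictly increasing")
  }
  if (length(image_size) != 2 || !all(vapply(image_size, is_count, TRUE)) ||
      any(image_size < 2)) {
    stopf("image_size must be two integers >= 2")
  }
  channel_set <- if (length(channel_set) == 0) character(0) else
    match.arg(channel_set, c("multispectral", "thermal", "dem"),
              several.ok = TRUE)
  if (is.null(residual_sd)) {
    if (h2_target <= 0) stopf("h2_target must be > 0 when residual_sd is derived")
    resid_var <- 1 / h2_target - 1 - trial_sd^2
    if (resid_var < 0) {
      stopf("h2_target %.2f unattainable with trial_sd %.2f (derived residual variance negative)",
            h2_target, trial_sd)
    }
    residual_sd <- sqrt(resid_var)
  }
  structure(list(n_lines = as.integer(n_lines),
                 n_markers = as.integer(n_markers),
                 n_causal = as.integer(n_causal),
                 maf_range = as.numeric(maf_range),
                 marker_missing_rate = marker_missing_rate,
                 het_rate = het_rate,
                 h2_target = h2_target,
                 n_trials = as.integer(n_trials),
                 n_reps = as.integer(n_reps),
                 trial_sd = trial_sd,
                 residual_sd = residual_sd,
                 mean_yield = mean_yield,
                 flight_dates = flight_dates,
                 images_per_plot_per_date_mean = images_per_plot_per_date_mean,
                 image_size = as.integer(image_size),
                 channel_set = channel_set,
                 thermal_signal = thermal_signal,
                 dem_signal = dem_signal,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d lines x %d markers (%d causal), h2=%.2f, ",
                     "%d trials x %d reps, %d flight dates, channels: %s, seed %d\n"),
              x$n_lines, x$n_markers, x$n_causal, x$h2_target, x$n_trials,
              x$n_reps, length(x$flight_dates),
              paste(x$channel_set, collapse = "/"), x$seed))
  invisible(x)
}

#' Default UAV flight calendar
#'
#' Eight irregularly spaced flights spanning a late-January to mid-March
#' growing window, matching the cadence of UAV campaigns over winter-sown
#' spring wheat.
#'
#' @return A `Date` vector.
#' @export
default_flight_dates <- function() {
  as.Date(c("2018-01-20", "2018-01-29", "2018-02-07", "2018-02-14",
            "2018-02-21", "2018-03-01", "2018-03-09", "2018-03-18"))
}

# Season geometry shared by the growth curve and the image renderer.
# t in [0,1] over the flight-date span; the mean canopy curve is logistic,
# the line-separation window w(d) is Gaussian and peaks at mid-season.
season_geometry <- function(flight_dates) {
  d <- as.numeric(flight_dates)
  span <- max(d) - min(d)
  if (span == 0) span <- 1
  t <- (d - min(d)) / span
  mean_curve <- 0.15 + 0.70 * stats::plogis((t - 0.45) / 0.12)
  w <- exp(-0.5 * ((t - 0.5) / 0.15)^2)
  cumgrow <- (mean_curve - mean_curve[1]) /
    max(mean_curve[length(mean_curve)] - mean_curve[1], 1e-12)
  list(t = t, mean_curve = mean_curve, w = w, cumgrow = cumgrow)
}

#' Simulate SNP genotypes for a breeding panel
#'
#' Draws a per-marker allele frequency uniformly from `cfg$maf_range` and
#' samples dosage calls from an inbred-line genotype model that preserves the
#' allele frequency exactly while fixing the expected heterozygosity at
#' `cfg$het_rate`: `P(1) = het_rate`, `P(2) = p - het_rate/2`,
#' `P(0) = 1 - p - het_rate/2` (Hardy-Weinberg sampling with inbreeding).
#' Missing calls are placed i.i.d. at `cfg$marker_missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 1))
  n <- cfg$n_lines
  m <- cfg$n_markers
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  h <- cfg$het_rate
  calls <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    probs <- c(1 - p[j] - h / 2, h, p[j] - h / 2)
    calls[, j] <- sample(0:2, n, replace = TRUE, prob = probs)
  }
  if (cfg$marker_missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < cfg$marker_missing_rate, n, m)
    calls[miss] <- NA_integer_
  }
  genotype_matrix(calls,
                  sprintf("L%04d", seq_len(n)),
                  sprintf("M%05d", seq_len(m)))
}

#' Simulate additive breeding values
#'
#' Chooses `cfg$n_causal` markers at random, draws zero-mean Gaussian effect
#' sizes, and computes each line's breeding value as the centered (mean
#' imputed) dosage times the effects, standardized to unit variance.
#'
#' @param G A [genotype_matrix()] for the panel.
#' @param cfg A [sim_config()].
#' @return A list of class `ground_truth` with `causal_marker_ids`,
#'   `effect_sizes` and per-line `g` (named by line id).
#' @export
simulate_breeding_values <- function(G, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_causal > length(G$marker_ids)) {
    stopf("n_causal (%d) exceeds the number of markers (%d)",
          cfg$n_causal, length(G$marker_ids))
  }
  set.seed(derive_seed(cfg$seed, 2))
  X <- impute_dosage(G)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  g <- rep(0, nrow(X))
  causal <- integer(0)
  effects <- numeric(0)
  if (cfg$n_causal > 0) {
    causal <- sort(sample(ncol(X), cfg$n_causal))
    effects <- stats::rnorm(cfg$n_causal)
    g <- drop(Xc[, causal, drop = FALSE] %*% effects)
    sdg <- stats::sd(g)
    if (sdg > 0) {
      g <- g / sdg
      effects <- effects / sdg
    }
  }
  names(g) <- G$line_ids
  structure(list(causal_marker_ids = G$marker_ids[causal],
                 effect_sizes = effects,
                 g = g),
            class = "ground_truth")
}

#' Simulate a replicated multi-trial field season
#'
#' Assigns each line to one trial, replicates it `cfg$n_reps` times, and
#' draws plot yields as `mean_yield + g + trial effect + residual` with the
#' configured variance components (t/ha). Also attaches the latent per-plot
#' canopy-health trajectory `s(d)` used by the image renderer: a logistic
#' mean growth curve shifted by the plot's standardized yield deviation
#' through a Gaussian mid-season separation window, clamped to `[0, 1]`.
#'
#' @param truth A `ground_truth` from [simulate_breeding_values()].
#' @param cfg A [sim_config()].
#' @return The `ground_truth` extended with `plots` (a data.frame with
#'   `plot_id`, `entry_id`, `trial_id`, `yield`), `trial_effects`,
#'   `ydev` (standardized plot deviations) and `s` (plots x dates latent
#'   health matrix).
#' @export
simulate_field_trial <- function(truth, cfg) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 3))
  n <- length(truth$g)
  line_ids <- names(truth$g)
  trial_of_line <- sample(rep(seq_len(cfg$n_trials), length.out = n))
  trial_ids <- sprintf("T%02d", seq_len(cfg$n_trials))
  trial_eff <- stats::rnorm(cfg$n_trials, 0, cfg$trial_sd)
  names(trial_eff) <- trial_ids

  rows <- n * cfg$n_reps
  entry <- rep(line_ids, each = cfg$n_reps)
  gline <- rep(truth$g, each = cfg$n_reps)
  trial <- rep(trial_ids[trial_of_line], each = cfg$n_reps)
  resid <- stats::rnorm(rows, 0, cfg$residual_sd)
  yield <- cfg$mean_yield + gline + trial_eff[trial] + resid
  plots <- data.frame(plot_id = sprintf("P%05d", seq_len(rows)),
                      entry_id = entry,
                      trial_id = trial,
                      yield = yield,
                      stringsAsFactors = FALSE)

  sdy <- stats::sd(yield)
  ydev <- if (is.na(sdy) || sdy == 0) rep(0, rows) else (yield - mean(yield)) / sdy
  geom <- season_geometry(cfg$flight_dates)
  # beta scales how far one sd of yield deviation moves the canopy curve
  beta <- 0.12
  s <- outer(rep(1, rows), geom$mean_curve) +
    beta * outer(ydev, geom$w)
  s <- clamp(s, 0, 1)
  dimnames(s) <- list(plots$plot_id, as.character(cfg$flight_dates))

  truth$plots <- plots
  truth$trial_effects <- trial_eff
  truth$ydev <- stats::setNames(ydev, plots$plot_id)
  truth$s <- s
  truth
}

# Programmed multispectral band means for latent health s: chosen so that the
# image-level NDVI of a noiseless image equals s exactly.
# Band order: blue, green, red, rededge, nir.
band_means_for_health <- function(s) {
  c(blue = 0.15,
    green = 0.25 * (1 - 0.7 * s),
    red = 0.25 * (1 - s),
    rededge = 0.25 * (1 - 0.5 * s),
    nir = 0.25 * (1 + s))
}

# Date-dependent sd of the image-level NDVI perturbation: smallest at the
# mid-season separation peak, 4x larger at the season edges.
ndvi_noise_sd <- function(w) 0.03 * (1 + 3 * (1 - w))

#' Render the image bag of one plot
#'
#' For each configured channel and flight date, draws a Poisson image count
#' and renders multi-band pixel arrays whose channel statistics track the
#' plot's latent health trajectory `s(d)`:
#' \itemize{
#' \item multispectral (5 bands, order blue/green/red/rededge/nir): band
#'   means are set so the image-level NDVI equals `s(d)` plus a
#'   date-dependent perturbation whose sd is smallest at mid-season, i.e.
#'   informativeness peaks at mid-growth;
#' \item thermal (1 band): canopy temperature proxy `0.7 - 0.4 s(d)` with the
#'   largest image-level noise of the three channels;
#' \item dem (1 band): plant height proxy proportional to cumulative growth,
#'   with a line-specific stature factor, hence informative late in the
#'   season.
#' }
#' Pixel-level texture noise (sd `pixel_noise`) is added to every band and
#' values are clamped to `[0, 1]`.
#'
#' @param plot_id A plot identifier present in `truth$plots`.
#' @param truth A `ground_truth` from [simulate_field_trial()].
#' @param cfg A [sim_config()].
#' @param pixel_noise Pixel texture noise sd (default 0.02).
#' @return A list of `image_instance` objects (possibly empty for a channel
#'   or date, emulating irregular acquisition).
#' @export
render_plot_images <- function(plot_id, truth, cfg, pixel_noise = 0.02) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$flight_dates) == 0) stopf("flight_dates must be non-empty")
  if (is.null(truth$s) || !(plot_id %in% rownames(truth$s))) {
    stopf("plot %s has no latent health trajectory; run simulate_field_trial()", plot_id)
  }
  idx <- match(plot_id, truth$plots$plot_id)
  set.seed(derive_seed(cfg$seed, 1000 + idx))
  geom <- season_geometry(cfg$flight_dates)
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  npx <- h * w
  ydev <- truth$ydev[[plot_id]]
  stature <- 1 + (cfg$dem_signal %||% 0.15) * ydev
  out <- list()
  for (channel in cfg$channel_set) {
    for (di in seq_along(cfg$flight_dates)) {
      date <- cfg$flight_dates[di]
      s_d <- truth$s[plot_id, di]
      n_img <- stats::rpois(1, cfg$images_per_plot_per_date_mean)
      if (n_img == 0) next
      for (k in seq_len(n_img)) {
        if (channel == "multispectral") {
          s_obs <- clamp(s_d + stats::rnorm(1, 0, ndvi_noise_sd(geom$w[di])), 0, 1)
          mu <- band_means_for_health(s_obs)
          px <- array(rep(mu, each = npx), dim = c(h, w, 5))
        } else if (channel == "thermal") {
          temp <- 0.7 - (cfg$thermal_signal %||% 0.4) * s_d +
            stats::rnorm(1, 0, 0.15)
          px <- array(temp, dim = c(h, w, 1))
        } else { # dem
          height <- 0.1 + 0.5 * geom$cumgrow[di] * stature +
            stats::rnorm(1, 0, 0.03)
          px <- array(height, dim = c(h, w, 1))
        }
        if (pixel_noise > 0) {
          px <- px + array(stats::rnorm(length(px), 0, pixel_noise), dim = dim(px))
        }
        px <- clamp(px, 0, 1)
        out[[length(out) + 1]] <- image_instance(channel, date, px)
      }
    }
  }
  out
}

#' Simulate a complete in-memory dataset
#'
#' Runs the full generative chain (genotypes, breeding values, field trial,
#' image rendering) and assembles one [plot_sample()] per plot, with the
#' line's mean-imputed dosage vector attached.
#'
#' @param cfg A [sim_config()].
#' @param pixel_noise Pixel texture noise sd passed to [render_plot_images()].
#' @return A list of class `sim_dataset` with elements `samples` (list of
#'   `plot_sample`), `genotypes` (the raw [genotype_matrix()]), `truth`
#'   (ground truth) and `config`.
#' @export
simulate_dataset <- function(cfg, pixel_noise = 0.02) {
  G <- simulate_genotypes(cfg)
  truth <- simulate_breeding_values(G, cfg)
  truth <- simulate_field_trial(truth, cfg)
  X <- impute_dosage(G)
  samples <- vector("list", nrow(truth$plots))
  for (i in seq_len(nrow(truth$plots))) {
    row <- truth$plots[i, ]
    imgs <- render_plot_images(row$plot_id, truth, cfg, pixel_noise)
    bags <- split_instances_by_channel(imgs)
    samples[[i]] <- plot_sample(plot_id = row$plot_id,
                                entry_id = row$entry_id,
                                trial_id = row$trial_id,
                                yield = row$yield,
                                bags = bags,
                                genotype = X[row$entry_id, ])
  }
  names(samples) <- truth$plots$plot_id
  structure(list(samples = samples, genotypes = G, truth = truth,
                 config = cfg),
            class = "sim_dataset")
}

#' Simulate a new environment sharing a genetic architecture
#'
#' Generates a fresh breeding population (new lines, newly drawn allele
#' frequencies and trial/residual effects) whose breeding values are driven
#' by the *same* causal markers and effect sizes as an existing ground
#' truth — the cross-environment prediction scenario: a model trained in
#' environment A is asked to rank the new lines of environment B from their
#' genotypes. Breeding values are not re-standardized, so the effect sizes
#' transfer unchanged.
#'
#' @param truth A `ground_truth` from [simulate_breeding_values()] (or a
#'   `sim_dataset$truth`) providing `causal_marker_ids` and `effect_sizes`.
#' @param cfg A [sim_config()] for the new environment; its marker panel
#'   must contain the causal markers (panels share marker naming when
#'   `n_markers` matches). `channel_set = character(0)` skips image
#'   rendering for genotype-only scenarios.
#' @param pixel_noise Pixel texture noise sd for rendered images.
#' @return A `sim_dataset` for the new environment.
#' @export
simulate_new_environment <- function(truth, cfg, pixel_noise = 0.02) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  G <- simulate_genotypes(cfg)
  found <- truth$causal_marker_ids %in% G$marker_ids
  if (!all(found)) {
    stopf("%d causal marker(s) absent from the new environment's panel",
          sum(!found))
  }
  X <- impute_dosage(G)
  Xc <- scale(X[, truth$causal_marker_ids, drop = FALSE],
              center = TRUE, scale = FALSE)
  g <- drop(Xc %*% truth$effect_sizes)
  names(g) <- G$line_ids
  truth_new <- structure(list(causal_marker_ids = truth$causal_marker_ids,
                              effect_sizes = truth$effect_sizes,
                              g = g),
                         class = "ground_truth")
  truth_new <- simulate_field_trial(truth_new, cfg)
  samples <- vector("list", nrow(truth_new$plots))
  for (i in seq_len(nrow(truth_new$plots))) {
    row <- truth_new$plots[i, ]
    imgs <- if (length(cfg$channel_set)) {
      render_plot_images(row$plot_id, truth_new, cfg, pixel_noise)
    } else {
      list()
    }
    samples[[i]] <- plot_sample(plot_id = row$plot_id,
                                entry_id = row$entry_id,
                                trial_id = row$trial_id,
                                yield = row$yield,
                                bags = split_instances_by_channel(imgs),
                                genotype = X[row$entry_id, ])
  }
  names(samples) <- truth_new$plots$plot_id
  structure(list(samples = samples, genotypes = G, truth = truth_new,
                 config = cfg),
            class = "sim_dataset")
}

split_instances_by_channel <- function(instances) {
  bags <- list(multispectral = list(), thermal = list(), dem = list())
  for (inst in instances) bags[[inst$channel]] <- c(bags[[inst$channel]], list(inst))
  bags
}

#' Write a simulated dataset to disk
#'
#' Materializes a dataset as the on-disk layout consumed by
#' [load_dataset()]: `genotypes.tsv`, `phenotypes.csv`, `groundtruth.json`,
#' one multi-page float TIFF per image (one page per band) under `images/`,
#' and `manifest.json` mapping each plot to its identifiers, yield, and
#' per-channel `(date, path)` image lists.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @param pixel_noise Pixel texture noise sd.
#' @return The manifest path, invisibly.
#' @export
generate_dataset <- function(cfg, out_dir, overwrite = FALSE,
                             pixel_noise = 0.02) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    stopf("output directory %s is non-empty; pass overwrite = TRUE", out_dir)
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_dataset(cfg, pixel_noise)
  write_genotype_tsv(ds$genotypes, file.path(out_dir, "genotypes.tsv"))
  utils::write.csv(ds$truth$plots, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  gt <- list(causal_marker_ids = ds$truth$causal_marker_ids,
             effect_sizes = ds$truth$effect_sizes,
             g = as.list(ds$truth$g),
             trial_effects = as.list(ds$truth$trial_effects),
             ydev = as.list(ds$truth$ydev),
             flight_dates = as.character(cfg$flight_dates),
             s = apply(ds$truth$s, 1, as.list, simplify = FALSE))
  jsonlite::write_json(gt, file.path(out_dir, "groundtruth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list()
  for (smp in ds$samples) {
    channels <- list()
    for (ch in names(smp$bags)) {
      entries <- list()
      for (i in seq_along(smp$bags[[ch]])) {
        inst <- smp$bags[[ch]][[i]]
        rel <- sprintf("images/%s_%s_%s_%02d.tif", smp$plot_id, ch,
                       format(inst$date, "%Y%m%d"), i)
        pages <- lapply(seq_len(dim(inst$pixels)[3]),
                        function(b) inst$pixels[, , b])
        tiff::writeTIFF(pages, file.path(out_dir, rel), bits.per.sample = 32L)
        entries[[i]] <- list(date = as.character(inst$date), path = rel)
      }
      channels[[ch]] <- entries
    }
    manifest[[smp$plot_id]] <- list(entry_id = smp$entry_id,
                                    trial_id = smp$trial_id,
                                    yield = smp$yield,
                                    channels = channels)
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
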