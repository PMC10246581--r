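test_that("genotype simulation honors shape, call domain and determinism", {
  cfg <- sim_config(n_lines = 50, n_markers = 100, n_causal = 10,
                    het_rate = 0, marker_missing_rate = 0, seed = 2)
  G <- simulate_genotypes(cfg)
  expect_equal(dim(G), c(50L, 100L))
  expect_true(all(G$calls %in% c(0L, 2L)))
  expect_false(anyNA(G$calls))
  G2 <- simulate_genotypes(cfg)
  expect_identical(G$calls, G2$calls)

  cfg3 <- sim_config(n_lines = 40, n_markers = 30, n_causal = 5,
                     het_rate = 0.1, maf_range = c(0.2, 0.5),
                     marker_missing_rate = 0.2, seed = 9)
  G3 <- simulate_genotypes(cfg3)
  expect_true(all(G3$calls[!is.na(G3$calls)] %in% 0:2))
  expect_gt(mean(is.na(G3$calls)), 0.15)
  expect_lt(mean(is.na(G3$calls)), 0.25)
})

test_that("empirical allele frequencies follow the programmed MAF", {
  # binomial sampling oracle: fully inbred lines carry two copies of one
  # allele draw, so the empirical frequency has standard error
  # sqrt(p(1-p)/n) over n lines; markers should sit within a few SE of p
  n <- 5000
  cfg <- sim_config(n_lines = n, n_markers = 40, n_causal = 0,
                    maf_range = c(0.3, 0.3), het_rate = 0,
                    marker_missing_rate = 0, seed = 4)
  G <- simulate_genotypes(cfg)
  freq <- colMeans(G$calls) / 2
  se <- sqrt(0.3 * 0.7 / n)
  expect_true(all(abs(freq - 0.3) < 4 * se))
  expect_lte(mean(abs(freq - 0.3) > 3 * se), 0.05)

  # heterozygosity sits at its programmed rate
  cfgh <- sim_config(n_lines = n, n_markers = 40, n_causal = 0,
                     maf_range = c(0.3, 0.3), het_rate = 0.08,
                     marker_missing_rate = 0, seed = 4)
  het <- marker_het_rate(simulate_genotypes(cfgh))
  expect_equal(mean(het), 0.08, tolerance = 0.01)
})

test_that("breeding values are additive, standardized and deterministic", {
  cfg <- sim_config(n_lines = 60, n_markers = 50, n_causal = 0, seed = 3)
  G <- simulate_genotypes(cfg)
  truth0 <- simulate_breeding_values(G, cfg)
  expect_true(all(truth0$g == 0))

  cfg2 <- sim_config(n_lines = 60, n_markers = 50, n_causal = 8, seed = 3)
  t1 <- simulate_breeding_values(G, cfg2)
  t2 <- simulate_breeding_values(G, cfg2)
  expect_identical(t1$g, t2$g)
  expect_equal(stats::sd(t1$g), 1, tolerance = 1e-8)
  expect_length(t1$causal_marker_ids, 8)
})

test_that("heritability and regression slope are recovered at scale", {
  # variance-ratio oracle: h2 = var(g) / var(yield) on the simulated plots
  cfg <- sim_config(n_lines = 1000, n_markers = 100, n_causal = 20,
                    n_reps = 2, n_trials = 10, h2_target = 0.5, seed = 6)
  G <- simulate_genotypes(cfg)
  truth <- simulate_breeding_values(G, cfg)
  truth <- simulate_field_trial(truth, cfg)
  g_plot <- truth$g[truth$plots$entry_id]
  ratio <- stats::var(g_plot) / stats::var(truth$plots$yield)
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
  slope <- unname(stats::coef(stats::lm(truth$plots$yield ~ g_plot))[2])
  expect_lt(abs(slope - 1), 0.1)
})

test_that("field trials replicate lines and realize the variance components", {
  # zero-noise case: replicate plots carry exactly mu + g
  cfg0 <- sim_config(n_lines = 100, n_markers = 30, n_causal = 5,
                     n_reps = 2, n_trials = 4, trial_sd = 0,
                     residual_sd = 0, seed = 8)
  G <- simulate_genotypes(cfg0)
  truth <- simulate_field_trial(simulate_breeding_values(G, cfg0), cfg0)
  expect_equal(nrow(truth$plots), 200)
  expect_false(anyDuplicated(truth$plots$plot_id) > 0)
  expected <- cfg0$mean_yield + truth$g[truth$plots$entry_id]
  expect_equal(truth$plots$yield, unname(expected))

  # one-way variance-decomposition oracle for the trial component
  cfg1 <- sim_config(n_lines = 400, n_markers = 30, n_causal = 5,
                     n_reps = 2, n_trials = 40, trial_sd = 1,
                     residual_sd = 0.5, seed = 8)
  G1 <- simulate_genotypes(cfg1)
  tr1 <- simulate_field_trial(simulate_breeding_values(G1, cfg1), cfg1)
  fit <- stats::aov(yield ~ trial_id, data = tr1$plots)
  ms <- summary(fit)[[1]]$`Mean Sq`
  n0 <- nrow(tr1$plots) / cfg1$n_trials
  sigma_trial2 <- (ms[1] - ms[2]) / n0
  expect_gt(sigma_trial2, 0.5)
  expect_lt(sigma_trial2, 1.7)
})

test_that("rendered multispectral images encode latent health in their NDVI", {
  cfg <- sim_config(n_lines = 40, n_markers = 30, n_causal = 5, n_trials = 2,
                    image_size = c(8, 8), channel_set = "multispectral",
                    images_per_plot_per_date_mean = 2, seed = 12)
  G <- simulate_genotypes(cfg)
  truth <- simulate_field_trial(simulate_breeding_values(G, cfg), cfg)
  pid <- truth$plots$plot_id[1]
  imgs <- render_plot_images(pid, truth, cfg, pixel_noise = 0)
  expect_gt(length(imgs), 0)
  errs <- vapply(imgs, function(im) {
    nir <- mean(im$pixels[, , 5]); red <- mean(im$pixels[, , 3])
    # structural invariant of the band programming at zero pixel noise
    expect_equal(nir + red, 0.5, tolerance = 1e-12)
    ndvi <- (nir - red) / (nir + red)
    di <- as.character(im$date)
    ndvi - truth$s[pid, di]
  }, 0)
  # recompute s(d) from truth: NDVI deviations stay within the programmed
  # date-dependent noise envelope (max sd 0.12, 5 sigma)
  expect_true(all(abs(errs) < 0.6))
  expect_lt(stats::sd(errs), 0.15)
})

test_that("single-band channels render one band and bags vary per date", {
  cfg <- sim_config(n_lines = 10, n_markers = 20, n_causal = 2, n_trials = 2,
                    image_size = c(4, 4), channel_set = "thermal", seed = 13)
  G <- simulate_genotypes(cfg)
  truth <- simulate_field_trial(simulate_breeding_values(G, cfg), cfg)
  imgs <- render_plot_images(truth$plots$plot_id[2], truth, cfg)
  expect_true(all(vapply(imgs, function(x) dim(x$pixels)[3], 0L) == 1L))
  expect_true(all(vapply(imgs, `[[`, "", "channel") == "thermal"))
})

test_that("image-yield correlation peaks at mid-season dates by construction", {
  cfg <- sim_config(n_lines = 300, n_reps = 2, n_markers = 30, n_causal = 5,
                    n_trials = 4, image_size = c(4, 4),
                    channel_set = "multispectral",
                    images_per_plot_per_date_mean = 1.5, seed = 14)
  ds <- simulate_dataset(cfg, pixel_noise = 0)
  dates <- as.character(cfg$flight_dates)
  cors <- vapply(dates, function(d) {
    vals <- vapply(ds$samples, function(s) {
      sel <- vapply(s$bags$multispectral, function(im) as.character(im$date) == d, TRUE)
      if (!any(sel)) return(NA_real_)
      mean(vapply(s$bags$multispectral[sel], function(im) {
        (mean(im$pixels[, , 5]) - mean(im$pixels[, , 3])) /
          (mean(im$pixels[, , 5]) + mean(im$pixels[, , 3]))
      }, 0))
    }, 0)
    y <- vapply(ds$samples, `[[`, 0, "yield")
    ok <- !is.na(vals)
    stats::cor(vals[ok], y[ok])
  }, 0)
  expect_true(which.max(cors) %in% 4:5)
})

test_that("datasets round-trip through disk and manifests are reproducible", {
  cfg <- sim_config(n_lines = 8, n_markers = 15, n_causal = 3, n_trials = 2,
                    image_size = c(4, 4),
                    flight_dates = as.Date(c("2018-02-01", "2018-02-20",
                                             "2018-03-10")),
                    images_per_plot_per_date_mean = 1, seed = 21)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  generate_dataset(cfg, dir1, overwrite = TRUE)
  generate_dataset(cfg, dir2, overwrite = TRUE)
  expect_identical(readBin(file.path(dir1, "manifest.json"), "raw", 1e6),
                   readBin(file.path(dir2, "manifest.json"), "raw", 1e6))
  expect_error(generate_dataset(cfg, dir1), "non-empty")

  ds <- simulate_dataset(cfg)
  loaded <- load_dataset(file.path(dir1, "manifest.json"),
                         file.path(dir1, "genotypes.tsv"))
  expect_setequal(names(loaded), names(ds$samples))
  pheno <- read_phenotypes(file.path(dir1, "phenotypes.csv"))
  expect_equal(length(loaded), nrow(pheno))
  for (pid in names(ds$samples)) {
    expect_equal(loaded[[pid]]$yield, ds$samples[[pid]]$yield,
                 tolerance = 1e-6)
    for (ch in c("multispectral", "thermal", "dem")) {
      expect_length(loaded[[pid]]$bags[[ch]], length(ds$samples[[pid]]$bags[[ch]]))
    }
    expect_equal(loaded[[pid]]$genotype, ds$samples[[pid]]$genotype,
                 tolerance = 1e-6)
  }
  # float TIFF pages preserve pixel values to single precision
  s1 <- ds$samples[[1]]$bags$multispectral[[1]]$pixels
  l1 <- loaded[[names(ds$samples)[1]]]$bags$multispectral[[1]]$pixels
  expect_equal(s1, l1, tolerance = 1e-6)
})

test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(sim_config(maf_range = c(0, 0.4)), "maf_range")
  expect_error(sim_config(n_causal = 50, n_markers = 20), "n_causal")
  expect_error(sim_config(n_trials = 30, n_lines = 10), "n_trials")
  expect_error(sim_config(flight_dates = as.Date(c("2018-02-01", "2018-01-01"))),
               "increasing")
  expect_error(sim_config(h2_target = 0.99, trial_sd = 2), "unattainable")
})
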