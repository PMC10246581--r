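VI_NAMES <- c("ndvi", "ndre", "gndvi")

#' Per-pixel vegetation index maps
#'
#' Computes NDVI = (NIR - Red) / (NIR + Red),
#' NDRE = (NIR - RedEdge) / (NIR + RedEdge) and
#' GNDVI = (NIR - Green) / (NIR + Green) from a 5-band multispectral
#' instance. Pixels whose denominator is zero are masked (`NA`) rather than
#' propagated as non-finite values.
#'
#' @param image A multispectral [image_instance()].
#' @return Named list of `height x width` matrices (`ndvi`, `ndre`, `gndvi`).
#' @export
compute_vegetation_indices <- function(image) {
  stopifnot(inherits(image, "image_instance"))
  if (image$channel != "multispectral") {
    stopf("vegetation indices require a multispectral instance, got %s",
          image$channel)
  }
  px <- image$pixels
  nir <- px[, , 5]; red <- px[, , 3]; rededge <- px[, , 4]; green <- px[, , 2]
  nd <- function(a, b) {
    den <- a + b
    out <- (a - b) / den
    out[den == 0] <- NA_real_
    out
  }
  list(ndvi = nd(nir, red), ndre = nd(nir, rededge), gndvi = nd(nir, green))
}

# Mode of a continuous pixel distribution: center of the most populated of
# n_bins equal-width bins over the observed range; ties break to the lowest
# bin; a constant input returns that constant.
pixel_mode <- function(v, n_bins = 256) {
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(lo)
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  best <- which.max(counts)          # which.max takes the first (lowest) tie
  lo + (best - 0.5) * (hi - lo) / n_bins
}

#' Channel and vegetation-index moments of one image
#'
#' For a multispectral instance, returns the 16 baseline features: mean and
#' mode of each of the 5 bands plus mean and mode of each of the 3
#' vegetation-index maps. For single-band instances, returns the band's mean
#' and mode.
#'
#' @param image An [image_instance()].
#' @param n_bins Histogram bins for the mode (default 256).
#' @return Named numeric vector (length 16 for multispectral, 2 otherwise).
#' @export
channel_moments <- function(image, n_bins = 256) {
  stopifnot(inherits(image, "image_instance"))
  px <- image$pixels
  if (image$channel == "multispectral") {
    vis <- compute_vegetation_indices(image)
    band_mean <- vapply(1:5, function(b) mean(px[, , b]), 0)
    band_mode <- vapply(1:5, function(b) pixel_mode(px[, , b], n_bins), 0)
    vi_mean <- vapply(vis, function(m) mean(m, na.rm = TRUE), 0)
    vi_mode <- vapply(vis, function(m) pixel_mode(m, n_bins), 0)
    stats::setNames(c(band_mean, band_mode, vi_mean, vi_mode),
                    c(paste0("mean_", MS_BANDS), paste0("mode_", MS_BANDS),
                      paste0("mean_", VI_NAMES), paste0("mode_", VI_NAMES)))
  } else {
    stats::setNames(c(mean(px), pixel_mode(px, n_bins)),
                    paste0(c("mean_", "mode_"), image$channel))
  }
}

#' Define a temporal date grouping
#'
#' Ordered, non-overlapping inclusive date ranges used to aggregate image
#' features by growth stage.
#'
#' @param starts,ends Equal-length `Date` vectors of inclusive group bounds.
#' @return An object of class `date_grouping`.
#' @export
date_grouping <- function(starts, ends) {
  starts <- as.Date(starts); ends <- as.Date(ends)
  if (length(starts) != length(ends) || length(starts) == 0) {
    stopf("starts and ends must be non-empty and equal length")
  }
  if (any(ends < starts)) stopf("each group end must be on or after its start")
  if (any(utils::head(ends, -1) >= utils::tail(starts, -1))) {
    stopf("date groups must be non-overlapping and increasing")
  }
  structure(list(starts = starts, ends = ends, n_groups = length(starts)),
            class = "date_grouping")
}

#' The 2018 Obregon season date grouping
#'
#' The four named growth-stage windows used for the 2017-2018 field season:
#' 18-31 January, 1 February - 2 March, 3-10 March, 11-21 March 2018,
#' roughly tracking vegetative growth, flowering, grain filling and
#' maturity.
#'
#' @return A [date_grouping()] with four groups.
#' @export
season2018_grouping <- function() {
  date_grouping(starts = as.Date(c("2018-01-18", "2018-02-01",
                                   "2018-03-03", "2018-03-11")),
                ends = as.Date(c("2018-01-31", "2018-03-02",
                                 "2018-03-10", "2018-03-21")))
}

#' Build a quantile-balanced grouping from observed dates
#'
#' Splits the distinct observed dates into `n_groups` contiguous groups of
#' near-equal size (sizes differ by at most one date).
#'
#' @param dates Observed acquisition dates.
#' @param n_groups Number of groups (default 4).
#' @return A [date_grouping()].
#' @export
quantile_grouping <- function(dates, n_groups = 4) {
  u <- sort(unique(as.Date(dates)))
  if (length(u) < n_groups) n_groups <- length(u)
  grp <- floor((seq_along(u) - 1) * n_groups / length(u)) + 1
  date_grouping(starts = as.Date(tapply(u, grp, min), origin = "1970-01-01"),
                ends = as.Date(tapply(u, grp, max), origin = "1970-01-01"))
}

#' Assign dates to temporal groups
#'
#' Maps each date to the group whose inclusive range contains it. With
#' `grouping = "quantile-default"` a four-group quantile-balanced grouping is
#' built from the supplied dates; `"season2018"` uses the shipped
#' [season2018_grouping()] preset.
#'
#' @param dates Dates to assign.
#' @param grouping A [date_grouping()], `"quantile-default"`, or
#'   `"season2018"`.
#' @return Integer group labels, one per date.
#' @export
assign_date_groups <- function(dates, grouping = "quantile-default") {
  dates <- as.Date(dates)
  grouping <- resolve_grouping(grouping, dates)
  labels <- integer(length(dates))
  for (i in seq_along(dates)) {
    hit <- which(dates[i] >= grouping$starts & dates[i] <= grouping$ends)
    if (length(hit) == 0) {
      stopf("date %s falls outside every date group (%s .. %s)",
            format(dates[i]), format(min(grouping$starts)),
            format(max(grouping$ends)))
    }
    labels[i] <- hit[1]
  }
  labels
}

resolve_grouping <- function(grouping, dates = NULL) {
  if (inherits(grouping, "date_grouping")) return(grouping)
  if (identical(grouping, "quantile-default")) {
    if (is.null(dates) || length(dates) == 0) {
      stopf("quantile-default grouping needs observed dates")
    }
    return(quantile_grouping(dates))
  }
  if (identical(grouping, "season2018")) return(season2018_grouping())
  stopf("unknown grouping specification")
}

#' Baseline feature vector of one plot
#'
#' Averages the 16 per-image moment-and-VI features of a plot's
#' multispectral images within each date group. `scope = "all"` concatenates
#' the four group vectors (length 64); `scope = "g1" .. "g4"` returns the 16
#' features of a single group. Groups without images yield masked (`NA`)
#' entries, to be imputed at fit time.
#'
#' @param sample A [plot_sample()] with at least one multispectral image.
#' @param grouping Passed to [assign_date_groups()]; when
#'   `"quantile-default"`, the grouping is built from the sample's own dates,
#'   so prefer passing a fixed [date_grouping()] when featurizing a dataset.
#' @param scope `"all"` or `"g<k>"`.
#' @param n_bins Histogram bins for the mode.
#' @return Named numeric vector of length 16 or `16 * n_groups`.
#' @export
plot_feature_vector <- function(sample, grouping = "quantile-default",
                                scope = "all", n_bins = 256) {
  stopifnot(inherits(sample, "plot_sample"))
  imgs <- sample$bags$multispectral
  if (length(imgs) == 0) {
    stopf("plot %s has no multispectral images; baseline features undefined",
          sample$plot_id)
  }
  dates <- as.Date(vapply(imgs, function(x) as.character(x$date), ""))
  grouping <- resolve_grouping(grouping, dates)
  labels <- assign_date_groups(dates, grouping)
  feats <- t(vapply(imgs, channel_moments, numeric(16), n_bins = n_bins))
  per_group <- lapply(seq_len(grouping$n_groups), function(g) {
    rows <- which(labels == g)
    if (length(rows) == 0) {
      stats::setNames(rep(NA_real_, 16), colnames(feats))
    } else {
      colMeans(feats[rows, , drop = FALSE])
    }
  })
  if (identical(scope, "all")) {
    out <- unlist(lapply(seq_along(per_group), function(g) {
      stats::setNames(per_group[[g]], paste0("g", g, "_", names(per_group[[g]])))
    }))
    return(out)
  }
  g <- suppressWarnings(as.integer(sub("^g", "", scope)))
  if (is.na(g) || g < 1 || g > grouping$n_groups) {
    stopf("scope must be 'all' or 'g1'..'g%d'", grouping$n_groups)
  }
  per_group[[g]]
}

#' Baseline feature table for a set of plots
#'
#' Applies [plot_feature_vector()] to every sample, using one shared
#' grouping; plots without multispectral images are dropped with a warning.
#'
#' @param samples List of [plot_sample()] objects.
#' @param grouping A [date_grouping()] or preset name; the default builds a
#'   quantile grouping from all observed multispectral dates.
#' @param scope `"all"` or `"g<k>"`.
#' @param n_bins Histogram bins for the mode.
#' @return List with `features` (matrix, rownames = plot ids), `yields`
#'   (named numeric) and `grouping`.
#' @export
feature_table <- function(samples, grouping = "quantile-default",
                          scope = "all", n_bins = 256) {
  all_dates <- unlist(lapply(samples, function(s) {
    vapply(s$bags$multispectral, function(x) as.character(x$date), "")
  }))
  grouping <- resolve_grouping(grouping, as.Date(all_dates))
  usable <- vapply(samples, function(s) length(s$bags$multispectral) > 0, TRUE)
  if (!all(usable)) {
    warnf("%d plot(s) without multispectral images dropped from the feature table",
          sum(!usable))
  }
  samples <- samples[usable]
  rows <- lapply(samples, plot_feature_vector, grouping = grouping,
                 scope = scope, n_bins = n_bins)
  features <- do.call(rbind, rows)
  rownames(features) <- vapply(samples, `[[`, "", "plot_id")
  yields <- vapply(samples, `[[`, 0, "yield")
  names(yields) <- rownames(features)
  list(features = features, yields = yields, grouping = grouping)
}

#' Fit a baseline yield regressor
#'
#' Fits either an L1-regularized linear model (`"l1-linear"`, glmnet lasso
#' with the penalty chosen by internal cross-validation) or a random forest
#' (`"forest"`, ranger, with `mtry` and `min.node.size` tuned by internal
#' cross-validation on the training rows only). Masked (`NA`) features are
#' imputed with training-set column means; the means are stored and reused
#' at prediction time.
#'
#' @param features Numeric matrix (plots x features), `NA` allowed.
#' @param yields Numeric response aligned with `features` rows.
#' @param kind `"l1-linear"` or `"forest"`.
#' @param nfolds Internal CV folds (default 5).
#' @param seed RNG seed for fold assignment and the forest.
#' @return An object of class `baseline_model` with a [predict()] method.
#' @export
fit_baseline <- function(features, yields, kind = c("l1-linear", "forest"),
                         nfolds = 5, seed = 1) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  if (nrow(features) != length(yields)) {
    stopf("features (%d rows) and yields (%d) are not aligned",
          nrow(features), length(yields))
  }
  col_means <- colMeans(features, na.rm = TRUE)
  col_means[!is.finite(col_means)] <- 0
  X <- impute_feature_matrix(features, col_means)
  set.seed(derive_seed(seed, 11))
  if (kind == "l1-linear") {
    cv <- glmnet::cv.glmnet(X, yields, alpha = 1, nfolds = nfolds)
    fit <- list(cv = cv, lambda = cv$lambda.min)
  } else {
    p <- ncol(X)
    grid <- expand.grid(mtry = unique(pmax(1, round(c(sqrt(p), p / 3, p / 2)))),
                        min.node.size = c(3, 5, 10))
    folds <- sample(rep(seq_len(nfolds), length.out = nrow(X)))
    cv_mse <- vapply(seq_len(nrow(grid)), function(i) {
      errs <- vapply(seq_len(nfolds), function(k) {
        tr <- folds != k
        rf <- ranger::ranger(x = X[tr, , drop = FALSE], y = yields[tr],
                             num.trees = 300, mtry = grid$mtry[i],
                             min.node.size = grid$min.node.size[i],
                             seed = derive_seed(seed, 100 + i))
        mean((stats::predict(rf, X[!tr, , drop = FALSE])$predictions -
                yields[!tr])^2)
      }, 0)
      mean(errs)
    }, 0)
    best <- grid[which.min(cv_mse), ]
    fit <- list(forest = ranger::ranger(x = X, y = yields, num.trees = 500,
                                        mtry = best$mtry,
                                        min.node.size = best$min.node.size,
                                        seed = derive_seed(seed, 12)),
                tuned = best, cv_mse = cv_mse)
  }
  structure(list(kind = kind, fit = fit, col_means = col_means,
                 feature_names = colnames(features)),
            class = "baseline_model")
}

impute_feature_matrix <- function(X, col_means) {
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- col_means[idx[, 2]]
  X
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  X <- impute_feature_matrix(X, object$col_means)
  if (object$kind == "l1-linear") {
    drop(stats::predict(object$fit$cv, newx = X, s = object$fit$lambda))
  } else {
    stats::predict(object$fit$forest, X)$predictions
  }
}
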