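#' Attention mass by data channel
#'
#' Runs the model over the samples with full bags (no subsampling) and sums
#' the per-head attention weights over the instances of each data source
#' (the genotype instance is its own category). Per sample and head the
#' channel masses form a partition of unity; the summary reports their mean
#' over samples, per head and averaged across heads.
#'
#' @param model A [mil_model()].
#' @param samples List of [plot_sample()] objects.
#' @return A list of class `attention_summary` with `channel_mass`
#'   (`n_heads x 4` matrix of mean masses), `head_mean` (length-4 vector),
#'   `per_sample` (`samples x heads x channels` array) and `n_samples`.
#' @export
attention_by_channel <- function(model, samples) {
  stopifnot(inherits(model, "mil_model"))
  n_heads <- model$config$n_heads
  per_sample <- array(0, c(length(samples), n_heads, length(ALL_SOURCES)),
                      dimnames = list(NULL, NULL, ALL_SOURCES))
  for (i in seq_along(samples)) {
    res <- predict_yield(samples[[i]], model, return_attention = TRUE)
    for (h in seq_len(n_heads)) {
      mass <- tapply(res$attention[[h]], res$provenance$channel, sum)
      per_sample[i, h, names(mass)] <- mass
    }
  }
  channel_mass <- apply(per_sample, c(2, 3), mean)
  structure(list(channel_mass = channel_mass,
                 head_mean = colMeans(channel_mass),
                 per_sample = per_sample,
                 n_samples = length(samples)),
            class = "attention_summary")
}

#' Attention mass by acquisition date
#'
#' Considers dated (image) instances only and renormalizes their attention
#' weights within each head and sample, so the genotype instance does not
#' dilute the temporal picture. Reports the mean per-date mass per head,
#' both over all image instances and within each image channel.
#'
#' @param model A [mil_model()].
#' @param samples List of [plot_sample()] objects.
#' @return A list of class `attention_summary` with `dates`, `date_mass`
#'   (`n_heads x n_dates`, mean over samples with dated instances),
#'   `channel_date_mass` (named list of `n_heads x n_dates` matrices, one
#'   per image channel, masses renormalized within that channel) and
#'   `n_samples`. Empty when no sample has dated instances.
#' @export
attention_by_date <- function(model, samples) {
  stopifnot(inherits(model, "mil_model"))
  n_heads <- model$config$n_heads
  all_dates <- sort(unique(unlist(lapply(samples, function(s) {
    unlist(lapply(s$bags, function(b) {
      vapply(b, function(x) as.character(x$date), "")
    }))
  }))))
  if (length(all_dates) == 0) {
    return(structure(list(dates = as.Date(character(0)),
                          date_mass = matrix(0, n_heads, 0),
                          channel_date_mass = list(), n_samples = 0L),
                     class = "attention_summary"))
  }
  D <- length(all_dates)
  acc <- matrix(0, n_heads, D, dimnames = list(NULL, all_dates))
  acc_n <- 0
  ch_acc <- list()
  ch_n <- list()
  for (smp in samples) {
    res <- predict_yield(smp, model, return_attention = TRUE)
    dated <- !is.na(res$provenance$date)
    if (!any(dated)) next
    acc_n <- acc_n + 1
    for (h in seq_len(n_heads)) {
      wts <- res$attention[[h]][dated]
      wts <- wts / sum(wts)
      mass <- tapply(wts, res$provenance$date[dated], sum)
      acc[h, names(mass)] <- acc[h, names(mass)] + mass
    }
    for (ch in unique(res$provenance$channel[dated])) {
      sel <- dated & res$provenance$channel == ch
      if (is.null(ch_acc[[ch]])) {
        ch_acc[[ch]] <- matrix(0, n_heads, D, dimnames = list(NULL, all_dates))
        ch_n[[ch]] <- 0
      }
      ch_n[[ch]] <- ch_n[[ch]] + 1
      for (h in seq_len(n_heads)) {
        wts <- res$attention[[h]][sel]
        wts <- wts / sum(wts)
        mass <- tapply(wts, res$provenance$date[sel], sum)
        ch_acc[[ch]][h, names(mass)] <- ch_acc[[ch]][h, names(mass)] + mass
      }
    }
  }
  for (ch in names(ch_acc)) ch_acc[[ch]] <- ch_acc[[ch]] / ch_n[[ch]]
  structure(list(dates = as.Date(all_dates),
                 date_mass = if (acc_n > 0) acc / acc_n else acc,
                 channel_date_mass = ch_acc,
                 n_samples = acc_n),
            class = "attention_summary")
}

#' Summarize date-level attention into temporal groups
#'
#' Sums a per-date attention-mass matrix from [attention_by_date()] into
#' the groups of a [date_grouping()], averaged across heads.
#'
#' @param summary An `attention_summary` from [attention_by_date()].
#' @param grouping A [date_grouping()] (or preset accepted by
#'   [assign_date_groups()]).
#' @param channel Image channel to summarize, or `NULL` for the overall
#'   dated mass.
#' @return Named numeric vector of group masses (head-mean), summing to 1.
#' @export
attention_mass_by_group <- function(summary, grouping = "quantile-default",
                                    channel = NULL) {
  mass <- if (is.null(channel)) summary$date_mass
          else summary$channel_date_mass[[channel]]
  if (is.null(mass) || ncol(mass) == 0) stopf("no dated attention mass available")
  grouping <- resolve_grouping(grouping, summary$dates)
  labels <- assign_date_groups(summary$dates, grouping)
  head_mean <- colMeans(mass)
  out <- tapply(head_mean, labels, sum)
  full <- stats::setNames(rep(0, grouping$n_groups),
                          paste0("g", seq_len(grouping$n_groups)))
  full[paste0("g", names(out))] <- out
  full
}

#' Selection-gain curve
#'
#' For each selection fraction `f`, selects the `ceiling(f * N)` entries
#' with the highest predicted yield (ties broken by ascending id for
#' reproducibility) and reports the mean *observed* yield of the selected
#' set — the realized gain a breeder would obtain by advancing the top-`f`
#' fraction of the ranking. At `f = 1` the value equals the population
#' mean.
#'
#' @param predictions,observations Aligned (typically entry-level) vectors.
#' @param fractions Selection fractions in `(0, 1]` (default 0.05 to 0.40
#'   by 0.05).
#' @param ids Optional identifiers for tie-breaking (defaults to
#'   `names(predictions)` or index order).
#' @return A data.frame of class `selection_curve` with `fraction`,
#'   `n_selected`, `mean_yield`.
#' @export
selection_gain_curve <- function(predictions, observations,
                                 fractions = seq(0.05, 0.40, by = 0.05),
                                 ids = NULL) {
  if (length(predictions) != length(observations)) {
    stopf("predictions and observations are not aligned")
  }
  if (any(fractions <= 0) || any(fractions > 1)) {
    stopf("selection fractions must lie in (0, 1]")
  }
  ids <- ids %||% names(predictions) %||% as.character(seq_along(predictions))
  ord <- order(-predictions, ids)
  n <- length(predictions)
  out <- data.frame(fraction = fractions,
                    n_selected = pmin(ceiling(fractions * n), n))
  out$mean_yield <- vapply(out$n_selected, function(k) {
    mean(observations[ord[seq_len(k)]])
  }, 0)
  class(out) <- c("selection_curve", "data.frame")
  out
}
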