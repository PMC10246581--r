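#' Model configuration
#'
#' Architecture and bag-handling choices for the multi-modal attention-MIL
#' yield model: per-source encoders map every instance (image or genotype)
#' to a 256-dimensional embedding; optional one-hot date and channel
#' encodings are appended; a multi-head tanh-gated attention pooling
#' combines all instance embeddings of a sample into one vector per head;
#' the concatenated head outputs feed a final fully connected regressor.
#'
#' @param channels Data sources to use, subset of
#'   `c("multispectral", "thermal", "dem", "genotype")`.
#' @param embedding_dim Instance embedding dimension (default 256).
#' @param genotype_hidden Hidden widths of the genotype encoder (default
#'   `c(1024, 512)`).
#' @param n_heads Number of attention heads (search grid: 1, 4, 8).
#' @param bag_size Maximum images sampled per channel per training
#'   iteration (search grid: 8, 16, 32); all instances are used at
#'   inference.
#' @param temporal_encoding Append a one-hot date block to image embeddings
#'   (genotype instances get an all-zero block); unseen dates map to a
#'   reserved "other" slot.
#' @param channel_encoding Append a one-hot data-source block.
#' @param attention_width Hidden width `l` of the attention gate.
#' @param encoder_scale `"tiny"` (pooled band statistics through a small
#'   MLP; the desk-scale default) or `"resnet"` (residual CNN on raw
#'   pixels).
#' @param regressor_hidden Hidden width of the final regressor.
#' @param tiny_hidden Hidden width of the tiny image encoder.
#' @param conv_base_width,conv_blocks Residual CNN width/depth;
#'   `conv_blocks = c(2, 2, 2, 2)` with `conv_base_width = 64` gives the
#'   full 18-layer residual layout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(channels = c("multispectral", "thermal", "dem",
                                      "genotype"),
                         embedding_dim = 256,
                         genotype_hidden = c(1024, 512),
                         n_heads = 4,
                         bag_size = 16,
                         temporal_encoding = TRUE,
                         channel_encoding = TRUE,
                         attention_width = 128,
                         encoder_scale = c("tiny", "resnet"),
                         regressor_hidden = 128,
                         tiny_hidden = 64,
                         conv_base_width = 16,
                         conv_blocks = c(2, 2)) {
  channels <- match.arg(channels, ALL_SOURCES, several.ok = TRUE)
  encoder_scale <- match.arg(encoder_scale)
  if (!is_count(n_heads) || n_heads < 1) stopf("n_heads must be a positive integer")
  if (!is_count(bag_size) || bag_size < 1) stopf("bag_size must be a positive integer")
  structure(list(channels = channels,
                 embedding_dim = as.integer(embedding_dim),
                 genotype_hidden = as.integer(genotype_hidden),
                 n_heads = as.integer(n_heads),
                 bag_size = as.integer(bag_size),
                 temporal_encoding = isTRUE(temporal_encoding),
                 channel_encoding = isTRUE(channel_encoding),
                 attention_width = as.integer(attention_width),
                 encoder_scale = encoder_scale,
                 regressor_hidden = as.integer(regressor_hidden),
                 tiny_hidden = as.integer(tiny_hidden),
                 conv_base_width = as.integer(conv_base_width),
                 conv_blocks = as.integer(conv_blocks)),
            class = "model_config")
}

IMAGE_BANDS <- c(multispectral = 5L, thermal = 1L, dem = 1L)

# Pooled per-band statistics feeding the tiny image encoder: mean, sd and
# the four quadrant means of every band.
image_stats <- function(pixels) {
  d <- dim(pixels)
  hs <- seq_len(ceiling(d[1] / 2)); ws <- seq_len(ceiling(d[2] / 2))
  unlist(lapply(seq_len(d[3]), function(b) {
    band <- pixels[, , b]
    c(mean(band), stats::sd(as.vector(band)),
      mean(band[hs, ws]), mean(band[hs, -ws]),
      mean(band[-hs, ws]), mean(band[-hs, -ws]))
  }))
}

#' Build a multi-modal attention-MIL yield model
#'
#' Initializes all weights (per-channel image encoders, genotype encoder,
#' attention heads, final regressor) from a seed. The date vocabulary and
#' marker list are frozen into the model at construction and stored in
#' checkpoints so that new data can be harmonized.
#'
#' @param config A [model_config()].
#' @param marker_ids Character vector of SNP marker ids the genotype encoder
#'   is trained on (required when `"genotype"` is among the channels).
#' @param marker_means Training-set mean dosage per marker, used to fill
#'   markers absent from new datasets (see [harmonize_markers()]).
#' @param date_vocab Training flight dates (coerced to character); the
#'   temporal one-hot has one slot per date plus a reserved "other" slot for
#'   unseen dates.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mil_model`.
#' @export
mil_model <- function(config = model_config(), marker_ids = NULL,
                      marker_means = NULL, date_vocab = character(0),
                      seed = 1) {
  stopifnot(inherits(config, "model_config"))
  set.seed(derive_seed(seed, 21))
  date_vocab <- as.character(date_vocab)
  m <- config$embedding_dim
  m_aug <- m +
    (if (config$temporal_encoding) length(date_vocab) + 1L else 0L) +
    (if (config$channel_encoding) length(ALL_SOURCES) else 0L)

  arch <- list()
  params <- list(encoders = list())
  for (ch in intersect(config$channels, CHANNEL_TAGS)) {
    bands <- IMAGE_BANDS[[ch]]
    if (config$encoder_scale == "tiny") {
      mlp <- mlp_init(c(6 * bands, config$tiny_hidden, m), act = "relu")
      arch[[ch]] <- list(type = "tiny", mlp = mlp)
      params$encoders[[ch]] <- mlp_params(mlp)
    } else {
      enc <- conv_encoder_init(bands, m, config$conv_base_width,
                               config$conv_blocks)
      arch[[ch]] <- list(type = "conv", enc = enc)
      params$encoders[[ch]] <- enc$params
    }
  }
  if ("genotype" %in% config$channels) {
    if (is.null(marker_ids)) stopf("marker_ids required for a genotype channel")
    mlp <- mlp_init(c(length(marker_ids), config$genotype_hidden, m),
                    act = "relu")
    arch$genotype <- list(type = "mlp", mlp = mlp)
    params$encoders$genotype <- mlp_params(mlp)
  }
  params$heads <- lapply(seq_len(config$n_heads), function(i) {
    list(V = t(init_weight(m_aug, config$attention_width, "tanh")),
         w = drop(init_weight(config$attention_width, 1, "tanh")))
  })
  reg <- mlp_init(c(config$n_heads * m_aug, config$regressor_hidden, 1),
                  act = "relu")
  arch$regressor <- reg
  params$regressor <- mlp_params(reg)

  structure(list(config = config, arch = arch, params = params,
                 marker_ids = marker_ids, marker_means = marker_means,
                 date_vocab = date_vocab, m_aug = m_aug,
                 version = "yieldmil-checkpoint-1"),
            class = "mil_model")
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("mil_model: channels %s | %d heads | embed %d (+%d encodings) | %s encoder | %d dates | %s markers\n",
              paste(x$config$channels, collapse = "/"), x$config$n_heads,
              x$config$embedding_dim, x$m_aug - x$config$embedding_dim,
              x$config$encoder_scale, length(x$date_vocab),
              if (is.null(x$marker_ids)) "no" else length(x$marker_ids)))
  invisible(x)
}

#' Attention parameters
#'
#' The gate of one attention head: scores are
#' `s_i = w' tanh(V h_i')` and weights `a_i = softmax(s)_i`, so `V` is
#' `l x m` and `w` has length `l` for embeddings of dimension `m`.
#'
#' @param V Numeric `l x m` matrix.
#' @param w Numeric length-`l` vector.
#' @return An object of class `attention_params`.
#' @export
attention_params <- function(V, w) {
  V <- as.matrix(V)
  w <- as.numeric(w)
  if (nrow(V) != length(w)) stopf("V has %d rows but w has length %d",
                                  nrow(V), length(w))
  if (!all(is.finite(V)) || !all(is.finite(w))) stopf("attention parameters must be finite")
  structure(list(V = V, w = w), class = "attention_params")
}

#' Attention-based MIL pooling
#'
#' Pools a bag of `k` instance embeddings into one vector:
#' `a_i = exp(w' tanh(V h_i')) / sum_j exp(w' tanh(V h_j'))`,
#' `z = sum_i a_i h_i`. The softmax is computed with max-subtraction for
#' numerical stability. The weights are nonnegative and sum to one, and the
#' result is invariant to the ordering of the rows of `H`.
#'
#' @param H Numeric `k x m` matrix of embeddings (rows are instances), or a
#'   single embedding vector.
#' @param params An [attention_params()] object.
#' @return A list of class `attention_result` with `z` (pooled vector,
#'   length `m`) and `weights` (length `k`, summing to 1).
#' @export
attention_pool <- function(H, params) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1)
  stopifnot(inherits(params, "attention_params"))
  if (ncol(H) != ncol(params$V)) {
    stopf("embedding dim %d does not match attention V with %d columns",
          ncol(H), ncol(params$V))
  }
  if (nrow(H) < 1) stopf("attention pooling needs at least one instance")
  Tm <- tanh(H %*% t(params$V))          # k x l
  s <- drop(Tm %*% params$w)             # k
  a <- softmax_stable(s)
  z <- drop(crossprod(H, a))
  structure(list(z = z, weights = a, scores = s, gate = Tm),
            class = "attention_result")
}

#' Multi-head attention pooling
#'
#' Pools the same bag independently with each head and concatenates the
#' pooled vectors (output length `n_heads * m`).
#'
#' @param H Numeric `k x m` embedding matrix.
#' @param heads List of [attention_params()], one per head.
#' @return List with `pooled` (concatenated vector) and `heads` (per-head
#'   [attention_pool()] results).
#' @export
multi_head_pool <- function(H, heads) {
  if (length(heads) < 1) stopf("at least one attention head is required")
  results <- lapply(heads, function(p) attention_pool(H, p))
  list(pooled = unlist(lapply(results, `[[`, "z"), use.names = FALSE),
       heads = results)
}

#' Encode images to fixed-size embeddings
#'
#' Applies the model's channel-specific encoder. With the `"tiny"` scale,
#' pooled per-band statistics pass through a small MLP; with `"resnet"`,
#' raw pixels pass through the residual CNN (single-band channels first go
#' through a learned 1x1 channel adapter). Deterministic in evaluation;
#' a batch (list) of images equals the row-stack of single-image calls.
#'
#' @param image An [image_instance()] or a list of them (all same channel).
#' @param model A [mil_model()].
#' @return A length-256 embedding vector, or a `k x 256` matrix for a list.
#' @export
encode_image <- function(image, model) {
  if (inherits(image, "image_instance")) {
    return(drop(encode_image_batch(list(image), model)$E))
  }
  encode_image_batch(image, model)$E
}

encode_image_batch <- function(images, model) {
  ch <- images[[1]]$channel
  if (!all(vapply(images, `[[`, "", "channel") == ch)) {
    stopf("a batch must contain a single channel")
  }
  arch <- model$arch[[ch]]
  if (is.null(arch)) stopf("model has no encoder for channel %s", ch)
  if (arch$type == "tiny") {
    S <- t(vapply(images, function(im) image_stats(im$pixels),
                  numeric(6 * IMAGE_BANDS[[ch]])))
    mlp <- mlp_set_params(arch$mlp, model$params$encoders[[ch]])
    fw <- mlp_forward(mlp, S)
    list(E = fw$out, cache = list(type = "tiny", mlp_cache = fw$cache))
  } else {
    enc <- arch$enc
    enc$params <- model$params$encoders[[ch]]
    caches <- vector("list", length(images))
    E <- matrix(0, length(images), model$config$embedding_dim)
    for (i in seq_along(images)) {
      fw <- conv_encoder_forward(enc, images[[i]]$pixels)
      E[i, ] <- fw$embedding
      caches[[i]] <- fw$cache
    }
    list(E = E, cache = list(type = "conv", conv_caches = caches))
  }
}

#' Encode a genotype dosage vector
#'
#' Passes an imputed, fixed-length dosage vector through the genotype
#' encoder (fully connected, hidden widths 1024 and 512 by default, output
#' 256). The vector must match the model's trained marker set; use
#' [harmonize_markers()] to align new-environment genotypes.
#'
#' @param dosage Numeric dosage vector (or matrix, rows = lines).
#' @param model A [mil_model()].
#' @return A length-256 embedding vector (or matrix for matrix input).
#' @export
encode_genotype <- function(dosage, model) {
  arch <- model$arch$genotype
  if (is.null(arch)) stopf("model has no genotype encoder")
  X <- if (is.null(dim(dosage))) matrix(dosage, nrow = 1) else as.matrix(dosage)
  if (ncol(X) != length(model$marker_ids)) {
    stopf("genotype length %d does not match the trained marker set (%d); align with harmonize_markers()",
          ncol(X), length(model$marker_ids))
  }
  mlp <- mlp_set_params(arch$mlp, model$params$encoders$genotype)
  out <- mlp_forward(mlp, X)$out
  if (is.null(dim(dosage))) drop(out) else out
}

#' Append one-hot date and channel encodings to an embedding
#'
#' When temporal encoding is on, a one-hot block over the model's training
#' date vocabulary (plus a reserved "other" slot for unseen dates) is
#' appended; genotype instances get an all-zero date block. When channel
#' encoding is on, a one-hot over the four data sources is appended. With
#' both flags off this is the identity.
#'
#' @param h Embedding vector (length `embedding_dim`) or matrix (rows).
#' @param date Acquisition date, or `NULL` for genotype instances.
#' @param channel One of `"multispectral"`, `"thermal"`, `"dem"`,
#'   `"genotype"`.
#' @param model A [mil_model()].
#' @return The extended embedding (length `m_aug`).
#' @export
augment_embedding <- function(h, date = NULL, channel, model) {
  channel <- match.arg(channel, ALL_SOURCES)
  single <- is.null(dim(h))
  H <- if (single) matrix(h, nrow = 1) else h
  dates <- if (is.null(date)) NA_character_ else as.character(as.Date(date))
  dates <- rep_len(dates, nrow(H))
  out <- augment_rows(H, dates, channel, model)
  if (single) drop(out) else out
}

#' Subsample a bag of instances
#'
#' Returns all instances when there are at most `bag_size`; otherwise a
#' uniform sample without replacement of exactly `bag_size`. Training draws
#' a fresh subsample each iteration; inference uses all instances.
#'
#' @param instances A list of instances.
#' @param bag_size Maximum bag size (>= 1).
#' @return A list of instances.
#' @export
sample_bag <- function(instances, bag_size) {
  if (!is_count(bag_size) || bag_size < 1) stopf("bag_size must be >= 1")
  if (length(instances) <= bag_size) return(instances)
  instances[sample(length(instances), bag_size)]
}

#' Mean squared error loss
#'
#' `mean((predicted - observed)^2)`.
#'
#' @param predictions,observations Equal-length numeric vectors.
#' @return A scalar.
#' @export
mse_loss <- function(predictions, observations) {
  if (length(predictions) != length(observations) || length(predictions) < 1) {
    stopf("predictions (%d) and observations (%d) must be equal non-zero length",
          length(predictions), length(observations))
  }
  mean((predictions - observations)^2)
}

# Full forward pass over one sample. training = TRUE applies bag
# subsampling with the current RNG; inference uses every instance.
mil_forward <- function(model, sample, training = FALSE, genotype_only = FALSE) {
  cfg <- model$config
  emb_list <- list()
  prov_channel <- character(0)
  prov_date <- character(0)
  caches <- list()
  active_imgch <- if (genotype_only) character(0)
                  else intersect(cfg$channels, CHANNEL_TAGS)
  for (ch in active_imgch) {
    imgs <- sample$bags[[ch]]
    if (length(imgs) == 0) next
    if (training) imgs <- sample_bag(imgs, cfg$bag_size)
    eb <- encode_image_batch(imgs, model)
    dates <- vapply(imgs, function(x) as.character(x$date), "")
    emb_list[[length(emb_list) + 1]] <-
      augment_rows(eb$E, dates, ch, model)
    prov_channel <- c(prov_channel, rep(ch, length(imgs)))
    prov_date <- c(prov_date, dates)
    caches[[ch]] <- eb$cache
  }
  if ("genotype" %in% cfg$channels && !is.null(sample$genotype)) {
    mlp <- mlp_set_params(model$arch$genotype$mlp,
                          model$params$encoders$genotype)
    if (length(sample$genotype) != length(model$marker_ids)) {
      stopf("sample %s genotype length %d does not match trained marker set (%d); align with harmonize_markers()",
            sample$plot_id, length(sample$genotype), length(model$marker_ids))
    }
    fw <- mlp_forward(mlp, matrix(sample$genotype, nrow = 1))
    emb_list[[length(emb_list) + 1]] <-
      augment_rows(fw$out, NA_character_, "genotype", model)
    prov_channel <- c(prov_channel, "genotype")
    prov_date <- c(prov_date, NA_character_)
    caches$genotype <- fw$cache
  }
  if (length(emb_list) == 0) {
    stopf("sample %s has no instances in any active channel", sample$plot_id)
  }
  H <- do.call(rbind, emb_list)
  heads <- lapply(model$params$heads, function(p) {
    attention_pool(H, attention_params(p$V, p$w))
  })
  u <- unlist(lapply(heads, `[[`, "z"), use.names = FALSE)
  reg <- mlp_set_params(model$arch$regressor, model$params$regressor)
  rf <- mlp_forward(reg, matrix(u, nrow = 1))
  list(yhat = drop(rf$out),
       heads = heads,
       provenance = data.frame(channel = prov_channel, date = prov_date,
                               stringsAsFactors = FALSE),
       H = H, u = u,
       caches = caches, reg_cache = rf$cache)
}

augment_rows <- function(E, dates, channel, model) {
  cfg <- model$config
  if (cfg$temporal_encoding) {
    D <- length(model$date_vocab)
    block <- matrix(0, nrow(E), D + 1)
    if (!identical(channel, "genotype")) {
      slot <- match(dates, model$date_vocab)
      slot[is.na(slot)] <- D + 1L
      block[cbind(seq_len(nrow(E)), slot)] <- 1
    }
    E <- cbind(E, block)
  }
  if (cfg$channel_encoding) {
    block <- matrix(0, nrow(E), length(ALL_SOURCES))
    block[, match(channel, ALL_SOURCES)] <- 1
    E <- cbind(E, block)
  }
  E
}

# Backward pass for one sample; returns a gradient tree mirroring
# model$params.
mil_backward <- function(model, fw, dyhat) {
  cfg <- model$config
  m <- cfg$embedding_dim
  m_aug <- model$m_aug
  grads <- list(encoders = stats::setNames(
                  vector("list", length(model$params$encoders)),
                  names(model$params$encoders)),
                heads = vector("list", length(model$params$heads)),
                regressor = NULL)
  reg <- mlp_set_params(model$arch$regressor, model$params$regressor)
  rb <- mlp_backward(reg, fw$reg_cache, matrix(dyhat, 1, 1))
  grads$regressor <- rb$grads
  du <- drop(rb$dX)
  H <- fw$H
  k <- nrow(H)
  dH <- matrix(0, k, m_aug)
  for (hidx in seq_along(model$params$heads)) {
    p <- model$params$heads[[hidx]]
    res <- fw$heads[[hidx]]
    dz <- du[((hidx - 1) * m_aug + 1):(hidx * m_aug)]
    a <- res$weights
    Tm <- res$gate
    da <- drop(H %*% dz)
    dH <- dH + outer(a, dz)
    ds <- a * (da - sum(a * da))
    dpre <- outer(ds, p$w) * (1 - Tm^2)
    grads$heads[[hidx]] <- list(V = crossprod(dpre, H),
                                w = drop(crossprod(Tm, ds)))
    dH <- dH + dpre %*% p$V
  }
  dE <- dH[, seq_len(m), drop = FALSE]
  prov <- fw$provenance$channel
  for (ch in unique(prov)) {
    rows <- which(prov == ch)
    drows <- dE[rows, , drop = FALSE]
    if (ch == "genotype") {
      mlp <- mlp_set_params(model$arch$genotype$mlp,
                            model$params$encoders$genotype)
      gb <- mlp_backward(mlp, fw$caches$genotype, drows)
      grads$encoders$genotype <- gb$grads
    } else if (fw$caches[[ch]]$type == "tiny") {
      mlp <- mlp_set_params(model$arch[[ch]]$mlp, model$params$encoders[[ch]])
      gb <- mlp_backward(mlp, fw$caches[[ch]]$mlp_cache, drows)
      grads$encoders[[ch]] <- gb$grads
    } else {
      enc <- model$arch[[ch]]$enc
      enc$params <- model$params$encoders[[ch]]
      acc <- NULL
      for (i in seq_along(rows)) {
        gb <- conv_encoder_backward(enc, fw$caches[[ch]]$conv_caches[[i]],
                                    drows[i, ])
        acc <- if (is.null(acc)) gb else tree_add(acc, gb)
      }
      grads$encoders[[ch]] <- acc
    }
  }
  # untouched encoders (e.g. channels absent from this sample) contribute
  # zero gradient but must keep the tree shape for the optimizer
  for (ch in names(grads$encoders)) {
    if (is.null(grads$encoders[[ch]])) {
      grads$encoders[[ch]] <- tree_zeros(model$params$encoders[[ch]])
    }
  }
  grads
}

#' Predict plot yield
#'
#' Runs the full model on one sample using every available instance (no bag
#' subsampling), so the prediction is deterministic and permutation
#' invariant in the sample's instances. Channels absent from the sample
#' simply contribute no instances; a sample with no instances at all is an
#' error.
#'
#' @param sample A [plot_sample()].
#' @param model A [mil_model()].
#' @param genotype_only Ignore image bags and predict from the genotype
#'   instance alone.
#' @param return_attention Also return per-head attention weights with
#'   their channel/date provenance.
#' @return A scalar predicted yield (t/ha); with
#'   `return_attention = TRUE`, a list with `yhat`, `attention` (list of
#'   per-head weight vectors) and `provenance`.
#' @export
predict_yield <- function(sample, model, genotype_only = FALSE,
                          return_attention = FALSE) {
  fw <- mil_forward(model, sample, training = FALSE,
                    genotype_only = genotype_only)
  yhat <- fw$yhat * (model$y_scale %||% 1) + (model$y_center %||% 0)
  if (!return_attention) return(yhat)
  list(yhat = yhat,
       attention = lapply(fw$heads, `[[`, "weights"),
       provenance = fw$provenance)
}

#' Predict yields for many samples
#'
#' @param model A [mil_model()].
#' @param samples List of [plot_sample()] objects.
#' @param genotype_only Predict from genotypes alone.
#' @return Named numeric vector of predictions.
#' @export
predict_samples <- function(model, samples, genotype_only = FALSE) {
  out <- vapply(samples, predict_yield, 0, model = model,
                genotype_only = genotype_only)
  names(out) <- vapply(samples, `[[`, "", "plot_id")
  out
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single-file archive embedding the model configuration,
#' trained marker-id list and marker means, date vocabulary, and all
#' weights, version-stamped for compatibility checks.
#'
#' @param model A [mil_model()].
#' @param path Checkpoint file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mil_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mil_model") ||
      !identical(model$version, "yieldmil-checkpoint-1")) {
    stopf("%s is not a compatible model checkpoint", path)
  }
  model
}
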