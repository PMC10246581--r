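# im2col-based 2D convolutions and a compact residual CNN image encoder.
# Geometry index maps are cached per (input dims, kernel, stride, pad).

.conv_idx_cache <- new.env(parent = emptyenv())

conv_geom <- function(h, w, cin, kh, kw, stride, pad) {
  key <- paste(h, w, cin, kh, kw, stride, pad, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  ph <- h + 2 * pad
  pw <- w + 2 * pad
  oh <- (ph - kh) %/% stride + 1
  ow <- (pw - kw) %/% stride + 1
  out_i <- rep(seq_len(oh), times = ow)
  out_j <- rep(seq_len(ow), each = oh)
  n_cols <- kh * kw * cin
  idx <- matrix(0L, oh * ow, n_cols)
  col <- 0
  for (c in seq_len(cin)) {
    for (kj in seq_len(kw)) {
      for (ki in seq_len(kh)) {
        col <- col + 1
        r <- (out_i - 1) * stride + ki
        cl <- (out_j - 1) * stride + kj
        idx[, col] <- r + (cl - 1) * ph + (c - 1) * ph * pw
      }
    }
  }
  geom <- list(idx = idx, oh = oh, ow = ow, ph = ph, pw = pw,
               h = h, w = w, cin = cin, kh = kh, kw = kw,
               stride = stride, pad = pad)
  .conv_idx_cache[[key]] <- geom
  geom
}

conv_layer_init <- function(cin, cout, k = 3) {
  list(K = init_weight(k * k * cin, cout, "relu"), b = rep(0, cout))
}

# x: array(h, w, cin). Returns y: array(oh, ow, cout) plus cache.
conv_forward <- function(x, layer, stride = 1, pad = 1) {
  d <- dim(x)
  k <- as.integer(sqrt(nrow(layer$K) / d[3]))
  g <- conv_geom(d[1], d[2], d[3], k, k, stride, pad)
  if (pad > 0) {
    xp <- array(0, c(g$ph, g$pw, d[3]))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  } else {
    xp <- x
  }
  P <- matrix(xp[as.vector(g$idx)], nrow(g$idx), ncol(g$idx))
  Y <- sweep(P %*% layer$K, 2, layer$b, `+`)
  list(y = array(Y, c(g$oh, g$ow, ncol(layer$K))),
       cache = list(P = P, g = g))
}

conv_backward <- function(dy, layer, cache) {
  g <- cache$g
  f <- ncol(layer$K)
  dYm <- matrix(dy, g$oh * g$ow, f)
  dK <- crossprod(cache$P, dYm)
  db <- colSums(dYm)
  dP <- tcrossprod(dYm, layer$K)
  dxp <- numeric(g$ph * g$pw * g$cin)
  for (j in seq_len(ncol(g$idx))) {
    ii <- g$idx[, j]
    dxp[ii] <- dxp[ii] + dP[, j]
  }
  dxp <- array(dxp, c(g$ph, g$pw, g$cin))
  dx <- if (g$pad > 0) {
    dxp[g$pad + seq_len(g$h), g$pad + seq_len(g$w), , drop = FALSE]
  } else {
    dxp
  }
  list(grads = list(K = dK, b = db), dx = dx)
}

# Residual CNN encoder: optional 1x1 learned channel adapter (single-band
# inputs -> 3 channels), a stride-2 stem convolution, stages of residual
# blocks (3x3 conv pairs; the first block of each later stage downsamples
# with stride 2 and a 1x1 projection skip), global average pooling, and a
# dense map to the embedding dimension. blocks = c(2,2,2,2) with
# base_width = 64 reproduces the classic 18-layer residual layout (without
# batch normalization); the package default is a compact variant.
conv_encoder_init <- function(in_bands, embed_dim, base_width = 16,
                              blocks = c(2, 2)) {
  use_adapter <- in_bands == 1
  stem_in <- if (use_adapter) 3L else in_bands
  widths <- base_width * 2^(seq_along(blocks) - 1)
  params <- list(stem = conv_layer_init(stem_in, widths[1]))
  if (use_adapter) params$adapter <- conv_layer_init(in_bands, 3L, k = 1)
  stages <- vector("list", length(blocks))
  cin <- widths[1]
  for (s in seq_along(blocks)) {
    stage <- vector("list", blocks[s])
    for (b in seq_len(blocks[s])) {
      downsample <- s > 1 && b == 1
      blk <- list(conv1 = conv_layer_init(cin, widths[s]),
                  conv2 = conv_layer_init(widths[s], widths[s]))
      if (downsample || cin != widths[s]) {
        blk$proj <- conv_layer_init(cin, widths[s], k = 1)
      }
      stage[[b]] <- blk
      cin <- widths[s]
    }
    stages[[s]] <- stage
  }
  params$stages <- stages
  params$head <- list(W = init_weight(cin, embed_dim, "linear"),
                      b = rep(0, embed_dim))
  list(params = params, blocks = blocks, widths = widths,
       use_adapter = use_adapter, embed_dim = embed_dim)
}

res_block_forward <- function(x, blk, stride) {
  c1 <- conv_forward(x, blk$conv1, stride = stride, pad = 1)
  r1 <- pmax(c1$y, 0)
  c2 <- conv_forward(r1, blk$conv2, stride = 1, pad = 1)
  if (!is.null(blk$proj)) {
    pr <- conv_forward(x, blk$proj, stride = stride, pad = 0)
    skip <- pr$y
  } else {
    pr <- NULL
    skip <- x
  }
  out <- pmax(skip + c2$y, 0)
  list(y = out, cache = list(c1 = c1, c2 = c2, pr = pr, r1 = r1, out = out))
}

res_block_backward <- function(dy, blk, cache) {
  d <- dy * (cache$out > 0)
  b2 <- conv_backward(d, blk$conv2, cache$c2$cache)
  dr1 <- b2$dx * (cache$r1 > 0)
  b1 <- conv_backward(dr1, blk$conv1, cache$c1$cache)
  grads <- list(conv1 = b1$grads, conv2 = b2$grads)
  if (!is.null(blk$proj)) {
    bp <- conv_backward(d, blk$proj, cache$pr$cache)
    grads$proj <- bp$grads
    dx <- b1$dx + bp$dx
  } else {
    dx <- b1$dx + d
  }
  list(grads = grads, dx = dx)
}

conv_encoder_forward <- function(enc, x) {
  p <- enc$params
  cache <- list()
  if (enc$use_adapter) {
    ad <- conv_forward(x, p$adapter, stride = 1, pad = 0)
    cache$adapter <- ad
    x <- ad$y
  }
  st <- conv_forward(x, p$stem, stride = 2, pad = 1)
  cache$stem <- st
  a <- pmax(st$y, 0)
  cache$stem_relu <- a
  cache$stages <- vector("list", length(p$stages))
  for (s in seq_along(p$stages)) {
    cache$stages[[s]] <- vector("list", length(p$stages[[s]]))
    for (b in seq_along(p$stages[[s]])) {
      stride <- if (s > 1 && b == 1) 2 else 1
      bf <- res_block_forward(a, p$stages[[s]][[b]], stride)
      cache$stages[[s]][[b]] <- bf$cache
      a <- bf$y
    }
  }
  dpool <- dim(a)
  v <- apply(a, 3, mean)
  cache$pool_dim <- dpool
  e <- drop(v %*% p$head$W) + p$head$b
  cache$pooled <- v
  list(embedding = e, cache = cache)
}

conv_encoder_backward <- function(enc, cache, de) {
  p <- enc$params
  grads <- list(head = list(W = outer(cache$pooled, de),
                            b = de))
  dv <- drop(p$head$W %*% de)
  dpool <- cache$pool_dim
  npx <- dpool[1] * dpool[2]
  da <- array(rep(dv / npx, each = npx), dpool)
  grads$stages <- vector("list", length(p$stages))
  for (s in rev(seq_along(p$stages))) {
    grads$stages[[s]] <- vector("list", length(p$stages[[s]]))
    for (b in rev(seq_along(p$stages[[s]]))) {
      bb <- res_block_backward(da, p$stages[[s]][[b]], cache$stages[[s]][[b]])
      grads$stages[[s]][[b]] <- bb$grads
      da <- bb$dx
    }
  }
  dst <- da * (cache$stem_relu > 0)
  bs <- conv_backward(dst, p$stem, cache$stem$cache)
  grads$stem <- bs$grads
  if (enc$use_adapter) {
    ba <- conv_backward(bs$dx, p$adapter, cache$adapter$cache)
    grads$adapter <- ba$grads
  }
  # reorder to match the parameter tree layout
  grads[names(p)]
}
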