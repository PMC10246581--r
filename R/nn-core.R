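# Minimal neural-network primitives with manual backpropagation.
# Parameters live in nested named lists of numeric arrays ("parameter
# trees"); gradients mirror the same structure, so the optimizer and the
# freezing logic can walk both generically.

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else {
    f(x, y)
  }
}

tree_zeros <- function(x) tree_map(function(a) a * 0, x)

tree_add <- function(x, y) tree_map2(`+`, x, y)

tree_scale <- function(x, k) tree_map(function(a) a * k, x)

tree_max_abs <- function(x) {
  if (is.list(x)) max(0, vapply(x, tree_max_abs, 0)) else max(0, abs(x))
}

# He-scaled Gaussian init for rectifier layers, Xavier for tanh/linear.
init_weight <- function(n_in, n_out, act = "relu") {
  sd <- if (act == "relu") sqrt(2 / n_in) else sqrt(1 / n_in)
  matrix(stats::rnorm(n_in * n_out, 0, sd), n_in, n_out)
}

act_forward <- function(x, act) {
  switch(act,
         relu = pmax(x, 0),
         tanh = tanh(x),
         linear = x,
         stopf("unknown activation %s", act))
}

act_backward <- function(dy, x, y, act) {
  switch(act,
         relu = dy * (x > 0),
         tanh = dy * (1 - y^2),
         linear = dy,
         stopf("unknown activation %s", act))
}

# A multilayer perceptron: sizes = c(d_in, hidden..., d_out); the output
# layer uses out_act (default linear), all hidden layers use act.
mlp_init <- function(sizes, act = "relu", out_act = "linear") {
  n_layers <- length(sizes) - 1
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    layer_act <- if (i < n_layers) act else out_act
    W[[i]] <- init_weight(sizes[i], sizes[i + 1], layer_act)
    b[[i]] <- rep(0, sizes[i + 1])
  }
  list(W = W, b = b, act = act, out_act = out_act, sizes = sizes)
}

# X: n x d_in (rows are samples). Returns output and the per-layer caches
# needed for the backward pass.
mlp_forward <- function(mlp, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  n_layers <- length(mlp$W)
  pre <- vector("list", n_layers)
  post <- vector("list", n_layers + 1)
  post[[1]] <- X
  for (i in seq_len(n_layers)) {
    z <- post[[i]] %*% mlp$W[[i]]
    z <- sweep(z, 2, mlp$b[[i]], `+`)
    a <- act_forward(z, if (i < n_layers) mlp$act else mlp$out_act)
    pre[[i]] <- z
    post[[i + 1]] <- a
  }
  list(out = post[[n_layers + 1]], cache = list(pre = pre, post = post))
}

# dOut: gradient at the output (n x d_out). Returns parameter gradients in
# the same shape as the mlp and the gradient at the input.
mlp_backward <- function(mlp, cache, dOut) {
  n_layers <- length(mlp$W)
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  grad <- dOut
  for (i in rev(seq_len(n_layers))) {
    act <- if (i < n_layers) mlp$act else mlp$out_act
    dz <- act_backward(grad, cache$pre[[i]], cache$post[[i + 1]], act)
    dW[[i]] <- crossprod(cache$post[[i]], dz)
    db[[i]] <- colSums(dz)
    grad <- dz %*% t(mlp$W[[i]])
  }
  list(grads = list(W = dW, b = db), dX = grad)
}

mlp_params <- function(mlp) list(W = mlp$W, b = mlp$b)

mlp_set_params <- function(mlp, params) {
  mlp$W <- params$W
  mlp$b <- params$b
  mlp
}

# Adam with decoupled weight decay; state mirrors the parameter tree.
adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  if (weight_decay > 0) {
    params <- tree_map(function(p) p * (1 - lr * weight_decay), params)
  }
  list(params = params, state = state)
}

# Numerically stable softmax of a vector of logits.
softmax_stable <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}
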