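# Minimal dense multilayer perceptron with manual backpropagation.
# Used for the navigator VAE encoder/decoder; kept generic (layer sizes,
# ReLU hidden activations, linear output).

mlp_init <- function(sizes, seed = 1L) {
  set.seed(seed)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    n_in <- sizes[l]; n_out <- sizes[l + 1L]
    # He initialization for ReLU hidden layers
    layers[[l]] <- list(
      W = matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
      b = numeric(n_out))
  }
  structure(list(layers = layers, sizes = sizes), class = "mlp")
}

# X: n x n_in. Returns output n x n_out and per-layer activations for backprop.
mlp_forward <- function(net, X) {
  acts <- vector("list", length(net$layers) + 1L)
  acts[[1]] <- X
  L <- length(net$layers)
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% net$layers[[l]]$W
    Z <- sweep(Z, 2, net$layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z   # ReLU hidden, linear out
  }
  list(out = acts[[L + 1L]], acts = acts)
}

# gout: gradient at the output (n x n_out). Returns parameter gradients and
# the gradient at the input.
mlp_backward <- function(net, cache, gout) {
  L <- length(net$layers)
  grads <- vector("list", L)
  g <- gout
  for (l in rev(seq_len(L))) {
    a_in <- cache$acts[[l]]
    if (l < L) {
      # ReLU derivative via the stored post-activation
      g <- g * (cache$acts[[l + 1L]] > 0)
    }
    grads[[l]] <- list(W = crossprod(a_in, g), b = colSums(g))
    g <- g %*% t(net$layers[[l]]$W)
  }
  list(grads = grads, gin = g)
}

# Adam state / update over a flat list of parameter matrices.
adam_init <- function(net) {
  lapply(net$layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (l in seq_along(net$layers)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[l]]$W <- net$layers[[l]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}
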