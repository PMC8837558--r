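# Small feed-forward network toolkit used by both the surrogate and the
# adversarial generator/discriminators. Dense layers with tanh hidden
# activations and a linear output (discriminators return logits; squashing of
# generator outputs to the prior box is applied outside, with its own
# gradient). Backpropagation returns weight gradients and, when requested,
# the gradient with respect to the inputs, which is what lets the adversarial
# losses flow through the frozen surrogate. Optimization is Adam.
#
# Everything is plain base-R matrix algebra: the networks involved are small
# (a few dense layers of width 64-128), so BLAS-backed matmuls are entirely
# adequate and keep the package dependency-free on this front.

mlp_init <- function(sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    sd <- sqrt(2 / (fan_in + fan_out))  # Glorot
    W[[l]] <- matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out)
    b[[l]] <- rep(0, fan_out)
  }
  structure(list(W = W, b = b, sizes = sizes), class = "mlp")
}

# Forward pass; X is n x d. Returns the output (n x k) and a cache of hidden
# activations for backprop.
mlp_forward <- function(net, X) {
  L <- length(net$W)
  H <- vector("list", L + 1L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- H[[l]] %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))
    H[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  list(out = H[[L + 1L]], H = H)
}

# Backward pass given upstream gradient dOut (n x k) on the (linear) output.
# Returns per-layer weight/bias gradients (averaged over the batch is the
# caller's choice: dOut should already carry any 1/n factor) and the gradient
# with respect to the inputs.
mlp_backward <- function(net, fwd, dOut) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$H[[l]], delta)
    gb[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
    if (l > 1L) delta <- delta * (1 - fwd$H[[l]]^2)  # tanh'
  }
  list(gW = gW, gb = gb, dX = delta)
}

mlp_predict <- function(net, X) mlp_forward(net, X)$out

# Gradient of sum(dOut * f(X)) with respect to X.
mlp_input_gradient <- function(net, X, dOut) {
  mlp_backward(net, mlp_forward(net, X), dOut)$dX
}

adam_init <- function(net) {
  z <- function(x) {
    x[] <- 0
    x
  }
  list(mW = lapply(net$W, z), vW = lapply(net$W, z),
       mb = lapply(net$b, z), vb = lapply(net$b, z), t = 0L)
}

adam_step <- function(net, opt, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (opt$mW[[l]] / bc1) / (sqrt(opt$vW[[l]] / bc2) + eps)
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (opt$mb[[l]] / bc1) / (sqrt(opt$vb[[l]] / bc2) + eps)
  }
  list(net = net, opt = opt)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable softplus log(1 + exp(z)).
softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# Binary cross-entropy on logits: mean over the batch. Gradient w.r.t. the
# logits is sigmoid(z) - y.
bce_logits <- function(z, y) mean(softplus(z) - y * z)
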