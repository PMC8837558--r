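# The network toolkit underpins both the surrogate and the adversarial
# fit; backpropagated gradients are checked against finite differences.

test_that("backpropagated weight and input gradients match finite differences", {
  set.seed(1)
  net <- sarcopop:::mlp_init(c(3, 8, 5, 2), seed = 1)
  X <- matrix(rnorm(12), 4, 3)
  Tgt <- matrix(rnorm(8), 4, 2)
  loss <- function(n, x) mean((sarcopop:::mlp_predict(n, x) - Tgt)^2)
  fwd <- sarcopop:::mlp_forward(net, X)
  gr <- sarcopop:::mlp_backward(net, fwd, 2 * (fwd$out - Tgt) / length(Tgt))
  h <- 1e-6
  # a few weight entries in each layer
  for (l in 1:3) {
    for (idx in list(c(1, 1), c(2, 2))) {
      np <- net
      np$W[[l]][idx[1], idx[2]] <- np$W[[l]][idx[1], idx[2]] + h
      num <- (loss(np, X) - loss(net, X)) / h
      expect_equal(gr$gW[[l]][idx[1], idx[2]], num, tolerance = 1e-4)
    }
  }
  # input gradient
  for (idx in list(c(1, 1), c(3, 2))) {
    Xp <- X
    Xp[idx[1], idx[2]] <- Xp[idx[1], idx[2]] + h
    num <- (loss(net, Xp) - loss(net, X)) / h
    expect_equal(gr$dX[idx[1], idx[2]], num, tolerance = 1e-4)
  }
})

test_that("adam drives a small regression problem to low loss", {
  set.seed(2)
  X <- matrix(runif(600, -1, 1), 200, 3)
  Y <- matrix(sin(2 * X[, 1]) + X[, 2] * X[, 3], ncol = 1)
  net <- sarcopop:::mlp_init(c(3, 32, 1), seed = 2)
  opt <- sarcopop:::adam_init(net)
  for (i in 1:800) {
    fwd <- sarcopop:::mlp_forward(net, X)
    gr <- sarcopop:::mlp_backward(net, fwd, 2 * (fwd$out - Y) / length(Y))
    st <- sarcopop:::adam_step(net, opt, gr, lr = 5e-3)
    net <- st$net; opt <- st$opt
  }
  expect_lt(mean((sarcopop:::mlp_predict(net, X) - Y)^2), 5e-3)
})

test_that("binary cross-entropy on logits is chance-level log(2) at zero", {
  z <- rep(0, 10)
  y <- rep(c(0, 1), 5)
  expect_equal(sarcopop:::bce_logits(z, y), log(2))
  expect_equal(sarcopop:::softplus(-745), 0, tolerance = 1e-12)
  expect_true(is.finite(sarcopop:::softplus(1e4)))
})
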