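# Tests of the factorized adversarial fit. The fully trained model is built
# once in the helper and shared across tests; structural properties that do
# not need training quality are checked on it as well.

test_that("generated groups share the drug-insensitive block exactly", {
  vp <- test_vpop()
  pops <- simulate(vp, nsim = 500, seed = 7)
  shared <- param_names()[shared_param_idx()]
  for (nm in shared)
    expect_identical(pops$control[[nm]], pops$drug[[nm]])
  # drug-target block differs
  expect_false(isTRUE(all.equal(pops$control$n_A, pops$drug$n_A)))
})

test_that("generated parameters never leave the prior box", {
  vp <- test_vpop()
  pops <- simulate(vp, nsim = 1000, seed = 8)
  box <- prior_box()
  for (grp in c("control", "drug")) {
    X <- as.matrix(pops[[grp]][param_names()])
    expect_true(all(sweep(X, 2, box$low, ">=")))
    expect_true(all(sweep(X, 2, box$high, "<=")))
  }
})

test_that("generation is reproducible from the seed", {
  vp <- test_vpop()
  a <- simulate(vp, nsim = 50, seed = 11)
  b <- simulate(vp, nsim = 50, seed = 11)
  expect_identical(a$control, b$control)
  expect_identical(a$drug, b$drug)
})

test_that("adversarial losses are finite and structured as configured", {
  vp <- test_vpop()
  l <- gan_losses(vp, n = 256, seed = 1)
  expect_true(all(is.finite(l)))
  # with lambda_p = 0 the generator objective reduces to the output terms
  l0 <- gan_losses(vp, n = 256, lambda_p = 0, seed = 1)
  expect_equal(l0[["gen_total"]], l0[["gen_output"]])
  # a converged discriminator on near-identical distributions sits near
  # chance level log(2); allow a generous band
  expect_lt(abs(l[["d3"]] - log(2)), 0.35)
  expect_lt(abs(l[["d4"]] - log(2)), 0.35)
})

test_that("identical real and fake batches pin a discriminator at chance", {
  # train a fresh discriminator where real and fake are the same sample:
  # the optimal classifier cannot beat 0.5 accuracy / log(2) loss
  set.seed(42)
  X <- matrix(rnorm(256 * 3), 256, 3)
  net <- sarcopop:::mlp_init(c(3, 32, 1), seed = 1)
  opt <- sarcopop:::adam_init(net)
  for (i in 1:200) {
    st <- sarcopop:::disc_step(net, opt, X, X, lr = 2e-3)
    net <- st$net; opt <- st$opt
  }
  expect_equal(st$loss, log(2), tolerance = 0.02)
  z <- drop(sarcopop:::mlp_predict(net, X))
  acc <- (mean(z > 0) + mean(z <= 0)) / 2  # real copy + fake copy of X
  expect_equal(acc, 0.5, tolerance = 1e-12)
})

test_that("generator gradients flow through the surrogate and are finite", {
  sur <- test_surrogate()
  x <- sample_prior(prior_box(), 8, seed = 3)
  dY <- matrix(rnorm(24), 8, 3)
  g <- sarcopop:::surrogate_input_gradient(sur, x, dY)
  expect_true(all(is.finite(g)))
  expect_equal(dim(g), dim(x))
})

test_that("symmetric targets drive G2 and G3 to matching output distributions", {
  gt <- test_ground_truth()
  sur <- test_surrogate()
  # same target density for both groups: the two drug-target generators
  # should converge to statistically indistinguishable (n_A, A_50)
  vp <- suppressWarnings(fit_vpop(
    gt$density_c, gt$density_c, sur, prior = prior_box(),
    slack = test_slack(),
    config = gan_config(iters = 1000, d_hidden = c(64, 64), seed = 99)))
  pops <- simulate(vp, nsim = 2000, seed = 5)
  for (nm in c("n_A", "A_50")) {
    ks <- suppressWarnings(
      stats::ks.test(pops$control[[nm]], pops$drug[[nm]]))$statistic
    expect_lt(unname(ks), 0.15)
  }
})

test_that("population report flags the n_A-A_50 coupling and is symmetric", {
  vp <- test_vpop()
  pops <- simulate(vp, nsim = 1500, seed = 21)
  rep <- population_report(pops, list(c = vp$target_c, d = vp$target_d),
                           vp$surrogate)
  for (grp in c("control", "drug")) {
    C <- rep[[grp]]$cor
    expect_equal(C, t(C), tolerance = 1e-12)
    expect_equal(unname(diag(C)), rep(1, 6), tolerance = 1e-12)
  }
  # independent parameters show no spurious coupling
  Xi <- as.data.frame(sample_prior(prior_box(), 3000, seed = 4))
  rep_i <- population_report(list(control = Xi, drug = Xi),
                             list(c = vp$target_c, d = vp$target_d),
                             vp$surrogate)
  off <- rep_i$control$cor[upper.tri(rep_i$control$cor)]
  expect_true(all(abs(off) < 4 / sqrt(3000) * 2))
})
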