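test_that("a perfectly informative parameter gets the full R2 drop", {
  set.seed(1)
  X <- matrix(runif(1000 * 3), 1000, 3,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- X[, 1]
  fit <- mda(X, y, regressor = "linear", n_repeats = 10, seed = 2)
  expect_gt(fit$r2_base, 0.999)
  expect_equal(fit$scores[["x1"]], fit$r2_base, tolerance = 0.05)
  expect_lt(abs(fit$scores[["x2"]]), 3 * max(fit$spread[["x2"]], 1e-3))
  expect_lt(abs(fit$scores[["x3"]]), 3 * max(fit$spread[["x3"]], 1e-3))
})

test_that("pure-noise parameters score near zero under a forest regressor", {
  set.seed(3)
  X <- matrix(runif(600 * 4), 600, 4,
              dimnames = list(NULL, c("a", "b", "noise1", "noise2")))
  y <- 2 * X[, "a"] + X[, "b"]^2 + rnorm(600, 0, 0.05)
  fit <- mda(X, y, regressor = "rf", n_repeats = 10, seed = 4, ntree = 300)
  expect_gt(fit$scores[["a"]], 0.2)
  for (nm in c("noise1", "noise2"))
    expect_lt(abs(fit$scores[[nm]]), 3 * max(fit$spread[[nm]], 0.01))
})

test_that("duplicated informative columns mask each other", {
  set.seed(5)
  x1 <- runif(800)
  X <- cbind(x1 = x1, x2 = x1, z = runif(800))
  y <- x1
  dup <- mda(X, y, regressor = "rf", n_repeats = 5, seed = 6, ntree = 300)
  alone <- mda(cbind(x1 = x1, z = X[, "z"]), y, regressor = "rf",
               n_repeats = 5, seed = 6, ntree = 300)
  expect_lt(dup$scores[["x1"]], alone$scores[["x1"]])
  expect_lt(dup$scores[["x2"]], alone$scores[["x1"]])
})

test_that("scores are invariant to column order and reproducible by seed", {
  set.seed(7)
  X <- matrix(runif(300 * 3), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(300, 0, 0.02)
  f1 <- mda(X, y, regressor = "linear", seed = 8)
  f2 <- mda(X[, c(3, 1, 2)], y, regressor = "linear", seed = 8)
  expect_equal(f1$scores[["a"]], f2$scores[["a"]], tolerance = 0.02)
  f3 <- mda(X, y, regressor = "linear", seed = 8)
  expect_identical(f1$scores, f3$scores)
  expect_error(mda(X, rep(1, 300)), "constant")
  expect_error(mda(X[1:20, ], y[1:20]), "at least 50")
})
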