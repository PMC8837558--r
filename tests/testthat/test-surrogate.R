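test_that("prior sampling is uniform inside the box and reproducible", {
  box <- prior_box()
  X <- sample_prior(box, 2000, seed = 1)
  expect_true(all(sweep(X, 2, box$low, ">=")))
  expect_true(all(sweep(X, 2, box$high, "<=")))
  expect_identical(X, sample_prior(box, 2000, seed = 1))
  big <- sample_prior(box, 1e5, seed = 2)
  mid <- (box$low + box$high) / 2
  se <- (box$high - box$low) / sqrt(12) / sqrt(1e5)
  expect_true(all(abs(colMeans(big) - mid) < 3 * se))
})

test_that("training-set rows match direct simulation", {
  ts <- build_training_set(prior_box(), 60, seed = 5)
  expect_lt(ts$dropped, 12)
  cst <- model_constants()
  set.seed(99)
  for (i in sample.int(nrow(ts$X), 5)) {
    tr <- simulate_unloaded(sarcopop:::row_params(ts$X[i, ]), cst,
                            seq(0, 800, by = 2))
    expect_equal(unname(coef(fit_features(tr))), unname(ts$Y[i, ]),
                 tolerance = 1e-10)
  }
  # deterministic: same seed, same set
  ts2 <- build_training_set(prior_box(), 60, seed = 5)
  expect_identical(ts$Y, ts2$Y)
})

test_that("surrogate reaches high held-out accuracy and matches the simulator", {
  sur <- test_surrogate()
  expect_true(all(sur$r2 >= 0.98))
  # fresh prior sample: error well below the prior-induced spread
  ts <- build_training_set(prior_box(), 150, seed = 777)
  pred <- predict(sur, ts$X)
  rel <- sqrt(colMeans((pred - ts$Y)^2)) / apply(ts$Y, 2, stats::sd)
  expect_true(all(rel < 0.10))
})

test_that("surrogate prediction is deterministic, vectorized and differentiable", {
  sur <- test_surrogate()
  x <- sample_prior(prior_box(), 5, seed = 3)
  expect_identical(predict(sur, x), predict(sur, x))
  one <- do.call(rbind, lapply(seq_len(5), function(i) predict(sur, x[i, ])))
  expect_equal(unname(one), unname(predict(sur, x)), tolerance = 1e-12)
  # input gradient vs finite differences
  dY <- matrix(c(1, 0, 0), 1)
  g <- sarcopop:::surrogate_input_gradient(sur, x[1, , drop = FALSE], dY)
  expect_true(all(is.finite(g)))
  h <- 1e-4
  for (j in 1:6) {
    xp <- x[1, , drop = FALSE]; xp[j] <- xp[j] + h
    xm <- x[1, , drop = FALSE]; xm[j] <- xm[j] - h
    num <- (predict(sur, xp)[1] - predict(sur, xm)[1]) / (2 * h)
    expect_equal(unname(g[1, j]), num, tolerance = 1e-2 * max(1, abs(num)))
  }
})
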